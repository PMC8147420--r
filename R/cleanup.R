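# ---- edge/branch utilities ----

delete_edge <- function(g, e) {
  u <- g$edge_from[e]; v <- g$edge_to[e]
  g$out_edges[[u]] <- setdiff(g$out_edges[[u]], e)
  g$in_edges[[v]] <- setdiff(g$in_edges[[v]], e)
  g$edge_alive[e] <- FALSE
  g
}

# follow the unary path that starts with edge `e`, for at most `max_edges`
# edges. Returns the edges traversed, the node where the walk stopped and
# why: "dead_end" (terminal node), "converge" (in-degree > 1), "branch"
# (out-degree > 1), "cycle" (node revisited), "maxed" (length cap hit
# while the path could continue).
walk_branch <- function(g, e, max_edges) {
  edges <- integer(0)
  seen <- g$edge_from[e]
  cur_e <- e
  repeat {
    edges <- c(edges, cur_e)
    nxt <- g$edge_to[cur_e]
    if (nxt %in% seen)
      return(list(edges = edges, end = nxt, status = "cycle"))
    seen <- c(seen, nxt)
    if (in_degree(g, nxt) > 1)
      return(list(edges = edges, end = nxt, status = "converge"))
    if (out_degree(g, nxt) == 0)
      return(list(edges = edges, end = nxt, status = "dead_end"))
    if (out_degree(g, nxt) > 1)
      return(list(edges = edges, end = nxt, status = "branch"))
    if (length(edges) >= max_edges)
      return(list(edges = edges, end = nxt, status = "maxed"))
    cur_e <- g$out_edges[[nxt]][1]
  }
}

#' Remove tips
#'
#' A tip is a short unary dead-end branch created when errors make an
#' otherwise unary path fork. At every node with out-degree greater than
#' one, any branch that is a unary path of at most `max_tip_len` edges
#' ending in a terminal node is deleted (all of its edges, starting at the
#' branching node) provided another branch longer than the threshold
#' exists.
#'
#' @param g a glued `bilabel_graph`.
#' @param max_tip_len maximum tip length in edges; defaults to
#'   `g$params$max_tip_len`.
#' @return The cleaned `bilabel_graph`.
#' @export
remove_tips <- function(g, max_tip_len = g$params$max_tip_len) {
  for (v in live_nodes(g)) {
    if (out_degree(g, v) <= 1) next
    walks <- lapply(g$out_edges[[v]], walk_branch, g = g,
                    max_edges = max_tip_len + 1L)
    is_tip <- vapply(walks, function(w)
      w$status == "dead_end" && length(w$edges) <= max_tip_len, TRUE)
    if (!any(is_tip) || all(is_tip)) next
    for (w in walks[is_tip])
      for (e in w$edges) g <- delete_edge(g, e)
  }
  g
}

#' Pop bubbles
#'
#' A bubble is a pair of short unary paths that leave the same branching
#' node and reconverge at the same node (unmerged bi-labels from one
#' genomic locus). For each bubble whose paths are at most
#' `max_bubble_len` edges long (twice the 2k-fragment size of a bi-label by
#' default), the path with the lower total support is disconnected by
#' deleting only its first edge -- the remainder of the path survives as a
#' separate component.
#'
#' @param g a `bilabel_graph`, tips already removed.
#' @param max_bubble_len maximum bubble path length in edges; defaults to
#'   `g$params$max_bubble_len`.
#' @return The cleaned `bilabel_graph`.
#' @export
pop_bubbles <- function(g, max_bubble_len = g$params$max_bubble_len) {
  for (v in live_nodes(g)) {
    if (out_degree(g, v) <= 1) next
    walks <- lapply(g$out_edges[[v]], walk_branch, g = g,
                    max_edges = max_bubble_len + 1L)
    ok <- vapply(walks, function(w)
      w$status == "converge" && length(w$edges) <= max_bubble_len, TRUE)
    walks <- walks[ok]
    if (length(walks) < 2) next
    ends <- vapply(walks, `[[`, 1L, "end")
    for (end in unique(ends[duplicated(ends)])) {
      grp <- walks[ends == end]
      supp <- vapply(grp, function(w) sum(g$edge_support[w$edges]), 0)
      first_edge <- vapply(grp, function(w) w$edges[1], 1L)
      keep <- order(-supp, first_edge)[1]
      for (j in seq_along(grp))
        if (j != keep && g$edge_alive[first_edge[j]])
          g <- delete_edge(g, first_edge[j])
    }
  }
  g
}

#' Extract unitigs
#'
#' Depth-first traversal from every node with zero incoming edges. A path
#' is extended while the next node is unary (in-degree and out-degree
#' exactly one) and terminates at a branching node, a convergence node, a
#' terminal node or when a node repeats (cycle). Nodes where a path stops
#' are expanded in turn, so every live edge reachable from a
#' zero-in-degree node appears in exactly one reported path. Edges in
#' purely cyclic components are unreachable; their count is attached as
#' attribute `n_cyclic_edges`.
#'
#' @param g a cleaned `bilabel_graph`.
#' @return List of paths, each a list with `nodes` and `edges` (ids into
#'   the graph arrays).
#' @export
extract_unitigs <- function(g) {
  nn <- length(g$nodes)
  used <- !g$edge_alive
  enqueued <- rep(FALSE, nn)
  starts <- Filter(function(v) in_degree(g, v) == 0 && out_degree(g, v) > 0,
                   live_nodes(g))
  stack <- as.list(starts)
  enqueued[unlist(starts)] <- TRUE
  paths <- list()
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (e in g$out_edges[[v]]) {
      if (used[e]) next
      path_nodes <- v
      path_edges <- integer(0)
      cur_e <- e
      repeat {
        used[cur_e] <- TRUE
        path_edges <- c(path_edges, cur_e)
        nxt <- g$edge_to[cur_e]
        revisit <- nxt %in% path_nodes
        path_nodes <- c(path_nodes, nxt)
        if (revisit || in_degree(g, nxt) != 1 || out_degree(g, nxt) != 1) {
          if (!revisit && !enqueued[nxt] && out_degree(g, nxt) > 0) {
            stack[[length(stack) + 1]] <- nxt
            enqueued[nxt] <- TRUE
          }
          break
        }
        ne <- g$out_edges[[nxt]][1]
        if (used[ne]) break
        cur_e <- ne
      }
      paths[[length(paths) + 1]] <- list(nodes = path_nodes,
                                         edges = path_edges)
    }
  }
  attr(paths, "n_cyclic_edges") <- sum(!used & g$edge_alive)
  paths
}

# consensus fragment vector of one edge: coordinate-wise mean over the
# bi-labels the edge represents (all members for the k-mers; for the skip
# segment only members with the representative's fragment count, since
# other members' skip fragments do not align coordinate-wise), rounded to
# integer bp
edge_consensus <- function(g, e) {
  b <- g$edge_bilabel[[e]]
  set <- g$member_set
  m <- g$member_idx[[e]]
  if (is.null(set) || is.null(m) || length(m) <= 1)
    return(c(b$kmer1, b$skip, b$kmer2))
  k <- set$k
  km <- set$kmers[m, , drop = FALSE]
  kmer1 <- colMeans(km[, 1:k, drop = FALSE])
  kmer2 <- colMeans(km[, (k + 1):(2 * k), drop = FALSE])
  same_shape <- m[vapply(set$skips[m], length, 1L) == length(b$skip)]
  skip <- colMeans(do.call(rbind, set$skips[same_shape]))
  round_half_up(c(kmer1, skip, kmer2))
}

#' Spell a unitig path into a contig
#'
#' Consecutive edges of a unary path overlap in all but their first
#' fragment, so the contig is: the first fragment of every edge but the
#' last, followed by all fragments (first k-mer, skip segment, second
#' k-mer) of the last edge. Each emitted fragment is the consensus
#' (member-mean, see the package vignette) of the corresponding fragments
#' of the bi-labels represented by the edge. A junction whose suffix/prefix
#' bi-labels are not proximal raises an assembly-integrity error.
#'
#' @param path one element of [extract_unitigs()] output.
#' @param g the `bilabel_graph` the path came from.
#' @param params an [rmap_params].
#' @param id contig name.
#' @return An object of class `contig` with fields `fragments`, `n_frags`,
#'   `genomic_length`, `support_profile`, `source_path` and `members`.
#' @export
spell_contig <- function(path, g, params, id = "contig") {
  params <- as_rmap_params(params)
  edges <- path$edges
  if (length(edges) < 1) stop("path must contain at least one edge")
  for (j in seq_len(length(edges) - 1)) {
    if (g$edge_to[edges[j]] != g$edge_from[edges[j + 1]])
      stop("assembly-integrity error: path edges ", edges[j], " and ",
           edges[j + 1], " do not share a node")
    a <- suffix_bilabel(g$edge_bilabel[[edges[j]]], params)
    b <- prefix_bilabel(g$edge_bilabel[[edges[j + 1]]], params)
    if (!is_proximal(a, b, params$t_f, params$t_l))
      stop("assembly-integrity error: non-proximal junction between edges ",
           edges[j], " and ", edges[j + 1])
  }
  cons <- lapply(edges, edge_consensus, g = g)
  last <- cons[[length(cons)]]
  fragments <- c(vapply(cons[-length(cons)], `[`, 0, 1), last)
  members <- do.call(rbind, g$edge_members[edges])
  structure(list(id = id, fragments = as.numeric(fragments),
                 n_frags = length(fragments),
                 genomic_length = sum(fragments),
                 support_profile = g$edge_support[edges],
                 source_path = path, members = members),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat("contig ", x$id, ": ", x$n_frags, " fragments, ",
      x$genomic_length, " bp, mean support ",
      round(mean(x$support_profile), 1), "\n", sep = "")
  invisible(x)
}

#' Convert a contig to an Rmap record
#' @param x a `contig`.
#' @return An [rmap] (forward orientation) carrying the consensus
#'   fragments.
#' @export
as_rmap <- function(x) rmap(x$id, x$fragments)

#' Write contigs as an optical-map file plus a summary table
#'
#' The consensus maps go to `<prefix>.contigs.maps` in the same 3-line text
#' format as the input Rmaps; a companion TSV `<prefix>.contigs.tsv` lists
#' id, n_frags, genomic_length and mean support.
#'
#' @param contigs list of `contig` objects.
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_contigs <- function(contigs, prefix) {
  maps <- paste0(prefix, ".contigs.maps")
  tsv <- paste0(prefix, ".contigs.tsv")
  write_rmaps(lapply(contigs, as_rmap), maps)
  df <- data.frame(
    id = vapply(contigs, `[[`, "", "id"),
    n_frags = vapply(contigs, `[[`, 1L, "n_frags"),
    genomic_length = vapply(contigs, function(x) x$genomic_length, 0),
    mean_support = vapply(contigs, function(x)
      round(mean(x$support_profile), 3), 0))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(maps, tsv))
}
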