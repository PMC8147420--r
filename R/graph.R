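#' Count proximal bi-labels (support)
#'
#' The support of a bi-label is the number of other stored bi-labels
#' proximal to it (self excluded; exact duplicates of the same item at
#' other positions count).
#'
#' @param bilabels a `bilabel_set`.
#' @param params an [rmap_params].
#' @return The same `bilabel_set` with its `support` field filled.
#' @export
compute_support <- function(bilabels, params) {
  params <- as_rmap_params(params)
  if (bilabels$n == 0) return(bilabels)
  forest <- build_forest(bilabels, params$t_l)
  bilabels$support <- vapply(seq_len(bilabels$n), function(i)
    length(query_proximal_idx(forest, i, params$t_f, params$t_l)), 1L)
  bilabels
}

#' Filter low-frequency bi-labels
#'
#' Bi-labels with few proximal partners typically arise from highly
#' erroneous Rmap regions; they are dropped before graph construction.
#'
#' @param bilabels a `bilabel_set` with supports computed.
#' @param min_support keep exactly the bi-labels with support >=
#'   `min_support`.
#' @return The filtered `bilabel_set`.
#' @export
filter_low_frequency <- function(bilabels, min_support) {
  if (bilabels$n == 0) return(bilabels)
  if (any(is.na(bilabels$support)))
    stop("supports not computed; call compute_support() first")
  bl_subset(bilabels, which(bilabels$support >= min_support))
}

#' Greedy proximal reduced set
#'
#' Scans the bi-labels in descending support order (ties broken by Rmap id,
#' position and orientation, for determinism) and inserts a bi-label into
#' the reduced set B' unless it is proximal to a member already in B'.
#' Every input bi-label is mapped to the first B' member it is proximal to
#' (or to itself, if it was inserted), so every bi-label is proximal to
#' some representative. Edge support is 1 plus the number of
#' non-representative bi-labels mapped to the representative.
#'
#' @param bilabels a `bilabel_set` with supports computed.
#' @param params an [rmap_params].
#' @return A list with elements `representatives` (a `bilabel_set`),
#'   `rep_of` (for each input bi-label, the index of its representative in
#'   `representatives`), `edge_support` and `members` (per representative,
#'   the input indices it represents, the representative first).
#' @export
reduce_to_representatives <- function(bilabels, params) {
  params <- as_rmap_params(params)
  n <- bilabels$n
  if (n == 0)
    return(list(representatives = bilabels, rep_of = integer(0),
                edge_support = integer(0), members = list()))
  if (any(is.na(bilabels$support)))
    stop("supports not computed; call compute_support() first")
  ord <- order(-bilabels$support, bilabels$rmap, bilabels$pos,
               bilabels$orientation)
  t_f <- params$t_f; t_l <- params$t_l; k <- bilabels$k
  # incremental bucket index over accepted representatives: bucket key ->
  # indices (into `bilabels`) of accepted members, scanned vectorised
  index <- new.env(parent = emptyenv())
  accept_order <- integer(0)           # accepted input indices, in order
  rep_of_input <- integer(n)           # input index -> accepted input index
  for (i in ord) {
    lens <- bilabels$lens[i, ]
    keys <- candidate_keys(lens, k, t_f, t_l)
    match_idx <- integer(0)
    for (key in keys) {
      rows <- index[[key]]
      if (is.null(rows)) next
      dk <- abs(bilabels$kmers[rows, , drop = FALSE] -
                  matrix(bilabels$kmers[i, ], length(rows), 2 * k,
                         byrow = TRUE))
      dl <- abs(bilabels$lens[rows, , drop = FALSE] -
                  matrix(lens, length(rows), 3, byrow = TRUE))
      ok <- rowSums(dk <= t_f) == 2L * k & rowSums(dl <= t_l) == 3L
      match_idx <- c(match_idx, rows[ok])
    }
    if (length(match_idx) == 0) {
      key <- paste(floor(lens / t_l), collapse = "_")
      index[[key]] <- c(index[[key]], i)
      accept_order <- c(accept_order, i)
      rep_of_input[i] <- i
    } else {
      # map to the earliest-accepted proximal representative
      first <- match_idx[which.min(match(match_idx, accept_order))]
      rep_of_input[i] <- first
    }
  }
  rep_pos <- match(rep_of_input, accept_order)  # representative rank
  members <- split(seq_len(n), rep_pos)
  members <- lapply(seq_along(accept_order), function(r) {
    m <- members[[as.character(r)]]
    c(accept_order[r], setdiff(m, accept_order[r]))
  })
  reps <- bl_subset(bilabels, accept_order)
  res <- list(representatives = reps, rep_of = rep_pos,
              edge_support = vapply(members, length, 1L), members = members)
  attr(res, "input_set") <- bilabels
  res
}

# ---- graph container ----

new_bilabel_graph <- function(k, params, nodes, node_keys, edge_from,
                              edge_to, edge_support, edge_bilabel,
                              edge_members) {
  nn <- length(nodes)
  ne <- length(edge_from)
  in_edges <- rep(list(integer(0)), nn)
  out_edges <- rep(list(integer(0)), nn)
  for (e in seq_len(ne)) {
    out_edges[[edge_from[e]]] <- c(out_edges[[edge_from[e]]], e)
    in_edges[[edge_to[e]]] <- c(in_edges[[edge_to[e]]], e)
  }
  structure(list(k = k, params = params, nodes = nodes,
                 node_keys = node_keys,
                 node_alive = rep(TRUE, nn),
                 in_edges = in_edges, out_edges = out_edges,
                 edge_from = edge_from, edge_to = edge_to,
                 edge_alive = rep(TRUE, ne),
                 edge_support = edge_support,
                 edge_bilabel = edge_bilabel,
                 edge_members = edge_members),
            class = "bilabel_graph")
}

#' @export
print.bilabel_graph <- function(x, ...) {
  cat("bilabel_graph:", sum(x$node_alive), "live nodes,",
      sum(x$edge_alive), "live edges (k =", x$k, ")\n")
  invisible(x)
}

node_label_key <- function(nl) {
  paste(c(length(nl$skip), nl$kmer1, nl$skip, nl$kmer2), collapse = ",")
}

in_degree <- function(g, v) length(g$in_edges[[v]])
out_degree <- function(g, v) length(g$out_edges[[v]])

live_nodes <- function(g) which(g$node_alive)
live_edges <- function(g) which(g$edge_alive)

#' Build the bi-labelled de Bruijn graph (before gluing)
#'
#' Creates one directed edge per representative bi-label, labelling its
#' incoming node with the prefix bi-label and its outgoing node with the
#' suffix bi-label. Node labels are deduplicated on exact equality at
#' insertion; proximal-but-unequal node labels are merged later by
#' [glue_nodes()].
#'
#' @param reduced the result of [reduce_to_representatives()], or a plain
#'   `bilabel_set` (each bi-label then forms its own edge with support 1).
#' @param params an [rmap_params].
#' @return A `bilabel_graph`.
#' @export
build_graph <- function(reduced, params) {
  params <- as_rmap_params(params)
  if (inherits(reduced, "bilabel_set")) {
    ms <- lapply(seq_len(reduced$n), identity)
    input <- reduced
    reduced <- list(representatives = reduced,
                    rep_of = seq_len(reduced$n),
                    edge_support = rep(1L, reduced$n), members = ms)
    attr(reduced, "input_set") <- input
  }
  reps <- reduced$representatives
  if (reps$n == 0) stop("cannot build a graph from an empty reduced set")
  nodes <- list()
  node_keys <- character(0)
  edge_from <- integer(reps$n)
  edge_to <- integer(reps$n)
  edge_bilabel <- vector("list", reps$n)
  input_set <- attr(reduced, "input_set")
  member_sources <- lapply(reduced$members, function(m)
    data.frame(rmap = reps_source_field(reduced, m, "rmap"),
               pos = reps_source_field(reduced, m, "pos"),
               orientation = reps_source_field(reduced, m, "orientation"),
               size = 2L * input_set$k +
                 vapply(input_set$skips[m], length, 1L),
               stringsAsFactors = FALSE))
  get_node <- function(nl) {
    key <- node_label_key(nl)
    j <- match(key, node_keys)
    if (!is.na(j)) return(j)
    nodes[[length(nodes) + 1L]] <<- nl
    node_keys[length(node_keys) + 1L] <<- key
    length(nodes)
  }
  for (e in seq_len(reps$n)) {
    b <- bl_get(reps, e)
    edge_from[e] <- get_node(prefix_bilabel(b, params))
    edge_to[e] <- get_node(suffix_bilabel(b, params))
    edge_bilabel[[e]] <- b
  }
  g <- new_bilabel_graph(reps$k, params, nodes, node_keys, edge_from,
                         edge_to, reduced$edge_support, edge_bilabel,
                         vector("list", reps$n))
  g$edge_members <- member_sources
  # keep full member fragment data for consensus spelling
  g$member_set <- attr(reduced, "input_set")
  g$member_idx <- reduced$members
  g
}

# helper: pull a source field for member indices into the original input set
reps_source_field <- function(reduced, m, field) {
  set <- attr(reduced, "input_set")
  switch(field,
         rmap = set$rmap[m],
         pos = set$pos[m],
         orientation = set$orientation[m])
}

#' Glue proximal nodes
#'
#' Builds a k-d forest over the live node labels ((k-1)-mer proximity, same
#' t_f and t_l) and, processing nodes in array order, merges every node
#' found proximal to the current node into it: the merged node's incident
#' edges are rewritten to the surviving node and the merged node is
#' tombstoned. Merged nodes adopt the survivor's coordinates for subsequent
#' queries. Passes repeat until no two live nodes are proximal.
#'
#' @param g a `bilabel_graph` from [build_graph()].
#' @param params an [rmap_params].
#' @return The glued `bilabel_graph`.
#' @export
glue_nodes <- function(g, params) {
  params <- as_rmap_params(params)
  repeat {
    live <- live_nodes(g)
    if (length(live) < 2) break
    nl_set <- bl_from_list(g$nodes[live])
    forest <- build_forest(nl_set, params$t_l)
    merged_any <- FALSE
    dead <- rep(FALSE, length(live))  # positions in `live` tombstoned now
    for (vi in seq_along(live)) {
      if (dead[vi]) next
      v <- live[vi]
      prox <- query_proximal_idx(forest, vi, params$t_f, params$t_l)
      prox <- prox[!dead[prox]]
      for (ui in prox) {
        u <- live[ui]
        g <- merge_node_into(g, u, v)
        dead[ui] <- TRUE
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  g
}

# rewrite u's incident edges to v and tombstone u
merge_node_into <- function(g, u, v) {
  for (e in g$in_edges[[u]]) g$edge_to[e] <- v
  for (e in g$out_edges[[u]]) g$edge_from[e] <- v
  g$in_edges[[v]] <- c(g$in_edges[[v]], g$in_edges[[u]])
  g$out_edges[[v]] <- c(g$out_edges[[v]], g$out_edges[[u]])
  g$in_edges[[u]] <- integer(0)
  g$out_edges[[u]] <- integer(0)
  g$node_alive[u] <- FALSE
  g
}

# internal consistency audit used by the tests: adjacency lists and edge
# endpoint arrays must agree, with multiplicity
audit_graph <- function(g) {
  for (e in live_edges(g)) {
    if (!g$node_alive[g$edge_from[e]] || !g$node_alive[g$edge_to[e]])
      stop("edge ", e, " touches a dead node")
    if (!e %in% g$out_edges[[g$edge_from[e]]])
      stop("edge ", e, " missing from out-adjacency of its source")
    if (!e %in% g$in_edges[[g$edge_to[e]]])
      stop("edge ", e, " missing from in-adjacency of its target")
  }
  for (v in live_nodes(g)) {
    for (e in g$out_edges[[v]])
      if (!g$edge_alive[e] || g$edge_from[e] != v)
        stop("stale out-adjacency at node ", v)
    for (e in g$in_edges[[v]])
      if (!g$edge_alive[e] || g$edge_to[e] != v)
        stop("stale in-adjacency at node ", v)
  }
  ne <- sum(vapply(live_nodes(g), function(v) out_degree(g, v), 1L))
  if (ne != length(live_edges(g))) stop("edge count mismatch")
  invisible(TRUE)
}

#' Dump a graph as GFA-like text (debugging aid; not a stable format)
#'
#' @param g a `bilabel_graph`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_graph_dump <- function(g, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (v in live_nodes(g)) {
    nl <- g$nodes[[v]]
    writeLines(paste("N", v, sum(nl$kmer1), sum(nl$skip), sum(nl$kmer2),
                     sep = "\t"), con)
  }
  for (e in live_edges(g))
    writeLines(paste("E", g$edge_from[e], g$edge_to[e], g$edge_support[e],
                     sep = "\t"), con)
  invisible(path)
}
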