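#' Disjoint forest of k-d trees over bi-labels
#'
#' Bi-labels are bucketed by the floor-quantised lengths of their three
#' segments: a bi-label with segment lengths (l1, l2, ls) lives in bucket
#' `(floor(l1/t_l), floor(l2/t_l), floor(ls/t_l))`, so that each bucket
#' holds bi-labels that are close in all three lengths. Within each bucket
#' the 2k fragment lengths of the two k-mers form a 2k-dimensional point
#' stored in a k-d tree, which answers the orthogonal range queries used by
#' [query_proximal()].
#'
#' @param x a `bilabel_set` (see [extract_bilabels()]) or a list of
#'   [bilabel] objects sharing one k.
#' @param t_l bucket width in bp (the length-proximity tolerance).
#' @return An object of class `kdforest`.
#' @export
build_forest <- function(x, t_l) {
  if (!inherits(x, "bilabel_set")) x <- bl_from_list(x)
  if (t_l <= 0) stop("t_l must be > 0")
  keys <- bucket_keys(x$lens, t_l)
  buckets <- list()
  if (x$n > 0) {
    split_idx <- split(seq_len(x$n), keys)
    buckets <- lapply(split_idx, function(idx)
      list(idx = idx,
           tree = .kdtree_build(x$kmers[idx, , drop = FALSE])))
  }
  structure(list(k = x$k, t_l = as.numeric(t_l), n = x$n, items = x,
                 buckets = buckets),
            class = "kdforest")
}

bucket_keys <- function(lens, t_l) {
  a <- floor(lens / t_l)
  paste(a[, 1], a[, 2], a[, 3], sep = "_")
}

#' @export
print.kdforest <- function(x, ...) {
  cat("kdforest:", x$n, "bi-labels of k =", x$k, "in", length(x$buckets),
      "buckets (t_l =", x$t_l, ")\n")
  invisible(x)
}

# window of bucket keys that can contain bi-labels proximal to one with
# segment lengths `lens` (numeric length 3), for buckets of width `bw`.
# The k-mer length windows use m = min(k t_f, t_l) (a k-mer can change
# length by at most k t_f under fragment proximity); the skip-length
# window spans the full +-t_l allowed by length proximity, which covers
# the home bucket and its neighbours.
candidate_keys <- function(lens, k, t_f, t_l, bw = t_l) {
  m <- min(k * t_f, t_l)
  a1 <- floor((lens[1] - m) / bw):floor((lens[1] + m) / bw)
  a2 <- floor((lens[2] - m) / bw):floor((lens[2] + m) / bw)
  a3 <- floor((lens[3] - t_l) / bw):floor((lens[3] + t_l) / bw)
  g <- expand.grid(a1 = a1, a2 = a2, a3 = a3, KEEP.OUT.ATTRS = FALSE)
  paste(g$a1, g$a2, g$a3, sep = "_")
}

# core search shared by the exported wrappers: returns sorted item indices
# of all stored bi-labels proximal to the query point, before
# self-exclusion
forest_search <- function(forest, kmer_pt, lens, t_f, t_l) {
  keys <- candidate_keys(lens, forest$k, t_f, t_l, bw = forest$t_l)
  keys <- keys[keys %in% names(forest$buckets)]
  if (length(keys) == 0) return(integer(0))
  lo <- kmer_pt - t_f
  hi <- kmer_pt + t_f
  hits <- lapply(forest$buckets[keys], function(bk)
    bk$idx[.kdtree_range(bk$tree, lo, hi)])
  cand <- unlist(hits, use.names = FALSE)
  if (length(cand) == 0) return(integer(0))
  # the range box enforces fragment proximity exactly; enforce length
  # proximity with the exact predicate
  dl <- abs(forest$items$lens[cand, , drop = FALSE] -
              matrix(lens, length(cand), 3, byrow = TRUE))
  sort(cand[rowSums(dl <= t_l) == 3L])
}

#' Find all stored bi-labels proximal to a query bi-label
#'
#' Visits every bucket whose length ranges can contain a proximal bi-label,
#' performs a 2k-dimensional orthogonal range query with the box
#' `[kmer - t_f, kmer + t_f]`, and post-filters candidates with the exact
#' proximity predicate. The query bi-label itself (identified by identical
#' fragments and source coordinates) is excluded from its own result.
#'
#' @param forest a [build_forest()] index.
#' @param b a [bilabel] with the forest's k.
#' @param t_f fragment tolerance in bp.
#' @param t_l length tolerance in bp; defaults to the forest bucket width.
#' @return Integer indices (into the indexed set) of the proximal
#'   bi-labels.
#' @export
query_proximal <- function(forest, b, t_f, t_l = forest$t_l) {
  if (length(b$kmer1) != forest$k)
    stop("query bi-label k does not match the forest")
  pt <- c(b$kmer1, b$kmer2)
  lens <- c(sum(b$kmer1), sum(b$kmer2), sum(b$skip))
  res <- forest_search(forest, pt, lens, t_f, t_l)
  if (length(res) == 0) return(res)
  res[!vapply(res, function(j) same_item(forest$items, j, b), TRUE)]
}

# query by index of a stored item; excludes the item itself
query_proximal_idx <- function(forest, i, t_f, t_l = forest$t_l) {
  set <- forest$items
  res <- forest_search(forest, set$kmers[i, ], set$lens[i, ], t_f, t_l)
  res[res != i]
}

same_item <- function(set, j, b) {
  k <- set$k
  identical(as.numeric(set$kmers[j, ]), as.numeric(c(b$kmer1, b$kmer2))) &&
    identical(as.numeric(set$skips[[j]]), as.numeric(b$skip)) &&
    identical(set$rmap[j], b$rmap) &&
    (identical(set$pos[j], b$pos) || (is.na(set$pos[j]) && is.na(b$pos))) &&
    identical(set$orientation[j], b$orientation)
}
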