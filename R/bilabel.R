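#' Construct a single bi-label
#'
#' A bi-label is a pair of k-mers (k consecutive fragment lengths) separated
#' by the shortest *skip segment* whose total length is at least D. The two
#' k-mers are constrained fragment-by-fragment; the skip segment is
#' constrained only by its length, which is what absorbs added and missed
#' cut sites. Node labels of the graph are the same shape with (k-1)-mers.
#'
#' @param kmer1,kmer2 numeric vectors of k fragment lengths (bp).
#' @param skip numeric vector of >= 1 fragment lengths (bp).
#' @param rmap_id,pos,orientation source coordinates (Rmap id, 1-based start
#'   position, extraction direction).
#' @param support number of proximal bi-labels (filled by
#'   [compute_support()]).
#' @return An object of class `bilabel`.
#' @export
bilabel <- function(kmer1, skip, kmer2, rmap_id = NA_character_,
                    pos = NA_integer_, orientation = "forward",
                    support = NA_integer_) {
  if (length(kmer1) != length(kmer2))
    stop("kmer1 and kmer2 must have the same number of fragments")
  if (length(skip) < 1L) stop("skip segment must have at least one fragment")
  structure(list(kmer1 = as.numeric(kmer1), skip = as.numeric(skip),
                 kmer2 = as.numeric(kmer2), rmap = as.character(rmap_id),
                 pos = as.integer(pos), orientation = orientation,
                 support = as.integer(support)),
            class = "bilabel")
}

#' @export
print.bilabel <- function(x, ...) {
  cat("bilabel ([", paste(x$kmer1, collapse = ","), "] | [",
      paste(x$skip, collapse = ","), "] | [",
      paste(x$kmer2, collapse = ","), "]) ",
      "from ", x$rmap, ":", x$pos, ":", substr(x$orientation, 1, 1),
      " support ", x$support, "\n", sep = "")
  invisible(x)
}

#' @export
format.bilabel <- function(x, ...) {
  paste0("([", paste(x$kmer1, collapse = ","), "]|[",
         paste(x$skip, collapse = ","), "]|[",
         paste(x$kmer2, collapse = ","), "])")
}

# ---- bi-label sets (column-oriented, used by the index and the graph) ----

# A bilabel_set stores n bi-labels of a common k as:
#   kmers: n x 2k matrix (kmer1 columns then kmer2 columns)
#   lens:  n x 3 matrix  (l(b1), l(b2), l(bs))
#   skips: list of n numeric vectors
#   rmap, pos, orientation, support: per-item vectors
new_bilabel_set <- function(k, kmers, lens, skips, rmap_id, pos, orientation,
                            support = NULL) {
  n <- nrow(kmers)
  if (is.null(support)) support <- rep(NA_integer_, n)
  structure(list(k = as.integer(k), n = n, kmers = kmers, lens = lens,
                 skips = skips, rmap = rmap_id, pos = as.integer(pos),
                 orientation = orientation, support = as.integer(support)),
            class = "bilabel_set")
}

empty_bilabel_set <- function(k) {
  new_bilabel_set(k, matrix(numeric(0), 0, 2L * k),
                  matrix(numeric(0), 0, 3), list(),
                  character(0), integer(0), character(0), integer(0))
}

#' @export
length.bilabel_set <- function(x) x$n

#' @export
print.bilabel_set <- function(x, ...) {
  cat("bilabel_set:", x$n, "bi-labels, k =", x$k, "\n")
  invisible(x)
}

#' Extract one bi-label from a set
#' @param set a `bilabel_set`.
#' @param i index.
#' @return A [bilabel].
#' @export
bl_get <- function(set, i) {
  k <- set$k
  bilabel(set$kmers[i, 1:k], set$skips[[i]], set$kmers[i, (k + 1):(2 * k)],
          set$rmap[i], set$pos[i], set$orientation[i],
          ifelse(is.na(set$support[i]), 0L, set$support[i]))
}

#' Subset a bi-label set
#' @param set a `bilabel_set`.
#' @param idx indices to keep.
#' @return A `bilabel_set`.
#' @export
bl_subset <- function(set, idx) {
  new_bilabel_set(set$k, set$kmers[idx, , drop = FALSE],
                  set$lens[idx, , drop = FALSE], set$skips[idx],
                  set$rmap[idx], set$pos[idx], set$orientation[idx],
                  set$support[idx])
}

#' Build a bi-label set from a list of bi-labels
#' @param bls list of [bilabel] objects sharing one k.
#' @return A `bilabel_set`.
#' @export
bl_from_list <- function(bls) {
  if (length(bls) == 0) stop("cannot infer k from an empty list")
  k <- length(bls[[1]]$kmer1)
  if (any(vapply(bls, function(b) length(b$kmer1), 1L) != k))
    stop("all bi-labels must share one k")
  kmers <- t(vapply(bls, function(b) c(b$kmer1, b$kmer2), numeric(2 * k)))
  lens <- t(vapply(bls, function(b)
    c(sum(b$kmer1), sum(b$kmer2), sum(b$skip)), numeric(3)))
  new_bilabel_set(k, kmers, lens, lapply(bls, `[[`, "skip"),
                  vapply(bls, `[[`, "", "rmap"),
                  vapply(bls, `[[`, 1L, "pos"),
                  vapply(bls, `[[`, "", "orientation"),
                  vapply(bls, `[[`, 1L, "support"))
}

bl_bind <- function(sets) {
  sets <- sets[vapply(sets, function(s) s$n > 0, TRUE)]
  if (length(sets) == 0) stop("no bi-labels to bind")
  k <- sets[[1]]$k
  new_bilabel_set(k, do.call(rbind, lapply(sets, `[[`, "kmers")),
                  do.call(rbind, lapply(sets, `[[`, "lens")),
                  do.call(c, lapply(sets, `[[`, "skips")),
                  do.call(c, lapply(sets, `[[`, "rmap")),
                  do.call(c, lapply(sets, `[[`, "pos")),
                  do.call(c, lapply(sets, `[[`, "orientation")),
                  do.call(c, lapply(sets, `[[`, "support")))
}

# ---- extraction ----

# the bi-label of `fragments` anchored at position i (1-based) for k-mer
# size k and minimum skip length D, or NULL if it does not fit
bilabel_at <- function(fragments, i, k, D, rmap_id = NA_character_,
                       orientation = "forward") {
  n <- length(fragments)
  p <- i + k
  if (p > n) return(NULL)
  cs <- cumsum(fragments)
  target <- D + (if (p == 1) 0 else cs[p - 1])
  q <- findInterval(target - 0.5, cs) + 1L  # smallest q with cs[q] >= target
  if (q > n || q + k > n) return(NULL)
  bilabel(fragments[i:(i + k - 1)], fragments[p:q],
          fragments[(q + 1):(q + k)], rmap_id, i, orientation)
}

#' Extract all bi-labels of an Rmap
#'
#' One bi-label is produced at every position i (left to right, 1-based) at
#' which k fragments, a minimal skip segment of total length >= D, and k
#' further fragments all fit inside the Rmap. Rmaps too short for any
#' bi-label yield an empty set. With `params$both_directions`, the reversed
#' fragment list is processed identically and the resulting bi-labels carry
#' `orientation = "reverse"` (positions are 1-based in the reversed list).
#'
#' @param r an [rmap].
#' @param params an [rmap_params].
#' @return A `bilabel_set`.
#' @export
#' @examples
#' p <- rmap_params(k = 3, D = 25, t_f = 1, t_l = 3, min_support = 0)
#' extract_bilabels(rmap("R", c(7,18,13,3,15,12,4,3,6,5,13,2)), p)
extract_bilabels <- function(r, params) {
  params <- as_rmap_params(params)
  k <- params$k
  D <- params$D
  fwd <- extract_one_direction(r$fragments, k, D, r$id, "forward")
  if (!params$both_directions) return(fwd)
  rev_ <- extract_one_direction(rev(r$fragments), k, D, r$id, "reverse")
  if (rev_$n == 0) return(fwd)
  if (fwd$n == 0) return(rev_)
  bl_bind(list(fwd, rev_))
}

extract_one_direction <- function(f, k, D, rmap_id, orientation) {
  n <- length(f)
  if (n < 2L * k + 1L) return(empty_bilabel_set(k))
  cs <- cumsum(f)
  is <- seq_len(n - 2L * k)          # candidate anchors; p = i + k <= n - k
  ps <- is + k
  target <- D + c(0, cs)[ps]         # cs[p-1], with cs[0] = 0
  qs <- findInterval(target - 0.5, cs) + 1L
  keep <- qs + k <= n
  is <- is[keep]; ps <- ps[keep]; qs <- qs[keep]
  if (length(is) == 0) return(empty_bilabel_set(k))
  kmer_idx <- outer(is, 0:(k - 1), `+`)
  kmer2_idx <- outer(qs + 1L, 0:(k - 1), `+`)
  kmers <- cbind(matrix(f[kmer_idx], ncol = k),
                 matrix(f[kmer2_idx], ncol = k))
  skips <- mapply(function(p, q) f[p:q], ps, qs, SIMPLIFY = FALSE)
  lens <- cbind(rowSums(kmers[, 1:k, drop = FALSE]),
                rowSums(kmers[, (k + 1):(2 * k), drop = FALSE]),
                vapply(skips, sum, 0))
  new_bilabel_set(k, kmers, lens, skips,
                  rep(rmap_id, length(is)), is,
                  rep(orientation, length(is)))
}

#' Extract bi-labels from a list of Rmaps
#'
#' @param rmaps list of [rmap] objects.
#' @param params an [rmap_params].
#' @param verbose log a summary of skipped (too short) Rmaps.
#' @return A single `bilabel_set` over all Rmaps (possibly empty).
#' @export
extract_all_bilabels <- function(rmaps, params, verbose = FALSE) {
  params <- as_rmap_params(params)
  sets <- lapply(rmaps, extract_bilabels, params = params)
  ns <- vapply(sets, function(s) s$n, 1L)
  if (verbose && any(ns == 0))
    message(sum(ns == 0), " of ", length(rmaps),
            " Rmaps too short for any bi-label; skipped")
  if (all(ns == 0)) return(empty_bilabel_set(params$k))
  bl_bind(sets)
}

# ---- prefix / suffix node labels ----

#' Prefix bi-label (incoming node label)
#'
#' The prefix bi-label of a bi-label b is the (k-1)-mer bi-label whose first
#' (k-1)-mer is the (k-1)-size prefix of b's first k-mer; its skip segment
#' starts at the last fragment of b's first k-mer and extends minimally to
#' length >= D; its second (k-1)-mer is drawn from the remainder of the
#' skip segment and b's second k-mer (it is not necessarily the prefix of
#' b's second k-mer).
#'
#' @param b a [bilabel] with k >= 2.
#' @param params an [rmap_params] (supplies D).
#' @return A [bilabel] with (k-1)-mers (a node label).
#' @export
prefix_bilabel <- function(b, params) {
  params <- as_rmap_params(params)
  k <- length(b$kmer1)
  if (k < 2L) stop("prefix bi-label undefined for k = 1")
  all_f <- c(b$kmer1, b$skip, b$kmer2)
  nb <- bilabel_at(all_f, 1L, k - 1L, params$D, b$rmap, b$orientation)
  if (is.null(nb))
    stop("invalid bi-label: no (k-1) prefix bi-label fits")
  nb$pos <- b$pos
  nb
}

#' Suffix bi-label (outgoing node label)
#'
#' The suffix bi-label of a bi-label b is the (k-1)-mer bi-label whose first
#' (k-1)-mer is the (k-1)-size suffix of b's first k-mer; its skip segment
#' is b's skip segment unchanged and its second (k-1)-mer is the (k-1)-size
#' prefix of b's second k-mer. For consecutive positions i, i+1 of one
#' Rmap, `suffix_bilabel(b_i)` equals `prefix_bilabel(b_{i+1})` exactly,
#' which is what connects the graph.
#'
#' @inheritParams prefix_bilabel
#' @return A [bilabel] with (k-1)-mers (a node label).
#' @export
suffix_bilabel <- function(b, params) {
  params <- as_rmap_params(params)
  k <- length(b$kmer1)
  if (k < 2L) stop("suffix bi-label undefined for k = 1")
  all_f <- c(b$kmer1[-1], b$skip, b$kmer2)
  nb <- bilabel_at(all_f, 1L, k - 1L, params$D, b$rmap, b$orientation)
  if (is.null(nb))
    stop("invalid bi-label: no (k-1) suffix bi-label fits")
  nb$pos <- b$pos + 1L
  nb
}

# vectorized node labels for a whole set: returns a list(prefix =
# bilabel_set, suffix = bilabel_set) with k-1 mers
node_labels_of <- function(set, params) {
  pre <- lapply(seq_len(set$n), function(i)
    prefix_bilabel(bl_get(set, i), params))
  suf <- lapply(seq_len(set$n), function(i)
    suffix_bilabel(bl_get(set, i), params))
  list(prefix = bl_from_list(pre), suffix = bl_from_list(suf))
}

# ---- proximity predicates ----

#' Fragment proximity
#'
#' Two bi-labels are fragment proximal iff every coordinate-wise difference
#' between their first k-mers and between their second k-mers is at most
#' `t_f`. Symmetric and reflexive, not transitive.
#'
#' @param a,b [bilabel] objects with equal k-mer sizes.
#' @param t_f tolerance in bp.
#' @return Logical.
#' @export
fragment_proximal <- function(a, b, t_f) {
  if (length(a$kmer1) != length(b$kmer1))
    stop("bi-labels have different k-mer sizes")
  all(abs(a$kmer1 - b$kmer1) <= t_f) && all(abs(a$kmer2 - b$kmer2) <= t_f)
}

#' Length proximity
#'
#' Two bi-labels are length proximal iff the lengths of their first k-mers,
#' of their second k-mers, and of their skip segments each differ by at
#' most `t_l`.
#'
#' @param a,b [bilabel] objects with equal k-mer sizes.
#' @param t_l tolerance in bp.
#' @return Logical.
#' @export
length_proximal <- function(a, b, t_l) {
  if (length(a$kmer1) != length(b$kmer1))
    stop("bi-labels have different k-mer sizes")
  abs(sum(a$kmer1) - sum(b$kmer1)) <= t_l &&
    abs(sum(a$kmer2) - sum(b$kmer2)) <= t_l &&
    abs(sum(a$skip) - sum(b$skip)) <= t_l
}

#' Proximity
#'
#' Two bi-labels are proximal iff they are both fragment proximal and
#' length proximal.
#'
#' @inheritParams fragment_proximal
#' @param t_l segment-length tolerance in bp.
#' @return Logical.
#' @export
is_proximal <- function(a, b, t_f, t_l) {
  fragment_proximal(a, b, t_f) && length_proximal(a, b, t_l)
}
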