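#' Assembly parameters
#'
#' Bundle of the tunable parameters of the bi-labelled de Bruijn graph
#' assembler. Defaults follow the recommended setting for error-corrected
#' Bionano-scale data: `k = 6` (largest k such that a k-mer is error-free
#' with probability at least 50% at a 10% per-cut error rate), `D = 15000`
#' bp minimum skip-segment length, fragment tolerance `t_f = 500` bp,
#' segment-length tolerance `t_l = 2000` bp, and only contigs longer than
#' 250 fragments reported.
#'
#' @param k k-mer size in fragments (>= 2).
#' @param D minimum skip-segment length in bp.
#' @param t_f per-fragment sizing tolerance in bp (fragment proximity).
#' @param t_l per-segment length tolerance in bp (length proximity); also the
#'   bucket width of the k-d forest.
#' @param min_support minimum number of proximal bi-labels a bi-label must
#'   have to survive low-frequency filtering.
#' @param both_directions if `TRUE`, bi-labels are additionally extracted
#'   from the reversed fragment list of every Rmap (dual-direction mode).
#' @param min_contig_frags contigs with fewer fragments are suppressed from
#'   the main output.
#' @param max_tip_len maximum length (in edges) of a dead-end branch removed
#'   as a tip; defaults to `4 * k`.
#' @param max_bubble_len maximum length (in edges) of the parallel paths of a
#'   popped bubble, i.e. twice the 2k-fragment size of a bi-label; defaults
#'   to `4 * k`.
#'
#' @return An object of class `rmap_params`.
#' @export
#' @examples
#' rmap_params(k = 3, D = 25, t_f = 1, t_l = 3)
rmap_params <- function(k = 6L, D = 15000, t_f = 500, t_l = 2000,
                        min_support = 3L, both_directions = FALSE,
                        min_contig_frags = 250L,
                        max_tip_len = 4L * k, max_bubble_len = 4L * k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (D <= 0) stop("D must be > 0")
  if (t_f <= 0) stop("t_f must be > 0")
  if (t_l <= 0) stop("t_l must be > 0")
  if (min_support < 0) stop("min_support must be >= 0")
  structure(list(k = k, D = as.numeric(D), t_f = as.numeric(t_f),
                 t_l = as.numeric(t_l), min_support = as.integer(min_support),
                 both_directions = isTRUE(both_directions),
                 min_contig_frags = as.integer(min_contig_frags),
                 max_tip_len = as.integer(max_tip_len),
                 max_bubble_len = as.integer(max_bubble_len)),
            class = "rmap_params")
}

#' @export
print.rmap_params <- function(x, ...) {
  cat("rmap_params: k =", x$k, " D =", x$D, " t_f =", x$t_f, " t_l =", x$t_l,
      "\n  min_support =", x$min_support,
      " both_directions =", x$both_directions,
      " min_contig_frags =", x$min_contig_frags,
      "\n  max_tip_len =", x$max_tip_len,
      " max_bubble_len =", x$max_bubble_len, "\n")
  invisible(x)
}

as_rmap_params <- function(x) {
  if (inherits(x, "rmap_params")) return(x)
  do.call(rmap_params, as.list(x))
}

#' Default k-mer size from the per-cut error rate
#'
#' The k-mer size is chosen as the largest k such that the probability that
#' k consecutive fragments are all error-free is at least `p_target`, given
#' a per-cut error rate `error_rate`: the largest k with
#' `(1 - error_rate)^k >= p_target`.
#'
#' @param error_rate per-cut (missed/added) error rate after correction;
#'   default 0.10.
#' @param p_target minimum probability that an extracted k-mer is error
#'   free; default 0.5.
#' @return Integer k-mer size (k = 6 at the defaults).
#' @export
default_kmer_size <- function(error_rate = 0.10, p_target = 0.5) {
  if (error_rate <= 0) return(Inf)
  as.integer(floor(log(p_target) / log(1 - error_rate)))
}
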