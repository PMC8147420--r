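#' Assembly size statistics
#'
#' Maximum and mean contig size in fragments and bp, following the usual
#' reporting convention for optical-map assemblies (fragments, with
#' genomic length in parentheses).
#'
#' @param contigs list of `contig` objects.
#' @param genome_fraction optional percent of the reference covered (from
#'   [genome_fraction_truth()] or fit alignment).
#' @param n_unaligned optional count of contigs no fit alignment was found
#'   for.
#' @return An object of class `assembly_stats`.
#' @export
assembly_stats <- function(contigs, genome_fraction = NA_real_,
                           n_unaligned = NA_integer_) {
  if (length(contigs) == 0) {
    warning("empty contig list; zero statistics")
    return(structure(list(n_contigs = 0L, max_frags = 0L, max_bp = 0,
                          mean_frags = 0L, mean_bp = 0,
                          genome_fraction = genome_fraction,
                          n_unaligned = n_unaligned),
                     class = "assembly_stats"))
  }
  nf <- vapply(contigs, `[[`, 1L, "n_frags")
  bp <- vapply(contigs, function(x) x$genomic_length, 0)
  structure(list(n_contigs = length(contigs),
                 max_frags = max(nf), max_bp = max(bp),
                 mean_frags = as.integer(round_half_up(mean(nf))),
                 mean_bp = mean(bp),
                 genome_fraction = genome_fraction,
                 n_unaligned = n_unaligned),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("contigs: %d  max: %d (%.3f Mbp)  mean: %d (%.3f Mbp)",
              x$n_contigs, x$max_frags, x$max_bp / 1e6, x$mean_frags,
              x$mean_bp / 1e6))
  if (!is.na(x$genome_fraction))
    cat(sprintf("  GF: %.2f%%", x$genome_fraction))
  if (!is.na(x$n_unaligned)) cat("  unaligned:", x$n_unaligned)
  cat("\n")
  invisible(x)
}

# genomic interval (0-based half-open) covered by one member bi-label of a
# contig, via simulator ground truth
member_interval <- function(bnd, pos, size, extraction_orientation) {
  if (extraction_orientation == "reverse") bnd <- rev(bnd)
  if (pos < 1 || pos + size > length(bnd))
    stop("member coordinates outside the source Rmap")
  ends <- c(bnd[pos], bnd[pos + size])
  c(min(ends), max(ends))
}

#' Genome fraction from simulator ground truth
#'
#' The union of the genomic intervals covered by each contig's constituent
#' bi-labels (looked up in the simulator's ground truth), divided by the
#' genome length, times 100.
#'
#' @param contigs list of `contig` objects whose `members` provenance
#'   traces back to simulated Rmaps.
#' @param truth the `truth` element of [simulate_rmaps()] output.
#' @param genome_length reference length in bp; defaults to
#'   `truth$genome_length`.
#' @return Percent of the genome covered, in `[0, 100]`.
#' @export
genome_fraction_truth <- function(contigs, truth,
                                  genome_length = truth$genome_length) {
  ivs <- list()
  for (ct in contigs) {
    mem <- ct$members
    if (is.null(mem) || nrow(mem) == 0)
      stop("contig lacks member provenance; use fit_align() for ",
           "reference-based evaluation instead")
    for (j in seq_len(nrow(mem))) {
      bnd <- truth$boundaries[[mem$rmap[j]]]
      if (is.null(bnd))
        stop("Rmap ", mem$rmap[j], " not present in ground truth; use ",
             "fit_align() for reference-based evaluation instead")
      ivs[[length(ivs) + 1]] <-
        member_interval(bnd, mem$pos[j], mem$size[j], mem$orientation[j])
    }
  }
  if (length(ivs) == 0) return(0)
  m <- do.call(rbind, ivs)
  cov <- IRanges::reduce(IRanges::IRanges(start = m[, 1] + 1,
                                          end = m[, 2]))
  100 * sum(IRanges::width(cov)) / genome_length
}

#' Fit-align a contig to a reference optical map
#'
#' Dynamic program over (contig cut, reference cut) pairs. Each step
#' consumes 1..`max_site_diff` consecutive fragments on either side
#' (allowing missed/added cut sites) at a cost equal to the absolute
#' difference of the aggregated lengths; a step is admissible if its cost
#' is at most `sizing_tol * max(number of merged fragments)`. The whole
#' contig must be consumed ("fit" alignment); the placement with the
#' smallest mean per-step cost is returned if that mean is at most
#' `sizing_tol`, otherwise `NULL` (the contig is counted unaligned -- a
#' candidate mis-assembly).
#'
#' @param contig a `contig` or [rmap] (its fragments are used).
#' @param refmap an [rmap]: the in-silico digest of the reference.
#' @param sizing_tol per-step cost tolerance in bp.
#' @param max_site_diff maximum fragments merged per step on either side.
#' @return `NULL`, or a list with `ref_start`/`ref_end` (bp interval on
#'   the reference, 0-based half-open), `ref_cuts` (cut-index window),
#'   `cost`, `steps` and `mean_cost`.
#' @export
fit_align <- function(contig, refmap, sizing_tol = 2000,
                      max_site_diff = 3L) {
  cf <- if (inherits(contig, "contig")) contig$fragments else
    contig$fragments
  rf <- refmap$fragments
  n <- length(cf); m <- length(rf)
  if (n < 1 || m < 1) stop("contig and reference must be non-empty")
  ccum <- c(0, cumsum(cf))
  rcum <- c(0, cumsum(rf))
  d <- as.integer(max_site_diff)
  INF <- Inf
  cost <- matrix(INF, n + 1, m + 1)
  steps <- matrix(0L, n + 1, m + 1)
  org <- matrix(NA_integer_, n + 1, m + 1)  # starting ref cut (0-based)
  cost[1, ] <- 0
  org[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (di in seq_len(min(d, i))) {
      clen <- ccum[i + 1] - ccum[i + 1 - di]
      prev <- i + 1 - di
      for (j in seq_len(m)) {
        best <- cost[i + 1, j + 1]
        for (dj in seq_len(min(d, j))) {
          pc <- cost[prev, j + 1 - dj]
          if (!is.finite(pc)) next
          stepc <- abs(clen - (rcum[j + 1] - rcum[j + 1 - dj]))
          if (stepc > sizing_tol * max(di, dj)) next
          tot <- pc + stepc
          if (tot < best) {
            best <- tot
            cost[i + 1, j + 1] <- tot
            steps[i + 1, j + 1] <- steps[prev, j + 1 - dj] + 1L
            org[i + 1, j + 1] <- org[prev, j + 1 - dj]
          }
        }
      }
    }
  }
  fin <- cost[n + 1, ]
  ok <- is.finite(fin) & steps[n + 1, ] > 0
  if (!any(ok)) return(NULL)
  mean_cost <- ifelse(ok, fin / steps[n + 1, ], INF)
  j <- which.min(mean_cost)
  if (mean_cost[j] > sizing_tol) return(NULL)
  start_cut <- org[n + 1, j]
  list(ref_start = rcum[start_cut + 1], ref_end = rcum[j],
       ref_cuts = c(start_cut, j - 1L), cost = fin[j],
       steps = steps[n + 1, j], mean_cost = mean_cost[j])
}

#' Evaluate an assembly
#'
#' Computes size statistics plus, when ground truth or a reference map is
#' supplied, the genome fraction and the number of unalignable contigs.
#' An unaligned contig whose two halves each fit-align at discordant loci
#' is flagged as a candidate mis-assembly.
#'
#' @param contigs list of `contig` objects.
#' @param truth optional simulator ground truth (preferred when present).
#' @param refmap optional reference [rmap] for fit alignment.
#' @param sizing_tol,max_site_diff see [fit_align()].
#' @return An `assembly_stats` with attribute `misassembled` (ids of
#'   flagged contigs) when a refmap was supplied.
#' @export
evaluate_assembly <- function(contigs, truth = NULL, refmap = NULL,
                              sizing_tol = 2000, max_site_diff = 3L) {
  gf <- NA_real_
  n_unaligned <- NA_integer_
  flagged <- character(0)
  if (!is.null(truth)) {
    gf <- genome_fraction_truth(contigs, truth)
  }
  if (!is.null(refmap)) {
    placements <- lapply(contigs, fit_align, refmap = refmap,
                         sizing_tol = sizing_tol,
                         max_site_diff = max_site_diff)
    unaligned <- vapply(placements, is.null, TRUE)
    n_unaligned <- sum(unaligned)
    for (idx in which(unaligned)) {
      ct <- contigs[[idx]]
      nf <- ct$n_frags
      if (nf < 4) next
      h1 <- rmap("h1", ct$fragments[1:(nf %/% 2)])
      h2 <- rmap("h2", ct$fragments[(nf %/% 2 + 1):nf])
      p1 <- fit_align(h1, refmap, sizing_tol, max_site_diff)
      p2 <- fit_align(h2, refmap, sizing_tol, max_site_diff)
      if (!is.null(p1) && !is.null(p2)) {
        gap <- p2$ref_start - p1$ref_end
        if (p2$ref_start < p1$ref_start ||
            abs(gap) > ct$genomic_length / 2)
          flagged <- c(flagged, ct$id)
      }
    }
    if (is.null(truth)) {
      placed <- placements[!unaligned]
      if (length(placed) > 0) {
        cov <- IRanges::reduce(IRanges::IRanges(
          start = vapply(placed, function(p) p$ref_start + 1, 0),
          end = vapply(placed, function(p) p$ref_end, 0)))
        gf <- 100 * sum(IRanges::width(cov)) / sum(refmap$fragments)
      } else gf <- 0
    }
  }
  st <- assembly_stats(contigs, genome_fraction = gf,
                       n_unaligned = n_unaligned)
  attr(st, "misassembled") <- flagged
  st
}

#' Write an evaluation report as TSV
#'
#' One row mirroring the usual table columns: n_contigs, max and mean (in
#' fragments and bp), genome fraction and number of mis-assembly
#' candidates.
#'
#' @param stats an `assembly_stats`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_stats <- function(stats, path) {
  df <- data.frame(n_contigs = stats$n_contigs,
                   max_frags = stats$max_frags, max_bp = stats$max_bp,
                   mean_frags = stats$mean_frags, mean_bp = stats$mean_bp,
                   genome_fraction = stats$genome_fraction,
                   n_unaligned = stats$n_unaligned,
                   n_misassembled = length(attr(stats, "misassembled")))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
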