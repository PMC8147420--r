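#' Rmap error model
#'
#' Observation model for single-molecule restriction maps. Missed cut
#' sites are Bernoulli trials with probability `p_miss`; spurious cut
#' sites arise from random breakage as a Poisson process with
#' `false_cut_rate` expected cuts per bp; observed fragment sizes are the
#' true size perturbed by length-dependent noise. Under the default
#' `"normal"` model an observed fragment is
#' `max(1, round(Normal(r, (sizing_scale * sqrt(r))^2)))`; under the
#' `"laplace"` model it is `r * Laplace(mu, beta)` with user-supplied
#' parameters. The defaults match common simulator settings for Bionano
#' data: 15% deleted cut sites and 1 added cut site per 100 kbp.
#'
#' @param p_miss probability a true cut site is not observed.
#' @param false_cut_rate expected spurious cuts per bp (1e-5 = 1 per
#'   100 kbp).
#' @param sizing_model `"normal"` or `"laplace"`.
#' @param sizing_scale dispersion of the normal model; the standard
#'   deviation of a fragment of true length r is `sizing_scale * sqrt(r)`.
#'   The default 3.35 gives sd(2 kbp) of roughly 150 bp.
#' @param laplace_mu,laplace_beta multiplicative Laplace parameters (only
#'   used by the `"laplace"` model).
#' @return An object of class `error_model`.
#' @export
error_model <- function(p_miss = 0.15, false_cut_rate = 1e-5,
                        sizing_model = c("normal", "laplace"),
                        sizing_scale = 3.35, laplace_mu = 1,
                        laplace_beta = 0.05) {
  sizing_model <- match.arg(sizing_model)
  if (p_miss < 0 || p_miss > 1) stop("p_miss must be in [0, 1]")
  if (false_cut_rate < 0) stop("false_cut_rate must be >= 0")
  if (sizing_scale < 0) stop("sizing_scale must be >= 0")
  structure(list(p_miss = p_miss, false_cut_rate = false_cut_rate,
                 sizing_model = sizing_model, sizing_scale = sizing_scale,
                 laplace_mu = laplace_mu, laplace_beta = laplace_beta),
            class = "error_model")
}

#' Error-free model shorthand
#' @return An [error_model] with no missed cuts, no false cuts and no
#'   sizing noise.
#' @export
error_model_none <- function()
  error_model(p_miss = 0, false_cut_rate = 0, sizing_scale = 0)

#' Random genome sequence
#'
#' @param length sequence length in bp (> 0).
#' @param gc GC fraction.
#' @param seed optional integer seed for reproducibility.
#' @return A single uppercase nucleotide string.
#' @export
random_genome <- function(length, gc = 0.5, seed = NULL) {
  if (length <= 0) stop("length must be > 0")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# merge fragments whose separating cuts were missed: `drop` flags the
# internal cut after each fragment but the last (length |frags| - 1)
drop_cuts <- function(fragments, drop) {
  if (length(drop) != length(fragments) - 1L)
    stop("drop must flag each internal cut site")
  grp <- cumsum(c(TRUE, !drop))
  as.numeric(tapply(fragments, grp, sum))
}

rlaplace <- function(n, mu, beta) {
  u <- runif(n) - 0.5
  mu - beta * sign(u) * log(1 - 2 * abs(u))
}

#' Simulate error-bearing Rmaps from a genome
#'
#' Molecules are drawn uniformly over the genome until their total length
#' reaches `coverage` times the genome length; molecule lengths are
#' Normal(`molecule_mean`, `molecule_sd`) truncated below. Each molecule is
#' digested in silico, then each true cut inside it is dropped
#' independently with probability `p_miss`, spurious cuts are added by a
#' Poisson process along the molecule, every resulting fragment is
#' perturbed by the sizing model, and about half of the molecules are
#' reversed (orientation is unknown in real data). Ground truth records
#' the placement of every molecule and the true genomic boundary
#' coordinate of every observed fragment.
#'
#' @param genome nucleotide string, or a precomputed reference [rmap]
#'   (in-silico digest) -- a genome string is required for spurious-cut
#'   placement only when `false_cut_rate > 0`.
#' @param enz an [enzyme] (used when `genome` is a sequence).
#' @param coverage target fold coverage (> 0).
#' @param molecule_mean,molecule_sd molecule length distribution in bp.
#'   The default mean of 350 kbp yields Rmaps of roughly 40 fragments at
#'   typical nicking-enzyme site densities (one site per 8-9 kbp).
#' @param model an [error_model].
#' @param seed optional integer seed.
#' @param min_frags molecules yielding fewer observed fragments are
#'   redrawn as part of coverage but not reported (default 1, i.e. keep
#'   everything).
#' @param trim_flanks drop the first and last fragment of every molecule.
#'   A molecule almost never starts or ends exactly at a cut site, so its
#'   two flank fragments are partial genomic fragments; downstream
#'   analyses that compare against the reference digest usually discard
#'   them. Default `FALSE` (report the full molecule).
#' @return A list with `rmaps` (list of [rmap]) and `truth` (see
#'   Details): `truth$molecules` is a data.frame (id, start, end,
#'   orientation; 0-based half-open genome coordinates) and
#'   `truth$boundaries` the per-Rmap numeric vector of true genome
#'   coordinates flanking each observed fragment, in observed order
#'   (decreasing for reversed molecules). `truth$genome_length` and
#'   `truth$n_true_cuts`/`n_missed`/`n_false` carry bookkeeping totals.
#' @export
simulate_rmaps <- function(genome, enz, coverage, molecule_mean = 350000,
                           molecule_sd = 50000, model = error_model(),
                           seed = NULL, min_frags = 1L,
                           trim_flanks = FALSE) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (molecule_mean <= 0) stop("molecule_mean must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(genome, "rmap")) {
    cuts <- cumsum(genome$fragments)
    L <- cuts[length(cuts)]
    cuts <- cuts[-length(cuts)]
  } else {
    L <- nchar(genome)
    cuts <- cut_positions(genome, enz)
  }
  if (length(cuts) == 0)
    warning("enzyme never cuts the genome; Rmaps will be single fragments")
  rmaps <- list()
  boundaries <- list()
  mol <- list()
  total <- 0
  n_true <- 0L; n_missed <- 0L; n_false <- 0L
  i <- 0L
  while (total < coverage * L) {
    len <- round(rnorm(1, molecule_mean, molecule_sd))
    len <- min(max(len, 2), L)
    start <- floor(runif(1, 0, L - len + 1))
    end <- start + len
    total <- total + len
    inside <- cuts[cuts > start & cuts < end]
    n_true <- n_true + length(inside)
    keep <- runif(length(inside)) >= model$p_miss
    n_missed <- n_missed + sum(!keep)
    kept <- inside[keep]
    nf <- rpois(1, model$false_cut_rate * len)
    if (nf > 0) {
      fc <- floor(runif(nf, start + 1, end))
      fc <- setdiff(fc, c(kept, start, end))
      n_false <- n_false + length(fc)
      kept <- sort(c(kept, fc))
    }
    bnd <- if (trim_flanks) kept else c(start, kept, end)
    if (length(bnd) < 2) next
    true_frags <- diff(bnd)
    obs <- true_frags
    if (model$sizing_scale > 0 && model$sizing_model == "normal")
      obs <- round_half_up(rnorm(length(obs), obs,
                                 model$sizing_scale * sqrt(obs)))
    else if (model$sizing_model == "laplace")
      obs <- round_half_up(obs * rlaplace(length(obs), model$laplace_mu,
                                          model$laplace_beta))
    obs <- pmax(obs, 1)
    orientation <- if (runif(1) < 0.5) "reverse" else "forward"
    if (orientation == "reverse") {
      obs <- rev(obs)
      bnd <- rev(bnd)
    }
    if (length(obs) < min_frags) next
    i <- i + 1L
    id <- sprintf("sim_%06d", i)
    rmaps[[i]] <- rmap(id, obs)
    boundaries[[id]] <- bnd
    mol[[i]] <- data.frame(id = id, start = start, end = end,
                           orientation = orientation,
                           stringsAsFactors = FALSE)
  }
  truth <- list(molecules = do.call(rbind, mol), boundaries = boundaries,
                genome_length = L, n_true_cuts = n_true,
                n_missed = n_missed, n_false = n_false)
  list(rmaps = rmaps, truth = truth)
}

#' Write simulator ground truth as TSV
#'
#' @param truth the `truth` element of [simulate_rmaps()] output.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  write.table(truth$molecules, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
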