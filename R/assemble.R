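#' Assemble Rmaps into contig optical maps
#'
#' Runs the five assembly stages in order: extract bi-labels, compute
#' proximal support and filter low-frequency bi-labels, reduce to the
#' proximal representative set and build the bi-labelled de Bruijn graph,
#' glue proximal nodes, remove tips and pop bubbles, and finally traverse
#' the graph to spell unitigs into consensus contigs. Deterministic for a
#' fixed input and parameter set.
#'
#' @param rmaps list of [rmap] objects (assumed error-corrected).
#' @param params an [rmap_params].
#' @param verbose log per-stage counts to stderr.
#' @return A list with `contigs` (contigs with at least
#'   `params$min_contig_frags` fragments), `all_contigs` (every spelled
#'   unitig), `graph` (the cleaned `bilabel_graph`) and `counts` (named
#'   per-stage tallies).
#' @export
assemble_rmaps <- function(rmaps, params = rmap_params(), verbose = FALSE) {
  params <- as_rmap_params(params)
  log_ <- function(...) if (verbose) message(...)
  counts <- list()
  empty <- function() list(contigs = list(), all_contigs = list(),
                           graph = NULL, counts = counts)

  bls <- extract_all_bilabels(rmaps, params, verbose = verbose)
  counts$bilabels_extracted <- bls$n
  log_("extracted ", bls$n, " bi-labels from ", length(rmaps), " Rmaps")
  if (bls$n == 0) return(empty())

  bls <- compute_support(bls, params)
  kept <- filter_low_frequency(bls, params$min_support)
  counts$bilabels_filtered <- bls$n - kept$n
  counts$bilabels_kept <- kept$n
  log_("filtered ", counts$bilabels_filtered, " low-frequency bi-labels (",
       kept$n, " kept)")
  if (kept$n == 0)
    stop("no bi-label survives filtering: insufficient coverage or ",
         "over-filtering (lower min_support or D)")

  red <- reduce_to_representatives(kept, params)
  counts$representatives <- red$representatives$n
  log_("reduced to ", counts$representatives, " representative bi-labels")

  g <- build_graph(red, params)
  counts$nodes_before_glue <- sum(g$node_alive)
  g <- glue_nodes(g, params)
  counts$nodes_after_glue <- sum(g$node_alive)
  log_("graph: ", counts$nodes_before_glue, " nodes before gluing, ",
       counts$nodes_after_glue, " after; ", sum(g$edge_alive), " edges")

  ne0 <- sum(g$edge_alive)
  g <- remove_tips(g)
  counts$tip_edges_removed <- ne0 - sum(g$edge_alive)
  ne1 <- sum(g$edge_alive)
  g <- pop_bubbles(g)
  counts$bubble_edges_removed <- ne1 - sum(g$edge_alive)
  log_("cleanup: ", counts$tip_edges_removed, " tip edges and ",
       counts$bubble_edges_removed, " bubble edges removed")

  paths <- extract_unitigs(g)
  counts$unitigs <- length(paths)
  counts$cyclic_edges_unreported <- attr(paths, "n_cyclic_edges")
  if (counts$cyclic_edges_unreported > 0)
    log_(counts$cyclic_edges_unreported,
         " edges in purely cyclic components were not traversed")

  all_contigs <- lapply(seq_along(paths), function(i)
    spell_contig(paths[[i]], g, params, id = sprintf("contig_%04d", i)))
  contigs <- Filter(function(ct) ct$n_frags >= params$min_contig_frags,
                    all_contigs)
  counts$contigs_reported <- length(contigs)
  log_(length(all_contigs), " unitigs spelled; ", length(contigs),
       " contigs of >= ", params$min_contig_frags, " fragments reported")
  list(contigs = contigs, all_contigs = all_contigs, graph = g,
       counts = counts)
}

#' File-level assembly driver
#'
#' Reads an Rmap file, assembles it, and writes `<prefix>.contigs.maps`,
#' `<prefix>.contigs.tsv` and `<prefix>.stats.tsv`.
#'
#' @param rmaps_path input optical-map text file.
#' @param out_prefix output path prefix.
#' @param params an [rmap_params].
#' @param verbose log per-stage counts to stderr.
#' @return Invisibly, the [assemble_rmaps()] result.
#' @export
run_assembly <- function(rmaps_path, out_prefix, params = rmap_params(),
                         verbose = TRUE) {
  rmaps <- read_rmaps(rmaps_path)
  if (length(rmaps) == 0) {
    message("no Rmaps in ", rmaps_path, "; writing zero contigs")
    write_contigs(list(), out_prefix)
    return(invisible(list(contigs = list(), all_contigs = list(),
                          graph = NULL, counts = list())))
  }
  res <- assemble_rmaps(rmaps, params, verbose = verbose)
  write_contigs(res$contigs, out_prefix)
  st <- assembly_stats(res$contigs)
  write_stats(st, paste0(out_prefix, ".stats.tsv"))
  invisible(res)
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher used by `inst/cli/rmapasm.R`:
#' `assemble`, `digest`, `simulate` and `evaluate`. All randomness is
#' seeded from `--seed`. See each subcommand's `--help` for options.
#'
#' @param args character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the command-line interface requires the 'optparse' package")
  if (length(args) == 0 ||
      !args[1] %in% c("assemble", "digest", "simulate", "evaluate")) {
    message("usage: rmapasm.R <assemble|digest|simulate|evaluate> [options]")
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    switch(sub,
           assemble = cli_assemble(rest),
           digest = cli_digest(rest),
           simulate = cli_simulate(rest),
           evaluate = cli_evaluate(rest))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_parser <- function(opts, usage) {
  optparse::OptionParser(usage = usage, option_list = opts)
}

cli_assemble <- function(args) {
  o <- optparse::parse_args(cli_parser(list(
    optparse::make_option("--rmaps", type = "character"),
    optparse::make_option("--out", type = "character", default = "assembly"),
    optparse::make_option("--k", type = "integer", default = 6L),
    optparse::make_option("--D", type = "double", default = 15000),
    optparse::make_option("--tf", type = "double", default = 500),
    optparse::make_option("--tl", type = "double", default = 2000),
    optparse::make_option("--min-support", type = "integer", default = 3L,
                          dest = "min_support"),
    optparse::make_option("--min-contig-frags", type = "integer",
                          default = 250L, dest = "min_contig_frags"),
    optparse::make_option("--both-directions", action = "store_true",
                          default = FALSE, dest = "both_directions"),
    optparse::make_option("--raw", action = "store_true", default = FALSE,
                          help = "input not error-corrected: relax min-support by 1")),
    "rmapasm.R assemble --rmaps FILE [options]"), args = args)
  if (is.null(o$rmaps)) stop("--rmaps is required")
  ms <- if (o$raw) max(o$min_support - 1L, 1L) else o$min_support
  p <- rmap_params(k = o$k, D = o$D, t_f = o$tf, t_l = o$tl,
                   min_support = ms, both_directions = o$both_directions,
                   min_contig_frags = o$min_contig_frags)
  run_assembly(o$rmaps, o$out, p)
}

cli_digest <- function(args) {
  o <- optparse::parse_args(cli_parser(list(
    optparse::make_option("--fasta", type = "character"),
    optparse::make_option("--site", type = "character"),
    optparse::make_option("--cut-offset", type = "integer", default = 0L,
                          dest = "cut_offset"),
    optparse::make_option("--out", type = "character", default = "ref.maps")),
    "rmapasm.R digest --fasta FILE --site SITE [options]"), args = args)
  if (is.null(o$fasta) || is.null(o$site))
    stop("--fasta and --site are required")
  maps <- digest_fasta(o$fasta, enzyme(o$site, o$cut_offset))
  write_rmaps(maps, o$out)
  message("wrote ", length(maps), " reference map(s) to ", o$out)
}

cli_simulate <- function(args) {
  o <- optparse::parse_args(cli_parser(list(
    optparse::make_option("--fasta", type = "character"),
    optparse::make_option("--site", type = "character"),
    optparse::make_option("--cut-offset", type = "integer", default = 0L,
                          dest = "cut_offset"),
    optparse::make_option("--coverage", type = "double", default = 50),
    optparse::make_option("--molecule-mean", type = "double",
                          default = 350000, dest = "molecule_mean"),
    optparse::make_option("--molecule-sd", type = "double", default = 50000,
                          dest = "molecule_sd"),
    optparse::make_option("--p-miss", type = "double", default = 0.15,
                          dest = "p_miss"),
    optparse::make_option("--false-per-100kbp", type = "double", default = 1,
                          dest = "false_per_100kbp"),
    optparse::make_option("--sizing-scale", type = "double", default = 3.35,
                          dest = "sizing_scale"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "sim")),
    "rmapasm.R simulate --fasta FILE --site SITE [options]"), args = args)
  if (is.null(o$fasta) || is.null(o$site))
    stop("--fasta and --site are required")
  genome <- read_fasta(o$fasta)[[1]]
  sim <- simulate_rmaps(genome, enzyme(o$site, o$cut_offset), o$coverage,
                        o$molecule_mean, o$molecule_sd,
                        error_model(p_miss = o$p_miss,
                                    false_cut_rate = o$false_per_100kbp / 1e5,
                                    sizing_scale = o$sizing_scale),
                        seed = o$seed)
  write_rmaps(sim$rmaps, paste0(o$out, ".rmaps"))
  write_truth(sim$truth, paste0(o$out, ".truth.tsv"))
  message("wrote ", length(sim$rmaps), " Rmaps to ", o$out, ".rmaps")
}

cli_evaluate <- function(args) {
  o <- optparse::parse_args(cli_parser(list(
    optparse::make_option("--contigs", type = "character"),
    optparse::make_option("--ref", type = "character"),
    optparse::make_option("--sizing-tol", type = "double", default = 2000,
                          dest = "sizing_tol"),
    optparse::make_option("--max-site-diff", type = "integer", default = 3L,
                          dest = "max_site_diff"),
    optparse::make_option("--out", type = "character", default = "eval.tsv")),
    "rmapasm.R evaluate --contigs FILE --ref FILE [options]"), args = args)
  if (is.null(o$contigs) || is.null(o$ref))
    stop("--contigs and --ref are required")
  contigs <- lapply(read_rmaps(o$contigs), function(r)
    structure(list(id = r$id, fragments = r$fragments,
                   n_frags = length(r$fragments),
                   genomic_length = sum(r$fragments),
                   support_profile = NA_real_, source_path = NULL,
                   members = NULL), class = "contig"))
  refmap <- read_rmaps(o$ref)[[1]]
  st <- evaluate_assembly(contigs, refmap = refmap,
                          sizing_tol = o$sizing_tol,
                          max_site_diff = o$max_site_diff)
  write_stats(st, o$out)
  print(st)
}
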