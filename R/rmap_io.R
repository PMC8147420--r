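#' Construct an Rmap
#'
#' An Rmap is an ordered list of fragment lengths (integer base pairs)
#' between consecutive enzyme cut sites on one molecule. The *size* of an
#' Rmap is its number of fragments, its *length* the sum of them.
#'
#' @param id record name.
#' @param fragments numeric vector of fragment lengths in bp; all > 0.
#' @param orientation `"forward"` or `"reverse"`.
#' @return An object of class `rmap`.
#' @export
#' @examples
#' rmap("toy", c(6, 11, 11, 6))
rmap <- function(id, fragments, orientation = "forward") {
  fragments <- as.numeric(fragments)
  if (length(fragments) < 1L) stop("an Rmap needs at least one fragment")
  if (any(!is.finite(fragments)) || any(fragments <= 0))
    stop("all fragments must be finite and > 0")
  if (!orientation %in% c("forward", "reverse"))
    stop("orientation must be 'forward' or 'reverse'")
  structure(list(id = as.character(id), fragments = fragments,
                 orientation = orientation),
            class = "rmap")
}

#' @export
print.rmap <- function(x, ...) {
  cat("rmap ", x$id, " (", length(x$fragments), " fragments, ",
      sum(x$fragments), " bp, ", x$orientation, ")\n", sep = "")
  invisible(x)
}

# round to nearest integer, ties away from zero (base round() is
# round-half-even); fragments are positive so this is floor(x + 0.5)
round_half_up <- function(x) floor(x + 0.5)

#' Read Rmaps from the 3-line optical-map text format
#'
#' Each record is three lines: the map name; the enzyme name, enzyme
#' abbreviation and the tab/space-separated fragment sizes in kbp; a blank
#' line. Fragment sizes are converted to integer bp (x1000, rounded to the
#' nearest integer, ties away from zero).
#'
#' @param path file to read.
#' @return A list of [rmap] objects, in file order, orientation `"forward"`.
#' @export
read_rmaps <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  # drop trailing blank lines but keep interior structure
  while (length(lines) > 0 && grepl("^\\s*$", lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0) return(list())
  if (length(lines) %% 3 == 2) lines <- c(lines, "")  # tolerate missing final blank
  if (length(lines) %% 3 != 0)
    stop("malformed Rmap file: ", length(lines),
         " non-trailing lines, expected records of 3 lines each")
  n <- length(lines) / 3
  out <- vector("list", n)
  for (i in seq_len(n)) {
    base <- (i - 1) * 3
    name <- trimws(lines[base + 1])
    if (!nzchar(name))
      stop("malformed record at line ", base + 1, ": empty map name")
    if (!grepl("^\\s*$", lines[base + 3]))
      stop("malformed record at line ", base + 3, ": expected blank separator")
    toks <- strsplit(trimws(lines[base + 2]), "[ \t]+")[[1]]
    if (length(toks) < 3)
      stop("malformed record at line ", base + 2,
           ": expected enzyme name, abbreviation and at least one fragment")
    frags_kbp <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (any(is.na(frags_kbp)))
      stop("malformed record at line ", base + 2, ": non-numeric fragment")
    if (any(frags_kbp <= 0))
      stop("malformed record at line ", base + 2, ": fragment <= 0")
    out[[i]] <- rmap(name, round_half_up(frags_kbp * 1000))
  }
  out
}

#' Write Rmaps in the 3-line optical-map text format
#'
#' Inverse of [read_rmaps()]: fragments are printed in kbp with three
#' decimals, so `read_rmaps(write_rmaps(x))` reproduces integer-bp fragment
#' lists exactly.
#'
#' @param rmaps list of [rmap] objects.
#' @param path output file.
#' @param enzyme_name,enzyme_abbr strings for the second field of each record.
#' @return Invisibly, `path`.
#' @export
write_rmaps <- function(rmaps, path, enzyme_name = "enzyme",
                        enzyme_abbr = "E") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in rmaps) {
    if (any(r$fragments <= 0)) stop("all fragments must be > 0")
    writeLines(c(r$id,
                 paste(enzyme_name, enzyme_abbr,
                       paste(sprintf("%.3f", r$fragments / 1000),
                             collapse = "\t"),
                       sep = "\t"),
                 ""), con)
  }
  invisible(path)
}

#' Restriction enzyme
#'
#' @param recognition_site nucleotide string (uppercase A/C/G/T).
#' @param cut_offset 0-based position within the site where the enzyme
#'   cleaves (0 <= cut_offset <= site length).
#' @return An object of class `enzyme`.
#' @export
#' @examples
#' enzyme("AACT", 2)  # cleaves in the middle of AACT
enzyme <- function(recognition_site, cut_offset) {
  if (!is.character(recognition_site) || length(recognition_site) != 1 ||
      !nzchar(recognition_site) ||
      grepl("[^ACGT]", recognition_site))
    stop("recognition_site must be a non-empty uppercase A/C/G/T string")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0 ||
      cut_offset > nchar(recognition_site))
    stop("cut_offset must be within [0, site length]")
  structure(list(recognition_site = recognition_site,
                 cut_offset = cut_offset), class = "enzyme")
}

# all cut coordinates of `enz` in `sequence` (positions after which the
# molecule is cleaved, in 0..nchar), overlapping occurrences included
cut_positions <- function(sequence, enz) {
  hits <- Biostrings::matchPattern(enz$recognition_site,
                                   Biostrings::DNAString(sequence))
  starts <- Biostrings::start(hits)
  cuts <- starts - 1L + enz$cut_offset  # 0-based coordinate of the cut
  sort(unique(cuts[cuts > 0 & cuts < nchar(sequence)]))
}

#' In-silico digestion of a sequence into an optical map
#'
#' Scans the sequence left to right for every (possibly overlapping)
#' occurrence of the recognition site, cuts at occurrence start +
#' `cut_offset`, and returns the fragment lengths between consecutive cuts
#' plus the two flanks. The fragments always sum to the sequence length.
#' Cuts falling on the sequence boundary (possible only for cut offsets at
#' the edge of the site) are dropped so no zero-length fragment is emitted.
#'
#' @param sequence nucleotide string (single sequence).
#' @param enz an [enzyme].
#' @param id name for the resulting map.
#' @return An [rmap] whose fragments are in bp (one letter = one bp).
#' @export
#' @examples
#' digest_sequence("TTTTAACTGGGGGGGAACTTTTTTTTAACTTTTT", enzyme("AACT", 2))
digest_sequence <- function(sequence, enz, id = "digest") {
  if (!is.character(sequence) || length(sequence) != 1)
    stop("sequence must be a single character string")
  L <- nchar(sequence)
  if (L == 0) stop("sequence must be non-empty")
  stopifnot(inherits(enz, "enzyme"))
  cuts <- cut_positions(sequence, enz)
  frags <- diff(c(0, cuts, L))
  frags <- frags[frags > 0]  # guard; adjacent identical cuts already deduped
  rmap(id, frags)
}

#' Read a FASTA file
#'
#' @param path FASTA file (uncompressed or gzip).
#' @return Named character vector of uppercase sequences, one per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Digest every record of a FASTA file
#'
#' @inheritParams read_fasta
#' @param enz an [enzyme].
#' @return List of [rmap] objects, one per FASTA record.
#' @export
digest_fasta <- function(path, enz) {
  seqs <- read_fasta(path)
  mapply(function(s, nm) digest_sequence(s, enz, id = nm),
         seqs, names(seqs), SIMPLIFY = FALSE)
}
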