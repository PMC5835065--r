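# Plain-text interchange: tab-separated tables for genomic data, comma for
# chemistry, headers mandatory, UTF-8.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

#' Write a synthetic community to disk
#'
#' Writes `contigs.fasta`, `coverage.tsv` (contig_id + one column per
#' sample), `links.tsv` (`contig_a`, `contig_b`, `n_pairs`), `truth.tsv`
#' (`contig_id`, `genome_id`) and `markers.tsv` (`contig_id`, `marker_id`).
#'
#' @param community a [generate_community()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "nitrifier_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    contigs = file.path(dir, "contigs.fasta"),
    coverage = file.path(dir, "coverage.tsv"),
    links = file.path(dir, "links.tsv"),
    truth = file.path(dir, "truth.tsv"),
    markers = file.path(dir, "markers.tsv")
  )
  Biostrings::writeXStringSet(community$contigs$seqs, paths["contigs"])
  cov <- data.frame(contig_id = rownames(community$coverage),
                    community$coverage, check.names = FALSE)
  write_tsv(cov, paths["coverage"])
  write_tsv(community$links, paths["links"])
  write_tsv(data.frame(contig_id = names(community$contigs$truth),
                       genome_id = unname(community$contigs$truth)),
            paths["truth"])
  write_tsv(community$contigs$markers, paths["markers"])
  invisible(paths)
}

#' Read a coverage table
#'
#' @param path TSV with `contig_id` plus one numeric column per sample.
#' @return numeric matrix with contig ids as row names.
#' @export
read_coverage_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, setdiff(names(df), "contig_id"), drop = FALSE])
  rownames(m) <- df$contig_id
  m
}

#' Read a paired-end link table
#' @param path TSV with `contig_a`, `contig_b`, `n_pairs`.
#' @return data frame.
#' @export
read_links_tsv <- function(path) read_tsv(path, colClasses = c(
  contig_a = "character", contig_b = "character", n_pairs = "integer"))

#' Read a truth-label table
#' @param path TSV with `contig_id`, `genome_id`.
#' @return named character vector (contig to genome).
#' @export
read_truth_tsv <- function(path) {
  df <- read_tsv(path)
  setNames(df$genome_id, df$contig_id)
}

#' Read a marker-placement table
#' @param path TSV with `contig_id`, `marker_id`.
#' @return data frame.
#' @export
read_markers_tsv <- function(path) read_tsv(path)

#' Read contigs from FASTA
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_contigs_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write or read bottle-chemistry growth curves
#'
#' CSV schema: `time_h, nh4_uM, no2_uM, no3_uM, replicate`.
#'
#' @param curves a [growth_curve()] or a list of them.
#' @param path CSV path.
#' @return `write_curves_csv` returns the path invisibly;
#'   `read_curves_csv` a list of `growth_curve` objects, one per replicate.
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, "growth_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    out <- data.frame(time_h = cv$time_h)
    out$nh4_uM <- if ("nh4_uM" %in% names(cv)) cv$nh4_uM else NA_real_
    out$no2_uM <- if ("no2_uM" %in% names(cv)) cv$no2_uM else NA_real_
    out$no3_uM <- if ("no3_uM" %in% names(cv)) cv$no3_uM else NA_real_
    out$replicate <- cv$replicate
    out
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$replicate), function(d) {
    growth_curve(d$time_h,
                 nh4_uM = if (all(is.na(d$nh4_uM))) NULL else d$nh4_uM,
                 no2_uM = if (all(is.na(d$no2_uM))) NULL else d$no2_uM,
                 no3_uM = if (all(is.na(d$no3_uM))) NULL else d$no3_uM,
                 replicate = d$replicate[1])
  })
}

#' Read a qPCR table
#'
#' CSV schema: `role` (`standard` or `unknown`), `log10_copies` (NA for
#' unknowns), `ct`.
#'
#' @param path CSV path.
#' @return list with `standards` (data frame) and `unknowns` (Ct vector).
#' @export
read_qpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(standards = df[df$role == "standard", c("log10_copies", "ct")],
       unknowns = df$ct[df$role == "unknown"])
}

#' Published kinetic constants of the three nitrifying cultures
#'
#' The printed study constants used as simulation defaults: maximum specific
#' growth rate, ammonium/nitrite half-saturation constant, and lag duration
#' at the lowest substrate dose (50 uM) for the coupled culture (AOB + NOB),
#' the ammonia-oxidiser-only culture, and the nitrite-oxidiser-only culture.
#' The NOB culture's Monod pair is flagged `ks_derived`: only its rate range
#' over the dose grid was printed (the Monod fit was reported as poor), so
#' `mu_max` and `ks` are back-calculated from the two printed rate
#' endpoints.
#'
#' @return data frame with columns `culture`, `guild`, `partner_present`,
#'   `mu_max_h`, `ks_uM`, `lag50_h`, `ks_derived`.
#' @export
reference_kinetics <- function() {
  path <- system.file("extdata", "reference_kinetics.csv",
                      package = "nitrobin", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
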