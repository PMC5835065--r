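# Canonical 4-mer machinery: 256 raw 4-mers collapse onto 136 canonical keys
# (16 palindromes + 120 strand pairs), each the lexicographically smaller of
# a 4-mer and its reverse complement.
canonical_tnf_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4L)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(kmers)))
      map <<- setNames(pmin(kmers, rc), kmers)
    }
    map
  }
})

collapse_canonical <- function(counts256) {
  map <- canonical_tnf_map()
  keys <- sort(unique(map))
  if (is.matrix(counts256)) {
    out <- t(rowsum(t(counts256[, names(map), drop = FALSE]), group = map))
    out[, keys, drop = FALSE]
  } else {
    rowsum(counts256[names(map)], group = map)[keys, ]
  }
}

#' Canonical tetranucleotide frequencies of a sequence
#'
#' Counts every width-4 sliding window (step 1), maps each 4-mer to the
#' lexicographically smaller of itself and its reverse complement (136
#' canonical keys), and normalises the counts to sum to one. Windows
#' containing non-ACGT symbols are skipped.
#'
#' @param sequence a character scalar or [Biostrings::DNAString].
#' @param id optional contig id used in error messages.
#' @return named numeric vector of length 136 summing to 1.
#' @export
#' @examples
#' v <- tetranucleotide_freqs("ACGTACGTAC")
#' sum(v)
tetranucleotide_freqs <- function(sequence, id = NULL) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  counts <- Biostrings::oligonucleotideFrequency(sequence, width = 4L)
  total <- sum(counts)
  if (total == 0) {
    stop("no valid 4-mer window in contig ",
         if (is.null(id)) "(unnamed)" else id)
  }
  collapse_canonical(counts) / total
}

#' GC content of a sequence
#'
#' (G + C) / (A + C + G + T); ambiguous symbols are excluded from both
#' numerator and denominator.
#'
#' @inheritParams tetranucleotide_freqs
#' @return GC fraction in \[0, 1\].
#' @export
gc_content <- function(sequence, id = NULL) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  f <- Biostrings::letterFrequency(sequence, c("A", "C", "G", "T"))
  total <- sum(f)
  if (total == 0) {
    stop("no A/C/G/T symbol in contig ",
         if (is.null(id)) "(unnamed)" else id)
  }
  unname((f[["C"]] + f[["G"]]) / total)
}

#' Per-contig composition features
#'
#' Vectorised GC and canonical tetranucleotide frequencies for a whole
#' contig set.
#'
#' @param seqs a named [Biostrings::DNAStringSet].
#' @return list with `gc` (named vector) and `tnf`
#'   (contigs x 136 matrix, rows summing to 1).
#' @export
contig_features <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = 4L)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("no valid 4-mer window in contig ",
         paste(names(seqs)[totals == 0], collapse = ", "))
  }
  tnf <- collapse_canonical(counts) / totals
  rownames(tnf) <- names(seqs)
  acgt <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  gc <- (acgt[, "C"] + acgt[, "G"]) / rowSums(acgt)
  names(gc) <- names(seqs)
  list(gc = gc, tnf = tnf)
}

#' Depth-normalise and log-transform a coverage matrix
#'
#' Scales every sample column so all column sums equal the largest column
#' sum (removing per-sample sequencing-depth differences), then applies
#' `log10(x + pseudocount)` to stabilise the multiplicative depth noise.
#'
#' @param cov non-negative contigs x samples matrix.
#' @param pseudocount positive value added before the log.
#' @return transformed matrix of the same shape.
#' @export
prepare_coverage <- function(cov, pseudocount = 1) {
  cov <- as.matrix(cov)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(cov < 0)) stop("coverage values must be non-negative")
  if (ncol(cov) < 2) stop("differential binning needs at least 2 samples")
  cs <- colSums(cov)
  if (any(cs == 0)) {
    stop("degenerate all-zero sample column: ",
         paste(colnames(cov)[cs == 0], collapse = ", "))
  }
  scaled <- sweep(cov, 2L, max(cs) / cs, `*`)
  log10(scaled + pseudocount)
}

#' Classical (Torgerson) multidimensional scaling of coverage profiles
#'
#' Embeds the rows of `X` by classical scaling of their Euclidean distance
#' matrix: double-centre the squared distances, take the top-`d` eigenpairs,
#' and scale eigenvectors by the square roots of the eigenvalues. Negative
#' eigenvalues are clamped to zero; if fewer than `d` positive eigenvalues
#' exist, the coordinates are padded with zero columns and flagged.
#'
#' @param X numeric matrix (rows are contigs); row names are preserved.
#' @param d target dimensionality (at least 1, at most `nrow(X) - 1`).
#' @return object of class `mds_embedding`: `coords` (n x d, centred),
#'   `eigenvalues` (length d, descending, non-negative), `padded` flag.
#' @export
classical_mds <- function(X, d = 2) {
  X <- as.matrix(X)
  if (d < 1) stop("d must be at least 1")
  if (nrow(X) < d + 1) stop("need at least d + 1 rows")
  fit <- suppressWarnings(cmdscale(dist(X), k = d, eig = TRUE))
  pts <- fit$points
  padded <- FALSE
  if (ncol(pts) < d) {
    pts <- cbind(pts, matrix(0, nrow(pts), d - ncol(pts)))
    padded <- TRUE
  }
  ev <- sort(fit$eig, decreasing = TRUE)[seq_len(d)]
  ev[ev < 0] <- 0
  rownames(pts) <- rownames(X)
  colnames(pts) <- sprintf("mds%d", seq_len(d))
  structure(list(coords = pts, eigenvalues = ev, padded = padded),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("Classical MDS embedding: %d points in %d dimensions\n",
              nrow(x$coords), ncol(x$coords)))
  cat("  eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  if (x$padded) cat("  note: padded with zero columns (rank-deficient)\n")
  invisible(x)
}

new_bin_assignment <- function(contig_id, bin, provenance, k = NA_integer_,
                               silhouette = NA_real_, degenerate = FALSE) {
  structure(
    data.frame(contig_id = contig_id, bin = as.integer(bin),
               provenance = provenance, stringsAsFactors = FALSE),
    class = c("bin_assignment", "data.frame"),
    k = k, silhouette = silhouette, degenerate = degenerate
  )
}

#' Cluster an embedding into genome bins
#'
#' Runs k-medoids (PAM) over the embedding coordinates for every `k` in
#' `[k_min, k_max]` and keeps the partition with the largest mean silhouette
#' width; silhouette ties break towards the smaller `k`. If all points are
#' identical the silhouette is undefined and a single bin is returned with a
#' degenerate-geometry flag.
#'
#' @param emb an [classical_mds()] embedding.
#' @param k_min,k_max search range for the number of bins
#'   (`2 <= k_min <= k_max < n`).
#' @param seed integer seed (the search is deterministic given the seed).
#' @return a `bin_assignment` data frame (`contig_id`, `bin`, `provenance`)
#'   with attributes `k`, `silhouette` and `degenerate`.
#' @export
cluster_bins <- function(emb, k_min = 2, k_max = 16, seed = 1) {
  stopifnot(inherits(emb, "mds_embedding"))
  X <- emb$coords
  n <- nrow(X)
  if (!(2 <= k_min && k_min <= k_max && k_max < n)) {
    stop("need 2 <= k_min <= k_max < number of contigs")
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  n_distinct <- nrow(unique(X))
  if (n_distinct == 1L) {
    return(new_bin_assignment(ids, 1L, "cluster", k = 1L,
                              degenerate = TRUE))
  }

  set.seed(seed)
  best <- NULL
  for (k in seq(k_min, min(k_max, n_distinct - 1L))) {
    fit <- tryCatch(cluster::pam(X, k = k), error = function(e) NULL)
    if (is.null(fit)) next
    sil <- fit$silinfo$avg.width
    if (is.null(best) || sil > best$sil + 1e-12) {
      best <- list(k = k, sil = sil, clustering = fit$clustering)
    }
  }
  if (is.null(best)) {
    return(new_bin_assignment(ids, 1L, "cluster", k = 1L, degenerate = TRUE))
  }
  new_bin_assignment(ids, best$clustering, "cluster", k = best$k,
                     silhouette = best$sil)
}

#' @export
print.bin_assignment <- function(x, ...) {
  n_bins <- length(unique(x$bin[!is.na(x$bin)]))
  cat(sprintf("Bin assignment: %d contigs in %d bins, %d unbinned\n",
              nrow(x), n_bins, sum(is.na(x$bin))))
  if (!is.na(attr(x, "silhouette"))) {
    cat(sprintf("  chosen k = %d (mean silhouette %.3f)\n",
                attr(x, "k"), attr(x, "silhouette")))
  }
  if (isTRUE(attr(x, "degenerate"))) {
    cat("  degenerate geometry: all points identical\n")
  }
  print(table(provenance = x$provenance))
  invisible(x)
}

#' Refine bins by sequence composition
#'
#' Flags composition outliers within each bin and moves them to the unbinned
#' state. A contig is an outlier if its GC deviates from the bin median by
#' more than `z_max` robust (MAD-scaled) deviations, or if its Euclidean
#' distance to the bin's median tetranucleotide vector exceeds the median
#' within-bin distance by more than `z_max` robust deviations. Bins with
#' fewer than 3 contigs are never pruned (insufficient statistics). The
#' operation is conservative: it never adds contigs to a bin and never
#' renames bins.
#'
#' @param bins a `bin_assignment`.
#' @param feats per-contig features from [contig_features()]; must cover
#'   every binned contig.
#' @param z_max robust-deviation threshold (default 3).
#' @return the refined `bin_assignment` (removed contigs carry provenance
#'   `"composition_removed"`).
#' @export
refine_by_composition <- function(bins, feats, z_max = 3) {
  stopifnot(inherits(bins, "bin_assignment"))
  if (z_max <= 0) stop("z_max must be positive")
  binned <- which(!is.na(bins$bin))
  missing <- setdiff(bins$contig_id[binned], names(feats$gc))
  if (length(missing) > 0) {
    stop("no features for binned contig(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  # MAD floors guard quantisation artefacts in near-identical bins
  gc_floor <- 0.002
  tnf_floor <- 1e-5
  for (b in unique(bins$bin[binned])) {
    idx <- which(!is.na(bins$bin) & bins$bin == b)
    if (length(idx) < 3L) next
    ids <- bins$contig_id[idx]
    gcs <- feats$gc[ids]
    gc_med <- median(gcs)
    gc_mad <- max(mad(gcs), gc_floor)
    tnf <- feats$tnf[ids, , drop = FALSE]
    tnf_med <- apply(tnf, 2L, median)
    d <- sqrt(rowSums(sweep(tnf, 2L, tnf_med)^2))
    d_med <- median(d)
    d_mad <- max(mad(d), tnf_floor)
    out <- abs(gcs - gc_med) > z_max * gc_mad | d > d_med + z_max * d_mad
    if (any(out)) {
      drop <- idx[out]
      bins$bin[drop] <- NA_integer_
      bins$provenance[drop] <- "composition_removed"
    }
  }
  bins
}

#' Recruit and reassign contigs by paired-end links
#'
#' One pass over the contigs (in lexicographic id order) against the frozen
#' pre-pass assignment, so decisions never cascade within the pass. An
#' unbinned contig is recruited to bin `b` when its links to `b` strictly
#' exceed `add_frac` of all its links and its total link count is at least
#' `min_links`. A binned contig moves to another bin `b'` when its links to
#' `b'` reach at least `reassign_frac` of its total and the total is at
#' least `min_links`.
#'
#' @param bins a `bin_assignment`.
#' @param links link-graph data frame (`contig_a`, `contig_b`, `n_pairs`).
#' @param add_frac recruitment majority threshold (default 0.5).
#' @param reassign_frac reassignment threshold (default 0.7);
#'   `0.5 <= add_frac <= reassign_frac <= 1`.
#' @param min_links minimum total link-pair count to act (default 2).
#' @return the updated `bin_assignment` (provenance `"link_recruited"` or
#'   `"link_reassigned"`).
#' @export
recruit_by_links <- function(bins, links, add_frac = 0.5,
                             reassign_frac = 0.7, min_links = 2) {
  stopifnot(inherits(bins, "bin_assignment"))
  if (!(0.5 <= add_frac && add_frac <= reassign_frac && reassign_frac <= 1)) {
    stop("need 0.5 <= add_frac <= reassign_frac <= 1")
  }
  if (min_links < 1) stop("min_links must be at least 1")
  if (nrow(links) == 0) return(bins)

  pre_bin <- setNames(bins$bin, bins$contig_id)
  # incidence list: per contig, pair counts to each partner
  ends <- rbind(
    data.frame(contig = links$contig_a, partner = links$contig_b,
               n = links$n_pairs),
    data.frame(contig = links$contig_b, partner = links$contig_a,
               n = links$n_pairs)
  )
  ends$partner_bin <- pre_bin[ends$partner]
  totals <- tapply(ends$n, ends$contig, sum)

  to_bin <- !is.na(ends$partner_bin)
  bin_counts <- tapply(ends$n[to_bin],
                       list(ends$contig[to_bin], ends$partner_bin[to_bin]),
                       sum)

  new_bin <- pre_bin
  new_prov <- setNames(bins$provenance, bins$contig_id)
  for (cid in sort(intersect(rownames(bin_counts), bins$contig_id))) {
    tot <- totals[[cid]]
    if (is.na(tot) || tot < min_links) next
    counts <- bin_counts[cid, ]
    counts[is.na(counts)] <- 0
    cur <- pre_bin[[cid]]
    if (is.na(cur)) {
      j <- which.max(counts)
      if (counts[j] > add_frac * tot) {
        new_bin[[cid]] <- as.integer(colnames(bin_counts)[j])
        new_prov[[cid]] <- "link_recruited"
      }
    } else {
      others <- counts[colnames(bin_counts) != as.character(cur)]
      if (length(others) > 0) {
        j <- which.max(others)
        if (others[j] >= reassign_frac * tot) {
          new_bin[[cid]] <- as.integer(names(others)[j])
          new_prov[[cid]] <- "link_reassigned"
        }
      }
    }
  }
  bins$bin <- unname(new_bin[bins$contig_id])
  bins$provenance <- unname(new_prov[bins$contig_id])
  bins
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items, from
#' the standard contingency-table formula.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return the ARI (1 for identical partitions, about 0 at chance level).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) == 0) stop("empty labelings")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Score a bin assignment against simulation truth
#'
#' @param bins a `bin_assignment`.
#' @param truth named character vector mapping every contig id to its true
#'   genome.
#' @return list with `ari` (adjusted Rand index over binned contigs),
#'   `per_bin` data frame (`bin`, `majority_genome`, `precision`, `recall`,
#'   `n_contigs`) and `unbinned_frac`.
#' @export
evaluate_bins <- function(bins, truth) {
  stopifnot(inherits(bins, "bin_assignment"))
  missing <- setdiff(bins$contig_id, names(truth))
  if (length(missing) > 0) {
    stop("truth does not cover contig(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  binned <- bins[!is.na(bins$bin), , drop = FALSE]
  if (nrow(binned) == 0) stop("empty assignment: no binned contigs")
  truth_binned <- truth[binned$contig_id]
  ari <- adjusted_rand_index(binned$bin, truth_binned)

  genome_sizes <- table(truth[bins$contig_id])
  per_bin <- do.call(rbind, lapply(sort(unique(binned$bin)), function(b) {
    tg <- truth_binned[binned$bin == b]
    maj <- names(sort(table(tg), decreasing = TRUE))[1]
    data.frame(bin = b, majority_genome = maj,
               precision = mean(tg == maj),
               recall = sum(tg == maj) / genome_sizes[[maj]],
               n_contigs = length(tg))
  }))
  list(ari = ari, per_bin = per_bin,
       unbinned_frac = mean(is.na(bins$bin)))
}

#' Marker-based bin quality
#'
#' Completeness and contamination against the planted single-copy marker
#' set: completeness is the percentage of distinct marker ids present in the
#' bin at least once; contamination is the percentage of excess marker
#' copies (total copies minus distinct ids) relative to the marker-set size.
#'
#' @param bins a `bin_assignment`.
#' @param markers placements data frame (`contig_id`, `marker_id`).
#' @param n_markers size of the planted marker set per genome.
#' @param contig_lengths optional named vector of contig lengths in bp, used
#'   to report per-bin total size.
#' @return data frame, one row per bin: `bin`, `completeness`,
#'   `contamination` (both percent), `n_contigs`, `total_bp`.
#' @export
marker_quality <- function(bins, markers, n_markers, contig_lengths = NULL) {
  stopifnot(inherits(bins, "bin_assignment"))
  if (n_markers < 1) stop("n_markers must be at least 1")
  bin_of <- setNames(bins$bin, bins$contig_id)
  out <- lapply(sort(unique(bins$bin[!is.na(bins$bin)])), function(b) {
    ids <- bins$contig_id[!is.na(bins$bin) & bins$bin == b]
    mk <- markers$marker_id[markers$contig_id %in% ids]
    distinct <- length(unique(mk))
    data.frame(
      bin = b,
      completeness = 100 * distinct / n_markers,
      contamination = 100 * (length(mk) - distinct) / n_markers,
      n_contigs = length(ids),
      total_bp = if (is.null(contig_lengths)) NA_real_ else
        sum(contig_lengths[ids])
    )
  })
  do.call(rbind, out)
}
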