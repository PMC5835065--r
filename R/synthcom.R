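#' Configuration for a synthetic nitrifier community
#'
#' Bundles and validates every knob of the synthetic metagenome generator.
#' The defaults mirror the study design the generator emulates: eight genomes
#' (the eight high-quality draft genomes recoverable from the coupled
#' culture), three sampling time points (days 1, 3 and 5 of a bottle
#' incubation), a 1.2 kb assembly floor on contig length, 20% multiplicative
#' coverage noise and a 2% spurious paired-end link rate. Two of the default
#' genomes ("nitrifier-like") have their abundance maximum at the middle time
#' point, as the targeted populations did in the mid-incubation samples.
#'
#' @param n_genomes number of genomes (at least 2).
#' @param genome_length_bp length of each genome in bp.
#' @param contig_min_bp minimum contig length (assembly floor), bp.
#' @param contig_mean_bp mean contig length of the shifted-exponential length
#'   law, bp; must exceed `contig_min_bp`.
#' @param n_timepoints number of coverage samples.
#' @param abundance_trajectories `n_genomes x n_timepoints` matrix of strictly
#'   positive expected mean depths. `NULL` uses [default_trajectories()].
#' @param coverage_noise_cv coefficient of variation of the multiplicative
#'   lognormal coverage noise.
#' @param links_per_contig mean number of intra-genome read-pair links per
#'   contig.
#' @param spurious_link_rate fraction of links drawn uniformly across all
#'   contigs regardless of genome, in \[0, 1\].
#' @param n_markers single-copy markers planted per genome.
#' @param gc_targets per-genome GC fraction in (0, 1); `NULL` spreads the
#'   genomes evenly over 0.38–0.62.
#' @param composition_order Markov order of the per-genome sequence model.
#' @param seed integer seed; the whole community is a deterministic function
#'   of the configuration including this seed.
#' @return a validated list of class `community_config`.
#' @export
#' @examples
#' cfg <- community_config(n_genomes = 4, genome_length_bp = 20000, seed = 1)
community_config <- function(n_genomes = 8,
                             genome_length_bp = 150000,
                             contig_min_bp = 1200,
                             contig_mean_bp = 3000,
                             n_timepoints = 3,
                             abundance_trajectories = NULL,
                             coverage_noise_cv = 0.2,
                             links_per_contig = 3,
                             spurious_link_rate = 0.02,
                             n_markers = 100,
                             gc_targets = NULL,
                             composition_order = 3,
                             seed = 1) {
  if (n_genomes < 2) stop("n_genomes must be at least 2")
  if (n_timepoints < 1) stop("n_timepoints must be at least 1")
  if (genome_length_bp <= 0 || contig_min_bp <= 0) {
    stop("genome and contig lengths must be positive")
  }
  if (contig_mean_bp <= contig_min_bp) {
    stop("contig_mean_bp must exceed contig_min_bp")
  }
  if (genome_length_bp < contig_min_bp) {
    stop("genome_length_bp must be at least contig_min_bp")
  }
  if (spurious_link_rate < 0 || spurious_link_rate > 1) {
    stop("spurious_link_rate must lie in [0, 1]")
  }
  if (coverage_noise_cv < 0) stop("coverage_noise_cv must be non-negative")
  if (n_markers < 1) stop("n_markers must be at least 1")
  if (composition_order < 1) stop("composition_order must be at least 1")

  if (is.null(abundance_trajectories)) {
    abundance_trajectories <- default_trajectories(n_genomes, n_timepoints)
  }
  abundance_trajectories <- as.matrix(abundance_trajectories)
  if (!all(dim(abundance_trajectories) == c(n_genomes, n_timepoints))) {
    stop("abundance_trajectories must be n_genomes x n_timepoints")
  }
  if (any(abundance_trajectories <= 0)) {
    stop("every abundance trajectory entry must be strictly positive")
  }

  if (is.null(gc_targets)) {
    gc_targets <- seq(0.38, 0.62, length.out = n_genomes)
  }
  if (length(gc_targets) != n_genomes || any(gc_targets <= 0) ||
      any(gc_targets >= 1)) {
    stop("gc_targets must be n_genomes values in (0, 1)")
  }

  structure(list(
    n_genomes = as.integer(n_genomes),
    genome_length_bp = as.integer(genome_length_bp),
    contig_min_bp = as.integer(contig_min_bp),
    contig_mean_bp = as.integer(contig_mean_bp),
    n_timepoints = as.integer(n_timepoints),
    abundance_trajectories = abundance_trajectories,
    coverage_noise_cv = coverage_noise_cv,
    links_per_contig = links_per_contig,
    spurious_link_rate = spurious_link_rate,
    n_markers = as.integer(n_markers),
    gc_targets = gc_targets,
    composition_order = as.integer(composition_order),
    seed = as.integer(seed)
  ), class = "community_config")
}

#' Default per-genome abundance trajectories
#'
#' Deterministic trajectories with well-separated log-coverage profiles:
#' genomes cycle through five shapes (mid-point peak, rise, fall, flat,
#' mid-point dip) at geometrically increasing depth scales. The first genome
#' of each scale block peaks at the middle time point, so with the default
#' eight genomes two "nitrifier-like" genomes are mid-point maximal.
#'
#' @param n_genomes,n_timepoints community dimensions.
#' @return an `n_genomes x n_timepoints` matrix of mean depths.
#' @export
default_trajectories <- function(n_genomes, n_timepoints) {
  x <- if (n_timepoints == 1) 0.5 else seq(0, 1, length.out = n_timepoints)
  shapes <- list(
    function(x) 1 + 4 * sin(pi * x),        # mid-point peak
    function(x) exp(2.5 * x),               # rise
    function(x) exp(2.5 * (1 - x)),         # fall
    function(x) rep(1, length(x)),          # flat
    function(x) 1 + 4 * abs(2 * x - 1)      # mid-point dip
  )
  traj <- matrix(0, n_genomes, n_timepoints)
  for (g in seq_len(n_genomes)) {
    shape <- shapes[[(g - 1L) %% 5L + 1L]]
    scale <- 4 * 4^((g - 1L) %/% 5L)
    traj[g, ] <- scale * shape(x)
  }
  rownames(traj) <- sprintf("g%02d", seq_len(n_genomes))
  traj
}

# GC-constrained random transition table for one genome: each context gets
# its own next-base law, but P(G or C) equals gc exactly in every context, so
# the expected GC of the chain is the target while the 4-mer signature stays
# genome-specific.
genome_transition_cumprob <- function(gc, order) {
  ncontext <- 4L^order
  w <- matrix(rgamma(ncontext * 4L, shape = 1), ncontext, 4L)  # A C G T
  at <- w[, c(1L, 4L)] / rowSums(w[, c(1L, 4L), drop = FALSE])
  cg <- w[, c(2L, 3L)] / rowSums(w[, c(2L, 3L), drop = FALSE])
  p <- cbind((1 - gc) * at[, 1L], gc * cg[, 1L], gc * cg[, 2L],
             (1 - gc) * at[, 2L])
  cp <- t(apply(p, 1L, cumsum))
  cp[, 4L] <- 1
  cp
}

# One genome sequence as a character scalar.
generate_genome_sequence <- function(length_bp, gc, order) {
  cp <- genome_transition_cumprob(gc, order)
  init <- sample.int(4L, order, replace = TRUE) - 1L
  u <- runif(length_bp - order)
  bases <- markov_sample_bases(cp, init, u)
  paste(c("A", "C", "G", "T")[c(init, bases) + 1L], collapse = "")
}

# Shifted-exponential contig lengths partitioning one genome; a short
# terminal remainder is folded into the previous contig.
draw_contig_lengths <- function(genome_length_bp, min_bp, mean_bp) {
  n_draw <- max(2L, ceiling(genome_length_bp / min_bp))
  lens <- round(min_bp + rexp(n_draw, rate = 1 / (mean_bp - min_bp)))
  ends <- cumsum(lens)
  keep <- which(ends < genome_length_bp)
  lens <- lens[keep]
  rest <- genome_length_bp - sum(lens)
  if (rest >= min_bp || length(lens) == 0L) {
    lens <- c(lens, rest)
  } else {
    lens[length(lens)] <- lens[length(lens)] + rest
  }
  lens
}

#' Generate a labelled synthetic metagenome
#'
#' Produces the three inputs the binner consumes, with full ground truth:
#' contig sequences (per-genome Markov chains hitting genome-specific GC
#' targets, fragmented by a shifted-exponential length law with a hard
#' minimum), a contigs-by-timepoints coverage matrix (expected mean depth
#' follows each genome's abundance trajectory, independent of contig length,
#' times multiplicative lognormal noise of the configured CV), and a
#' paired-end link graph (intra-genome links plus a configured fraction of
#' spurious links drawn uniformly across all contigs). Single-copy markers
#' are planted with [plant_markers()].
#'
#' The output is a deterministic function of the configuration: re-running
#' with the same `community_config` reproduces it exactly.
#'
#' @param config a [community_config()].
#' @return a list of class `nitrifier_community` with elements
#'   \describe{
#'     \item{contigs}{`contig_set`: named [Biostrings::DNAStringSet] `seqs`,
#'       named character `truth` (contig to genome), and `markers`
#'       data frame (`contig_id`, `marker_id`).}
#'     \item{coverage}{numeric matrix, contigs x timepoints, mean depths.}
#'     \item{links}{data frame `contig_a`, `contig_b`, `n_pairs`
#'       (unordered edges, no self links).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' com <- generate_community(community_config(n_genomes = 4,
#'   genome_length_bp = 20000, seed = 7))
#' table(com$contigs$truth)
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)

  genome_ids <- rownames(config$abundance_trajectories)
  if (is.null(genome_ids)) {
    genome_ids <- sprintf("g%02d", seq_len(config$n_genomes))
  }

  seqs <- character(0)
  truth <- character(0)
  for (g in seq_len(config$n_genomes)) {
    gseq <- generate_genome_sequence(config$genome_length_bp,
                                     config$gc_targets[g],
                                     config$composition_order)
    lens <- draw_contig_lengths(config$genome_length_bp,
                                config$contig_min_bp, config$contig_mean_bp)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    ids <- sprintf("%s_c%04d", genome_ids[g], seq_along(lens))
    pieces <- substring(gseq, starts, ends)
    names(pieces) <- ids
    seqs <- c(seqs, pieces)
    truth <- c(truth, setNames(rep(genome_ids[g], length(ids)), ids))
  }
  contig_ids <- names(seqs)
  n_contigs <- length(contig_ids)

  # coverage: expected depth per genome per timepoint, lognormal noise with
  # unit mean so the trajectory is recovered in expectation
  expected <- config$abundance_trajectories[match(truth, genome_ids), ,
                                            drop = FALSE]
  cv <- config$coverage_noise_cv
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- matrix(rlnorm(n_contigs * config$n_timepoints,
                           meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    n_contigs, config$n_timepoints)
  } else {
    noise <- matrix(1, n_contigs, config$n_timepoints)
  }
  coverage <- expected * noise
  dimnames(coverage) <- list(contig_ids,
                             sprintf("t%d", seq_len(config$n_timepoints)))

  links <- generate_links(truth, genome_ids, config$links_per_contig,
                          config$spurious_link_rate)

  contigs <- structure(list(
    seqs = Biostrings::DNAStringSet(seqs),
    truth = truth,
    markers = data.frame(contig_id = character(0), marker_id = integer(0))
  ), class = "contig_set")
  contigs <- plant_markers(contigs, config$n_markers,
                           seed = config$seed + 1L)

  structure(list(contigs = contigs, coverage = coverage, links = links,
                 config = config),
            class = "nitrifier_community")
}

# Paired-end link edges. Each link is intra-genome (genome chosen with
# probability proportional to contig count) unless flagged spurious, in which
# case both endpoints are uniform over all contigs: the worst-case confounder
# for link-based recruitment.
generate_links <- function(truth, genome_ids, links_per_contig,
                           spurious_rate) {
  n_contigs <- length(truth)
  contig_ids <- names(truth)
  by_genome <- split(contig_ids, factor(truth, levels = genome_ids))
  eligible <- names(by_genome)[vapply(by_genome, length, 1L) >= 2L]
  n_links <- round(links_per_contig * n_contigs / 2)
  if (n_links < 1 || length(eligible) == 0L) {
    return(data.frame(contig_a = character(0), contig_b = character(0),
                      n_pairs = integer(0)))
  }
  spurious <- runif(n_links) < spurious_rate
  a <- character(n_links)
  b <- character(n_links)
  sizes <- vapply(by_genome[eligible], length, 1L)
  g_pick <- eligible[sample.int(length(eligible), n_links, replace = TRUE,
                                prob = sizes)]
  for (i in seq_len(n_links)) {
    if (spurious[i] && n_contigs >= 2L) {
      pair <- sample(contig_ids, 2L)
    } else {
      pair <- sample(by_genome[[g_pick[i]]], 2L)
    }
    a[i] <- min(pair)
    b[i] <- max(pair)
  }
  agg <- table(paste(a, b, sep = "\r"))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(
    contig_a = vapply(parts, `[`, "", 1L),
    contig_b = vapply(parts, `[`, "", 2L),
    n_pairs = as.integer(agg),
    row.names = NULL
  )
  edges[order(edges$contig_a, edges$contig_b), , drop = FALSE]
}

#' Plant single-copy markers on a contig set
#'
#' Gives every truth genome one copy of each marker id `1..n_markers`, placed
#' on a uniformly random contig of that genome. This is the planted-truth
#' stand-in for a universal single-copy marker-gene set: a perfectly
#' recovered bin holds every marker id exactly once.
#'
#' @param contigs a `contig_set` with truth labels.
#' @param n_markers markers per genome (at least 1).
#' @param seed integer seed for the placements.
#' @return the `contig_set` with its `markers` data frame replaced.
#' @export
plant_markers <- function(contigs, n_markers, seed = 1) {
  stopifnot(inherits(contigs, "contig_set"))
  if (n_markers < 1) stop("n_markers must be at least 1")
  set.seed(seed)
  by_genome <- split(names(contigs$truth), contigs$truth)
  empty <- vapply(by_genome, length, 1L) < 1L
  if (any(empty)) {
    stop("genome(s) without contigs: ", paste(names(by_genome)[empty],
                                              collapse = ", "))
  }
  placements <- lapply(names(by_genome), function(g) {
    ids <- by_genome[[g]]
    data.frame(
      contig_id = if (length(ids) == 1L) rep(ids, n_markers) else
        sample(ids, n_markers, replace = TRUE),
      marker_id = seq_len(n_markers)
    )
  })
  contigs$markers <- do.call(rbind, placements)
  rownames(contigs$markers) <- NULL
  contigs
}

#' @export
print.nitrifier_community <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic nitrifier community\n")
  cat(sprintf("  %d genomes, %d contigs, %d timepoints (seed %d)\n",
              cfg$n_genomes, length(x$contigs$seqs), cfg$n_timepoints,
              cfg$seed))
  cat(sprintf("  coverage noise CV %.2f, spurious link rate %.2f\n",
              cfg$coverage_noise_cv, cfg$spurious_link_rate))
  cat(sprintf("  %d link edges, %d planted marker placements\n",
              nrow(x$links), nrow(x$contigs$markers)))
  invisible(x)
}
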