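# Orchestration: configuration handling, per-stage seed expansion, logging,
# and the two end-to-end drivers.

# Per-stage seeds derived from one global seed by a fixed counter scheme, so
# any stage can be re-run in isolation with a reproducible stream. Kept
# within the 31-bit integer range.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage) %% 2147483647)
}

# Merge a user configuration into defaults, rejecting unknown keys at every
# nesting level.
merge_config <- function(defaults, config, path = "config") {
  if (is.null(config)) return(defaults)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in names(config)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], config[[key]],
                                      paste(path, key, sep = "$"))
    } else {
      defaults[[key]] <- config[[key]]
    }
  }
  defaults
}

open_run_log <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  unlink(log_path)
  function(...) {
    line <- paste0(...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
    invisible(line)
  }
}

write_resolved_config <- function(config, out_dir) {
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Default configuration of the binning pipeline
#'
#' Community block: see [community_config()]. Binning block: embedding
#' dimensionality `d` (kept at the number of timepoints so no coverage
#' signal is projected away), k-medoids search range, composition
#' refinement threshold `z_max`, link recruitment thresholds, and the
#' coverage pseudocount.
#'
#' @return nested list of defaults.
#' @export
default_binning_config <- function() {
  list(
    community = list(
      n_genomes = 8L, genome_length_bp = 150000L, contig_min_bp = 1200L,
      contig_mean_bp = 3000L, n_timepoints = 3L, coverage_noise_cv = 0.2,
      links_per_contig = 3, spurious_link_rate = 0.02, n_markers = 100L,
      composition_order = 3L
    ),
    binning = list(
      d = 3L, k_min = 2L, k_max = 16L, z_max = 3, add_frac = 0.5,
      reassign_frac = 0.7, min_links = 2L, pseudocount = 1
    )
  )
}

#' Run the full simulation-to-evaluation binning pipeline
#'
#' Stages, in order: synthetic community generation, input files written to
#' disk, coverage normalisation + log transform, classical MDS, k-medoids
#' clustering with silhouette model selection, composition refinement,
#' paired-end recruitment, truth evaluation (ARI) and marker-based quality
#' scoring. Every output directory receives the resolved configuration, a
#' log, the bin map (`bins.tsv`: `contig_id`, `bin_id`, `provenance`), the
#' quality table (`quality.tsv`) and a metrics report (`metrics.json`). The
#' whole run is a deterministic function of (config, seed).
#'
#' @param config optional (possibly partial) configuration overriding
#'   [default_binning_config()]; unknown keys are rejected.
#' @param out_dir output directory.
#' @param seed global seed, expanded to per-stage seeds.
#' @return invisibly, a list with `bins`, `quality`, `metrics` and `paths`.
#' @export
run_binning_pipeline <- function(config = NULL, out_dir = tempfile("binrun"),
                                 seed = 1) {
  cfg <- merge_config(default_binning_config(), config)
  log <- open_run_log(out_dir)
  resolved <- c(cfg, list(seed = seed))
  write_resolved_config(resolved, out_dir)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  log("binning pipeline: seed ", seed)
  com <- run_stage("community", {
    cc <- do.call(community_config,
                  c(cfg$community, list(seed = stage_seed(seed, 1L))))
    generate_community(cc)
  })
  log("community: ", length(com$contigs$seqs), " contigs from ",
      cfg$community$n_genomes, " genomes")
  input_paths <- run_stage("write-inputs",
                           write_community(com, file.path(out_dir, "inputs")))

  b <- cfg$binning
  emb <- run_stage("mds", {
    X <- prepare_coverage(com$coverage, pseudocount = b$pseudocount)
    classical_mds(X, d = min(b$d, ncol(X)))
  })
  bins <- run_stage("cluster",
                    cluster_bins(emb, k_min = b$k_min, k_max = b$k_max,
                                 seed = stage_seed(seed, 2L)))
  log("clustering: k = ", attr(bins, "k"), ", mean silhouette ",
      round(attr(bins, "silhouette"), 3))
  feats <- run_stage("features", contig_features(com$contigs$seqs))
  bins <- run_stage("refine",
                    refine_by_composition(bins, feats, z_max = b$z_max))
  bins <- run_stage("recruit",
                    recruit_by_links(bins, com$links, add_frac = b$add_frac,
                                     reassign_frac = b$reassign_frac,
                                     min_links = b$min_links))
  metrics <- run_stage("evaluate", evaluate_bins(bins, com$contigs$truth))
  quality <- run_stage("quality", {
    lens <- setNames(Biostrings::width(com$contigs$seqs),
                     names(com$contigs$seqs))
    marker_quality(bins, com$contigs$markers, cfg$community$n_markers,
                   contig_lengths = lens)
  })
  log("evaluation: ARI ", round(metrics$ari, 4), ", unbinned fraction ",
      round(metrics$unbinned_frac, 4))

  paths <- c(
    input_paths,
    bins = file.path(out_dir, "bins.tsv"),
    quality = file.path(out_dir, "quality.tsv"),
    metrics = file.path(out_dir, "metrics.json")
  )
  write_tsv(data.frame(contig_id = bins$contig_id,
                       bin_id = ifelse(is.na(bins$bin), "UNBINNED",
                                       as.character(bins$bin)),
                       provenance = bins$provenance),
            paths["bins"])
  write_tsv(quality, paths["quality"])
  jsonlite::write_json(
    list(seed = seed, k = attr(bins, "k"), ari = metrics$ari,
         unbinned_frac = metrics$unbinned_frac,
         n_bins = nrow(quality),
         completeness = quality$completeness,
         contamination = quality$contamination),
    paths["metrics"], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(bins = bins, quality = quality, metrics = metrics,
                 community = com, paths = paths))
}

#' Default configuration of the kinetics pipeline
#'
#' One simulated dose-response experiment per culture in
#' [reference_kinetics()], over the published substrate grid (50, 200, 500,
#' 1000, 1500 uM). Each bottle is simulated with a small inoculum
#' (`x0 / yield` far below the dose, so the substrate stays effectively at
#' its initial concentration throughout the regression window), sampled at
#' `n_obs` evenly spaced times over an assay horizon of `horizon_e_folds`
#' e-folds of the culture's maximum rate.
#'
#' @return nested list of defaults.
#' @export
default_kinetics_config <- function() {
  list(
    substrate_grid = c(50, 200, 500, 1000, 1500),
    assay = list(
      x0 = 1e-4, yield = 1, n_obs = 60L, horizon_e_folds = 8,
      noise_cv = 0, r2_min = 0.99, min_points = 4L, dt_factor = 0.1
    ),
    cultures = NULL  # NULL = all cultures in reference_kinetics()
  )
}

# One dose-response bottle: the culture's guild grows alone on its substrate.
simulate_assay_bottle <- function(culture, S0, assay, seed) {
  horizon <- ceiling(assay$horizon_e_folds / culture$mu_max_h / 10) * 10
  t_end <- culture$lag50_h + horizon
  obs_times <- seq(0, t_end, length.out = assay$n_obs)
  dt <- (obs_times[2] - obs_times[1]) * assay$dt_factor
  if (culture$guild == "AOB") {
    params <- cascade_params(
      mu_max_a = culture$mu_max_h, ks_a = culture$ks_uM,
      yield_a = assay$yield, x_a0 = assay$x0, x_b0 = 0,
      lag_a = culture$lag50_h, nh4_0 = S0, no2_0 = 0, no3_0 = 0,
      t_end = t_end, dt = dt, noise_cv = assay$noise_cv, seed = seed)
  } else {
    params <- cascade_params(
      mu_max_b = culture$mu_max_h, ks_b = culture$ks_uM,
      yield_b = assay$yield, x_b0 = assay$x0, x_a0 = 0,
      lag_b = culture$lag50_h, nh4_0 = 0, no2_0 = S0, no3_0 = 0,
      t_end = t_end, dt = dt, noise_cv = assay$noise_cv, seed = seed)
  }
  simulate_cascade(params, obs_times = obs_times)
}

#' Run the dose-response kinetics pipeline
#'
#' For every culture and substrate dose, simulates a bottle with the
#' culture's kinetic parameters, extracts the oxidation-product series,
#' selects the exponential window under the R-squared acceptance rule,
#' estimates the growth rate and lag, and finally fits the Monod model to
#' the per-culture (dose, rate) pairs. Writes `rates.csv` (per bottle),
#' `monod.csv` (per culture), the resolved configuration and a log.
#'
#' @param config optional overrides of [default_kinetics_config()].
#' @param out_dir output directory.
#' @param seed global seed.
#' @return invisibly, list with `rates` (data frame), `monod` (data frame),
#'   `fits` (list of [fit_monod()] objects) and `paths`.
#' @export
run_kinetics_pipeline <- function(config = NULL,
                                  out_dir = tempfile("kinrun"), seed = 1) {
  cfg <- merge_config(default_kinetics_config(), config)
  log <- open_run_log(out_dir)
  write_resolved_config(c(cfg, list(seed = seed)), out_dir)

  ref <- reference_kinetics()
  if (!is.null(cfg$cultures)) {
    ref <- ref[ref$culture %in% cfg$cultures, , drop = FALSE]
  }
  if (nrow(ref) == 0) stop("stage 'cultures' failed: no cultures selected")

  rates <- NULL
  fits <- list()
  for (ci in seq_len(nrow(ref))) {
    culture <- ref[ci, ]
    log("culture ", culture$culture, " (", culture$guild, "), grid: ",
        paste(cfg$substrate_grid, collapse = ", "), " uM")
    for (si in seq_along(cfg$substrate_grid)) {
      S0 <- cfg$substrate_grid[si]
      sim <- tryCatch(
        simulate_assay_bottle(culture, S0, cfg$assay,
                              seed = stage_seed(seed, ci * 100L + si)),
        error = function(e) stop("stage 'simulate' failed: ",
                                 conditionMessage(e), call. = FALSE))
      gf <- tryCatch(
        estimate_growth(sim$curve, guild = culture$guild,
                        r2_min = cfg$assay$r2_min,
                        min_points = cfg$assay$min_points),
        error = function(e) stop("stage 'growth-rate' failed: ",
                                 conditionMessage(e), call. = FALSE))
      rates <- rbind(rates, data.frame(
        culture = culture$culture, guild = culture$guild, S_uM = S0,
        mu_h = gf$mu, r2 = gf$r2, lag_h = gf$lag_h,
        n_points = gf$n_points))
    }
    sub <- rates[rates$culture == culture$culture, ]
    fits[[culture$culture]] <- tryCatch(
      fit_monod(sub$S_uM, sub$mu_h),
      error = function(e) stop("stage 'monod' failed: ",
                               conditionMessage(e), call. = FALSE))
    log("  Monod: mu_max ", signif(fits[[culture$culture]]$mu_max, 4),
        " /h, ks ", signif(fits[[culture$culture]]$ks, 4), " uM")
  }

  monod <- do.call(rbind, lapply(names(fits), function(cu) {
    f <- fits[[cu]]
    data.frame(culture = cu, mu_max_h = f$mu_max, ks_uM = f$ks,
               rss = f$rss, converged = f$converged, n_obs = f$n_obs,
               lag50_h = rates$lag_h[rates$culture == cu &
                                       rates$S_uM == min(rates$S_uM)])
  }))

  paths <- c(rates = file.path(out_dir, "rates.csv"),
             monod = file.path(out_dir, "monod.csv"))
  utils::write.csv(rates, paths["rates"], row.names = FALSE, quote = FALSE)
  utils::write.csv(monod, paths["monod"], row.names = FALSE, quote = FALSE)
  invisible(list(rates = rates, monod = monod, fits = fits, paths = paths))
}
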