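# Shared fixture builders; everything is generated in code at test time.

# A small, fast community for property-style loops.
small_config <- function(seed, ...) {
  community_config(n_genomes = 4, genome_length_bp = 30000,
                   n_markers = 20, seed = seed, ...)
}

# Directly construct a bin assignment for stage-level unit tests.
make_bins <- function(ids, bin, provenance = "cluster") {
  nitrobin:::new_bin_assignment(ids, bin, provenance)
}

# Multiplicative lognormal noise with unit mean and the given CV.
ln_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Published dose grid used across the kinetics tests.
substrate_grid <- c(50, 200, 500, 1000, 1500)
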