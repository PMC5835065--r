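---
title: "Models and methods of the nitrifier workbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the nitrifier workbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nitrobin` packages two analyses that usually live in ad hoc scripts around
nitrifier enrichment studies — multi-timepoint differential-coverage genome
binning and bottle-experiment growth kinetics — together with the synthetic
generators needed to validate them against known truth. This vignette is
the package's own account of the models, the choices behind their defaults,
and what passing tests do and do not establish.

## 1. The synthetic community generator

`generate_community()` emulates the inputs a binner sees after assembly and
read mapping, without simulating reads:

* **Sequences.** Each genome is an order-3 Markov chain over {A,C,G,T}
  with its own random transition table, constrained so that every context
  emits G or C with exactly the genome's target GC fraction. This yields
  genomes that differ both in GC and in tetranucleotide signature — the two
  composition features the refinement stage uses. The default GC targets
  spread eight genomes evenly over 0.38–0.62, a realistic span for a
  freshwater enrichment. The Markov order is tunable
  (`composition_order`); order 3 is the smallest order that gives
  distinguishable 4-mer signatures.
* **Contigs.** Genomes are fragmented by a shifted-exponential length law
  with a hard floor of 1,200 bp (the assembly minimum of the study design
  this emulates) and a mean of 3,000 bp. Exponential-like length decay is
  what short-read assemblies of uneven communities produce; chimeric
  contigs and assembly graphs are out of scope.
* **Coverage.** The binner's signal is mean depth per contig per sample.
  Expected depth equals the genome's abundance trajectory value at that
  time point — independent of contig length, because mean depth already
  normalises length — and observed depth multiplies it by lognormal noise
  with unit mean and configurable CV (default 0.2). Depth noise is
  multiplicative and positive, which is exactly what a lognormal gives;
  read-count (Poisson) granularity is not modelled.
* **Trajectories.** The study design samples three time points, and the
  real nitrifier populations peaked mid-incubation. The default
  trajectories (`default_trajectories()`) cycle five shapes (mid-point
  peak, rise, fall, flat, mid-point dip) over geometrically increasing
  depth scales, so with eight genomes two "nitrifier-like" genomes are
  mid-point maximal. The true abundance dynamics of the real populations
  are unpublished; these defaults are a deliberate construction chosen for
  well-separated log-coverage profiles, not a reconstruction.
* **Links.** Paired-end information is reduced to an unordered contig
  graph with per-edge read-pair counts. Each link is intra-genome unless
  flagged spurious (default rate 2%), in which case both endpoints are
  uniform over *all* contigs — the worst case for link-based recruitment,
  since a spurious link is indistinguishable from a true one.
* **Markers.** Bin quality needs a marker set; instead of a curated
  lineage-specific database the generator plants `n_markers` (default 100)
  single-copy markers per genome on uniformly random contigs. Completeness
  and contamination against planted markers behave like their real
  counterparts but are not calibrated to any real marker catalogue.

Everything is a deterministic function of the configuration, including its
seed; the marker stage draws from a seed offset by one so it can be re-run
in isolation.

## 2. Binning

The pipeline mirrors the stages of differential-coverage binning, with
every manual or visual step replaced by an explicit rule:

1. **Transform** (`prepare_coverage`): per-sample depth normalisation
   (columns scaled to the maximum column sum) followed by
   `log10(x + 1)`. The log stabilises multiplicative depth noise; the
   pseudocount of 1 keeps zero coverage finite and maps it to 0. Distances
   between contigs are invariant to the normalisation constant (a
   per-column additive shift in log space), so the choice of scaling
   target is cosmetic.
2. **Embed** (`classical_mds`): Torgerson classical scaling of Euclidean
   distances, computed via `stats::cmdscale`. Negative eigenvalues are
   clamped to zero; if fewer positive eigenvalues exist than requested
   dimensions, zero columns pad the coordinates and the embedding is
   flagged. The pipeline default keeps `d` equal to the number of samples
   (3), so no coverage signal is projected away; classical MDS on a full-
   rank Euclidean configuration is then exact, which the tests verify at
   1e-9.
3. **Cluster** (`cluster_bins`): k-medoids (`cluster::pam`) for each k in
   2–16, keeping the partition with the largest mean silhouette width,
   ties towards smaller k. PAM is robust to non-spherical clusters and
   deterministic given the data, which makes seeded runs bit-reproducible.
   If all points coincide the silhouette is undefined; the operation then
   returns a single bin with a degenerate-geometry flag rather than
   failing.
4. **Refine** (`refine_by_composition`): within each bin, a contig is
   unbinned if its GC deviates from the bin median by more than `z_max`
   (default 3) MAD-scaled robust deviations, or its Euclidean distance to
   the bin's median tetranucleotide vector exceeds the median within-bin
   distance by more than `z_max` robust deviations. Tetranucleotides are
   canonical (136 strand-collapsed 4-mers) because contig orientation is
   arbitrary. Bins with fewer than 3 contigs are never pruned — two points
   give no spread estimate. MADs are floored (0.002 GC units, 1e-5 TNF
   distance) so that quantisation in near-identical bins cannot turn the
   threshold into zero and purge everything.
5. **Recruit** (`recruit_by_links`): one pass in lexicographic contig
   order against the frozen pre-pass assignment — no cascade within a
   pass, so the outcome does not depend on processing order. An unbinned
   contig joins a bin holding a strict majority (> 0.5) of its links; a
   binned contig moves only under a stricter 0.7 supermajority; both
   require at least 2 link pairs. Recruitment is the stage that recovers
   refinement's false positives, since intra-genome links dominate.
6. **Score** (`evaluate_bins`, `marker_quality`): adjusted Rand index over
   binned contigs (standard contingency-table formula, cross-checked in
   the tests against an independent implementation), per-bin
   precision/recall under majority-truth mapping, unbinned fraction, and
   marker completeness/contamination.

On the default community (8 genomes, 3 time points, CV 0.2, 2% spurious
links; about 400 contigs) the acceptance test requires ARI ≥ 0.95 with at
least 6 of 8 bins at completeness ≥ 87.8% and contamination ≤ 2.4% — the
quality band reported for real draft genomes recovered this way.

**What passing does not show.** The generator's genomes are homogeneous
Markov chains; real genomes carry mobile elements, rRNA operons and
strain-level variation that blur both coverage and composition signals.
Passing here demonstrates the algorithmic chain is correct and
well-calibrated on data satisfying its assumptions, not that it matches
binning performance on any particular real metagenome.

## 3. Growth kinetics

The estimators formalise the published measurement protocol:

* **Product series** (`oxidation_product`): AOB growth is proxied by
  NO₂⁻ + NO₃⁻ accumulation, NOB growth by NO₃⁻ alone.
* **Window selection** (`select_window`): exhaustive search over all
  contiguous windows of at least 4 points with all-positive values,
  keeping the longest whose ln-linear regression has positive slope and
  R² ≥ 0.99 (ties to the earliest start). Series of at most ~120 points
  make exhaustive search trivial. Zeros are excluded as below detection
  rather than pseudocounted — early bottle samples with no product are
  censored observations, not data. A consequence of the longest-window
  rule worth knowing: a short *positive* plateau before growth can be
  absorbed into an accepted window, because a few flat points cost little
  R² against a long exponential span; a plateau at zero cannot, because
  zeros are excluded outright.
* **Rate and lag** (`growth_rate`): the natural-log slope *is* the rate in
  h⁻¹ (no base conversion), and the lag is the window start minus the
  inoculation time. On noiseless exponentials the slope is exact to
  machine precision.
* **Monod fitting** (`fit_monod`): bounded Levenberg–Marquardt
  (`minpack.lm::nlsLM`), initialised at μ_max⁰ = max(μ) and K_s⁰ = the S
  whose rate is nearest μ_max⁰/2, with positive lower bounds. If the
  optimiser errors the package falls back to bounded quasi-Newton and
  reports `converged = FALSE` with the best iterate — poorly fitting
  cultures must surface diagnostics (`rss`, `converged`), not fail.
* **qPCR** (`qpcr_quantify`): standard-curve line fit, inversion of
  unknown Ct values, efficiency 10^(−1/slope) − 1; inverted (positive
  slope) standards are an error.

`run_kinetics_pipeline()` simulates one dose-response experiment per
reference culture over the 50–1500 µM grid, with a deliberately small
inoculum (x₀/Y = 1e-4 µM-equivalents) so the substrate stays effectively
at its dose throughout the regression window, and an assay horizon of 8
e-folds of the culture's maximum rate. Rates are fitted per dose and the
Monod model per culture.

**A known, honest bias.** The observable product of an exponentially
growing converter is P(t) ∝ e^{μt} − 1, which is log-linear only once
μt ≳ 3. The longest window satisfying R² ≥ 0.99 necessarily reaches back
into the pre-asymptotic curvature, biasing the slope upward by a few
percent (and the window-start-based lag upward by roughly 1/μ). This is a
property of the measurement protocol itself, not of the implementation;
the pipeline's self-consistency test therefore asserts recovery of μ_max
within 10% and K_s within 25% — bands measured from pilot runs of the full
chain — rather than the near-exact recovery `fit_monod` achieves on clean
(S, μ) pairs. Users comparing cultures should compare quantities estimated
under the same protocol, where the bias largely cancels.

The reference culture table (`reference_kinetics()`) carries the published
kinetic constants used as simulation defaults. For the solo
nitrite-oxidiser culture only the rate range over the dose grid was
published (its Monod fit was reported as poor), so its μ_max ≈ 0.0052 h⁻¹
and K_s ≈ 38 µM are back-calculated from the two printed rate endpoints
and flagged `ks_derived` in the table.

## 4. The cascade simulator

`simulate_cascade()` integrates the minimal two-guild Monod cascade
consistent with the stoichiometry of nitrification:

dX_A/dt = a_A μ_A X_A, dNH₄/dt = −a_A μ_A X_A / Y_A,
dNO₂/dt = +a_A μ_A X_A / Y_A − a_B μ_B X_B / Y_B,
dNO₃/dt = +a_B μ_B X_B / Y_B,

with μ_A, μ_B the Monod rates on NH₄⁺ and NO₂⁻ and a_g ∈ {0,1} hard lag
switches. Design choices:

* **No biomass nitrogen uptake.** The derivatives sum to zero exactly, so
  total inorganic N is conserved to machine precision at every step — a
  built-in invariant the tests assert at 1e-6 µM, and consistent with the
  stoichiometric conversions the bottles show.
* **Hard lag switch.** The operational definition of lag (nothing happens,
  then growth) is a step function; smooth lag formulations would add a
  parameter the data cannot constrain.
* **Piecewise fixed-step RK4.** Integration runs at fixed step `dt`
  (default 0.1 h) but is segmented at the lag switch points, so the
  right-hand side is smooth within every segment. Integrating a
  discontinuous switch mid-step costs RK4 its fourth-order convergence;
  with segmentation, halving `dt` moves terminal concentrations by far
  less than the 1e-4 µM the step-convergence test demands. A step that
  drives any state below −1e-9 aborts with a message naming `dt`.
* **Observation noise** is multiplicative lognormal, seeded, and applied
  only to the returned concentration samples — never to the integrated
  state — so noisy and noiseless runs share identical dynamics.
* **Bicarbonate** dose response is a single scalar multiplier
  (`hco3_factor`) on both μ_max values: the observed effect is a rate
  elevation, and no carbon-limitation law is available to model it more
  mechanistically.

Default parameters emulate the coupled bottle: published AOB kinetics
(μ_max 0.028 h⁻¹, K_s 25.9 µM, 23 h lag) oxidising 500 µM NH₄⁺, plus a
large, slow nitrite-oxidising population (x_B0/Y_B = 800 µM-equivalents at
μ_max 0.0052 h⁻¹) sized so the transient nitrite peak is cleared within
the incubation. Yields and inoculum sizes are unpublished; these values
were chosen once to reproduce the qualitative shape (transient interior
NO₂⁻ peak, complete conversion to NO₃⁻) and are not fitted to any real
trace. Setting `x_b0 = 0` reproduces the ammonia-oxidiser-only bottle,
which converts NH₄⁺ to NO₂⁻ stoichiometrically with no NO₃⁻ — the tests
assert terminal NO₂⁻ equals the NH₄⁺ input to 1e-3 µM.

## 5. Orchestration and reproducibility

`run_binning_pipeline()` and `run_kinetics_pipeline()` tie the stages
together. Configurations are nested lists merged into defaults with
unknown keys rejected at every level; each run writes its resolved
configuration, a log, and its tables next to the outputs, and is a
deterministic function of (configuration, seed). The global seed expands
into per-stage seeds by a fixed affine counter (`seed · 1009 + stage`,
mod 2³¹ − 1), so individual stages can be re-run in isolation with the
stream they had inside the full pipeline.

Problem sizes throughout (150 kb genomes, ~400 contigs, 60-sample assay
curves, 20-seed property loops) are chosen so the entire test suite runs
in well under a minute while leaving each assertion statistically
comfortable; they are package choices, not measured limits.

## 6. Known limitations

* No read-level simulation: coverage noise is lognormal on mean depth;
  mapping artefacts, GC bias in sequencing depth, and shared (conserved)
  regions between genomes are absent.
* Marker-based quality uses planted markers, not a curated single-copy
  marker catalogue; absolute completeness numbers are not comparable to
  tools that use one.
* The kinetics estimators assume batch bottles with a single limiting
  substrate per guild; product inhibition, pH drift and oxygen limitation
  are not modelled.
* The cascade's lag is phenomenological; it does not distinguish
  physiological adaptation from population-size detection thresholds.
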