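# nitrobin

Differential-coverage genome binning and nitrification growth kinetics for
two-guild nitrifier enrichment cultures, exercised entirely on synthetic
data with known ground truth.

Freshwater nitrification is carried out by two interdependent guilds:
ammonia-oxidising bacteria (AOB, NH₄⁺ → NO₂⁻) and nitrite-oxidising
bacteria (NOB, NO₂⁻ → NO₃⁻). Studies of such enrichment cultures lean on
two computational workhorses that are hard to validate on real data because
the truth is unknown: (i) recovering draft genomes from metagenome contigs
by clustering their coverage profiles across sampling time points, and
(ii) extracting growth rates, lag durations and Monod parameters from
bottle-experiment chemistry. `nitrobin` implements both analyses as tested,
reusable R functions, together with generators that produce labelled
synthetic inputs with the statistical structure the analyses assume — so
every stage can be scored against planted truth.

The package is for microbial ecologists and bioinformaticians who want an
algorithmic, reproducible version of this workflow, or a controlled test
bed for binning and kinetics methods.

## What it computes

**Binning.** Contig coverage profiles over *T* time points are
depth-normalised, log-transformed, embedded by classical (Torgerson)
multidimensional scaling, and clustered by k-medoids with the number of
bins chosen by mean silhouette width. Bins are then refined by sequence
composition (GC content and canonical tetranucleotide frequencies; robust
MAD-scaled outlier rule) and by paired-end links (majority-vote recruitment
and reassignment). Quality is scored two ways: adjusted Rand index against
the planted genome labels, and completeness/contamination against a planted
single-copy marker set,

```
completeness  = 100 · (distinct markers present) / n_markers
contamination = 100 · (marker copies − distinct) / n_markers
```

**Kinetics.** Growth rates are the ordinary-least-squares slopes of
ln(oxidation product) against time — NO₂⁻ + NO₃⁻ for AOB, NO₃⁻ for NOB —
over the longest contiguous window whose regression reaches R² ≥ 0.99
(the published acceptance rule); the lag is the time from inoculation to
the window start. Dose-response pairs (S, μ) are fitted to the Monod model

```
μ = μ_max · S / (K_s + S)
```

by bounded Levenberg–Marquardt. qPCR gene-copy numbers come from a
standard-curve inversion with amplification efficiency 10^(−1/slope) − 1.
A fixed-step RK4 simulator of the coupled Monod cascade (with hard lag
switches and exact nitrogen conservation) stands in for the wet bottle
experiments.

## Worked example

```r
library(nitrobin)

# simulate an 8-genome community sampled at 3 time points, bin it, score it
res <- run_binning_pipeline(out_dir = "demo", seed = 7)
#> binning pipeline: seed 7
#> community: 375 contigs from 8 genomes
#> clustering: k = 8, mean silhouette 0.788
#> evaluation: ARI 1, unbinned fraction 0.0107
res$quality[, c("bin", "completeness", "contamination", "n_contigs")]
#>   bin completeness contamination n_contigs
#> 1   1          100             0        55
#> 2   2          100             0        44
#> 3   3          100             0        42
#> 4   4           97             0        50
#> 5   5           95             0        46
#> 6   6          100             0        45
#> 7   7          100             0        43
#> 8   8          100             0        46
```

The silhouette search recovers the true number of genomes (k = 8), the
adjusted Rand index of 1 means every binned contig sits with its own
genome, and all eight bins land inside the quality band reported for real
draft genomes of this kind (completeness ≥ 87.8%, contamination ≤ 2.4%).

```r
# a coupled AOB+NOB bottle: transient nitrite, complete conversion to nitrate
simulate_cascade(cascade_params(t_end = 250, dt = 0.1))
#> Two-guild nitrification cascade simulation
#>   2501 samples over 250 h (dt = 0.1 h)
#>   terminal: NH4 0.00, NO2 0.00, NO3 500.00 uM

# Monod fit on a noiseless dose-response at the coupled culture's parameters
S <- c(50, 200, 500, 1000, 1500)
fit_monod(S, monod_mu(S, 0.028, 25.9))
#> Monod kinetics fit: mu = mu_max * S / (ks + S)
#>   mu_max = 0.02800 h^-1, ks = 25.90 uM  (n = 5)
#>   rss = 3.61e-35, converged = TRUE
```

`run_kinetics_pipeline()` chains the two: it simulates dose-response
bottles for each reference culture over the 50–1500 µM substrate grid,
estimates per-dose rates and lags under the R² rule, and fits the
per-culture Monod parameters.

The methods vignette (`vignettes/nitrifier-workbench.Rmd`) gives the full
account of the models, defaults and their limitations.

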