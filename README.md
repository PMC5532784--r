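# beadpeaks

Peak calling for LINCS L1000 bead-level data with an aggregate Gaussian
mixture model.

The L1000 assay measures ~1000 landmark genes on ~500 Luminex bead
colors, so each color carries beads for **two** genes: per well and
color, ~60 fluorescence intensities split about 2:1 between the genes.
Recovering one expression value per gene means splitting each color's
intensity distribution into two peaks, and mistakes — especially
assigning the peaks to the wrong genes ("flips") — contaminate every
downstream signature. This package is for analysts working with
bead-level L1000 (or other two-analyte Luminex) data who want peak calls
that are robust to stray beads and consistent across replicates.

## The model

Within sample *i* of a color, bead intensities follow the shared-variance
two-component mixture

    P(x | mu1_i, mu2_i, sigma) =
        lambda * f(x; mu1_i, sigma) + (1 - lambda) * f(x; mu2_i, sigma)

with *f* the normal density and `lambda` the bead proportion of the
higher-expressed gene. The **aggregate** Gaussian mixture model (AGMM)
fits the *m* replicate samples of a color jointly — `sigma` and `lambda`
are shared — under the reparametrization

    mu_i = (mu1_i + mu2_i) / 2,    delta_i = mu1_i - mu2_i >= 0,

so the assumption that the two genes keep the same expression order in
all replicates becomes a box constraint (`delta_i >= 0`), handled by
L-BFGS-B with analytic gradients. Before fitting, a density-gap filter
removes outlier beads: kernel-density regions below `dy_thr = 1e-4` are
data-free gaps, and gap-separated clusters with fewer than
`clustersize_thr = 3` beads are discarded. The per-sample baselines used
for comparison — exact two-cluster k-medians and a naïve per-sample
GMM — plus a hierarchical plate simulator and benchmark metrics (pooled
Pearson correlation, true-prediction counts at the strict 0.05 rule,
mean absolute error, flip counts, Williams's test for dependent
correlations) are all included.

## Worked example

```r
library(beadpeaks)

# a small simulated plate: 3 colors x 4 replicate samples
d   <- simulate_dataset(sim_params(n_colors = 3, n_samples = 4, seed = 3))
fit <- agmm(d$beads[["c02"]])   # outlier filter on by default
summary(fit)
#> Aggregate Gaussian mixture fit: color 'c02', 4 sample(s)
#>   shared sigma = 0.2039, lambda = 0.6606, logLik = -108.21
#>   mean separation delta = 0.9663
#>
#> Per-sample peaks:
#>  sample_id  mu_high   mu_low n_used n_outliers_removed
#>        s01 6.736426 5.737682     61                  0
#>        s02 6.717695 5.720837     61                  1
#>        s03 6.702031 5.807530     60                  0
#>        s04 6.729123 5.754199     60                  1

d$truth[d$truth$color_id == "c02", ][1, c("true_mu_high", "true_mu_low")]
#>   true_mu_high true_mu_low
#>        6.7461      5.7624
```

The fit pools the four replicates: `sigma` (0.204, truth 0.2) and
`lambda` (0.66, truth 2/3) are estimated once from ~240 beads, two stray
beads were removed by the density-gap filter, and every sample's peak
pair lands within ~0.05 of the true peaks with the high/low order
consistent across samples by construction. `peak_calls(fit)` returns the
table as a data frame; `write_peaks()` serializes it.

Full benchmarks against the baselines:

```r
rep <- benchmark(simulate_dataset(sim_params(seed = 1)))
benchmark_table(rep)   # pcc / true predictions / MAE / flips per method
```

A command-line wrapper with `simulate`, `deconv`, `evaluate` and
`benchmark` subcommands ships in `inst/cli/beadpeaks.R`; see
`?cli_main`.

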