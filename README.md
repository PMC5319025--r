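# cernasim

Stochastic simulation and analysis of miRNA-mediated crosstalk between
competing RNAs.

## The problem

When two mRNAs (`r1`, `r2`) are targets of the same microRNA (`s`), they
compete for the shared pool of free miRNA molecules: each target acts as
a *sponge* that indirectly de-represses the other (the competing
endogenous RNA, or ceRNA, effect).  Because miRNA–target binding is a
titration reaction, the regulated target responds ultrasensitively: its
protein output `p1` stays repressed while miRNA is in excess and rises
steeply once target transcription out-titrates the effective miRNA
supply.  Near that **threshold** the model predicts three coupled
fluctuation phenotypes in single cells:

* a local maximum of the regulated target's noise
  (`CV = sd/mean`) — retroactivity couples the target to the miRNA
  pool's fluctuations;
* a maximum of the Pearson correlation between the two target proteins
  — titration synchronises otherwise independent genes;
* bimodal copy-number distributions (distinct high/low expression
  states) for strong binding.

`cernasim` implements the full chain from model to measurement, for
researchers who study post-transcriptional regulation or who need a
worked, testable example of titration-driven cross-regulation:

* **model core** — the reaction network (transcription `k_s`, `k_r1`,
  `k_r2`; free degradation `g_s`, `g_r1`, `g_r2`; bimolecular
  interaction `g_i·s·r_i` that always removes the target and removes
  the miRNA with probability `alpha`; translation `k_pi`; protein
  degradation `g_pi`), exact mean-field steady state, threshold
  locator (maximal log–log slope of `⟨p1⟩(p0)`);
* **moments** — Gaussian (linear-noise) stationary covariance from the
  fluctuation–dissipation relation `A C + C Aᵀ + B = 0`, giving CVs and
  Pearson correlations;
* **ssa** — exact Gillespie simulation (compiled), stationary sampling
  of virtual cells, and a Hartigan dip test for bimodality
  (implemented from scratch, with a Monte-Carlo uniform null);
* **phenotypes** — parameter sweeps (threshold shifts with competitor
  transcription/binding and miRNA supply, `g_2 → ∞` limiting regimes,
  fold-repression `F`), and a crosstalk/bimodality phase diagram over
  `g_2/g_1` versus target mRNA abundance;
* **synthetic cytometry** — a generator of two-plasmid, four-colour
  cotransfection populations (log-normal correlated plasmid copies,
  per-cell model statistics, gains + autofluorescence background) with
  full ground truth;
* **cytometry analysis** — the single-cell pipeline: background
  correction (control mean + 2 SD), double-positive gating, equal-width
  eYFP binning with per-bin mean/CV/Pearson and replicate errors,
  fold-repression with jackknife errors, and the Pearson-ratio
  statistic with Gaussian p-values against the `N = 0` null.

## Worked example

```r
library(cernasim)

# a cell at the titration threshold: strong binding on target 1,
# weak competitor, recycling probability 0.5
pars <- cerna_params(k_s = 20, k_r1 = 40, k_r2 = 5, g_s = 0.2,
                     g_1 = 2, g_2 = 0.05, alpha = 0.5)
stationary_covariance(pars)
#> Gaussian (linear-noise) stationary moments
#>           s     r1     r2      p1      p2
#> mean 5.5497 3.3059 3.9139 33.0594 39.1394
#> cv   0.9713 1.0303 0.5368  0.4363  0.2296
#> fano 5.2356 3.5096 1.1279  6.2930  2.0630
#> pearson(p1,p2) = 0.3653   pearson(s,r1) = -0.8269
```

At this operating point the two target proteins, which share no
regulator other than the miRNA, are correlated at 0.37, and the free
miRNA is strongly anticorrelated with its target — the signature of
titration.  Sweeping the constitutive expression of target 1:

```r
grid <- exp(seq(log(2), log(4000), length.out = 40))
sw  <- sweep_p0(pars, grid)
thr <- sensitivity_threshold(sw$p0, sw$mean_p1)
#> threshold p0* = 385.8   max log-log slope = 5.7
which.max(sw$pearson_p1p2)  # rho(p1,p2) peaks at p0 = 385.8, rho = 0.398
```

The response is strongly supralinear (slope 5.7 versus 1 for an
unregulated gene) and the target–target correlation peaks exactly at
the threshold.  An end-to-end synthetic experiment — generate a
cotransfected population, then analyse it blind —

```r
cfg   <- population_config(n_cells = 20000, n_replicates = 3,
                           N_cherry = 4, N_cerulean = 1, seed = 14)
cells <- generate_population(cfg, cerna_params(k_s = 20, k_r2 = 5,
                                               g_s = 0.2, alpha = 0.5))
gated <- gate_positive(background_correct(cells))
bs    <- bin_and_summarize(gated, n_bins = 40)
binned_threshold(bs)$bin   # threshold bin recovered from fluorescence
```

recovers the generator's threshold within one eYFP bin, and the
Pearson-ratio statistic (`pearson_ratio()`, `ratio_pvalue()`) shows the
miRNA-induced correlation enrichment is maximal around the threshold.

A pipeline-style interface with manifests is available through
`cerna_run()` (subcommands `simulate`, `sweep`, `generate`, `analyze`,
`phase`) and the thin wrapper script `inst/cli/cernasim.R`.

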