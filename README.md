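# stat1dyn

Dynamic modeling of IFN-γ → STAT1 signaling in pancreatic cancer cells.

Interferon-γ binds its receptor, the activated receptor phosphorylates the
transcription factor STAT1, phospho-STAT1 dimerizes, enters the nucleus,
binds DNA and induces its target genes — among them *SOCS1*, which feeds
back to inhibit STAT1 phosphorylation, and *STAT1* itself. In pancreatic
cancer cells this response is weak: immunoblots show a biphasic rise of
phospho-STAT1, confocal images show an almost unchanged nuclear:cytoplasmic
STAT1 ratio, and the interesting quantity — how much STAT1 ever sits in the
nucleus in phosphorylated form — is not directly measurable, because every
immunoblot series carries an arbitrary gain.

`stat1dyn` is for systems biologists who want to fit this kind of pathway
model to multi-dose immunoblot/qPCR/confocal time courses and extract an
upper bound on that unobservable nuclear pool. It provides:

* **Model core** — a deterministic ODE model of the pathway with
  distributed delays realized as linear chains (gamma transit-time kernels
  with mean τ̄ and shape `n_chain`). States: active receptor `IIr` (total
  receptor `I` conserved, `Ir = I − IIr`), cytoplasmic and nuclear
  unphosphorylated STAT1 (`SUc`, `SUn`), cytoplasmic/nuclear/DNA-bound
  phospho-dimers (`SDc`, `SDn`, `SDnd`), and *SOCS1*/*STAT1* mRNA.
  Phosphorylation flux `v = k_phos · IIr · SUc / (1 + k_inh · z_fb)` with
  `z_fb` the delayed SOCS1 signal; only free nuclear dimers are
  dephosphorylated; unphosphorylated STAT1 shuttles diffusively.
* **Observation model** — immunoblot scaling factors (`WB_•`), the
  species→observable algebra, the nuclear:cytoplasmic ratio RSNC, and the
  study's time-average normalization.
* **Assay arithmetic** — loading-control normalization, `2^−ΔCt` qPCR
  relative expression, per-cell RSNC, replicate mean ± SEM, and the
  ellipsoid tumor-volume formula `V = width² × length × 0.52`.
* **Fitting** — the SEM-weighted cost
  `χ²(θ) = Σ_k Σ_l ((y_kl^exp − y_kl^mod)/σ_kl^exp)²`
  over all observables, doses and time points, minimized by a hybrid of
  seeded simulated annealing and local refinement, with global/local
  parameter scopes and analytic profiling of free blot gains.
* **Scaling-factor sweep** — fix the nuclear phospho blot gain
  `WB_STAT1Dn` at increasing values, re-optimize everything else along a
  profile walk, find the χ² plateau, and read off an upper bound on the
  nuclear phospho-STAT1 fraction.
* **Synthetic data** — a generator that emulates the raw assay tables
  (replicate blots with loading controls, qPCR Ct pairs, per-cell
  intensities) from known ground truth, so the whole pipeline is testable
  end to end.

## Worked example

```r
library(stat1dyn)

params <- stat1_parameters()                 # packaged demonstration set
traj   <- simulate_pathway(params, dose = 100, times = seq(0, 720, by = 5))
obs    <- observe(traj)                      # tidy observable table

npf <- nuclear_phospho_fraction(traj)        # free nuclear dimers
rs  <- obs$value[obs$observable == "RSNC"]
cat(sprintf("max nuclear phospho fraction: 1/%.0f\n", 1 / npf$max))
cat(sprintf("RSNC relative change: %.1f%%\n", 100 * (max(rs)/min(rs) - 1)))
tumor_volume(width = 6, length = 9)
```

prints

```
max nuclear phospho fraction: 1/526
RSNC relative change: 2.0%
[1] 168.48
```

i.e. at 100 ng/ml IFN-γ at most ~1/500 of total STAT1 is free nuclear
phospho-STAT1, the nuclear:cytoplasmic ratio stays within 2% of its
starting value over 12 h, and a 6 × 9 mm flank tumor is estimated at
168 mm³.

The full analysis lives in `analysis/` as numbered drivers:

```sh
Rscript analysis/01_simulate.R         # trajectories + observables
Rscript analysis/02_synthesize_data.R  # raw assay tables -> dataset.csv
Rscript analysis/03_fit.R              # hybrid chi-squared fit
Rscript analysis/04_scaling_sweep.R    # WB_STAT1Dn sweep -> bound
```

With the packaged settings, `03_fit.R` reports `chi2/n = 1.35` with fitted
curves within 2 SEM of the data at 90% of points, and `04_scaling_sweep.R`
finds the cost plateau at `WB_STAT1Dn = 100` and bounds the nuclear
phospho-STAT1 pool at ~1/80 of total STAT1 (free dimers alone: ~1/800).
Each driver writes its tables under `results/`.

## Vignette

`vignettes/stat1-pathway-modeling.Rmd` documents the model and its
assumptions, the normalization and identifiability conventions, the
optimizer and sweep design, and what the synthetic study conditions do and
do not establish about real data.
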