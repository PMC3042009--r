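---
title: "Modeling IFN-gamma/STAT1 signaling: model, fitting and the nuclear phospho-STAT1 bound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling IFN-gamma/STAT1 signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stat1dyn)
```

## The model

`stat1dyn` models IFN-γ signaling through STAT1 in a cell with two
well-mixed compartments of equal area (a quantification result from the
confocal data the model is built for). The species, all in arbitrary
concentration units with time in minutes, are the active receptor complex
`IIr`, unphosphorylated STAT1 in cytoplasm and nucleus (`SUc`, `SUn`),
the phosphorylated dimer in cytoplasm, free in the nucleus, and DNA-bound
(`SDc`, `SDn`, `SDnd`; dimer units, two monomers each), and the *SOCS1*
and *STAT1* transcripts (`mSOCS1`, `mSTAT1`).

The reactions, one term per arrow of the network:

* **Receptor activation.** `d IIr/dt = k_act · dose · (I_total − IIr)`.
  Ligand degradation and receptor deactivation are neglected, so the
  inactive receptor is implicit (`Ir = I_total − IIr`) and `IIr(t)` rises
  monotonically to `I_total` with rate constant `k_act · dose` — this is
  what makes the response *slower, not smaller*, at low dose.
* **Phosphorylation with SOCS1 feedback.**
  `v = k_phos · IIr · SUc / (1 + k_inh · z_fb)`, where `z_fb` is the
  delayed SOCS1-mRNA signal. Multiplicative saturating inhibition is the
  simplest form consistent with SOCS1 acting on the phosphorylation step;
  driving it by delayed mRNA (rather than an explicit SOCS1 protein
  species) lets the delay absorb translation.
* **Dimerization and transport.** Dimerization is treated as instantaneous
  and tight, so the flux `v` of phosphorylated monomers enters `SDc` as
  `v/2`. Dimers import irreversibly (`k_imp`); only unphosphorylated
  STAT1 shuttles, as symmetric first-order exchange `k_shut · (SUn − SUc)`
  (free diffusion between equal-area compartments).
* **Nuclear retention and recycling.** Reversible DNA binding
  (`k_bind`, `k_unbind`) holds part of the nuclear pool; only *free*
  nuclear dimers are dephosphorylated (`k_deph`), releasing two monomers
  into `SUn`.
* **Transcription and synthesis.** Both transcripts are produced from
  delayed DNA-bound-dimer signals (`k_txS`, `k_txT`), degrade first-order
  (`k_degS`, `k_degT`; set them to 0 to disable), and STAT1 mRNA is
  translated into `SUc` at `k_transl` with no basal STAT1 turnover — the
  measured total STAT1 rises monotonically within 12 h, so protein decay
  is not identifiable on this horizon and is omitted.

### Distributed delays

The three lagged processes — SOCS1 transcription, STAT1 transcription,
and the SOCS1 feedback — are distributed delays with mean delay times
`tau_socs`, `tau_stat1`, `tau_fb`, realized as linear chains of `n_chain`
first-order stages with per-stage rate `n_chain / tau`. The transit-time
kernel is then a gamma density with mean `tau` and variance
`tau² / n_chain` (`delay_chain_response()` evaluates it; the tests verify
the moments by quadrature). The default order 3 gives a unimodal,
moderately spread kernel; the order is a configuration knob because only
mean delays are empirically grounded.

### Initial conditions and the receptor total

`IIr`, `SDn` and `SDnd` start at zero structurally; mRNAs and chain stages
start at zero (unstimulated cells); `SUc`, `SUn`, `SDc` are free initial
conditions. The dose-0 state is a fixed point, so unstimulated
trajectories are flat — a test asserts this. Initial total STAT1 is
normalized to 1 by convention, and the receptor total defaults to 1/10 of
it (`I_total = 0.1`).

## Observation model and normalization conventions

Band intensities have no absolute units, so each blotted observable is a
species combination times a free positive gain: e.g.
`STAT1P_nuc = WB_STAT1Dn · 2(SDn + SDnd)` and
`STAT1_total = WB_STAT1 · (SUc + SUn + 2(SDc + SDn + SDnd))` (monomer
equivalents: a dimer contributes two monomers to a band). The data-side
convention mirrors the experimental pipeline: each band is divided by its
lane's loading control, each replicate series by its time average
(`time_average_normalize()`, mean exactly 1), and replicates are averaged
to mean ± SEM. mRNA observables carry no gain — after time-average
normalization on both sides any gain cancels, so one would be redundant —
and RSNC, the nuclear:cytoplasmic concentration ratio, is scaling-free by
the equal-area assumption and is compared unnormalized.

Because each dose's series is normalized to *its own* time average, the
effective gain differs between doses; the WB factors therefore default to
per-dose ("local") scope while all kinetics are global (the dose enters
the equations explicitly). Under this convention a single parameter vector
reproduces a noiseless two-dose dataset exactly, which the test suite
asserts (χ² < 1e−10 at the generating truth).

## Identifiability conventions

Two soft directions must be handled before any fit is meaningful:

* **Concentration scale.** Scaling every pool by λ (with `k_inh → k_inh/λ`
  and bimolecular fluxes compensating through the pools themselves) leaves
  every observable unchanged — absolute concentrations are not
  identifiable from normalized data. The default `parameter_space()`
  removes the symmetry by fixing initial total STAT1 at 1: `init_SUc` is
  searched as a share of that total and `init_SUn` is derived. This is the
  same convention that gives `I_total = 0.1` meaning.
* **Blot gains.** Conditional on a trajectory, the optimal gain of each
  blotted series is a weighted least-squares scalar, so free WB factors
  are profiled analytically inside `chi_squared()` instead of being
  searched stochastically; they are still reported with the fit. A factor
  fixed in the space — as the sweep does with `WB_STAT1Dn` — is applied
  as-is.

## Fitting

`fit_pathway()` minimizes the SEM-weighted χ² with a hybrid strategy:

1. **Global stage.** `n_restarts` independent simulated-annealing chains
   over the transformed search vector (log10 coordinates for rates and
   delays, linear for the initial-condition share). Proposals perturb one
   random coordinate with a standard deviation proportional to its bound
   range and the current temperature; Metropolis acceptance; geometric
   cooling every `sa_temperature_length` iterations. Integration failures
   inside the search return a large finite penalty (1e10) so chains
   continue through pathological corners.
2. **Local stage.** The best visited point is refined by alternating a
   bounded quasi-Newton minimization (`nlminb`) with a derivative-free
   Nelder–Mead simplex, iterated until the pair stalls. The alternation
   matters: finite-difference gradients sit on top of the integrator's
   truncation noise and stall at the percent level, which the simplex then
   works through.

Defaults (5 restarts × 2000 iterations, cooling 0.97, then local
refinement) fit the packaged two-dose problem (~140 data points, ~18 free
parameters) in about a minute. Everything is reproducible from
`OptimizerSettings$seed`; the acceptance tests run the full fit at fixed
seeds and require fitted observables within 2 SEM of the noiseless truth
at ≥ 90% of points with `χ²/n` in [0.3, 3].

## The scaling-factor sweep and the nuclear bound

The absolute size of the nuclear phospho-STAT1 pool hides behind
`WB_STAT1Dn`. The sweep makes the hidden scale explicit: fix the gain at
each value of an increasing grid (default
{10, 30, 100, 300, 1000, 3000, 10000}), re-optimize all other parameters,
and record the re-optimized χ². Since the normalized data pin
`WB_STAT1Dn · 2(SDn + SDnd)` to order one, larger fixed gains force
proportionally smaller nuclear pools. Where the cost has flattened — the
*plateau*, detected by `detect_plateau()` as the smallest grid value from
which all successive relative changes stay within 1% (a deliberately
simple, tunable criterion) — the data no longer resist shrinking the
pool, and the plateau fit realizes the *largest* nuclear fraction still
compatible with the data: the upper bound, `concentration_bound()`.

Design choices that make this procedure behave:

* **Profile walk with a continuation predictor.** The sweep anchors at the
  grid point nearest the unconstrained fit's implied gain and re-optimizes
  outward, warm-starting each point from its inward neighbor *rescaled
  along the compensation direction* (phosphorylation down by the gain
  step, feedback and transcription gains up to preserve their absolute
  effects). Refits are quenched annealing chains (single chain, low
  temperature) plus the alternating local polish. Naive independent refits
  at each grid point produce percent-level scatter that defeats any
  plateau criterion; the predictor–corrector walk keeps each point on the
  continuation branch of the optimum.
* **Wide sweep bounds.** The default sweep space uses 100-fold kinetic
  bounds (vs 30-fold for plain fitting): the grid drags the pool over
  three decades, and bounds tighter than that range bind the compensating
  rates, producing spurious cost rises that masquerade as
  non-identifiability.
* **Which pool the bound concerns.** The swept gain multiplies the nuclear
  phospho *band*, which contains free and DNA-bound dimers alike — a blot
  cannot separate them — so the sweep constrains their sum, and
  `concentration_bound()` reports that pool by default. The free-dimer
  reading (`include_dna_bound = FALSE`) is also reported, but the free:bound
  split is not pinned by the data (re-fits freely trade `k_bind` against
  `k_unbind`), so it inherits that indeterminacy.
* **Same-time totals.** Fractions divide by total STAT1 at the same time
  point; dividing by the initial total would differ once synthesis has
  raised the total (by up to ~50% at 12 h) and is not used.

A real caveat, documented rather than hidden: with this observation model
the bound is only informative when the cytoplasmic phospho pool is small
compared to the nuclear one. If the two pools are comparable, a re-fit can
inflate *all* phospho pools in concert and the near-constant RSNC never
notices (the ratio's numerator and denominator grow together) — the cost
stays flat down to small gains and no finite bound emerges. Rapid import
and nuclear retention of activated dimers (the established behavior of
phospho-STAT1, and the regime of the packaged demonstration set) is what
gives the low end of the sweep its cost rise.

## The synthetic study conditions

`generate_dataset()` fabricates the raw tables the real pipeline would
consume, at the study's scale: doses 10 and 100 ng/ml; time points
{0, 15, 30, 60, 120, 180, 360, 540, 720} min (the end point and overall
span are empirically grounded; the in-between spacing is a synthetic
choice); 4 replicates (of the study's 4–6); 30–40 cells per confocal time
point. Noise is multiplicative lognormal on band intensities (positive,
right-skewed; default CV 0.2) and loading controls (CV 0.1), additive
Gaussian on Ct values (0.15 cycles, two technical replicates averaged on
the Ct scale), and lognormal on per-cell ratios (CV 0.2). Per-replicate
lane gains (lognormal, σ_log 0.4) are included and must cancel in the
normalization chain — a pipeline test, not just a statistics test. SOCS1
qPCR omits the unstimulated time point (basal expression below detection,
and the model's basal transcript level is zero). Zero-variance SEMs from
noiseless generation are replaced by a configurable floor (default 0.05
normalized units) so that noiseless demonstrations remain fittable;
setting the floor to 0 turns them into errors instead.

The packaged truth (`demo_truth()`, also the `stat1_parameters()`
defaults) was designed once to exhibit the measured signatures: biphasic
phospho-STAT1 rise at 100 ng/ml, strictly slower rise at 10 ng/ml, late
total-STAT1 increase, RSNC within 5% over 12 h, maximal free nuclear
phospho fraction ≈ 1/500, and an import-dominated pool structure (see the
caveat above). What passing tests on these conditions establish is that
the *procedures* recover known ground truth under honest noise of the
study's magnitude; they cannot establish that the real system satisfies
the model's structural assumptions, that real blot noise is lognormal, or
that real RSNC measurement error matches the packaged cell-level scatter.

## Numerical choices

* Integration: `lsoda` with rtol 1e−8 / atol 1e−10 on a compiled C
  right-hand side; a pure-R twin of the derivatives is exported and the
  tests require the two engines and an independent fixed-step RK4
  integration to agree (per-species error normalized by dynamic range
  ≤ 1e−6).
* Negative undershoot below 1e−9 in magnitude is clipped to zero with a
  warning; anything larger is an error.
* Dataset rows are ordered with locale-independent radix sorting so that
  floating-point summation order — and with it every seeded optimization
  path — is identical across sessions and locales.
* χ² of a failed integration is the documented penalty 1e10; penalized
  evaluations are counted and reported with the fit.
* All randomness (generator, annealing) flows from explicit integer seeds;
  generators and fitters restore the caller's RNG state.

## Limitations

* Deterministic, two-compartment, single-cell-type model: no molecule
  counts, no spatial gradients, no explicit JAK kinases, no receptor
  turnover.
* The fitted parameters are not claimed to be individually identifiable —
  the sweep exists precisely because one direction is not; other soft
  directions (e.g. the free:bound nuclear split) remain.
* The plateau criterion certifies flatness only across the supplied grid;
  a grid that ends before the plateau, or optimizer budgets too small to
  converge each refit to well under the 1% tolerance, yield "no plateau"
  rather than a bound.
* Hypothesis testing on assay summaries (t-tests and the like) is left to
  standard R functions; the package's contract is the measurement
  arithmetic and the model pipeline.
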