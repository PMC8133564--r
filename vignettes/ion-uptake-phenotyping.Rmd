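---
title: "Multiple ion-uptake phenotyping from depletion time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple ion-uptake phenotyping from depletion time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

In a closed hydroponic chamber the fall of a nutrient's solution
concentration is taken as equal to the net uptake by the root system —
influx minus efflux, with no attempt to separate the two. For a chamber of
volume $V$ (default 250 mL) sampled at times $t_0 < t$, the net influx is

$$I_n = \frac{(C_0 - C_t)\,V}{t - t_0} \quad [\mu\mathrm{mol\,h^{-1}}],$$

with $C_0, C_t$ in µM and $V$ in litres. The volume term is what turns a
concentration difference into an amount; without it the reported units
(µmol cm⁻¹ h⁻¹ after normalization) cannot arise. Uptake is reported
positive; a rising concentration gives a negative $I_n$ that is retained
and flagged `efflux` rather than discarded.

Specific uptake rates divide $I_n$ by total root length (µmol cm⁻¹ h⁻¹) or
root dry weight (µmol g⁻¹ h⁻¹). Two companions use the same pattern:
specific root respiration (total CO₂ efflux over root length, reported per
metre, nmol CO₂ m⁻¹ s⁻¹) and specific root length (cm g⁻¹).

**Interval selection.** Rates are computed over $(0, t^\*)$ where $t^\*$ is
the earliest sampling time at which *every* focal ion (ammonium, nitrate,
phosphate, potassium, sulfate) is depleted by at least 10% of its starting
concentration — a depletion small enough to stay near the initial
concentration, large enough to clear instrument noise. Under the packaged
high/low assay solutions and the default population parameters this rule
lands on $(0, 1)$ h for the low solution and $(0, 4)$ h for the high
solution. If no time qualifies the last sample is used and the record is
flagged `fallback_interval`. The rule is monotone in the threshold: a
stricter threshold never selects an earlier time.

**Sample withdrawal.** Each 1.5 mL sample slightly shrinks the chamber. The
default treats the volume as constant (the draws are small and the
platform's pump reversal returns line contents); an optional volume-ledger
mode debits each draw and computes influx from the amount balance across
all observed timepoints. Both are exposed because the correction matters
only when draws are large relative to the chamber.

## Michaelis–Menten kinetics from depletion curves

With a root system of length $L$ taking nutrient up at the Michaelis–Menten
specific rate, the chamber concentration obeys

$$\frac{dC}{dt} = -\frac{I_{max} L}{V}\,\frac{C - C_{min}}{K_m + (C - C_{min})},$$

whose integral is the implicit relation
$K_m \ln\frac{C_0 - C_{min}}{C - C_{min}} + (C_0 - C) = \frac{I_{max} L}{V} t$.
The package evaluates the explicit solution
$C(t) = C_{min} + K_m\,W\!\big(e^{a}\big)$ with
$a = \ln\frac{C_0 - C_{min}}{K_m} + \frac{C_0 - C_{min} - kt}{K_m}$, where
$W$ is the principal Lambert W branch. $W(e^a)$ is computed directly from
the *log* of the argument by a Newton iteration on $u + e^u = a$
($u = \ln w$): the map is smooth, convex, and increasing, so the iteration
converges globally, and no intermediate $e^a$ is ever formed — low-affinity
regimes with $C_0/K_m \gg 1$ (arguments up to $10^8$ and beyond) evaluate
without overflow. The closed form agrees with a tight-tolerance `lsoda`
integration to better than $10^{-6}$ relative across 100 random parameter
draws (a standing test).

**Fitting.** `fit_depletion()` runs bounded Levenberg–Marquardt least
squares of observed concentrations — the observable, not derived rates —
against the closed form. Initialization is data driven ($I_{max}$ from the
steepest early two-point slope scaled by $V/L$; $K_m = C_0/2$), augmented
by a deterministic five-point $K_m$ start grid. The grid is on by default
because the objective holds a spurious local minimum at the zero-order
limit $K_m \to 0$, which a single start occasionally finds on realistic
series. $C_{min}$ is fixed at 0 by default: freeing it costs
identifiability on an 8-point assay series, and it is only estimable from
long series that approach the floor (a standing test recovers a true
$C_{min}$ from a 27-hour series). Poor fits set a non-convergence flag
rather than raising; a series that never leaves saturation (all
concentrations above $10 \hat K_m$) flags `km_reliable = FALSE`, since such
data cannot pin the half-saturation constant.

`fit_rates()` fits the plain Michaelis–Menten response to
rate-versus-concentration pairs, for across-concentration experiment types;
`depletion_to_rates()` converts a depletion series to interval rates at
midpoint concentrations. The two routes agree (a standing test) when the
series is sampled densely enough for the midpoint approximation — on the
coarse 8-point assay schedule the conversion itself biases $K_m$ by
roughly 10%, which is why depletion fits, not rate fits, are the default
route.

**What recovery is possible.** Noiseless 8-point series return the
generating $(I_{max}, K_m)$ to well under 1%. Under 2% multiplicative
concentration noise at the high-solution operating point
($C_0 = 1000$ µM, $K_m = 150$ µM, $L = 500$ cm), however, the series only
sweeps $C$ from 1000 down to roughly 720 µM — never near $K_m$ — and the
linearized information matrix puts the $I_{max}$–$K_m$ correlation at
0.9995. The constrained estimator then achieves a median relative error on
$I_{max}$ near 18%, and no estimator can do much better from that data;
designs that deplete through the $K_m$ region (longer assays, larger root
systems, lower $C_0$) recover $I_{max}$ to a few percent. The package
reports this honestly rather than tuning the simulation toward a nicer
number.

## The 50-trait battery

Each plant's standardized row holds 35 uptake parameters — per ion the net
uptake rate, both specific rates, and the fractional depletion (20); the 10
pairwise uptake-rate ratios; the 5 stoichiometric fractions — plus 15 plant
traits (three root class lengths from the 0–0.15 / 0.15–0.8 / 0.8–4.25 mm
diameter thresholds and their total; five dry weights including derived
shoot and total; specific root length; total and specific respiration;
leaf area and length; root:shoot ratio). The enumeration is pinned in
`trait_schema()` (versioned, so a revised list can replace it without
touching downstream code). Ratio pairs are ordered alphabetically by ion
identifier to make the 10 unordered pairs unambiguous; figure-style
orderings such as ammonium:nitrate coincide with the alphabetical one.
Efflux (negative) rates stay in the rate traits but contribute zero to the
stoichiometric fractions, with a flag — fractions of a signed total are
uninterpretable. Diameter bins landing exactly on a class threshold join
the coarser class; the thresholds as published touch, so some convention is
required, and this one is fixed and documented.

## Population statistics

Broad-sense heritability uses
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2 / r)$ on a one-way genotype
decomposition. The default estimator is method-of-moments from the one-way
ANOVA expected mean squares ($\sigma_e^2 = MS_e$,
$\sigma_g^2 = \max(0, (MS_g - MS_e)/\bar r)$), with $\bar r$ the arithmetic
mean replicate count per genotype — matching the use of an average
replication number under missingness — and a harmonic-mean option exposed.
Negative moment estimates are truncated at zero before the ratio (keeping
$h^2 \in [0,1]$); the raw value is kept in `sigma_g2_raw`. A REML backend
(`lme4`, random genotype intercept) is available; on balanced data the two
agree. At the study scale (26 genotypes × 6 replicates), a 500-simulation
recovery study at true $h^2 \in \{0.2, 0.5, 0.8\}$ returns mean estimates
within 0.05 of truth (a standing test); the small residual bias of the
ratio estimator is partly offset by the truncation.

Genotype × concentration ANOVA is a fixed-effects least-squares fit
(optionally with a block term) reported with Type II sums of squares, so
unbalanced data — missing chambers are a fact of the platform — are handled
symmetrically. Genotype is treated as fixed for these p-values while its
variance component feeds the heritability, reproducing both outputs from
one decomposition. Correlation matrices are Pearson on pairwise-complete
observations (sporadic missingness again), p-values from the t transform,
multiplicity adjustment off by default with Benjamini–Hochberg available.
PCA uses complete rows and unit-variance scaling by default, since the
traits mix units spanning orders of magnitude.

## The simulator

`sim_config()` defaults encode the emulated study design: 26 genotypes ×
6 replicates × the high/low concentration pair, runs of 48 chambers
(2 modules × 24, hence `plan_runs(312)` → 7 runs), sampling at
0, 0.5, 1, 2, 3, 4, 6, 8 h, 250 mL chambers, 1.5 mL draws. Genetic effects
are lognormal across genotypes on $(I_{max}, K_m)$ — genetic CV 0.3 and 0.2
respectively — correlated across ions (Gaussian copula on the log scale,
correlation 0.6) so the correlation stage has a non-trivial truth to
recover; plants add independent lognormal biological scatter (CV 0.25) and
a shared run effect (SD 0.05 on log $I_{max}$). Root lengths are gamma
(mean 500 cm, CV 0.3); dry weights and respiration derive from a mean
specific root length of 5000 cm g⁻¹ and specific respiration of
0.5 nmol m⁻¹ s⁻¹ with lognormal scatter — values in the range reported for
young maize root systems. Measurement noise is multiplicative Gaussian on
concentration (CV 2%, instrument-like relative error), floored at zero.

The per-ion mean kinetic parameters ($I_{max}$ 0.010–0.020 µmol cm⁻¹ h⁻¹,
$K_m$ 80–150 µM) were chosen once so that the typical plant's fractional
depletion sits near 12–33% at 4 h in the high solution and 13–21% at 1 h in
the low solution — the regime in which the 10% interval rule reproduces the
platform's (0, 4) h and (0, 1) h processed intervals — and were not
revisited afterwards.

What the simulator does *not* emulate: chromatographic artefacts
(carryover, drift, peak mis-integration), chamber-to-chamber volume error,
diurnal physiology, genotype-specific root architecture (class proportions
are fixed), or any transcriptome layer. Passing tests therefore demonstrate
correctness of the computational pipeline under a clean generative model,
not robustness to every failure mode of real instrument data.

## Numerical choices and degenerate inputs

* Lambert-W evaluation: Newton in log space, tolerance $10^{-15}$ on the
  log-scale step, 100-iteration cap (typical convergence in 4–6); arguments
  below $-36$ return $e^a$ directly (the correction term is below machine
  epsilon).
* Fits: bounds $I_{max} > 0$, $K_m > 0$, $0 \le C_{min} < \min C$;
  deterministic multistart; constant series and too-few points raise
  informative errors; identifiability problems flag rather than raise.
* Interval rule: missing observations at a time disqualify that time (the
  rule cannot be verified there); a zero starting concentration for any
  focal ion is an error naming the ion.
* Variance components: single genotype, zero total variance, or zero
  residual degrees of freedom raise; truncation at zero is applied after
  the raw estimate is stored.
* Strict number parsing at I/O boundaries: decimal commas and thousands
  separators are rejected with row numbers, never silently guessed.
  Canonical internal units are µM, h, cm, g, mL, µmol; conversions happen
  only at the boundaries.

## Problem sizes in the test suite

The standing suite exercises the pipeline at deliberately modest sizes —
simulated experiments of 4–12 genotypes for pipeline behaviour, 100+
plants for schema invariants, 100 random draws for the kinetics oracle,
200 noisy series for fit recovery, and 500 × 3 simulations for
heritability recovery — sizes at which every property above is already
decisive while the whole suite runs in a couple of minutes.

## Known limitations

* Net rates only: influx/efflux decomposition and compartmental efflux
  models are out of scope, as are dual-isotherm (high- plus low-affinity)
  composite transporters.
* $C_{min}$ is an optional model parameter, not a routine output.
* The moments/REML choice and the block term in the ANOVA are exposed
  because the original analysis choices are not fully determined; defaults
  follow the most common practice (moments, block included when supplied).
* Trace ammonium carried by the molybdate micronutrient salt is recorded in
  full compositions but excluded from focal-ion totals; at 0.68 µM against
  a 100 µM assay concentration it is three orders of magnitude below the
  signal.
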