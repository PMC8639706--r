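---
title: "Methods: from bottle incubations to oxygen budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bottle incubations to oxygen budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroxr)
```

nitroxr quantifies how much of the oxygen consumption in oxygen minimum
zones (OMZs) is attributable to aerobic nitrite oxidation. This vignette is
the package's account of its models and the choices behind them: the forward
simulator, the ¹⁵N tracer inversion, oxygen consumption rates and the
linearity screen, Michaelis–Menten oxygen affinities, the partitioning and
power-law threshold, and the dual nitrate-isotope deviation Δ(15,18).

## The forward process model

Every inference stage in the package is tested against a forward simulator
of a sealed bottle incubation. The state is four pools — dissolved O₂,
NH₄⁺, NO₂⁻, NO₃⁻, all in nM — plus the ¹⁵N atom content of each nitrogen
pool. Four processes couple them (rates in nmol L⁻¹ day⁻¹):

* ammonia oxidation `R_AO` (NH₄⁺ → NO₂⁻), zero order in NH₄⁺ until the pool
  nears exhaustion, consuming 1.5 mol O₂ per mol N;
* nitrite oxidation `R_NO = vmax_NO · [O₂] / (Km_NO + [O₂])`
  (NO₂⁻ → NO₃⁻), Michaelis–Menten in dissolved O₂, consuming 0.5 mol O₂ per
  mol N (one O atom appended per N);
* heterotrophic respiration `R_het = vmax_het · [O₂] / (Km_het + [O₂])`;
* nitrate reduction `R_NAR` (NO₃⁻ → NO₂⁻), the nitrite source that sustains
  the secondary nitrite maximum.

¹⁵N label advects with the fluxes: each process delivers nitrogen to its
product pool at the atom fraction of its substrate pool, so total N and
total ¹⁵N are conserved identically. The 1.5 stoichiometry for ammonia
oxidation is the canonical value for oxidation to nitrite and is exposed as
a configuration constant (`o2_per_nh4`); the 0.5 for nitrite oxidation is
definitional.

**Integrator.** A fixed-step explicit midpoint (RK2) scheme with a default
step of 0.01 h. The system is smooth and non-stiff at these scales; a
convergence test asserts that halving the step changes endpoint states by
less than 0.1%, and an independent adaptive ODE solver reproduces the same
endpoints to 10⁻⁴ relative. Process integrals are accumulated alongside the
state update with the same midpoint rates, so the O₂ budget closure
(net ΔO₂ = production − 0.5∫R_NO − 1.5∫R_AO − ∫R_het) is exact up to
rounding rather than holding only in the limit of small steps.

**Substrate exhaustion.** Every rate is multiplied by a cubic smoothstep of
its substrate pool(s) that ramps to zero over the last 1 nM. This prevents
negative pools without event detection; combined with the midpoint update
it is self-limiting (the midpoint sees the reduced rate before the full
step is taken). The price is that the last ~1 nM of any depletion curve is
not Michaelis–Menten — tests and fits that compare against closed forms
restrict themselves to the region above ~5 nM.

**Observation model.** `observe_bottle()` reports what the instruments see:
optode DO readings at chosen times with Gaussian sensor noise (default
2 nM) and a detection-limit floor (10 nM for trace-level sensor spots,
100 nM for wide-range spots) — readings below the limit are reported *at*
the limit and flagged censored — and endpoint atom-percent values with
Gaussian noise whose default (1.1 × 10⁻⁴ at%) is the 0.3‰ δ¹⁵N measurement
precision converted at natural abundance.

**Seeding.** One master seed; each bottle derives a child seed by stable
integer mixing of the master seed and the bottle index, so adding bottles
to a design never changes earlier bottles' noise. All randomness is scoped
with `withr::with_seed()` and never touches the caller's RNG state.

**What the simulator does and does not emulate.** It reproduces the
statistical structure the inference stages assume: Michaelis–Menten-limited
drawdown with sensor noise and censoring, isotope-label transfer and
dilution, nitrate reduction resupplying nitrite, and Rayleigh dual-isotope
evolution with reoxidation overprinting. It does not model anammox,
denitrification beyond the lumped `R_NAR`, sulfur or methane oxidation,
microbial growth, or any advective physics. Passing tests therefore show
that the estimators invert the processes they claim to invert — not that
those are the only processes in real OMZ water.

## Inverting ¹⁵N tracer endpoints into rates

Nitrite oxidation rates come from ¹⁵NO₂⁻-labelled bottles via

rate = (nₜ − n₀,NO₃) · [NO₃⁻] / (n̄_NO₂ · t)

where nₜ is the at% ¹⁵N of nitrate at the end of the incubation (corrected
for ¹⁵NO₃⁻ contamination of the spike by mass balance on the nitrate pool),
n₀,NO₃ the unlabeled-nitrate baseline, and n̄_NO₂ the average labelling of
the nitrite pool over the incubation.

**The exponential average.** The labelled NO₂⁻ pool is continuously diluted
by unlabeled NO₂⁻ produced from ammonia oxidation. With pool size held
constant by balanced production and consumption and a dilution constant
k = R_AO/[NO₂⁻], the labelling decays as n(τ) = n₀e^(−kτ) and its time mean
is n̄ = n₀(1 − e^(−kt))/(kt). This is the only closed form consistent with
constant measured pool sizes and a constant measured ammonia oxidation
rate; a series expansion below kt = 10⁻⁶ supplies the continuous k → 0
limit. Nitrate reduction also delivers (nearly unlabeled) nitrite, but no
incubation-scale measurement constrains its in-bottle rate, so it is not in
the dilution term; the simulator includes the pathway so its effect on the
inversion can be quantified.

**Known bias.** The equation uses the *absolute* at% of the nitrite pool in
the denominator while the numerator is the *excess* over the nitrate
baseline. On simulated truth this makes the inversion conservative by the
ratio of natural abundance to spike labelling (≈ −4% at a 10% spike of
98 at% tracer). The package implements the equation in its standard printed
form; the recovery tests document the bias and show it stays within the 5%
acceptance band.

**Detectability.** At%-measurement noise propagates to the rate by
first-order error propagation; a bottle is flagged non-detectable when the
at% excess is below 3× the propagated noise of the difference. Negative
excesses are reported as rate 0 and non-detectable — tracer accumulation
cannot be negative, so a negative excess is noise, not a rate.

Ammonia oxidation rates use the analogous product-pool form
(Δat% of NO₂⁻+NO₃⁻, normalized by the NH₄⁺ labelling), and low-concentration
nitrate isotope samples are corrected for carrier additions by two-member
mass balance.

## Oxygen consumption and the linearity screen

OCR is the decline of dissolved O₂: the endpoint estimator for every
bottle, and the OLS slope for continuously monitored bottles (censored
readings excluded; fewer than three usable points falls back to endpoints;
more than half censored is reported indeterminate). Replicate bottles at a
depth aggregate as mean ± sample SD, flagged when fewer than five
replicates are available.

Drawdown curves are screened for nonlinearity with the maximal information
coefficient: a series is linear iff r² > 0.6 **and** MIC − r² < 0.2 (both
thresholds configurable). MIC is ≈ 1 for any noiseless functional
relationship, so a large MIC − r² gap flags a strong but nonlinear
dependence — a consumption rate changing as O₂ is drawn down. At the series
lengths involved (≤ ~50 points) the package computes MIC exactly within its
grid family: one axis is split into equal-frequency bins, the other axis's
partition is optimized exactly by dynamic programming over all cut
positions (mutual information is additive over x-intervals, making the
search exact), both orientations are tried, and grids satisfy
a·b ≤ B(n) = max(4, n^0.6). A brute-force enumeration oracle in the test
suite confirms the DP search.

Two observation-handling rules differ deliberately between shape and rate:

* the **linearity screen** uses the reported values *including* censored
  readings held at the detection limit — a trace flattening onto the limit
  is precisely the signature of a drawdown curve bending over;
* **rate and kinetics fits** exclude censored readings, and the integrated
  depletion fit additionally excludes readings within ~3 sensor standard
  deviations of the limit (`min_do`): one-sided censoring keeps only upward
  noise excursions near the limit, which flattens the apparent tail and
  inflates Km by ~10% at 5 nM noise if left in.

## Michaelis–Menten oxygen affinities

**Overall fits** regress per-bottle rates on mean bottle DO across an
oxygen manipulation experiment, v = vmax·S/(Km + S), by multi-start
nonlinear least squares (initial Km at 0.1×, 1× and 10× the median DO,
initial vmax at the maximum observed rate; lowest converged SSE kept) —
saturation fits on narrow DO ranges are initialization-sensitive. A fit
whose Km Wald p ≥ 0.05 is reported but flagged NS; r² is 1 − SSres/SStot
about the mean, the conventional definition for nonlinear fits.

**Low-level fits** use bottles whose mean DO sits below ~235 nM and whose
drawdown bends as O₂ passes through the half-saturation range: the
integrated depletion model t(S) = (S₀−S)/vmax + (Km/vmax)·ln(S₀/S) is
inverted numerically on a log-spaced grid and fitted to the DO readings by
least squares. S₀ is fixed to the first usable reading by default
(estimable on request); vmax is a nuisance parameter. Both limits behave
correctly by construction: Km ≫ S₀ degenerates to exponential decay where
only vmax/Km is identified, and Km → 0 to a straight line of slope vmax.

Under realistic noise the Km estimate is right-skewed (it is a curvature
parameter); recovery studies therefore report the median over replicate
experiments, which carries a few percent of residual skew-induced error.
The per-fit standard error (~35% relative at 5 nM sensor noise on a 235 nM
decline) is the honest statement of what one bottle constrains.

## Partitioning oxygen consumption

Nitrogen oxidation rates convert to O₂ demand with the fixed stoichiometric
factors (0.5 and 1.5 mol O₂ per mol N), and nitrite oxidation's share of
oxygen consumption is 100·0.5·R_NO2ox/OCR. Shares above 100% are kept and
flagged, not capped — they carry information about rate-method mismatch,
and near-100% values are exactly the regime of interest. Records with
OCR ≤ 0 are undefined and dropped with a log entry; profile records above a
configurable DO ceiling (default 18 µM) are excluded from the DO-dependence
analysis.

The share-versus-DO relation is fitted as a power law pct = a·DO^b by OLS
in log₁₀–log₁₀ space — the standard choice, treating multiplicative scatter
symmetrically — using only records with positive share and DO. The DO at
which nitrite oxidation accounts for a target share (default 100%) is the
inverted fit DO* = (target/a)^(1/b), meaningful as a threshold only for
b < 0 (share rising as DO falls); the solver warns otherwise.

## Dual nitrate isotopes

Respiratory nitrate reduction enriches δ¹⁵N and δ¹⁸O of residual nitrate
1:1; nitrite reoxidation decouples them because reduction removes an O atom
and reoxidation appends a new, water-derived one while returning the same N
atoms. The deviation statistic is Δ(15,18) = (δ¹⁵N − ref15) −
slope·(δ¹⁸O − ref18) with slope 1 by default (configurable for ¹⁸ε/¹⁵ε ≠ 1
sensitivity runs); more negative values are larger departures. Measurement
precision (0.3 and 0.4‰) propagates to √(0.3² + slope²·0.4²) ≈ 0.5‰ per
value.

The reference pair anchoring the 1:1 line is a genuine free choice: the
package defaults to the shallowest measurement of a profile (source water
above the overprinted layer) with a fixed-value override, and records the
reference on every result — Δ magnitudes depend on it, though signs and the
peak-deviation depth within a profile do not.

The simulator's dual-isotope generator evolves both systems by Rayleigh
distillation (δ = δ₀ − ε·ln f) and mixes back a reoxidized fraction
carrying the accumulated-product δ¹⁵N and a water-derived δ¹⁸O end-member.
With equal isotope effects and no reoxidation the trajectory stays on the
1:1 line to rounding error, which the tests assert at 10⁻⁹ ‰.

## The pipeline and its design choices

`run_pipeline()` chains the stages on a synthetic station: profile →
bottles → tracer rates (ammonia first, feeding the dilution term of the
nitrite inversion) → OCR and the linearity screen → kinetics → partition →
isotopes, with one structured log line of record counts per stage, full
determinism under the config seed, and a config hash recorded in every
output file (mismatched output directories are refused unless forced).
Three choices deserve explanation:

* **Oxygen floor for deep bottles (`do_floor`, 300 nM).** Bottles filled
  from depths with no measurable O₂ would censor every reading. Sampling
  unavoidably introduces some O₂ at such depths, and the resulting rates
  are potential rates; the pipeline makes that explicit as a minimum
  starting DO.
* **Kinetics from a manipulation experiment, not across depths.** Rate
  versus DO across profile depths mixes assemblages with different maximal
  rates and is not a single saturation curve; the overall Km/vmax fits
  therefore use a simulated 24-bottle oxygen manipulation experiment
  (8 DO levels × 3 label treatments) at one depth.
* **Same-bottle pairing.** Where a bottle has both a nitrite oxidation rate
  and an OCR (the ¹⁵NO₂⁻ bottles of an experiment), its share of OCR is
  computed within that bottle; profile records pair depth-mean rates.

## Problem sizes and reproducibility

The recovery studies shipped with the package use 8-bottle experiments with
10% multiplicative rate noise and 200 replicate seeds for the overall
affinity fits; 200 replicate observations of a 19 h, 20-reading decline at
5 nM sensor noise for the low-level fit; and 50 replicate bottles per class
at 2 nM noise for the linearity screen — sizes chosen to pin medians to a
few percent while keeping the full suite runnable in about a minute.
`scripts/acceptance.R` recomputes every headline quantity from scratch at
those sizes under a caller-supplied seed.

## Known limitations

* Eq.-form tracer inversion is conservative by ≈ natural abundance / spike
  labelling (~4% at default spikes); it is implemented in its standard
  printed form rather than re-derived.
* The low-level Km estimator is median-biased upward by a few percent under
  noise (curvature parameter, right-skewed); per-fit standard errors are
  wide and honest.
* The in-bottle nitrate-reduction pathway dilutes the nitrite label but has
  no measurable incubation-scale constraint; the inversion ignores it (the
  simulator can quantify the resulting bias for any assumed rate).
* MIC is exact only within the equal-frequency × optimized-interval grid
  family; at n ≤ 50 with B(n) = n^0.6 this family is what the statistic's
  definition explores at these sizes, and the monotone-invariance tests
  bound the residual grid-granularity effect at 0.05.
* Percentages of OCR compare rates measured by different methods (tracer
  endpoint vs DO decline); values above 100% are possible and flagged, and
  the power-law threshold is an extrapolation whenever 100% lies outside
  the observed share range.
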