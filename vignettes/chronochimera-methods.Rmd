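---
title: "Methods: quantifying social bias in Dictyostelium chronochimeras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying social bias in Dictyostelium chronochimeras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

When starving *Dictyostelium discoideum* cells aggregate, some become
spores, some die building the stalk, and some never join an aggregate at
all (the "loners"). In a binary mix where a focal population makes up a
fraction $f$ of cells before aggregation, its social outcome is summarised
by two deviations:

* **spore bias** $f_S - f$: its share among spores minus its initial share;
* **loner bias** $f_L - f$: its share among non-aggregated cells minus its
  initial share.

A *chronochimera* is such a mix in which the two populations differ only in
the phase of vegetative growth at which they were harvested (early, mid,
late exponential, or early stationary: EE / ME / LE / ES). The package
computes these biases from two-colour count tables, corrects them for the
intrinsic bias introduced by the fluorescent labels, fits
frequency-dependent bias profiles, maps profiles onto multi-generation
evolutionary dynamics, and characterises the single-cell motility structure
that the go-or-grow hypothesis proposes as the mechanism.

## Bias profiles and the label correction

GFP- and RFP-transformed but otherwise identical populations show a
reproducible spore bias against each other. This *label bias* is estimated
from isogenic same-stage co-cultures across a range of frequencies and
summarised by a cubic polynomial constrained to vanish when either colour
is absent. Every cubic with $B(0)=B(1)=0$ can be written

$$B(f) = f\,(1-f)\,(a + b f),$$

a two-parameter linear family spanned by $\{f(1-f),\, f^2(1-f)\}$, so the
fit is an ordinary (optionally count-weighted) least-squares solve and the
endpoint constraints hold exactly by construction rather than as fitted
side conditions. We deliberately fit rather than interpolate: replicated,
noisy points at shared frequencies make exact interpolation ill-posed. The
default is unweighted; event-count weighting is exposed as an option
because either convention is defensible when all counts have similar size.

The corrected bias of a chimera is `raw_bias - L(f)`, with the fitted label
profile $L$ evaluated at the chimera's *measured* initial fraction, not its
nominal target mix, since pipetting errors shift the realised $f$.
Consistency of the calibration is checked by `label_swap_check()`: swapping
the labels exchanges focal and partner, so the two profiles must satisfy
$B_{AB}(f) \approx -B_{BA}(1-f)$ on a dense grid.

Admissibility of a label-bias model used for *generation* is stricter than
for a fitted summary: a bias shifts a measured fraction, so
$|L(f)| \le \min(f, 1-f)$ must hold everywhere; `validate_label_bias()`
enforces this on a 1001-point grid.

Bias measurements carry percentile bootstrap intervals (default 1000
resamples, seeded) obtained by parametrically resampling both binomial
counts; fractions of exactly 0 or 1 are retained without continuity
correction, since the bias remains well defined there.

## From bias profile to evolutionary dynamics

Treating one social cycle as one generation and assuming spores alone seed
the next cycle, the minimal between-generation map is

$$f' = \mathrm{clamp}\big(f + B(f),\, 0,\, 1\big).$$

Clamping makes the endpoints absorbing (an extinct type cannot recover).
The map composes spore formation only — no differential spore viability or
germination — because the bias is measured at the spore stage. Interior
fixed points are the roots of $a + b f$ (analytic, no root search), and
stability follows the one-dimensional multiplier $\lambda = 1 + B'(f^*)$:
stable if $|\lambda| < 1$, unstable if $|\lambda| > 1$, neutral within a
tolerance (default $10^{-8}$) of $|\lambda| = 1$. A stable interior fixed
point is a coexistence equilibrium; the derivative criterion is verified in
the test suite against brute-force iteration from perturbed starts and a
$10^5$-point grid scan.

Social behavior is classified per frequency: *cheater* where the corrected
bias is positive, *cooperator* where negative. The neutral band is by
preference tied to measurement uncertainty (a bootstrap interval covering
zero) rather than a fixed epsilon; a scalar noise floor is available as a
fallback.

## Single-cell motility

Per cell, the time-averaged mean squared displacement uses overlapping
frame pairs: $\mathrm{MSD}(k\,\Delta t) = \langle \lVert x_{i+k} - x_i
\rVert^2 \rangle_i$. Overlapping pairs are the standard per-trajectory
estimator; a non-overlapping variant is config-exposed because the
convention is not universal. The motility criterion is the ordinary
least-squares slope of $\log \mathrm{MSD}$ against $\log \Delta t$ over
lags strictly below 150 s with lag 0 excluded — at the 30-s frame interval
of the assay design that is exactly the four lags 30, 60, 90, 120 s. Cells
are classified *non-migrating* when the slope falls below 0.5, the valley
between the two modes of the slope distribution; a tie at the threshold
goes to *migrating*, a convention we document because equality is not
otherwise defined. A trajectory with a zero MSD among the usable lags never
moved at those scales and is assigned slope 0 instead of failing on
$\log 0$. Stored MSD curves are capped at a quarter of the track duration
to control estimator variance; the fit window is independent of that cap.

Group contrasts use the two-sample Student t test or the Mann–Whitney U
test. For designs where replicates rather than cells are the exchangeable
units we provide a replicate-stratified permutation test (difference of
group means of replicate means; group labels permuted across replicates,
default 5000 draws, seeded) instead of a linear mixed-effects model — a
deliberately simpler inference whose null distribution is exact under
exchangeability of replicates.

## The synthetic experiment

No public single-cell or count data accompany the measurement design the
package implements, so the generator module produces every input under
stated distributions and a single seed:

* **Counts.** A measured mix is a binomial draw of `n_events` events with
  success probability $\mathrm{clamp}(f + L(f), 0, 1)$. Clamping mirrors
  physical fractions. Default $10^4$ events per measurement, 9 frequencies
  ($0.1$–$0.9$), 3 technical replicates.
* **Trajectories.** Migrating cells follow a persistent random walk —
  constant speed $0.1\ \mu m/s$ (6 µm/min, a typical vegetative crawling
  speed) with heading angle diffusing so that direction decorrelates over a
  300-s persistence time. Any model with a tunable log-log MSD slope
  between ~1 and ~2 would do; the persistent random walk is the standard
  minimal choice. Non-migrating cells are modelled as confined jitter: an
  Ornstein–Uhlenbeck position process with diffusivity
  $0.01\ \mu m^2/s$ and confinement radius $0.5\ \mu m$ (relaxation time
  $r^2/D = 25$ s), giving a near-flat MSD at the sampled lags and hence a
  slope well below the 0.5 threshold. An *unconfined* low-diffusivity walk
  would have slope ~1 and be classified as migrating, contradicting the
  observation that these cells barely move; setting the radius to infinity
  deliberately recovers a pure Brownian walk (used as a benchmark), and
  zero diffusivity gives perfectly stationary cells. Frames every 30 s for
  1 h, ~600 cells per sample, matching the assay design.
* **Go-or-grow chimeras.** Each cell draws a motility class from its
  population's mixture weight, then loner status from a class-specific
  probability with $q_{nm} \ge q_m$ (the go-or-grow ordering: low-motility,
  putatively dividing cells aggregate less efficiently). The hypothesis
  fixes only this ordering, not the values; $q_{nm} = 0.8$ and
  $q_m = 0.1$ are free defaults chosen to separate the classes clearly, and
  are exposed in configuration rather than calibrated. Aggregated cells
  enter a weighted draw without replacement for a fixed total spore count
  (80% of aggregated cells), with a single multiplier isolating any
  developmental sporulation bias; weight 1 makes sporulation neutral
  (hypergeometric, exactly unbiased). Closed-form compartment expectations
  (`expected_chimera_fractions()`) provide the oracle against which the
  Monte-Carlo sampler is tested. With equal parameters and neutral weight,
  both expected biases are exactly zero.
* **Label-bias emulation.** The intrinsic label effect is a
  spore-production bias — isogenic co-cultures at frequency $f$ show spore
  bias $L(f)$ — so the measurement emulator shifts the spores compartment
  by $L$ evaluated at the chimera's initial frequency, matching how the
  correction later subtracts it.

One user-facing seed expands into named child streams
(`child_seed(seed, stream)`), so counts, classes and trajectories can be
regenerated independently; all outputs are bit-reproducible given the seed.

What the generator does *not* emulate: spatial aggregation (cAMP
signalling, streams, territory geometry), tracking artefacts (localisation
noise, gaps, broken tracks), cell division during the assay, and
between-replicate biological variance beyond sampling noise. Passing tests
therefore demonstrate correctness of the estimators and the internal
consistency of the mechanism, not that real chronochimeras obey the
go-or-grow model.

## Adhesion assays

Both adhesion assays reduce to a fraction $(\text{total} -
\text{free})/\text{total}$ of a total and a "free" density, with a Wilson
interval when an effective counted-cell number is supplied. The substrate
assay's written protocol literally defines the *unattached* fraction while
naming it the fraction of adhesive cells; we default to the attached
fraction, consistent with the cell-cell formula and with the direction of
the reported trend, and expose the literal reading behind a flag rather
than silently resolving the ambiguity. Trends across the growth-phase
order EE < ME < LE < ES combine a Spearman rank statistic (defined as 0,
p = 1 for constant fractions, where the correlation is otherwise
undefined) with pairwise consecutive-stage tests.

## Numerical choices and degenerate inputs

* Fractions require at least one counted event; zero-total rows raise an
  error naming the sample rather than producing NaN.
* The constrained-cubic fit requires two distinct interior frequencies and
  raises distinct errors for insufficient data and rank deficiency.
* Bias antisymmetry under focal/partner swap holds to floating-point
  round-off (two divisions), i.e. $\sim 10^{-16}$; tests assert it at
  $10^{-12}$.
* The degenerate profile $B \equiv 0$ makes every frequency a fixed point;
  `find_fixed_points()` flags this case and reports the endpoints as
  neutral instead of enumerating a continuum.
* Trajectory validation enforces $\ge 2$ frames, no duplicate frames, and
  a uniform frame interval (relative tolerance $10^{-6}$).

## Problem sizes

The shipped analysis uses 9 frequencies × 3 replicates × $10^4$ events per
count, $10^4$ cells per simulated chimera, and 600 tracked cells per
motility sample — the scale of one experimental campaign. Verification
runs use 200-seed replications for unbiasedness checks, 100 random
profiles for the fixed-point cross-validation, and 500 tracks for the
Brownian slope benchmark; these sizes give Monte-Carlo standard errors an
order of magnitude below the tolerances being asserted.

## Known limitations

* The frequency map is deterministic; demographic stochasticity between
  cycles (drift at finite spore counts) is out of scope, as are mixes of
  more than two populations.
* Loner-probability parameters are not identifiable from the package's own
  synthetic data at the design sizes (only their contrast enters the
  biases); they are inputs, not estimands.
* The weighted spore draw with a non-neutral weight follows successive
  sampling without replacement, whose expectation deviates from the simple
  reweighting formula at order $1/n_{\mathrm{agg}}$; with the neutral
  default the draw is exactly unbiased.
* The label correction assumes the intrinsic bias acts at the spore stage
  and is identical across chronochimeras, as in the calibration design; a
  stage-dependent label effect would not be removed.
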