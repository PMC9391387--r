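---
title: "Compression-complexity causality with ordinal patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression-complexity causality with ordinal patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccausality)
```

## The problem

Given two scalar time series \(x(t)\) and \(y(t)\) observed from coupled
dynamical systems, we want to decide whether \(x\) drives \(y\), \(y\)
drives \(x\), both, or neither — with short records, observational noise,
and missing or irregularly spaced samples, the regime typical of
paleoclimate proxies, physiological recordings and ecological counts.
Model-based Granger tests and density-based information measures degrade
quickly under exactly these conditions.  Compression-complexity causality
(CCC) replaces probability densities with lossless-compression effort, and
its permutation variant (PCCC) adds delay-embedding plus ordinal coding so
that the method applies to observables of multidimensional systems whose
remaining coordinates are unobserved.

## Effort-to-compress and the CCC statistic

The complexity primitive is the effort-to-compress (ETC) of a
finite-alphabet sequence: the number of non-sequential recursive pair
substitution (NSRPS) iterations needed to reduce the sequence to a
constant or length-1 sequence.  Each iteration replaces the most frequent
adjacent pair — counted non-overlapping, greedily left to right — with a
fresh symbol.

Two conventions are deliberately frozen here:

* **Tie-break.** When several pairs share the maximal count, the pair
  whose first counted occurrence appears earliest in the sequence wins.
  This positional rule makes the step count *exactly* invariant under any
  bijective relabeling of the alphabet.  A value-based rule (e.g. the
  lexicographically smallest pair) does not have this property: roughly 2%
  of short random sequences change their ETC under a symbol permutation,
  which would break the exact identity `ccc(x, x) = 0` that the causality
  statistic relies on.  All worked examples in the documentation are
  reproducible under the positional rule.
* **Termination.** A constant sequence is fully compressed (`etc = 0`),
  so ETC of a length-\(L\) sequence lies in \([0, L-1]\).

Windowed CCC from \(x\) to \(y\) compares two conditional
compression-complexities over sliding windows (past length \(L\), future
length \(w\), step \(\delta\)):

\[
CC(\Delta y \mid y_{past}) = ETC(y_{past}+\Delta y) - ETC(y_{past}),
\]
\[
CC(\Delta y \mid y_{past}, x_{past}) =
  ETC(y_{past}+\Delta y,\, x_{past}+\Delta y) - ETC(x_{past}, y_{past}),
\]

where the two-argument ETC compresses the product-alphabet pair sequence.
The averaged difference of the two terms over all windows is
\(CCC_{x \to y}\).  If the joint description of \(\Delta y\) with the
candidate cause is no more compressible than the self description, there
is no causation.

Two numerical facts about this estimator are worth knowing:

* `ccc(x, x)` is *exactly* zero for every window geometry: for identical
  inputs the pair coding is a relabeling, and ETC is relabeling-invariant
  under the positional tie-break.
* Under independence the raw-step CCC is *not* centered on zero: the
  product-alphabet joint sequences systematically need more substitution
  steps than the single-alphabet self sequences (about \(-2.8\) for iid
  4-symbol streams with \(L=25, w=15, \delta=20\)).  This offset is a
  property of the estimator, shared identically by the original pair and
  its surrogate pairs, and is therefore absorbed by the surrogate
  calibration below.  CC terms use raw step counts by default; a
  `normalized` option divides each ETC by its sequence length minus one.

## Ordinal patterns and PCCC

For multidimensional systems, the driver candidate is forward delay
embedded, \( \hat x(t) = (x(t), x(t+\eta), \ldots, x(t+(m-1)\eta)) \), and
each delay vector is replaced by its ordinal pattern: ranks \(0\) (lowest)
to \(m-1\) (highest), exact ties broken by order of occurrence (the
earlier occurrence takes the smaller label), then mapped to the
lexicographic index of the rank permutation, giving an alphabet of
\(m!\) symbols.  The target series is *not* embedded — full
dimensionality of the cause suffices to predict the effect — but is
truncated to the common time range and binned into \(m!\) equal-width
amplitude bins, so both inputs to the windowed CCC share the alphabet
size.  The embedding delay \(\eta\) is chosen as the first local minimum
of the binned auto mutual information.

## The conditional-mutual-information comparators

Three plug-in estimators are provided for comparison, all in nats with
raw empirical frequencies (no pseudocounts):

* `cmi1`: \(I(x(t);\, y(t+\tau) \mid y(t))\) after equiquantal binning
  with \(Q\) bins per series,
* `cmi3`: the same with the conditioning set extended to the backward
  embedding \((y(t), y(t-\eta), \ldots, y(t-(m-1)\eta))\),
* `pcmi`: both series ordinal-encoded, with the horizon shifted to
  \(\tau' = \tau + (m-1)\eta\) so the symbolized past and future of the
  response do not overlap (equivalent to symbolic transfer entropy).

The estimator for continuous series is marginal-equiprobable
(equiquantal) binning; \(Q = 8\) by default, configurable.  Plug-in bias
is not corrected analytically — the surrogate ensemble carries the same
bias and cancels it in the test.

## Significance protocol

Every causality decision uses surrogate calibration: `n_surr` surrogate
pairs (surrogate \(i\) of \(x\) with surrogate \(i\) of \(y\)) are
generated — classic single-iteration AAFT for simulation studies,
stationary bootstrap with geometric mean block length \(1/p\), \(p=0.1\),
for irregularly sampled records — the measure is evaluated on the
original and all surrogate pairs, and a one-sided z-test at
\(\alpha = 0.05\) (threshold \(z > 1.6449\)) decides significance.

For the signed CCC-family statistics the test is applied to the coupling
*strength* \(|CCC|\).  The sign of CCC carries the nature of the coupling
and the magnitude its strength; empirically, coupling in the oscillator
benchmark below drives the signed PCCC *below* its surrogate
distribution, so a one-sided test on the signed value would be blind to
it, while the magnitude test detects it and leaves the self-coupling case
(`ccc = 0` exactly) correctly non-significant.  The CMI family is
non-negative and tested as is.  When a record has missing samples,
surrogates are generated from the *full-length* series first and the same
deletion index sets are then applied to the original and every surrogate,
so the null ensemble shares the sampling structure of the tested pair.

## The benchmark generator

The synthetic benchmark is a pair of unidirectionally coupled Rössler
oscillators (parameters \(a=0.15\), \(b=0.2\), \(c=10\); frequencies
\(\omega_1 = 1.015\), \(\omega_2 = 0.985\); diffusive coupling
\(\epsilon\,(x_1 - x_2)\) entering only \(\dot x_2\), with
\(\epsilon = 0.09\)).  The six-dimensional system is integrated with an
adaptive high-accuracy scheme (`deSolve`'s lsoda at relative and absolute
tolerance \(10^{-9}\); only sampled statistics matter, not bit-exact
trajectories), sampled every 0.314 time units — 17 to 21 samples per
oscillation period — with 5000 transient samples discarded.  Initial
conditions are uniform in \(x, y \in [-5, 5]\), \(z \in [0, 1]\); the
transient removal makes this choice immaterial.  Perturbations emulate
measurement conditions: additive white Gaussian noise scaled as a
percentage of the signal standard deviation, and missing samples deleted
at random index sets — shared between the two series (synchronous) or
independent (asynchronous) — with the remainders concatenated, so the
analysis sees shortened series with no gap markers.

What the generator does *not* emulate: observational noise with temporal
structure, non-stationary drifts, age-model (time-stamp) uncertainty of
real proxy archives, and aggregation/smoothing of measurement kernels.
Passing the benchmark therefore shows correct directional inference for
chaotic oscillators under noise and missingness, not validity on any
particular observational archive.

## Parameters that matter

| Parameter | Meaning | Default (benchmark) |
|---|---|---|
| `L` | past-window length, samples | 25 (PCCC), 300 (scalar CCC) |
| `w` | future-window length, samples | 15 (PCCC), 30 (scalar CCC) |
| `delta` | window step, samples | 20 (PCCC), 30 (scalar CCC) |
| `B` | amplitude bins for scalar CCC | 8; forced to `m!` for PCCC |
| `m` | embedding dimension | 3 |
| `eta` | embedding delay, samples | 5 (first auto-MI minimum) |
| `tau` | CMI prediction horizon, samples | 20 |
| `Q` | equiquantal bins for continuous CMI | 8 |
| `n_surr` | surrogate pairs per decision | 100 |
| `alpha` | one-sided significance level | 0.05 |

Window geometries and embedding delays for the shipped real-data
protocols are available via `benchmark_presets()`.  For irregularly
sampled records the horizon is probed over \(\tau = 1\ldots30\) and the
reported statistic is the mean over the grid, computed identically for
original and surrogate series (averaging is the established convention
for this measure family; a maximum aggregation can be obtained by calling
the single-\(\tau\) measures directly).

## Numerical choices and degenerate inputs

* Equidistant bin edges span the full series once, before windowing, so
  windows reuse global symbols; the top bin is right-closed and a
  constant series maps to symbol 0.
* Equiquantal edges sit at empirical quantiles \(k/Q\); heavy ties can
  unbalance counts, and fewer than \(Q\) distinct values is an error.
* The auto-MI delay selector requires a bracketed local minimum; if none
  exists within `max_lag` it returns the global minimum and flags it.
* Degenerate surrogate distributions (zero variance) yield a flagged,
  non-significant decision rather than an error.
* Seeds: every stochastic entry point takes an integer seed and restores
  the caller's RNG state; ensemble runs spawn per-realization and
  per-surrogate seeds from one master seed, so any subset of a sweep is
  reproducible in isolation.

## Ensemble experiment sizes

The acceptance script and the heavier tests use reduced ensembles chosen
as the package's own desk-scale study conditions: 25 realizations per
condition (full-scale studies use 100), 100 surrogate pairs per
realization, series length 2048, and the benchmark parameter set above.
The null-calibration property uses 50 independent Gaussian pairs of
length 512 with 60 surrogate pairs each, both directions pooled, which
keeps the binomial band around the nominal 5% rejection rate meaningful.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_coupled_rossler(rossler_config(n_samples = 2048, seed = 1))
res <- causality_significance(
  sim$x1, sim$x2, measure = "pccc", n_surr = 100,
  surrogate_method = "aaft",
  ccc_params = ccc_params(L = 25, w = 15, delta = 20),
  m = 3, eta_x = 5, eta_y = 5, seed = 2)
res
```

The driver direction (`x -> y`) should be reported significant and the
reverse direction not; `res$x_to_y$signed_original` holds the signed
PCCC value.

## Known limitations

* The windowed CCC drops trailing samples that do not fill a complete
  \(L + w\) window; with short records and large \(\delta\) few windows
  remain and the statistic becomes noisy.
* Raw-step CC terms subtract ETCs of different-length sequences; their
  absolute scale is not comparable across window geometries (use the
  `normalized` option for cross-geometry comparisons).
* Series with non-synchronous time stamps must be aligned by the caller;
  `run_pair_analysis` documents but does not interpolate.
* Multivariate conditioning (partialling out a third observed process) is
  out of scope; the condition-embedded CMI conditions only on the
  response's own past.
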