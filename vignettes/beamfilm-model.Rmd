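---
title: "The beam-film model of crossover patterning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The beam-film model of crossover patterning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamfilm)
```

## The model

Meiotic crossovers (COs) are patterned: a CO-designation at one position
disfavours further designations nearby (CO interference), and multiple COs
on one bivalent tend to be evenly spaced. The beam-film (BF) mechanism
explains this with mechanical stress: a chromosome under stress "cracks"
at its most reactive recombination precursor, the crack relieves stress
locally, and the relief spreads outward with exponential decay, lowering
the probability of further designations nearby.

`beamfilm` simulates this process per bivalent:

1. **Precursor array.** A count is drawn from the binomial family indexed
   by the constancy parameter `B` (`Binomial(round(N/B), p = B)`; Poisson
   at `B = 0`, a constant `round(N)` at `B = 1`). Positions are placed
   along `[0, 1]` with evenness `E` (below) and warped through the inverse
   cumulative density transform of an optional precursor density profile
   (so a centromeric "black hole" stays empty). Each precursor gets a
   sensitivity `s ~ Uniform(0, 1)`.

2. **Designation.** The driving force `S` ramps from 0 to `Smax`. The
   local effective stress at position `x` is `S * R(x)` with

   `R(x) = max(0, 1 - sum_j e^{-|x - x_j|/L} - (1-cL) e^{-x/L} - (1-cR) e^{-(1-x)/L})`,

   summing the relief spreading from every existing designation `x_j` and
   from the two chromosome ends. A fully clamped end (`c = 1`) is neutral;
   a free end (`c = 0`) acts like a pre-existing crack; `c > 1`
   hyper-clamps, locally raising `R` above 1. Precursor `i` designates
   when `S * R(x_i) * reactivity(s_i)` first exceeds a unit-rate
   exponential deviate, where `reactivity` is `s^2`, `s`, `5/s` or `1/s`
   for the four laws `A = 1..4`. Designations are strictly sequential —
   the engine repeatedly designates the precursor with the smallest
   required force, updates the relief field, and stops when that force
   exceeds `Smax` — which is exactly equivalent to a continuous ramp
   because relief only accumulates.

3. **Maturation.** Each designated CO is retained independently with
   probability `M`.

### Why designation is stochastic given `s`

The designation rule is the one genuinely open modelling choice: the
verbal description ("the most reactive precursor goes critical first")
admits both a deterministic threshold (designate iff
`S * R >= 1/reactivity`) and a stochastic rate reading (reactivity is a
designation *hazard* per unit driving force, so the chance of escaping
designation up to force `S` at relief `R` is `exp(-reactivity * R * S)`).
We implemented both and compared them against the published simulation
outputs for yeast chromosome III and the Drosophila X chromosome. The
deterministic threshold over-predicts every zero-CO fraction by a factor
of 2–3 (e.g. 0.026 instead of 0.01 for yeast III with constant precursor
numbers). The hazard rule reproduces all four published zero-CO values
with no free parameters (0.013 / 0.044 / 5.1% / 0.0086 against
0.01 / 0.04 / 5% / 0.008), so it is the rule this package uses.
`designationThreshold()` still returns the deterministic scale
`1/reactivity`; the engine multiplies it by the exponential deviate.

The trade-off is documented rather than papered over: with a hazard rule,
very reactive precursors occasionally designate inside a partly relieved
zone, so short-range interference is softer than under a hard threshold.
For parameter sets where the interference distance is a large fraction of
the chromosome (grasshopper `L = 0.3`, tomato `L = 0.65`) the simulated
`L_CoC` comes out roughly half of `L` rather than approximately equal to
it, and the fitted inter-CO gamma shape co-varies weakly with `Smax`
instead of inversely. For the yeast-like regime (`L` up to ~0.25 of
length, `A = 1`) `L_CoC` tracks `L` within about 20%. A rule that
combines a stochastic first-designation stage with a harder short-range
blockade would reconcile both regimes; we did not invent the extra
parameter such a hybrid needs.

### Evenness calibration

`E` interpolates between random (`E = 0`) and perfectly even (`E = 1`)
precursor spacing. Positions are the per-bivalent mixture
`(1 - w) * sorted-uniform + w * even-grid` with grid
`g_i = (i - 0.5)/n` (half-gap margins keep the ends precursor-free on
average, like random placement). The weight `w(E)` is a fixed monotone
table calibrated once (`data-raw/evenness-calibration.R`): `w` at
`E = 0.6` and `E = 0.7` was found by bisection so that the
maximum-likelihood gamma shape of pooled interior gaps (13 precursors per
bivalent, 5000 bivalents) equals the published anchors 2.4 and 4.2;
`E = 0` and `E = 1` are exact limits (shape 1 and infinity); intermediate
values interpolate linearly. The calibrated weights are 0.227 and 0.398.
Only the anchors constrain the mechanism; the mixture itself is a package
choice.

## Descriptors

* **CoC curve** (`computeCoC`): equal intervals, per-bivalent
  presence/absence per interval (multiple COs in one interval count
  once), `CoC = observed/expected` double frequency per interval pair,
  averaged over pairs at the same centre-to-centre distance. Positions
  map to intervals by `floor(p/size)` with the last bin absorbing
  `p = 1`. Distances are quantized to interval multiples, which makes
  "same inter-interval distance" exact. A warning enforces the rule that
  the interval should be under 1/4 of the mean inter-CO spacing.
* **L_CoC** (`lCoC`): linear interpolation of the first upward crossing
  of 0.5; `NA` when the curve never drops below 0.5 (interpolation was
  chosen over nearest-point to remove the interval-width bias at coarse
  analyses).
* **Event distribution** (`eventDistribution`): exact histogram, mean,
  zero-CO fraction with a Wilson 95% interval.
* **Gamma shape** (`fitGamma`): two-parameter maximum likelihood, Newton
  iteration on `log(k) - digamma(k) = log(mean) - mean(log)` to 1e-8,
  initialised at the standard closed-form approximation; refuses fewer
  than 10 gaps; shape is scale-invariant so fraction and micron units
  agree. Gaps pool interior adjacent distances from bivalents with 2+
  COs.
* **Homeostasis and obligatory-CO sweeps** (`homeostasisSweep`,
  `zeroCOSweep`) and the strength ratio `L_CoC / inter-precursor
  distance` (`homeostasisStrength`).
* **Grid-search fitting** (`fitScan`): simulates every combination with
  common random numbers and scores CoC-curve RMSE, |Δ mean CO|,
  total-variation distance between event distributions, and |Δ zero-CO|,
  z-scaled across the grid and combined with user weights (default all
  1). The full ranked table is always returned so the user can apply
  their own judgement, mirroring the staged workflow (coarse `N`/`L`,
  then `Smax`, then refinement) that the `fit` CLI command supports via
  repeated config keys.

## Numerical and design choices

* Coordinates are fractions of chromosome length throughout; micrometres
  appear only at I/O boundaries (`length_um` column, `LUm` argument,
  `unit = "um"`). Conversions are exact inverses.
* Relief is additive with a floor at zero; hyper-clamped ends may raise
  `R` above 1. The per-side decay constant equals `L`. `R` is forced to 0
  exactly at a designation site (a crack supports no stress) even when a
  hyper-clamp term would lift it.
* Ties in required force break by lower precursor index, making replay
  under a seed deterministic; exact ties have probability zero for
  continuous positions.
* One user seed expands into per-bivalent substreams through a
  prefix-stable Lehmer sequence, so bivalent `i` is identical whether
  5,000 or 50,000 bivalents are simulated, and any CLI invocation is
  byte-for-byte reproducible.
* Two-round patterning redraws sensitivities for the intermediate array
  (nothing constrains them); a bivalent with an empty first round has an
  empty second round.
* Non-interfering COs: the per-precursor selection probability
  `p = f*T/((1-f)*A)` (clipped to 1) makes added COs the target fraction
  of the total in expectation; expectation-matching is the only stated
  constraint.
* The grasshopper centromeric density profile ramps linearly to an
  exactly-zero core over two bins on each side; only "density decreases
  to zero over a region" is constrained, and any bin touching the core
  is fully dead so that the hole carries no probability mass.

## Problem sizes

The test suite and the acceptance script use 5,000–20,000 bivalents per
simulation: 20,000 for small zero-CO tails (binomial tails need the
larger sample), 5,000–10,000 for means, CoC curves and gamma shapes —
the same order as the published analyses, which used 5,000-chromosome
simulation sets against ~300-bivalent experimental data sets. At these
sizes the Monte-Carlo standard error of a zero-CO fraction near 0.01 is
about 0.0007 and of a mean CO count about 0.015.

## What the synthetic data do and do not show

The simulator doubles as the package's data generator: simulated
`BivalentSet`s are written in the same per-bivalent TSV dialect as
experimental tables, and the shipped fixtures (a hand-checkable
4-bivalent CoC example, a yeast-XV-like set, an interference-free Poisson
set, a grasshopper-like set with a black hole — all labelled synthetic)
exercise every analysis path. Passing tests on these data show the
*descriptors* and the *engine* are internally correct and reproduce the
published simulation outputs; they do not validate the biological model
against new experimental data, cope with measurement error in focus
positions (positions are exact), or model inter-chromosome length
variation within a data set (experimental tables may carry per-bivalent
lengths, but simulations use one length).

## Known limitations

* The designation-rule ambiguity above: large-`L` parameter sets
  (grasshopper, tomato) under-reproduce the published `L_CoC`, and the
  gamma-shape/`Smax` relation is flatter than published.
* The reactivity laws are implemented exactly as tabulated
  (`A3 = 5/s`), although the published zero-CO ordering across laws
  (lowest for `A = 4`, rising through 3, 2, 1) suggests the third law may
  sit between `s` and `1/s`; no analysed organism's best fit is affected
  except tomato (`A = 3`).
* The published grasshopper homeostasis-strength spacing (2.6 um from
  94 um / 14 precursors = 6.7 um) is internally inconsistent;
  `homeostasisStrength()` therefore takes both distances as explicit user
  inputs and resolves nothing.
* The composite fit score replaces an external projected-likelihood
  score with a transparent weighted sum of exactly the comparisons the
  original fitting procedure says it uses; it is not a likelihood.
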