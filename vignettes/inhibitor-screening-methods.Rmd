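---
title: "Methods: inhibitor screening, kinetic mechanism selection, and SAS maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inhibitor screening, kinetic mechanism selection, and SAS maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibscreen)
```

This vignette documents the models behind each pipeline stage, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic generators do and do not emulate.

## Screening model

Percent inhibition is computed from 20-minute absorbance changes at 405 nm
as `(1 − ΔA_sample/ΔA_blank) × 100`. Values are deliberately not clipped:
negative values (activation or assay artifacts) and values above 100 are
informative, so they are flagged with a warning outside [−20, 120] instead
of being truncated. A zero blank change makes the ratio undefined and is an
error.

Triage uses the replicate **mean** at the screening concentration (20 µM
by default) against a 90 % threshold, with ≥ interpreted inclusively. The
alternative — requiring every replicate to clear the threshold — is
stricter and noisier for triplicates; the mean is what a screening decision
would normally use.

Concentration–response curves use the four-parameter logistic with
`bottom` fixed at 0 and `top` free within [80, 120]:

$$\%I(c) = \frac{top}{1 + (IC_{50}/c)^{h}}$$

Fixing `bottom` reflects the assay definition (0 % is the uninhibited
blank); letting `top` float near 100 absorbs plateau miscalibration
without allowing the plateau to explain away potency. IC50 and the Hill
slope are fitted on the log scale (guaranteeing positivity); a grid of 12
deterministic starting points (Hill slopes 0.5–4, IC50 at the half-max
concentration and ±5-fold) guards against the local minimum in which a
steep curve near the top of the tested range trades potency against the
`top` bound. Data whose mean response never reaches 20 % carry no IC50
information within the tested range and are reported as non-converged
rather than fitted. The goodness-of-fit measure is the reduced chi-squared
RSS/(N − 3).

`pIC50 = 6 − log10(IC50 in µM)` keeps µM at the interface and molar only
inside the log. Activity differences against a reference inhibitor are
reported as one-decimal **half-up** roundings of |ΔpIC50| — commercial
rounding, not banker's rounding, so 0.35 reports as 0.4. Potency bands are
hit (IC50 < 100 µM), active (100–1000 µM inclusive), inactive (> 1000 µM).

## Kinetic mechanism bank

All seven candidate rate laws share the form

$$v_0 = \frac{V_{MAX}\,S}{K_M\,f_{K_M}(I) + S\,f_S(I)}$$

| mechanism | $f_{K_M}(I)$ | $f_S(I)$ | parameters |
|---|---|---|---|
| linear competitive | $1+I/K_{IC}$ | $1$ | VMAX, KM, KIC |
| linear uncompetitive | $1$ | $1+I/K_{IU}$ | VMAX, KM, KIU |
| linear non-competitive | $1+I/K_{Icu}$ | $1+I/K_{Icu}$ | VMAX, KM, KIcu |
| linear mixed | $1+I/K_{IC}$ | $1+I/K_{IU}$ | VMAX, KM, KIC, KIU |
| parabolic competitive | $1+I/K_{IC}+I^2/K_{IC2}^2$ | $1$ | VMAX, KM, KIC, KIC2 |
| parabolic uncompetitive | $1$ | $1+I/K_{IU}+I^2/K_{IU2}^2$ | VMAX, KM, KIU, KIU2 |
| parabolic non-competitive | $1+I/K_{Icu}+I^2/K_{Icu2}^2$ | same | VMAX, KM, KIcu, KIcu2 |

Units are mM and mM·min⁻¹ throughout. Two choices deserve emphasis:

* **The parabolic quadratic term is $I^2/K_{IC2}^2$**, with $K_{IC2}$ an
  independent second constant in concentration units (not $(I/K_{IC})^2$).
  Parabolic inhibition arises when two inhibitor molecules bind; the two
  constants are the two binding events' scales and are reported
  separately.
* The parabolic uncompetitive and non-competitive second constants are
  named `KIU2` and `KIcu2` by extension of the `KIC2` pattern; these are
  the standard parabolic completions of the linear forms.

At $I = 0$ every law collapses to Michaelis–Menten exactly — this is both
an invariant of the implementation and the reason an uninhibited series is
required for well-posed fits.

### Global fitting

`global_fit()` fits **one** parameter vector to all inhibitor series
simultaneously (a global fit), minimizing (optionally 1/sd²-weighted)
squared residuals with Levenberg–Marquardt (`minpack.lm::nls.lm`).
Parameters are log-transformed, which enforces positivity without active
bounds. Starting values are scale-free heuristics: VMAX from the largest
observed velocity, KM from the substrate level nearest half-max on the
uninhibited series, inhibition constants from the median non-zero
inhibitor level. Five (by default) starting points are generated by a
fixed, deterministic grid of log-scale factors (1, 1/3, 3, 1/10, 10 cycled
across parameters) — the same multi-start robustness as random
perturbations but bit-reproducible without a seed argument. The best final
chi-squared wins.

Standard errors come from the delta method applied to the log-scale
covariance `reduced_χ² · H⁻¹`; a singular information matrix (e.g. no
inhibitor variation, so inhibition constants cannot be identified) yields
infinite standard errors rather than an error.

### Model selection

`select_mechanism()` fits all seven laws and ranks them by reduced
chi-squared `Σw·r²/(N − p)`. Because the three-parameter laws are nested
inside four-parameter laws, the richer model's chi-squared is never
meaningfully larger on the generating mechanism's own data; the selection
rule is therefore: among fits whose reduced chi-squared is within 5 %
(relative) of the best, the mechanism with the fewest parameters wins. An
absolute floor of `1e-9·mean(v0)²` is added to the tie window so that
noise-free datasets — where every nested law reaches a chi-squared of
numerical zero (~1e-19, pure rounding noise) — resolve by parsimony rather
than by which rounding error is smallest. Each fit's report also carries
the largest relative parameter standard error and a Wald–Wolfowitz runs
test p-value on residual signs taken in substrate order within inhibitor
series, so systematic lack of fit is visible even when chi-squared values
are close.

On the default design (below) with 5 % multiplicative noise and
triplicates, the generating mechanism is recovered in ≥ 90 of 100 seeded
runs for the non-competitive, mixed, and parabolic competitive cases —
this is asserted by the test suite.

`ic50_at_substrate()` converts a fit into the inhibitor concentration
halving the uninhibited rate at a chosen substrate level, using closed
forms for the linear laws (non-competitive: IC50 = KIcu independent of S;
competitive: KIC·(1 + S/KM); uncompetitive: KIU·(1 + KM/S); mixed:
(KM+S)/(KM/KIC + S/KIU)) and bisection for the parabolic laws (the
velocity is strictly decreasing in I, so the root is bracketed and unique;
the tests cross-check bisection against the quadratic closed form).

## Synthetic data: what it emulates

`gen_dose_response()` draws percent-inhibition data from the logistic
model; `gen_kinetic_dataset()` evaluates a mechanism's rate law on a
substrate × inhibitor grid; `gen_library()` builds a compound library from
five hard-coded scaffold families (flavone-, terpenoid-, quinoline-,
stilbene-, and xanthone-like SMILES templates with enumerated
substituents) with per-scaffold normal pIC50 distributions.

Noise is **multiplicative Gaussian** (sd = CV × mean) truncated at zero:
absorbance-derived rates have roughly proportional error and cannot be
negative. The default CV is 5 %, a typical replicate-level spread for
plate-reader enzyme assays; it is a free choice, as replicate noise
magnitude is rarely reported. All generators take an explicit seed and are
bit-reproducible; the caller's RNG state is left untouched.

The default kinetics design uses 8 substrate points log-spaced over
[KM/8, 8·KM] — spanning the informative curvature region around KM — and 6
inhibitor levels: zero plus 5 log-spaced levels over half to eight times
the geometric mean of the truth's inhibition constants, the range over
which inhibition goes from mild to strong. Real campaigns would use "at
least five" inhibitor levels chosen by pilot experiments; the default is
the idealized version of that design.

What the generators do **not** emulate: absorbance time courses,
instrument drift, plate effects, compound aggregation or insolubility at
high concentration, and real structural diversity (five templated scaffold
families are not a natural-product library). Passing recovery tests on
synthetic data therefore demonstrates the estimators' correctness and
stability, not robustness to every real-world assay pathology.

Scaffold template order matters only in that a two-family library uses the
first two templates: the order (flavone, terpenoid, quinoline, stilbene,
xanthone) puts chemically distant families first so that small planted
libraries have cleanly separated within/cross-scaffold similarity
populations. Note that "cleanly separated" does not mean "split at 0.5":
aliphatic terpenoid analogs legitimately share path-fingerprint similarity
well below 0.5, so planted-zone tests derive the boundary from the plant's
own two similarity populations.

## Fingerprints, TSD selection, and the projection

Fingerprint bit definitions are delegated to ChemmineR / Open Babel: FP2
(1024-bit linear paths), FP3/FP4 (SMARTS key sets), MACCS-like keys, and a
1024-bit folded atom-pair set. The contract the package owns is
determinism and fixed length, plus ingestion of externally computed bit
matrices (e.g. 881-bit PubChem strings) via `fingerprint_set()`.

Tanimoto similarity is |a∧b|/|a∨b|, with the 0/0 case of two featureless
(all-zero) fingerprints defined as 0 — dissimilar, not identical. The
similarity matrix is computed by bit-count cross-products and is tested to
equal a literal double-loop oracle exactly.

The TSD curve is the empirical CDF of the n(n−1)/2 pairwise similarities.
Fingerprint selection maximizes the area under this curve: the most
discriminative fingerprint is the one that keeps most pairs at low
similarity. There is no community-standard numeric rule for reading TSD
plots; AUC is the natural scalar for "dominates at every threshold", and
the full ranking is always returned so a user can override the choice.
Ties resolve by name order and are flagged.

The chemical-space projection is an exact t-SNE (the library sizes here —
tens to a few hundred compounds — do not need Barnes–Hut, and no R t-SNE
implementation is available in the package's dependency set, so the exact
algorithm is implemented in-package): squared Jaccard distances
(1 − Tanimoto) feed per-point Gaussian kernels whose bandwidths are
binary-searched to the target perplexity (default 40, auto-lowered by the
pipeline wrapper to (n−1)/3 for small libraries); the embedding minimizes
KL divergence by gradient descent with early exaggeration (×12 for 250
iterations), momentum 0.5→0.8, and adaptive gains, for 3000 iterations by
default. Coordinates are deterministic for a fixed seed but, as with any
t-SNE, individual coordinates are meaningless; only neighborhood structure
(e.g. scaffold families clustering together, which the tests assert) is
interpretable.

## SAS maps

A SAS map plots, for compound pairs, Tanimoto similarity (x) against
|ΔpIC50| (y), with quadrants ZI (low/low: scaffold hops), ZII (high sim,
low ΔpIC50: smooth SAR), ZIII (low/high: non-descript), ZIV (high/high:
activity cliffs). "High" includes the threshold (≥). Activity differences
here use **unrounded** pIC50 values; the one-decimal `delta_activity()` is
a reporting convention only.

Default thresholds are similarity 0.5 and 1.0 pIC50 units (a 10-fold
potency gap) — conventional round values consistent with hit-set activity
gaps well under one log unit; both are configurable, and passing an `NA`
similarity threshold uses the median pairwise similarity of the map's own
matrix (data-driven option). Both an all-pairs mode (zone counting over
every unordered pair) and a reference mode (pairs against one anchor
compound) exist because both analyses are useful: hop/analog reports are
anchored at a reference inhibitor, while cliff detection and zone censuses
read all pairs. Defaults: all-pairs for counting, with hop/analog reports
extracted relative to the reference.

## Problem sizes and runtime

The test suite and acceptance script are sized for interactive use: the
kinetics Monte-Carlo check uses 100 datasets per mechanism (8 × 6 grid,
triplicates, 5 % CV), the similarity oracle check uses 46 × 881-bit
fingerprints (1035 pairs), planted-zone libraries use 2–5 scaffolds with
up to 10 analogs each, and projection tests run a few hundred t-SNE
iterations on ≤ 30 compounds. These sizes keep the full suite under a few
minutes on one CPU while leaving every statistical margin (e.g. the ≥ 90 %
selection-accuracy bound) comfortably wide.

## Known limitations

* Kinetic model selection assumes the seven-law bank is exhaustive;
  slow/tight-binding and pre-steady-state behavior are out of scope.
* The logistic dose-response model fixes bottom = 0; partial inhibitors
  with a true non-zero floor will show it as lack of fit, not as a fitted
  floor.
* Fingerprint choice is limited to what Open Babel / ChemmineR compute;
  circular (Morgan-type) and PubChem fingerprints must be supplied as raw
  bit matrices if needed.
* t-SNE coordinates are seed- and implementation-dependent by nature;
  only cluster structure should be interpreted.
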