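# inhibscreen

Analysis toolkit for enzyme-inhibitor screening campaigns of the kind run
against protein tyrosine phosphatase 1B (PTP1B), an antidiabetic drug
target: a chromogenic assay (4-nitrophenyl phosphate hydrolysis read at
405 nm) screens a natural-product library, confirmed actives get IC50 /
pIC50 estimates, selected inhibitors get a full kinetic mechanism workup,
and the library's structure–activity landscape is mapped with fingerprint
similarity.

The package covers four stages, each usable on its own:

1. **Screening.** Percent inhibition from absorbance changes,
   `%I = (1 − ΔA_sample/ΔA_blank) × 100`; triage (mean inhibition ≥ 90 % at
   20 µM); four-parameter logistic concentration–response fits
   `%I(c) = top / (1 + (IC50/c)^h)` (bottom fixed at 0, top constrained to
   [80, 120]); `pIC50 = 6 − log10(IC50 µM)`; potency bands (hit < 100 µM ≤
   active ≤ 1000 µM < inactive) and activity differences
   `ΔA = |pIC50_ref − pIC50|` with half-up decimal rounding.
2. **Inhibition kinetics.** Seven candidate rate laws — linear competitive,
   uncompetitive, non-competitive, mixed, and parabolic competitive /
   uncompetitive / non-competitive, all of the form
   `v0 = VMAX·S / (KM·f_KM(I) + S·f_S(I))` with linear factors `1 + I/K` or
   parabolic factors `1 + I/K + I²/K2²` — fitted *globally* (one parameter
   vector for all inhibitor series) by multi-start Levenberg–Marquardt, and
   ranked by reduced χ² with a parsimony tie-break, residual runs tests,
   and parameter-uncertainty reporting. Double-reciprocal series and
   substrate-dependent IC50s come from the same fits.
3. **Chemical space.** Binary fingerprints (Open Babel FP2/FP3/FP4/MACCS and
   ChemmineR atom pairs), Tanimoto similarity matrices, Tanimoto-similarity
   cumulative distribution (TSD) curves to pick the most discriminative
   fingerprint, and an exact t-SNE projection (perplexity 40, 3000
   iterations by default) of the winning fingerprint.
4. **SAS maps.** Structure–activity similarity maps plot pairwise Tanimoto
   similarity against |ΔpIC50| and partition pairs into ZI (scaffold hops),
   ZII (smooth SAR), ZIII (non-descript), ZIV (activity cliffs); reports
   list scaffold hops and true analogs of a reference compound and all
   cliff pairs.

Synthetic generators with known ground truth (`gen_dose_response()`,
`gen_kinetic_dataset()`, `gen_library()`) make every stage testable end to
end without external data.

## Worked example

```r
library(inhibscreen)

# a noise-free velocity surface from a known non-competitive truth ...
tr <- kinetic_truth("linear_noncompetitive", vmax = 44.1, km = 0.2,
                    constants = c(KIcu = 0.009), noise_cv = 0,
                    replicates = 1)
sel <- select_mechanism(gen_kinetic_dataset(tr))
sel$winner
#> [1] "linear_noncompetitive"
round(sel$fits[[1]]$params, 4)
#>   VMAX     KM   KIcu
#> 44.100  0.200  0.009

# ... and potency bookkeeping against a reference inhibitor at pIC50 4.66
delta_activity(4.66, c(4.48, 4.39, 4.31, 4.08, 4.00))
#> [1] 0.2 0.3 0.4 0.6 0.7
```

The recovered `KIcu = 0.009 mM` is the generating inhibition constant: the
global refit reproduces the truth exactly on clean data. The activity
differences are the one-decimal half-up gaps between each compound and the
reference.

A full file-based pipeline is available through `run_simulate()`,
`run_screen()`, `run_kinetics()`, `run_chemspace()`, `run_sasmap()`, or the
command-line front end:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "inhibscreen.R",
                                       package = "inhibscreen"))')" \
    simulate --out-dir demo --seed 1
```

## Vignette

`vignettes/inhibitor-screening-methods.Rmd` documents the models, the
numerical choices (initialisation, multi-start, tie-breaking), what the
synthetic generators do and do not emulate, and known limitations.
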