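# Synthetic data generators with known ground truth.
#
# Every downstream stage (dose-response fitting, kinetic model selection,
# fingerprint similarity, SAS mapping) gets recovery tests against data whose
# generating parameters are known exactly. Noise is multiplicative Gaussian
# (sd = CV * mean) truncated at zero, matching the roughly proportional error
# of absorbance-derived rates; with noise_cv = 0 the generated values equal
# the closed-form model everywhere.

#' Ground truth for a concentration-inhibition experiment
#'
#' @param ic50 half-maximal inhibitory concentration, uM, > 0.
#' @param hill Hill slope, unitless, > 0.
#' @param top,bottom plateau percent-inhibition values; `top > bottom`.
#' @param noise_cv coefficient of variation of multiplicative noise, >= 0.
#' @param seed integer RNG seed; identical seeds give identical data.
#' @return an object of class `dose_response_truth`.
#' @export
dose_response_truth <- function(ic50, hill = 1, top = 100, bottom = 0,
                                noise_cv = 0.05, seed = 1) {
  stopifnot(ic50 > 0, hill > 0, top > bottom, noise_cv >= 0)
  structure(list(ic50 = ic50, hill = hill, top = top, bottom = bottom,
                 noise_cv = noise_cv, seed = seed),
            class = "dose_response_truth")
}

#' Generate synthetic percent-inhibition data
#'
#' Noise-free mean at concentration c is
#' `bottom + (top - bottom) / (1 + (ic50/c)^hill)`.
#'
#' @param truth a [dose_response_truth()].
#' @param concentrations inhibitor concentrations, uM, all > 0.
#' @param replicates number of replicates per concentration (>= 1).
#' @return data.frame with columns `concentration`, `replicate`,
#'   `inhibition` (percent).
#' @export
#' @examples
#' gen_dose_response(dose_response_truth(50, noise_cv = 0), c(10, 50, 250))
gen_dose_response <- function(truth, concentrations, replicates = 3) {
  stopifnot(inherits(truth, "dose_response_truth"), replicates >= 1)
  if (length(concentrations) == 0 || any(concentrations <= 0)) {
    stop("concentrations must be non-empty and all > 0", call. = FALSE)
  }
  conc <- rep(concentrations, each = replicates)
  mu <- truth$bottom +
    (truth$top - truth$bottom) / (1 + (truth$ic50 / conc)^truth$hill)
  inh <- with_seed(truth$seed, apply_noise(mu, truth$noise_cv))
  data.frame(concentration = conc,
             replicate = rep(seq_len(replicates), times = length(concentrations)),
             inhibition = inh)
}

#' Ground truth for an initial-velocity kinetics experiment
#'
#' Defines the mechanism, its parameters, and the measurement design of a
#' substrate-by-inhibitor initial velocity surface. The default design uses
#' 8 substrate points log-spaced over `[KM/8, 8*KM]` and 6 inhibitor levels
#' including zero, with the non-zero levels log-spaced over half to eight
#' times the geometric mean of the inhibition constants, spanning the region
#' where the inhibitor visibly bends the curves.
#'
#' @param mechanism mechanism label (see [mechanism_labels()]).
#' @param vmax maximum velocity, mM/min, > 0.
#' @param km Michaelis constant for the substrate, mM, > 0.
#' @param constants named numeric vector of inhibition constants (mM) as
#'   required by the mechanism, e.g. `c(KIcu = 0.009)`.
#' @param s_grid substrate concentrations (mM); default as described above.
#' @param i_grid inhibitor concentrations (mM), must include 0; default as
#'   described above.
#' @param noise_cv coefficient of variation of multiplicative noise.
#' @param replicates replicates per grid point (>= 1).
#' @param seed integer RNG seed.
#' @return an object of class `kinetic_truth`.
#' @export
kinetic_truth <- function(mechanism, vmax, km, constants,
                          s_grid = NULL, i_grid = NULL,
                          noise_cv = 0.05, replicates = 3, seed = 1) {
  spec <- mechanism_spec(mechanism)
  stopifnot(vmax > 0, km > 0, noise_cv >= 0, replicates >= 1)
  need <- setdiff(spec$parameter_names, c("VMAX", "KM"))
  missing <- setdiff(need, names(constants))
  if (length(missing) > 0) {
    stop("mechanism ", spec$label, " requires constant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  constants <- unlist(constants)[need]
  if (any(constants <= 0)) stop("all inhibition constants must be > 0", call. = FALSE)
  if (is.null(s_grid)) {
    s_grid <- exp(seq(log(km / 8), log(8 * km), length.out = 8))
  }
  if (is.null(i_grid)) {
    k_ref <- exp(mean(log(constants)))
    i_grid <- c(0, exp(seq(log(k_ref / 2), log(8 * k_ref), length.out = 5)))
  }
  if (length(s_grid) == 0 || length(i_grid) == 0) {
    stop("grids must be non-empty", call. = FALSE)
  }
  stopifnot(all(s_grid > 0), all(i_grid >= 0))
  structure(list(mechanism = spec, vmax = vmax, km = km, constants = constants,
                 s_grid = s_grid, i_grid = i_grid, noise_cv = noise_cv,
                 replicates = replicates, seed = seed),
            class = "kinetic_truth")
}

#' Generate a synthetic initial-velocity dataset
#'
#' Evaluates the mechanism's rate law on the full substrate x inhibitor grid
#' and applies multiplicative noise per replicate.
#'
#' @param truth a [kinetic_truth()].
#' @return a [kinetic_dataset()] (data.frame with columns `s`, `i`,
#'   `replicate`, `v0`).
#' @export
#' @examples
#' tr <- kinetic_truth("linear_noncompetitive", vmax = 44.1, km = 0.2,
#'                     constants = c(KIcu = 0.009), noise_cv = 0)
#' head(gen_kinetic_dataset(tr))
gen_kinetic_dataset <- function(truth) {
  stopifnot(inherits(truth, "kinetic_truth"))
  grid <- expand.grid(s = truth$s_grid, i = truth$i_grid,
                      replicate = seq_len(truth$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  params <- c(VMAX = truth$vmax, KM = truth$km, truth$constants)
  mu <- rate_law(truth$mechanism, params, grid$s, grid$i)
  grid$v0 <- with_seed(truth$seed, apply_noise(mu, truth$noise_cv))
  kinetic_dataset(grid)
}

# ---------------------------------------------------------------------------
# Synthetic compound library

# Scaffold templates: short SMILES families with one substitution slot.
# Within a family, members share the scaffold and differ only in the
# substituent, so within-scaffold fingerprint similarity exceeds
# cross-scaffold similarity by construction.
.SCAFFOLD_TEMPLATES <- c(
  flavone    = "O=c1cc(-c2ccc(%s)cc2)oc2ccccc12",
  terpenoid  = "CC1(C)CCC2(C)CCC(%s)CC2C1",
  quinoline  = "c1ccc2nc(%s)ccc2c1",
  stilbene   = "Oc1ccc(/C=C/c2ccc(%s)cc2)cc1",
  xanthone   = "O=c1c2ccccc2oc2cc(%s)ccc12"
)

.SUBSTITUENTS <- c("O", "OC", "C", "CC", "Cl", "F", "N", "C(C)C", "CCO",
                   "OCC", "Br", "C(C)(C)C", "OC(C)C", "CCC", "CN(C)C",
                   "C(F)(F)F", "OCCO", "CCl", "C#N", "CO")

#' Ground truth for a synthetic compound library
#'
#' Compounds are organized in scaffold families; each family draws its pIC50
#' values from its own normal distribution, so similarity structure and
#' activity structure are both known in advance.
#'
#' @param n_scaffolds number of scaffold families (2 to 5).
#' @param per_scaffold compounds per family (2 to 20).
#' @param pic50_by_scaffold optional list/matrix-like: one `c(mean, sd)` pair
#'   per scaffold. Default means 4.7, 4.3, 5.5, 3.9, 5.0 with sd 0.15,
#'   spanning the micromolar-to-submillimolar potency range typical of
#'   natural-product screens.
#' @param seed integer RNG seed.
#' @return an object of class `library_truth`.
#' @export
library_truth <- function(n_scaffolds = 3, per_scaffold = 8,
                          pic50_by_scaffold = NULL, seed = 1) {
  stopifnot(n_scaffolds >= 2, per_scaffold >= 2)
  if (n_scaffolds > length(.SCAFFOLD_TEMPLATES)) {
    stop("at most ", length(.SCAFFOLD_TEMPLATES), " scaffold families available",
         call. = FALSE)
  }
  if (per_scaffold > length(.SUBSTITUENTS)) {
    stop("at most ", length(.SUBSTITUENTS), " compounds per scaffold", call. = FALSE)
  }
  if (is.null(pic50_by_scaffold)) {
    means <- c(4.7, 4.3, 5.5, 3.9, 5.0)[seq_len(n_scaffolds)]
    pic50_by_scaffold <- lapply(means, function(m) c(mean = m, sd = 0.15))
  }
  stopifnot(length(pic50_by_scaffold) == n_scaffolds)
  structure(list(n_scaffolds = n_scaffolds, per_scaffold = per_scaffold,
                 pic50_by_scaffold = pic50_by_scaffold, seed = seed),
            class = "library_truth")
}

#' Generate a synthetic compound library
#'
#' @param truth a [library_truth()].
#' @return data.frame of compound records: `compound_id`, `smiles`, `name`,
#'   `pic50`, `source`, and the generating `scaffold` label.
#' @export
#' @examples
#' lib <- gen_library(library_truth(n_scaffolds = 2, per_scaffold = 3))
#' nrow(lib) # 6
gen_library <- function(truth) {
  stopifnot(inherits(truth, "library_truth"))
  scaff <- names(.SCAFFOLD_TEMPLATES)[seq_len(truth$n_scaffolds)]
  recs <- do.call(rbind, lapply(seq_along(scaff), function(k) {
    subs <- .SUBSTITUENTS[seq_len(truth$per_scaffold)]
    data.frame(
      compound_id = sprintf("%s_%02d", scaff[k], seq_len(truth$per_scaffold)),
      smiles = sprintf(.SCAFFOLD_TEMPLATES[[scaff[k]]], subs),
      name = sprintf("%s analog %d", scaff[k], seq_len(truth$per_scaffold)),
      scaffold = scaff[k],
      stringsAsFactors = FALSE
    )
  }))
  pic50 <- with_seed(truth$seed, {
    unlist(lapply(seq_along(scaff), function(k) {
      p <- truth$pic50_by_scaffold[[k]]
      stats::rnorm(truth$per_scaffold, mean = p[[1]], sd = p[[2]])
    }))
  })
  recs$pic50 <- pic50
  recs$source <- "synthetic"
  recs[, c("compound_id", "smiles", "name", "pic50", "source", "scaffold")]
}
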