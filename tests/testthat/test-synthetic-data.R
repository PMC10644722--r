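# Synthetic data generators: closed-form agreement, seeding, validity.

test_that("noise-free dose-response equals the logistic everywhere", {
  # midpoint, asymptote, and a directly evaluated off-midpoint value
  tr <- dose_response_truth(ic50 = 50, hill = 1, noise_cv = 0)
  d <- gen_dose_response(tr, c(50, 1e7), replicates = 1)
  expect_equal(d$inhibition[1], 50, tolerance = 1e-12)
  expect_gt(d$inhibition[2], 99.9)

  tr2 <- dose_response_truth(ic50 = 20, hill = 2, noise_cv = 0)
  d2 <- gen_dose_response(tr2, 10, replicates = 1)
  expect_equal(d2$inhibition, 100 / (1 + (20 / 10)^2), tolerance = 1e-12)

  # closed form across a parameter sweep
  for (ic50 in c(1, 30, 400)) {
    for (hill in c(0.5, 1.7)) {
      tr <- dose_response_truth(ic50, hill, noise_cv = 0)
      conc <- c(0.1, 1, 10, 100, 1000)
      d <- gen_dose_response(tr, conc, replicates = 1)
      expect_equal(d$inhibition, 100 / (1 + (ic50 / conc)^hill),
                   tolerance = 1e-12)
    }
  }
})

test_that("dose-response generation is seed-deterministic and validates input", {
  tr <- dose_response_truth(ic50 = 50, noise_cv = 0.1, seed = 9)
  d1 <- gen_dose_response(tr, c(10, 50, 100))
  d2 <- gen_dose_response(tr, c(10, 50, 100))
  expect_identical(d1, d2)
  tr2 <- dose_response_truth(ic50 = 50, noise_cv = 0.1, seed = 10)
  expect_false(identical(d1, gen_dose_response(tr2, c(10, 50, 100))))
  expect_error(gen_dose_response(tr, c(-1, 10)), "concentrations")
  expect_error(gen_dose_response(tr, numeric(0)), "concentrations")
})

test_that("noise-free kinetic datasets equal the rate law everywhere", {
  tr <- kinetic_truth("linear_noncompetitive", vmax = 44.1, km = 0.2,
                      constants = c(KIcu = 0.009), noise_cv = 0,
                      replicates = 1)
  d <- gen_kinetic_dataset(tr)
  # uninhibited row is plain Michaelis-Menten
  base <- d[d$i == 0, ]
  expect_equal(base$v0, 44.1 * base$s / (0.2 + base$s), tolerance = 1e-12)
  # S = KM, I = KIcu gives VMAX/4
  tr2 <- kinetic_truth("linear_noncompetitive", vmax = 44.1, km = 0.2,
                       constants = c(KIcu = 0.009),
                       s_grid = 0.2, i_grid = c(0, 0.009),
                       noise_cv = 0, replicates = 1)
  d2 <- gen_kinetic_dataset(tr2)
  expect_equal(d2$v0[d2$i == 0.009], 44.1 / 4, tolerance = 1e-12)
  # mixed law, direct evaluation at S = KM, I = KIC
  tr3 <- kinetic_truth("linear_mixed", vmax = 56.1, km = 0.5,
                       constants = c(KIC = 0.04, KIU = 0.11),
                       s_grid = 0.5, i_grid = c(0, 0.04),
                       noise_cv = 0, replicates = 1)
  d3 <- gen_kinetic_dataset(tr3)
  expect_equal(d3$v0[d3$i == 0.04],
               56.1 * 0.5 / (0.5 * 2 + 0.5 * (1 + 0.04 / 0.11)),
               tolerance = 1e-12)
})

test_that("kinetic truth validates mechanism constants and grids", {
  expect_error(kinetic_truth("linear_mixed", 50, 0.2, c(KIC = 0.04)), "KIU")
  expect_error(kinetic_truth("no_such_mechanism", 50, 0.2, c(KIC = 1)))
  expect_error(kinetic_truth("linear_competitive", 50, 0.2, c(KIC = -1)),
               "> 0")
  tr <- kinetic_truth("linear_competitive", 50, 0.2, c(KIC = 0.05))
  expect_length(tr$s_grid, 8)
  expect_length(tr$i_grid, 6)
  expect_true(0 %in% tr$i_grid)
  d1 <- gen_kinetic_dataset(tr)
  expect_identical(d1, gen_kinetic_dataset(tr))
})

test_that("synthetic libraries have the planted size, seeding, and chemistry", {
  lib <- gen_library(library_truth(n_scaffolds = 2, per_scaffold = 3, seed = 5))
  expect_equal(nrow(lib), 6)
  expect_equal(choose(nrow(lib), 2), 15)
  expect_identical(lib,
                   gen_library(library_truth(n_scaffolds = 2, per_scaffold = 3,
                                             seed = 5)))
  # every emitted structure string parses in the chemistry toolkit
  big <- gen_library(library_truth(n_scaffolds = 5, per_scaffold = 8, seed = 1))
  expect_silent(fps <- compute_fingerprints(big, "fp2_path"))
  expect_equal(nrow(fps$bits), 40)
  # within-scaffold pairs are more similar than cross-scaffold pairs
  sim <- similarity_matrix(fps)
  same <- outer(big$scaffold, big$scaffold, "==")[upper.tri(sim)]
  ps <- unclass(sim)[upper.tri(sim)]
  expect_gt(mean(ps[same]), mean(ps[!same]))
})

test_that("multiplicative noise is unbiased in scale and truncated at zero", {
  tr <- kinetic_truth("linear_competitive", 50, 0.2, c(KIC = 0.05),
                      noise_cv = 0.3, replicates = 200, seed = 3)
  d <- gen_kinetic_dataset(tr)
  expect_true(all(d$v0 >= 0))
  mu <- rate_law("linear_competitive", c(VMAX = 50, KM = 0.2, KIC = 0.05),
                 d$s, d$i)
  # 30% CV over 200 replicates: per-point means within a few percent
  rel <- tapply(d$v0 / mu, paste(d$s, d$i), mean)
  expect_true(all(abs(rel - 1) < 0.1))
})
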