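# Rate laws, global fitting, mechanism selection, derived quantities.

TABLE_TRUTHS <- list(
  list(mech = "linear_noncompetitive", vmax = 44.1, constants = c(KIcu = 0.009)),
  list(mech = "linear_mixed", vmax = 56.1, constants = c(KIC = 0.04, KIU = 0.11)),
  list(mech = "parabolic_competitive", vmax = 24.7,
       constants = c(KIC = 0.031, KIC2 = 0.020))
)

test_that("every rate law collapses to Michaelis-Menten at zero inhibitor", {
  s <- c(0.05, 0.2, 1.3)
  for (m in mechanism_labels()) {
    spec <- mechanism_spec(m)
    p <- c(VMAX = 10, KM = 0.2)
    for (nm in setdiff(spec$parameter_names, c("VMAX", "KM"))) p[nm] <- 0.05
    expect_equal(rate_law(m, p, s, 0), 10 * s / (0.2 + s), tolerance = 1e-12,
                 info = m)
  }
})

test_that("rate laws match their algebraic forms at reference points", {
  # non-competitive at S = KM, I = KIcu gives VMAX/4
  expect_equal(rate_law("linear_noncompetitive",
                        c(VMAX = 44.1, KM = 0.2, KIcu = 0.009), 0.2, 0.009),
               44.1 / 4, tolerance = 1e-12)
  # parabolic competitive, direct evaluation
  expect_equal(rate_law("parabolic_competitive",
                        c(VMAX = 24.7, KM = 0.2, KIC = 0.031, KIC2 = 0.020),
                        0.2, 0.031),
               24.7 * 0.2 / (0.2 * (1 + 1 + 0.031^2 / 0.020^2) + 0.2),
               tolerance = 1e-12)
  # mixed law, direct evaluation
  expect_equal(rate_law("linear_mixed",
                        c(VMAX = 56.1, KM = 0.5, KIC = 0.04, KIU = 0.11),
                        0.5, 0.04),
               56.1 * 0.5 / (0.5 * 2 + 0.5 * (1 + 0.04 / 0.11)),
               tolerance = 1e-12)
  expect_error(rate_law("linear_mixed", c(VMAX = 1, KM = 1, KIC = 1), 1, 1),
               "KIU")
  expect_error(rate_law("linear_competitive",
                        c(VMAX = 1, KM = 1, KIC = 0), 1, 1), "> 0")
})

test_that("velocities increase in substrate and never increase in inhibitor", {
  s <- exp(seq(log(0.02), log(2), length.out = 12))
  i <- c(0, 0.01, 0.05, 0.2)
  for (m in mechanism_labels()) {
    spec <- mechanism_spec(m)
    p <- c(VMAX = 30, KM = 0.2)
    for (nm in setdiff(spec$parameter_names, c("VMAX", "KM"))) p[nm] <- 0.04
    for (ii in i) {
      v <- rate_law(m, p, s, ii)
      expect_true(all(diff(v) > 0), info = paste(m, "monotone in s"))
    }
    for (ss in s[c(1, 6, 12)]) {
      v <- rate_law(m, p, ss, i)
      expect_true(all(diff(v) <= 1e-14), info = paste(m, "non-increasing in i"))
    }
  }
})

test_that("global fit recovers generating parameters for all seven mechanisms", {
  for (m in mechanism_labels()) {
    spec <- mechanism_spec(m)
    constants <- stats::setNames(
      c(0.03, 0.08, 0.05)[seq_along(setdiff(spec$parameter_names,
                                            c("VMAX", "KM")))],
      setdiff(spec$parameter_names, c("VMAX", "KM")))
    tr <- kinetic_truth(m, vmax = 37, km = 0.25, constants = constants,
                        noise_cv = 0, replicates = 1)
    fit <- global_fit(gen_kinetic_dataset(tr), m)
    expect_true(fit$converged, info = m)
    truth <- c(VMAX = 37, KM = 0.25, constants)
    expect_equal(fit$params[names(truth)], truth, tolerance = 1e-3, info = m)
  }
})

test_that("weighted and unweighted fits coincide for constant sd", {
  tr <- kinetic_truth("linear_mixed", 56.1, 0.2, c(KIC = 0.04, KIU = 0.11),
                      noise_cv = 0.05, replicates = 2, seed = 8)
  d <- gen_kinetic_dataset(tr)
  d$sd <- 0.5
  f1 <- global_fit(d, "linear_mixed", weights = "none")
  f2 <- global_fit(d, "linear_mixed", weights = "sd")
  expect_equal(f1$params, f2$params, tolerance = 1e-8)
  # chi-squared scales by 1/sd^2 but the optimum is unchanged
  expect_equal(f2$reduced_chi2, f1$reduced_chi2 / 0.25, tolerance = 1e-6)
})

test_that("inhibition constants are unidentifiable without inhibitor data", {
  tr <- kinetic_truth("linear_noncompetitive", 44.1, 0.2, c(KIcu = 0.009),
                      s_grid = exp(seq(log(0.025), log(1.6), length.out = 8)),
                      i_grid = 0, noise_cv = 0, replicates = 1)
  d <- gen_kinetic_dataset(tr)
  expect_warning(fit <- global_fit(d, "linear_noncompetitive"),
                 "identifiable")
  expect_true(is.infinite(fit$uncertainties[["KIcu"]]) ||
                fit$uncertainties[["KIcu"]] / fit$params[["KIcu"]] > 1e3)
})

test_that("the generating mechanism minimizes reduced chi-squared on clean data", {
  for (tt in TABLE_TRUTHS) {
    tr <- kinetic_truth(tt$mech, tt$vmax, 0.2, tt$constants,
                        noise_cv = 0, replicates = 1)
    sel <- select_mechanism(gen_kinetic_dataset(tr))
    chi2 <- sel$rationale$reduced_chi2
    gen_chi2 <- chi2[sel$rationale$mechanism == tt$mech]
    expect_lte(gen_chi2, min(chi2) + 1e-12)
    expect_equal(sel$winner, tt$mech)
    expect_equal(sel$rationale$mechanism[1], sel$winner)
    expect_equal(length(sel$fits), 7)
  }
})

test_that("parsimony prefers the simplest mechanism when the inhibitor is inert", {
  # no inhibitor effect: all mechanisms fit equally well, so the winner must
  # be a three-parameter law
  s_grid <- exp(seq(log(0.025), log(1.6), length.out = 8))
  d <- expand.grid(s = s_grid, i = c(0, 0.01, 0.05, 0.2, 0.5))
  d$v0 <- 30 * d$s / (0.2 + d$s)
  sel <- select_mechanism(kinetic_dataset(d))
  n_params <- length(mechanism_spec(sel$winner)$parameter_names)
  expect_equal(n_params, 3)
})

test_that("double-reciprocal series transform exactly and drop zero velocities", {
  d <- kinetic_dataset(data.frame(s = c(2, 1, 4), i = c(0, 0, 0.1),
                                  v0 = c(4, 0, 2)))
  rs <- reciprocal_series(d)
  expect_equal(nrow(rs), 2)
  expect_equal(attr(rs, "n_dropped"), 1)
  expect_equal(rs$inv_s[1], 0.5)
  expect_equal(rs$inv_v0[1], 0.25)

  # non-competitive: all inhibitor series share the x-intercept -1/KM
  tr <- kinetic_truth("linear_noncompetitive", 44.1, 0.2, c(KIcu = 0.009),
                      noise_cv = 0, replicates = 1)
  rs <- reciprocal_series(gen_kinetic_dataset(tr))
  x_int <- vapply(split(rs, rs$i), function(g) {
    cf <- stats::coef(stats::lm(inv_v0 ~ inv_s, data = g))
    -cf[1] / cf[2]
  }, numeric(1))
  expect_equal(unname(x_int), rep(-1 / 0.2, 6), tolerance = 1e-8)

  # competitive: shared y-intercept 1/VMAX
  tr2 <- kinetic_truth("linear_competitive", 44.1, 0.2, c(KIC = 0.03),
                       noise_cv = 0, replicates = 1)
  rs2 <- reciprocal_series(gen_kinetic_dataset(tr2))
  y_int <- vapply(split(rs2, rs2$i), function(g) {
    stats::coef(stats::lm(inv_v0 ~ inv_s, data = g))[1]
  }, numeric(1))
  expect_equal(unname(y_int), rep(1 / 44.1, 6), tolerance = 1e-8)
})

test_that("kinetic IC50 closed forms agree with bisection and known algebra", {
  tr <- kinetic_truth("linear_noncompetitive", 44.1, 0.2, c(KIcu = 0.009),
                      noise_cv = 0, replicates = 1)
  fit <- global_fit(gen_kinetic_dataset(tr), "linear_noncompetitive")
  # non-competitive: IC50 = KIcu at every substrate level (in uM)
  expect_equal(ic50_at_substrate(fit, 0.05), 9, tolerance = 1e-6)
  expect_equal(ic50_at_substrate(fit, 1.5), 9, tolerance = 1e-6)

  trc <- kinetic_truth("linear_competitive", 30, 0.2, c(KIC = 0.05),
                       noise_cv = 0, replicates = 1)
  fitc <- global_fit(gen_kinetic_dataset(trc), "linear_competitive")
  expect_equal(ic50_at_substrate(fitc, 0.4), 0.05 * (1 + 0.4 / 0.2) * 1000,
               tolerance = 1e-6)

  # parabolic competitive: bisection vs quadratic closed-form oracle
  trp <- kinetic_truth("parabolic_competitive", 24.7, 0.2,
                       c(KIC = 0.031, KIC2 = 0.020),
                       noise_cv = 0, replicates = 1)
  fitp <- global_fit(gen_kinetic_dataset(trp), "parabolic_competitive")
  s <- 0.125
  km <- 0.2; kic <- fitp$params[["KIC"]]; kic2 <- fitp$params[["KIC2"]]
  a <- km / kic2^2; b <- km / kic; cc <- -(km + s)
  oracle <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a) * 1000
  expect_equal(ic50_at_substrate(fitp, s), oracle, tolerance = 1e-6)
})
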