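# Global fitting of initial-velocity surfaces and mechanism selection.

#' Initial-velocity dataset
#'
#' Validates and classes a long-format substrate x inhibitor velocity table.
#'
#' @param data data.frame with columns `s` (substrate, mM, > 0), `i`
#'   (inhibitor, mM, >= 0), `v0` (initial velocity, mM/min, >= 0), and
#'   optionally `sd` (per-point standard deviation, > 0) and `replicate`.
#' @return the data.frame with class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(data) {
  check_columns(data, c("s", "i", "v0"), "kinetic dataset")
  if (nrow(data) == 0) stop("kinetic dataset is empty", call. = FALSE)
  stopifnot(all(data$s > 0), all(data$i >= 0), all(data$v0 >= 0))
  if (!is.null(data$sd) && any(data$sd <= 0)) {
    stop("per-point standard deviations must be > 0", call. = FALSE)
  }
  class(data) <- unique(c("kinetic_dataset", class(data)))
  data
}

# Heuristic, scale-free starting values: VMAX from the largest velocity,
# KM from the substrate at half-max of the uninhibited series, inhibition
# constants from the median non-zero inhibitor level.
.kinetic_start <- function(data, spec) {
  vmax0 <- max(data$v0)
  base <- data[data$i == min(data$i), ]
  mu <- tapply(base$v0, base$s, mean)
  ss <- as.numeric(names(mu))
  km0 <- ss[which.min(abs(mu - max(mu) / 2))]
  k0 <- stats::median(data$i[data$i > 0])
  if (!is.finite(k0) || k0 <= 0) k0 <- km0
  start <- c(VMAX = vmax0, KM = km0)
  for (nm in setdiff(spec$parameter_names, c("VMAX", "KM"))) start[nm] <- k0
  start
}

#' Global fit of one inhibition mechanism
#'
#' Fits a single parameter vector to all inhibitor series simultaneously by
#' Levenberg-Marquardt least squares on log-transformed parameters (which
#' enforces positivity). Runs `n_starts` deterministic perturbed starting
#' points and keeps the best final chi-squared. Residuals are weighted by
#' `1/sd^2` when the dataset carries per-point standard deviations and
#' `weights = "sd"`; otherwise unweighted.
#'
#' @param data a [kinetic_dataset()].
#' @param mechanism a `mechanism_spec` or mechanism label.
#' @param weights `"none"` or `"sd"`.
#' @param n_starts number of starting points (>= 1; 5 or more recommended).
#' @return an object of class `kinetic_fit`: `mechanism`, `params` (named),
#'   `uncertainties` (standard errors, `Inf` when unidentifiable),
#'   `reduced_chi2`, `residuals` (weighted), `converged`, `message`.
#' @export
#' @examples
#' tr <- kinetic_truth("linear_noncompetitive", 44.1, 0.2,
#'                     c(KIcu = 0.009), noise_cv = 0, replicates = 1)
#' fit <- global_fit(gen_kinetic_dataset(tr), "linear_noncompetitive")
#' fit$params["KIcu"]
global_fit <- function(data, mechanism, weights = c("none", "sd"),
                       n_starts = 5) {
  data <- kinetic_dataset(as.data.frame(data))
  weights <- match.arg(weights)
  if (!inherits(mechanism, "mechanism_spec")) mechanism <- mechanism_spec(mechanism)
  if (length(unique(data$s)) < 4) {
    stop("need at least 4 substrate levels", call. = FALSE)
  }
  if (length(unique(data$i)) < 2) {
    warning("fewer than 2 inhibitor levels: inhibition constants are not identifiable",
            call. = FALSE)
  }
  w <- if (weights == "sd" && !is.null(data$sd)) 1 / data$sd^2 else rep(1, nrow(data))
  sw <- sqrt(w)
  pn <- mechanism$parameter_names
  npar <- length(pn)

  resid_fn <- function(lp) {
    p <- exp(lp); names(p) <- pn
    f <- .mech_factors(mechanism$label, p, data$i)
    v <- p[["VMAX"]] * data$s / (p[["KM"]] * f[[1]] + data$s * f[[2]])
    (v - data$v0) * sw
  }

  start <- .kinetic_start(data, mechanism)[pn]
  # deterministic multi-start: cycle fixed log-scale offsets across parameters
  factors <- c(1, 1 / 3, 3, 1 / 10, 10, 1 / 30, 30)
  best <- NULL
  for (k in seq_len(n_starts)) {
    mult <- factors[((k - 1 + seq_len(npar) - 1) %% length(factors)) + 1]
    if (k == 1) mult <- rep(1, npar)
    lp0 <- log(start * mult)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = lp0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par))) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(mechanism = mechanism, params = NULL,
                          uncertainties = NULL, reduced_chi2 = NA_real_,
                          residuals = NULL, converged = FALSE,
                          message = "all starting points failed"),
                     class = "kinetic_fit"))
  }
  p <- exp(best$par); names(p) <- pn
  n <- nrow(data)
  red_chi2 <- best$deviance / max(1, n - npar)
  # standard errors via the delta method from the log-scale covariance;
  # singular information (e.g. no inhibitor data) gives Inf
  se <- rep(Inf, npar); names(se) <- pn
  cov_log <- tryCatch(red_chi2 * solve(best$hessian), error = function(e) NULL)
  if (!is.null(cov_log)) {
    dg <- diag(cov_log)
    ok <- is.finite(dg) & dg >= 0
    se[ok] <- p[ok] * sqrt(dg[ok])
    se[!ok] <- Inf
  }
  structure(list(mechanism = mechanism, params = p, uncertainties = se,
                 reduced_chi2 = red_chi2, residuals = best$fvec,
                 data = data, converged = TRUE, message = "ok"),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>", x$mechanism$label, "\n")
  if (x$converged) {
    for (nm in names(x$params)) {
      cat(sprintf("  %-6s = %.6g (se %.3g)\n", nm, x$params[[nm]],
                  x$uncertainties[[nm]]))
    }
    cat(sprintf("  reduced chi-squared = %.4g\n", x$reduced_chi2))
  } else cat("  not converged:", x$message, "\n")
  invisible(x)
}

# Wald-Wolfowitz runs test (normal approximation) on residual signs,
# ordered by inhibitor level then substrate. Detects systematic lack of fit.
.runs_test_p <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0 || n < 4) return(NA_real_)
  runs <- 1 + sum(s[-1] != s[-n])
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(NA_real_)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}

#' Fit all seven mechanisms and select the best
#'
#' Fits every candidate mechanism globally and ranks the fits by reduced
#' chi-squared. When two fits' reduced chi-squared differ by less than the
#' parsimony tolerance (relative), the mechanism with fewer parameters is
#' preferred. Each fit's report carries its reduced chi-squared, the largest
#' relative parameter standard error, and a runs-test p-value on the signs of
#' the residuals taken in substrate order within each inhibitor series.
#'
#' @param data a [kinetic_dataset()].
#' @param weights passed to [global_fit()].
#' @param n_starts passed to [global_fit()].
#' @param parsimony_tol relative reduced-chi-squared tolerance under which the
#'   fewer-parameter mechanism wins (default 0.05).
#' @return an object of class `mechanism_selection`: `fits` (list ordered by
#'   preference, winner first), `winner` (label), `rationale` (data.frame
#'   with one row per mechanism).
#' @export
select_mechanism <- function(data, weights = "none", n_starts = 5,
                             parsimony_tol = 0.05) {
  data <- kinetic_dataset(as.data.frame(data))
  ord <- order(data$i, data$s)
  fits <- lapply(MECHANISMS, function(m) {
    suppressWarnings(global_fit(data, m, weights = weights, n_starts = n_starts))
  })
  names(fits) <- MECHANISMS
  chi2 <- vapply(fits, function(f) {
    if (f$converged) f$reduced_chi2 else Inf
  }, numeric(1))
  max_rel_se <- vapply(fits, function(f) {
    if (!f$converged) return(Inf)
    max(f$uncertainties / f$params)
  }, numeric(1))
  runs_p <- vapply(fits, function(f) {
    if (!f$converged) return(NA_real_)
    .runs_test_p(f$residuals[ord])
  }, numeric(1))
  npar <- vapply(fits, function(f) length(f$mechanism$parameter_names), numeric(1))

  rank_order <- order(chi2)
  # parsimony: among fits within tolerance of the best chi-squared, prefer
  # the fewest parameters (ties broken by chi-squared); the absolute floor
  # makes numerically-zero chi-squared values (noise-free data) compare as
  # ties instead of by rounding noise
  best_chi2 <- min(chi2)
  floor_eps <- 1e-9 * mean(data$v0)^2
  cand <- which(chi2 <= best_chi2 * (1 + parsimony_tol) + floor_eps)
  winner_idx <- cand[order(npar[cand], chi2[cand])][1]
  pref <- c(winner_idx, setdiff(rank_order, winner_idx))

  rationale <- data.frame(
    mechanism = MECHANISMS[pref],
    n_params = npar[pref],
    reduced_chi2 = chi2[pref],
    max_rel_se = max_rel_se[pref],
    runs_p = runs_p[pref],
    row.names = NULL
  )
  structure(list(fits = fits[pref], winner = MECHANISMS[winner_idx],
                 rationale = rationale),
            class = "mechanism_selection")
}

#' @export
print.mechanism_selection <- function(x, ...) {
  cat("<mechanism_selection> winner:", x$winner, "\n")
  print(x$rationale, digits = 4)
  invisible(x)
}

#' Double-reciprocal (Lineweaver-Burk) series
#'
#' Transforms each inhibitor series to `(1/s, 1/v0)` points for diagnostic
#' plotting. Points with `v0 = 0` cannot be transformed; they are dropped and
#' counted.
#'
#' @param data a [kinetic_dataset()].
#' @return data.frame with columns `i`, `inv_s`, `inv_v0`; the number of
#'   dropped zero-velocity points is in attribute `n_dropped`.
#' @export
reciprocal_series <- function(data) {
  data <- kinetic_dataset(as.data.frame(data))
  keep <- data$v0 > 0
  out <- data.frame(i = data$i[keep], inv_s = 1 / data$s[keep],
                    inv_v0 = 1 / data$v0[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' IC50 at a given substrate concentration from a kinetic fit
#'
#' Solves `v(s, i) = v(s, 0) / 2` for the inhibitor concentration `i`.
#' Closed forms exist for the linear mechanisms (e.g. non-competitive:
#' `i = KIcu` for every `s`; competitive: `i = KIC * (1 + s/KM)`); parabolic
#' mechanisms are solved by bisection.
#'
#' @param fit a converged [global_fit()] result.
#' @param s substrate concentration, mM.
#' @return IC50 in uM (note: fit constants are mM; the result is scaled).
#' @export
ic50_at_substrate <- function(fit, s) {
  stopifnot(inherits(fit, "kinetic_fit"), fit$converged, s > 0)
  p <- fit$params
  km <- p[["KM"]]
  i_mM <- switch(fit$mechanism$label,
    linear_noncompetitive = p[["KIcu"]],
    linear_competitive    = p[["KIC"]] * (1 + s / km),
    linear_uncompetitive  = p[["KIU"]] * (1 + km / s),
    linear_mixed          = (km + s) / (km / p[["KIC"]] + s / p[["KIU"]]),
    {
      # parabolic laws: v is strictly decreasing in i, bisect for the midpoint
      target <- rate_law(fit$mechanism, p, s, 0) / 2
      g <- function(i) rate_law(fit$mechanism, p, s, i) - target
      hi <- 1e4 * max(p[setdiff(names(p), c("VMAX", "KM"))])
      if (g(hi) > 0) stop("no IC50 root in bracket", call. = FALSE)
      lo <- 0
      for (iter in 1:200) {
        mid <- (lo + hi) / 2
        if (g(mid) > 0) lo <- mid else hi <- mid
        if ((hi - lo) < 1e-12 * max(hi, 1)) break
      }
      (lo + hi) / 2
    }
  )
  unname(i_mM * 1000)
}
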