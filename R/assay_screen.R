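# Screening stage: absorbance -> percent inhibition -> triage -> IC50/pIC50.

#' Percent inhibition from absorbance readings
#'
#' Computes `(1 - dA_sample / dA_blank) * 100` where each dA is the 20-minute
#' absorbance change at 405 nm (`t20 - t0`). Values are not clipped; readings
#' outside [-20, 120] percent are reported via a warning so assay problems
#' surface instead of being silently truncated.
#'
#' @param a_t0_sample,a_t20_sample sample absorbances at t0 and t20.
#' @param a_t0_blank,a_t20_blank blank (no-inhibitor) absorbances.
#' @return percent inhibition, numeric (vectorized).
#' @export
#' @examples
#' percent_inhibition(0.1, 0.35, 0.1, 0.6) # 50
percent_inhibition <- function(a_t0_sample, a_t20_sample,
                               a_t0_blank, a_t20_blank) {
  da_s <- a_t20_sample - a_t0_sample
  da_b <- a_t20_blank - a_t0_blank
  if (any(da_b == 0)) {
    stop("blank absorbance change is zero: percent inhibition undefined",
         call. = FALSE)
  }
  pct <- (1 - da_s / da_b) * 100
  out <- pct < -20 | pct > 120
  if (any(out)) {
    warning(sum(out), " percent-inhibition value(s) outside [-20, 120]",
            call. = FALSE)
  }
  pct
}

#' Triage filter for the primary screen
#'
#' A compound advances to concentration-response follow-up when its mean
#' percent inhibition at the screening concentration (20 uM) is at least the
#' threshold (default 90 percent).
#'
#' @param inhibitions percent-inhibition replicate values at the screening
#'   concentration.
#' @param threshold pass threshold in percent.
#' @return logical: `TRUE` if the compound passes.
#' @export
#' @examples
#' triage_screen(c(92, 91, 90)) # TRUE
triage_screen <- function(inhibitions, threshold = 90) {
  if (length(inhibitions) == 0) stop("no inhibition values supplied", call. = FALSE)
  mean(inhibitions) >= threshold
}

#' Fit a concentration-inhibition curve
#'
#' Least-squares fit of the logistic (Hill) model
#' `%I(c) = bottom + (top - bottom) / (1 + (ic50/c)^hill)` with `bottom`
#' fixed at 0 and `top` free within [80, 120], the conventional model for
#' percent-inhibition data. Uses Levenberg-Marquardt with multiple starting
#' points; non-convergence is reported in the result, not raised.
#'
#' @param points data.frame with columns `concentration` (uM, > 0) and
#'   `inhibition` (percent); replicates may be included as extra rows.
#' @param signal_floor minimum observed mean inhibition (percent) required to
#'   attempt a fit; flat, signal-free data yields `converged = FALSE`.
#' @return an object of class `dose_response_fit`: list with `ic50` (uM),
#'   `hill`, `top`, `bottom`, `pic50`, `reduced_chi2`, `residuals`,
#'   `converged`, `message`.
#' @export
fit_dose_response <- function(points, signal_floor = 20) {
  check_columns(points, c("concentration", "inhibition"), "dose-response table")
  if (any(points$concentration <= 0)) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  if (length(unique(points$concentration)) < 4) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  conc <- points$concentration
  inh <- points$inhibition
  fail <- function(msg) {
    structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_, bottom = 0,
                   pic50 = NA_real_, reduced_chi2 = NA_real_, residuals = NULL,
                   converged = FALSE, message = msg),
              class = "dose_response_fit")
  }
  if (max(tapply(inh, conc, mean)) < signal_floor) {
    return(fail("no inhibition signal across the tested range"))
  }

  model <- function(p) p[3] / (1 + (exp(p[1]) / conc)^exp(p[2]))
  resid_fn <- function(p) model(p) - inh

  # crude ic50 start: concentration whose mean response is nearest half-max
  mu <- tapply(inh, conc, mean)
  cs <- as.numeric(names(mu))
  ic50_0 <- cs[which.min(abs(mu - max(mu) / 2))]
  starts <- c(
    lapply(c(0.5, 1, 2, 4), function(h) c(log(ic50_0), log(h), 100)),
    lapply(c(0.5, 1, 2, 4), function(h) c(log(ic50_0 * 5), log(h), 100)),
    lapply(c(0.5, 1, 2, 4), function(h) c(log(ic50_0 / 5), log(h), 100))
  )
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         lower = c(-Inf, -Inf, 80), upper = c(Inf, Inf, 120),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(fail("Levenberg-Marquardt failed from all starts"))
  p <- best$par
  ic50 <- exp(p[1])
  n <- length(inh); npar <- 3
  structure(list(
    ic50 = ic50, hill = exp(p[2]), top = p[3], bottom = 0,
    pic50 = to_pic50(ic50),
    reduced_chi2 = best$deviance / max(1, n - npar),
    residuals = resid_fn(p),
    converged = TRUE, message = "ok"
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit>\n")
  if (x$converged) {
    cat(sprintf("  IC50 = %.4g uM  (pIC50 = %.3f), hill = %.3f, top = %.1f%%\n",
                x$ic50, x$pic50, x$hill, x$top))
    cat(sprintf("  reduced chi-squared = %.4g\n", x$reduced_chi2))
  } else {
    cat("  not converged:", x$message, "\n")
  }
  invisible(x)
}

#' pIC50 from a micromolar IC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50; for an IC50
#' expressed in uM this is `6 - log10(ic50)`.
#'
#' @param ic50 IC50 in uM, > 0.
#' @return pIC50 (unitless).
#' @export
#' @examples
#' to_pic50(100) # 4
to_pic50 <- function(ic50) {
  if (any(ic50 <= 0)) stop("ic50 must be > 0", call. = FALSE)
  6 - log10(ic50)
}

#' Micromolar IC50 from a pIC50
#'
#' Inverse of [to_pic50()].
#'
#' @param pic50 pIC50 value(s).
#' @return IC50 in uM.
#' @export
from_pic50 <- function(pic50) 10^(6 - pic50)

#' Activity difference versus a reference compound
#'
#' Absolute pIC50 difference, reported to one decimal with half-up rounding
#' (0.35 rounds to 0.4), the convention used for tabulated activity gaps.
#'
#' @param pic50_ref reference compound pIC50.
#' @param pic50 compound pIC50 (vectorized).
#' @return absolute difference rounded half-up to one decimal.
#' @export
#' @examples
#' delta_activity(4.66, 4.48) # 0.2
delta_activity <- function(pic50_ref, pic50) {
  if (any(!is.finite(pic50_ref)) || any(!is.finite(pic50))) {
    stop("pIC50 values must be finite", call. = FALSE)
  }
  round_half_up(abs(pic50_ref - pic50), 1)
}

#' Potency band from an IC50
#'
#' Hits have IC50 below 100 uM; compounds with IC50 between 100 and 1000 uM
#' (inclusive) are labelled active; anything weaker is inactive.
#'
#' @param ic50 IC50 in uM, > 0 (vectorized).
#' @return character vector in `{"hit", "active", "inactive"}`.
#' @export
#' @examples
#' classify_activity(c(99, 100, 1500))
classify_activity <- function(ic50) {
  if (any(ic50 <= 0)) stop("ic50 must be > 0", call. = FALSE)
  ifelse(ic50 < 100, "hit", ifelse(ic50 <= 1000, "active", "inactive"))
}
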