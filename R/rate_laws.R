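# Candidate inhibition mechanisms and their steady-state rate laws.
#
# Every law has the form
#   v0 = VMAX * S / (KM * f_KM(I) + S * f_S(I))
# where f_KM and f_S are inhibitor-dependent factors. Linear mechanisms use
# 1 + I/K; parabolic mechanisms (two inhibitor molecules binding) add a
# quadratic term 1 + I/K + I^2/K2^2 with an independent second constant.
# At I = 0 every law collapses to Michaelis-Menten.

MECHANISMS <- c(
  "linear_competitive", "linear_uncompetitive", "linear_noncompetitive",
  "linear_mixed", "parabolic_competitive", "parabolic_uncompetitive",
  "parabolic_noncompetitive"
)

.MECH_PARAMS <- list(
  linear_competitive       = c("VMAX", "KM", "KIC"),
  linear_uncompetitive     = c("VMAX", "KM", "KIU"),
  linear_noncompetitive    = c("VMAX", "KM", "KIcu"),
  linear_mixed             = c("VMAX", "KM", "KIC", "KIU"),
  parabolic_competitive    = c("VMAX", "KM", "KIC", "KIC2"),
  parabolic_uncompetitive  = c("VMAX", "KM", "KIU", "KIU2"),
  parabolic_noncompetitive = c("VMAX", "KM", "KIcu", "KIcu2")
)

#' Mechanism specification
#'
#' Returns the specification of one of the seven candidate enzyme-inhibition
#' mechanisms: three-parameter linear competitive / uncompetitive /
#' non-competitive laws, the four-parameter linear mixed law, and the
#' four-parameter parabolic variants in which two inhibitor molecules bind,
#' contributing a quadratic inhibitor term.
#'
#' @param label one of `mechanism_labels()`.
#' @return an object of class `mechanism_spec` with elements `label` and
#'   `parameter_names` (ordered; `VMAX` in mM/min, all others mM).
#' @seealso [rate_law()], [global_fit()]
#' @export
#' @examples
#' mechanism_spec("parabolic_competitive")$parameter_names
mechanism_spec <- function(label) {
  label <- match.arg(label, MECHANISMS)
  structure(list(label = label, parameter_names = .MECH_PARAMS[[label]]),
            class = "mechanism_spec")
}

#' @rdname mechanism_spec
#' @export
mechanism_labels <- function() MECHANISMS

#' @export
print.mechanism_spec <- function(x, ...) {
  cat("<mechanism_spec>", x$label, "\n  parameters:",
      paste(x$parameter_names, collapse = ", "), "\n")
  invisible(x)
}

# Inhibitor-dependent denominator factors (f_KM, f_S) for one mechanism.
# Vectorized over i.
.mech_factors <- function(label, params, i) {
  lin <- function(k) 1 + i / k
  par2 <- function(k, k2) 1 + i / k + i^2 / k2^2
  switch(label,
    linear_competitive       = list(lin(params[["KIC"]]), rep(1, length(i))),
    linear_uncompetitive     = list(rep(1, length(i)), lin(params[["KIU"]])),
    linear_noncompetitive    = list(lin(params[["KIcu"]]), lin(params[["KIcu"]])),
    linear_mixed             = list(lin(params[["KIC"]]), lin(params[["KIU"]])),
    parabolic_competitive    = list(par2(params[["KIC"]], params[["KIC2"]]),
                                    rep(1, length(i))),
    parabolic_uncompetitive  = list(rep(1, length(i)),
                                    par2(params[["KIU"]], params[["KIU2"]])),
    parabolic_noncompetitive = {
      f <- par2(params[["KIcu"]], params[["KIcu2"]])
      list(f, f)
    },
    stop("unknown mechanism label: ", label, call. = FALSE)
  )
}

#' Evaluate an inhibition rate law
#'
#' Initial velocity v0 for one mechanism at substrate concentration(s) `s`
#' and inhibitor concentration(s) `i`. The non-competitive law reads
#' `VMAX*s / ((KM + s) * (1 + i/KIcu))`, the mixed law
#' `VMAX*s / (KM*(1 + i/KIC) + s*(1 + i/KIU))`, and the parabolic
#' competitive law `VMAX*s / (KM*(1 + i/KIC + i^2/KIC2^2) + s)`; the
#' remaining mechanisms use the corresponding standard linear/parabolic
#' factors.
#'
#' @param mechanism a `mechanism_spec` or mechanism label.
#' @param params named numeric vector/list with the mechanism's parameters
#'   (all strictly positive).
#' @param s substrate concentration(s), mM, > 0.
#' @param i inhibitor concentration(s), mM, >= 0. Recycled against `s`.
#' @return numeric vector of initial velocities (mM/min).
#' @export
#' @examples
#' rate_law("linear_noncompetitive",
#'          c(VMAX = 44.1, KM = 0.2, KIcu = 0.009), s = 0.2, i = 0.009)
rate_law <- function(mechanism, params, s, i) {
  if (!inherits(mechanism, "mechanism_spec")) mechanism <- mechanism_spec(mechanism)
  params <- unlist(params)
  need <- mechanism$parameter_names
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s) for ", mechanism$label, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(params[need])) || any(params[need] <= 0)) {
    stop("all parameters must be finite and > 0", call. = FALSE)
  }
  if (any(s <= 0)) stop("substrate concentrations must be > 0", call. = FALSE)
  if (any(i < 0)) stop("inhibitor concentrations must be >= 0", call. = FALSE)
  n <- max(length(s), length(i))
  s <- rep_len(s, n); i <- rep_len(i, n)
  f <- .mech_factors(mechanism$label, params, i)
  params[["VMAX"]] * s / (params[["KM"]] * f[[1]] + s * f[[2]])
}
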