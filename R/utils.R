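# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators with their own
#' seed fields do not disturb the global random stream.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero at a fixed number of decimals
#'
#' Decimal (commercial) rounding: 0.35 at one decimal becomes 0.4. Base R's
#' `round()` uses banker's rounding, which would give 0.4 only by accident of
#' binary representation; activity-difference reporting requires half-up.
#'
#' @param x numeric vector (non-negative values expected for ties to round up).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.35, 1) # 0.4
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Multiplicative Gaussian noise truncated at zero: sd = cv * mean.
# Absorbance-derived quantities have roughly proportional error and cannot be
# negative.
apply_noise <- function(mu, cv) {
  if (cv == 0) return(mu)
  pmax(0, mu * (1 + stats::rnorm(length(mu), sd = cv)))
}

# Stop with a consistent message when a required column is absent.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
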