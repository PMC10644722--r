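# Low-dimensional chemical space projection by exact t-SNE.
#
# Exact (non-Barnes-Hut) t-distributed stochastic neighbor embedding on the
# Jaccard distance (1 - Tanimoto) between binary fingerprints. Library sizes
# here are small (tens to hundreds of compounds), where the O(n^2) exact
# gradient is cheap and has no approximation error.

#' Embedding configuration
#'
#' @param perplexity effective number of neighbors balanced by the input
#'   kernel (default 40); must be smaller than the number of compounds.
#' @param iterations gradient-descent iterations (default 3000).
#' @param dimensions output dimensionality, 2 or 3.
#' @param seed integer RNG seed for the random initialization.
#' @return an object of class `embedding_config`.
#' @export
embedding_config <- function(perplexity = 40, iterations = 3000,
                             dimensions = 2, seed = 0) {
  stopifnot(perplexity > 0, iterations >= 1, dimensions %in% c(2, 3))
  structure(list(perplexity = perplexity, iterations = iterations,
                 dimensions = dimensions, seed = seed),
            class = "embedding_config")
}

# Binary search the Gaussian bandwidth for one point so that the conditional
# distribution's perplexity matches the target.
.tsne_row_probs <- function(d2_row, target_log_perp) {
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (iter in 1:60) {
    p <- exp(-d2_row * beta)
    sp <- sum(p)
    if (sp == 0) { h <- 0 } else {
      h <- log(sp) + beta * sum(d2_row * p) / sp
    }
    if (abs(h - target_log_perp) < 1e-7) break
    if (h > target_log_perp) {
      lo <- beta
      beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
    }
  }
  p <- exp(-d2_row * beta)
  if (sum(p) == 0) p[] <- 1 / length(p)
  p / sum(p)
}

#' Project compounds into a low-dimensional chemical space
#'
#' Exact t-SNE on the pairwise Jaccard distances of a fingerprint set, with
#' early exaggeration (factor 12 for the first 250 iterations) and momentum
#' (0.5 switching to 0.8). Deterministic for a fixed seed.
#'
#' @param fps a `fingerprint_set`.
#' @param config an [embedding_config()].
#' @return data.frame with `compound_id` and coordinate columns `x`, `y`
#'   (and `z` for 3 dimensions).
#' @export
project_chemspace <- function(fps, config = embedding_config()) {
  stopifnot(inherits(fps, "fingerprint_set"), inherits(config, "embedding_config"))
  n <- nrow(fps$bits)
  if (config$perplexity >= n) {
    stop("perplexity (", config$perplexity, ") must be smaller than the number ",
         "of compounds (", n, ")", call. = FALSE)
  }
  sim <- unclass(similarity_matrix(fps))
  d2 <- (1 - sim)^2

  log_perp <- log(config$perplexity)
  P <- matrix(0, n, n)
  for (k in seq_len(n)) {
    P[k, -k] <- .tsne_row_probs(d2[k, -k], log_perp)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps

  d <- config$dimensions
  Y <- with_seed(config$seed, matrix(stats::rnorm(n * d, sd = 1e-4), n, d))
  G <- matrix(0, n, d)          # update memory (momentum)
  gains <- matrix(1, n, d)
  eta <- 200
  exag <- 12
  for (it in seq_len(config$iterations)) {
    Pit <- if (it <= 250) P * exag else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.eps] <- .Machine$double.eps
    W <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  out <- data.frame(compound_id = rownames(fps$bits), Y)
  names(out)[-1] <- c("x", "y", "z")[seq_len(d)]
  rownames(out) <- NULL
  out
}
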