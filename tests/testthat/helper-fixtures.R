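# Shared fixtures and independent oracles for the test suite.

# Random 0/1 fingerprint matrix with given density.
random_bits <- function(n, len, density = 0.2, seed = 1) {
  m <- inhibscreen:::with_seed(seed, {
    matrix(as.integer(stats::runif(n * len) < density), n, len)
  })
  rownames(m) <- sprintf("r%03d", seq_len(n))
  m
}

# Brute-force Tanimoto oracle: literal bit counting, no vectorization.
tanimoto_oracle <- function(a, b) {
  inter <- 0L; un <- 0L
  for (k in seq_along(a)) {
    if (a[k] == 1L && b[k] == 1L) inter <- inter + 1L
    if (a[k] == 1L || b[k] == 1L) un <- un + 1L
  }
  if (un == 0L) 0 else inter / un
}

# Naive double-loop similarity matrix oracle.
similarity_oracle <- function(bits) {
  n <- nrow(bits)
  out <- diag(1, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      out[a, b] <- out[b, a] <- tanimoto_oracle(bits[a, ], bits[b, ])
    }
  }
  dimnames(out) <- list(rownames(bits), rownames(bits))
  out
}

# Planted SAS fixture: hand-set similarities and pIC50s with known zone
# membership relative to reference "ref" under default thresholds
# (similarity 0.5, |dpIC50| 1.0).
planted_sas_fixture <- function() {
  ids <- c("ref", "hop1", "hop2", "analog1", "cliff1", "dull1")
  sim <- diag(1, 6)
  dimnames(sim) <- list(ids, ids)
  set_pair <- function(a, b, v) {
    sim[a, b] <<- v; sim[b, a] <<- v
  }
  set_pair("ref", "hop1", 0.10)     # low sim, low dA  -> ZI
  set_pair("ref", "hop2", 0.30)     # low sim, low dA  -> ZI
  set_pair("ref", "analog1", 0.90)  # high sim, low dA -> ZII
  set_pair("ref", "cliff1", 0.95)   # high sim, high dA -> ZIV
  set_pair("ref", "dull1", 0.20)    # low sim, high dA -> ZIII
  # fill remaining off-reference pairs with low-similarity values
  others <- setdiff(ids, "ref")
  for (a in seq_along(others)) {
    for (b in seq_along(others)) {
      if (a < b && sim[others[a], others[b]] == 0) {
        sim[others[a], others[b]] <- sim[others[b], others[a]] <- 0.15
      }
    }
  }
  class(sim) <- c("similarity_matrix", "matrix")
  records <- data.frame(
    compound_id = ids,
    pic50 = c(4.66, 4.60, 4.30, 4.50, 6.10, 3.20)
  )
  list(records = records, sim = sim, ids = ids)
}

# Deterministic small compound library reused across cheminformatics tests.
small_library <- function(n_scaffolds = 2, per_scaffold = 5, seed = 42) {
  gen_library(library_truth(n_scaffolds, per_scaffold, seed = seed))
}
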