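# Tanimoto similarity, similarity matrices, TSD curves, fingerprint choice.

test_that("tanimoto handles identity, disjoint, partial, and zero vectors", {
  a <- c(1, 1, 1, 0)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)  # zero-vector convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
})

test_that("tanimoto matches the brute-force oracle on random pairs", {
  bits <- random_bits(80, 128, density = 0.3, seed = 11)
  idx <- inhibscreen:::with_seed(12, {
    cbind(sample(80, 300, replace = TRUE), sample(80, 300, replace = TRUE))
  })
  for (k in seq_len(nrow(idx))) {
    a <- bits[idx[k, 1], ]; b <- bits[idx[k, 2], ]
    expect_identical(tanimoto(a, b), tanimoto_oracle(a, b))
  }
  # symmetry and bounds on the same sample
  for (k in seq_len(50)) {
    a <- bits[idx[k, 1], ]; b <- bits[idx[k, 2], ]
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    expect_true(tanimoto(a, b) >= 0 && tanimoto(a, b) <= 1)
  }
})

test_that("similarity_matrix equals the naive double loop and is equivariant", {
  bits <- random_bits(30, 100, seed = 4)
  sim <- similarity_matrix(fingerprint_set(bits))
  expect_equal(unclass(sim), similarity_oracle(bits), tolerance = 0)
  expect_equal(diag(unclass(sim)), rep(1, 30), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(sim)))
  # permuting compounds permutes rows and columns identically
  perm <- rev(seq_len(30))
  sim_p <- similarity_matrix(fingerprint_set(bits[perm, ]))
  expect_equal(unclass(sim_p), unclass(sim)[perm, perm], tolerance = 0)
  # n(n-1)/2 distinct off-diagonal values
  expect_length(sim[upper.tri(sim)], 30 * 29 / 2)
})

test_that("TSD curves are monotone CDFs of the pair similarities", {
  # degenerate libraries: identical compounds vs disjoint compounds
  ident <- fingerprint_set(matrix(rep(c(1, 0, 1, 0), 3), 3, 4, byrow = TRUE,
                                  dimnames = list(c("a", "b", "c"), NULL)))
  cv <- tsd_curve(similarity_matrix(ident))
  expect_equal(cv$cumulative_fraction[cv$threshold < 1],
               rep(0, sum(cv$threshold < 1)))
  expect_equal(cv$cumulative_fraction[cv$threshold == 1], 1)

  disj_bits <- diag(1L, 3)
  rownames(disj_bits) <- c("a", "b", "c")
  disj <- fingerprint_set(disj_bits)
  cv2 <- tsd_curve(similarity_matrix(disj))
  expect_equal(cv2$cumulative_fraction, rep(1, nrow(cv2)))

  # general case: matches the sort-based empirical CDF
  bits <- random_bits(25, 64, seed = 9)
  sim <- similarity_matrix(fingerprint_set(bits))
  ps <- sort(unclass(sim)[upper.tri(sim)])
  cv3 <- tsd_curve(sim)
  ecdf_oracle <- vapply(cv3$threshold,
                        function(t) sum(ps <= t) / length(ps), numeric(1))
  expect_equal(cv3$cumulative_fraction, ecdf_oracle, tolerance = 0)
  expect_true(all(diff(cv3$cumulative_fraction) >= 0))
  expect_equal(cv3$cumulative_fraction[nrow(cv3)], 1)
})

test_that("fingerprint selection prefers the dominating (more discriminative) curve", {
  bits <- random_bits(20, 64, seed = 2)
  sim <- similarity_matrix(fingerprint_set(bits))
  # a constant-bit fingerprint makes everything look identical
  const_bits <- matrix(1L, 20, 64, dimnames = list(rownames(bits), NULL))
  sim_const <- similarity_matrix(fingerprint_set(const_bits))
  sel <- select_fingerprint(list(random = tsd_curve(sim),
                                 constant = tsd_curve(sim_const)))
  expect_equal(sel$winner, "random")
  expect_false(sel$tie)
  expect_equal(nrow(sel$ranking), 2)
  # identical curves tie and resolve by name order
  sel2 <- select_fingerprint(list(b = tsd_curve(sim), a = tsd_curve(sim)))
  expect_equal(sel2$winner, "a")
  expect_true(sel2$tie)
})

test_that("computed fingerprints are deterministic and structure-sensitive", {
  recs <- data.frame(compound_id = c("benzene", "benzene2", "hexane"),
                     smiles = c("c1ccccc1", "c1ccccc1", "CCCCCC"))
  fps <- compute_fingerprints(recs, "fp2_path")
  expect_equal(fps$length, 1024)
  expect_identical(fps$bits["benzene", ], fps$bits["benzene2", ])
  expect_lt(tanimoto(fps$bits["benzene", ], fps$bits["hexane", ]), 1)
  expect_identical(fps$bits, compute_fingerprints(recs, "fp2_path")$bits)
  expect_error(compute_fingerprints(recs, "nope"), "supported")
  bad <- data.frame(compound_id = c("ok", "broken"),
                    smiles = c("CCO", "C1CC"))
  expect_error(compute_fingerprints(bad, "fp2_path"), "broken")
})

test_that("the full fingerprint panel runs on a synthetic library", {
  lib <- small_library(2, 4)
  lens <- c(fp2_path = 1024, fp3_keys = 64, fp4_keys = 512, maccs = 256,
            atompair = 1024)
  for (fp in fingerprint_names()) {
    f <- compute_fingerprints(lib, fp)
    expect_equal(f$length, unname(lens[fp]), info = fp)
    expect_equal(nrow(f$bits), 8, info = fp)
  }
})
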