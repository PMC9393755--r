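test_that("matrix summation and depth normalization preserve structure", {
  set.seed(1)
  A <- matrix(rpois(64, 10), 8, 8); A <- A + t(A)
  Z <- matrix(0, 8, 8)
  a <- contact_matrix(A, "chr1", 1000)
  z <- contact_matrix(Z, "chr1", 1000)
  expect_equal(sum_matrices(a, z)$counts, A)
  expect_equal(sum_matrices(a, a)$counts, 2 * A)

  b <- contact_matrix(2.5 * A, "chr1", 1000)
  nn <- normalize_to_common_depth(a, b)
  expect_equal(matrix_mass(nn[[1]]), matrix_mass(nn[[2]]))
  expect_equal(matrix_mass(nn[[1]]), matrix_mass(a))
  # relative structure unchanged
  expect_equal(nn[[2]]$counts / nn[[2]]$counts[1, 2],
               b$counts / b$counts[1, 2])
  nn2 <- normalize_to_common_depth(a, a)
  expect_equal(nn2[[1]]$counts, A)
  expect_error(normalize_to_common_depth(a, z), "zero-mass")
  expect_error(sum_matrices(a, contact_matrix(A, "chr2", 1000)),
               "same bin table")
})

test_that("ICE agrees with an independent Sinkhorn oracle", {
  M <- matrix(c(0, 2, 4,
                2, 0, 2,
                4, 2, 0), 3, 3)
  m <- ice_correct(contact_matrix(M, "chr1", 1000), tol = 1e-9,
                   max_iter = 2000)
  marg <- rowSums(m$counts)
  expect_lt(diff(range(marg)), 1e-6 * mean(marg))
  oracle <- sinkhorn_oracle(M)
  expect_lt(max(abs(m$counts / sum(m$counts) - oracle)), 1e-5)
})

test_that("ICE fixed point, masking and weight semantics", {
  # doubly balanced matrix: unchanged up to global scale, weights equal
  B <- matrix(c(0.2, 0.5, 0.3,
                0.5, 0.3, 0.2,
                0.3, 0.2, 0.5), 3, 3)
  m <- ice_correct(contact_matrix(B, "chr1", 1000), mad_filter = Inf)
  expect_equal(m$counts / m$counts[1, 1], B / B[1, 1], tolerance = 1e-6)
  expect_lt(diff(range(m$weights)), 1e-6)

  # zero-coverage bin is masked, remainder balanced
  C <- matrix(5, 4, 4); C[2, ] <- C[, 2] <- 0
  mc <- ice_correct(contact_matrix(C, "chr1", 1000), mad_filter = Inf)
  expect_true(is.na(mc$weights[2]))
  expect_true(all(mc$counts[2, ] == 0))
  kept <- rowSums(mc$counts)[-2]
  expect_lt(diff(range(kept)), 1e-6 * mean(kept))

  expect_error(ice_correct(contact_matrix(matrix(0, 3, 3), "chr1", 1000)),
               "too sparse")
  # corrected = raw * w_i * w_j on retained bins
  set.seed(5)
  R <- matrix(rpois(100, 20), 10, 10); R <- R + t(R)
  mr <- ice_correct(contact_matrix(R, "chr1", 1000), mad_filter = Inf)
  w <- mr$weights
  expect_equal(mr$counts, R * outer(w, w), tolerance = 1e-6)
})

test_that("ICE drives marginal CV below tolerance on random matrices", {
  set.seed(11)
  for (rep in 1:5) {
    M <- matrix(rpois(400, 15) + 1, 20, 20)
    M <- M + t(M)
    m <- ice_correct(contact_matrix(M, "chr1", 1000), tol = 1e-6,
                     mad_filter = Inf)
    marg <- rowSums(m$counts)
    expect_lt(sd(marg) / mean(marg), 1e-6)
  }
})

test_that("expected_by_distance matches brute-force diagonal averaging", {
  u <- contact_matrix(matrix(3, 6, 6), "chr1", 1000)
  expect_equal(expected_by_distance(u), rep(3, 6))

  n <- 12
  Dd <- abs(outer(1:n, 1:n, "-"))
  dec <- contact_matrix(100 / (Dd + 1), "chr1", 1000)
  prof <- expected_by_distance(dec)
  expect_true(all(diff(prof) < 0))

  set.seed(3)
  M5 <- matrix(sample(0:9, 25, replace = TRUE), 5, 5)
  M5 <- M5 + t(M5)
  m5 <- contact_matrix(M5, "chr1", 1000)
  expect_equal(expected_by_distance(m5), diag_means_oracle(M5))
})

test_that("log2 ratio matrix is antisymmetric in its arguments", {
  set.seed(2)
  A <- matrix(rpois(36, 20) + 1, 6, 6); A <- A + t(A)
  a <- contact_matrix(A, "chr1", 1000)
  b <- contact_matrix(2 * A, "chr1", 1000)
  expect_equal(log2_ratio_matrix(a, a), matrix(0, 6, 6))
  expect_equal(log2_ratio_matrix(a, b, pseudocount = 0), matrix(1, 6, 6))
  R1 <- log2_ratio_matrix(a, b)
  R2 <- log2_ratio_matrix(b, a)
  expect_equal(R1 + R2, matrix(0, 6, 6))
})

test_that("coarsening conserves mass and triplet I/O round-trips", {
  set.seed(4)
  M <- matrix(rpois(400, 8), 20, 20); M <- M + t(M)
  m <- contact_matrix(M, "chr9", 5000)
  cm <- coarsen_matrix(m, 4)
  expect_equal(cm$n_bins, 5)
  expect_equal(sum(cm$counts), sum(M))
  expect_equal(cm$resolution, 20000)

  f <- withr::local_tempfile()
  write_contact_matrix(m, f)
  back <- read_contact_matrix(f)
  expect_equal(back$counts, m$counts)
  expect_equal(back$resolution, m$resolution)
  expect_equal(back$chrom, m$chrom)
})
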