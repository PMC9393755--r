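# decay matrix with focal peaks planted as 3x3 blobs (5x center, 3x ring)
peaked_matrix <- function(n = 500, peaks, depth = 300, seed = 1,
                          res = 10000, center = 5, ring = 3) {
  set.seed(seed)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- depth * (D + 1)^-1
  for (t in seq_len(nrow(peaks))) {
    i <- peaks[t, 1]; j <- peaks[t, 2]
    for (di in -1:1) for (dj in -1:1) {
      f <- if (di == 0 && dj == 0) center else ring
      E[i + di, j + dj] <- E[i + di, j + dj] * f
      E[j + dj, i + di] <- E[i + di, j + dj]
    }
  }
  M <- matrix(0, n, n)
  ut <- upper.tri(E, diag = TRUE)
  M[ut] <- rpois(sum(ut), E[ut])
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  contact_matrix(M, "chrL", res)
}

test_that("planted focal peaks are recovered within the distance limit", {
  set.seed(13)
  peaks <- cbind(seq(30, 410, by = 20), seq(30, 410, by = 20) +
                   sample(20:60, 20, replace = TRUE))
  m <- peaked_matrix(500, peaks)
  loops <- detect_loops(m)
  truth <- data.frame(chrom = "chrL", bin1 = peaks[, 1], bin2 = peaks[, 2])
  rec <- feature_recovery(truth, loops, tol = 1)
  expect_gte(rec$recall, 0.8)
  expect_true(all(loops$distance <= 1e6))

  # a peak at 1.5 Mb is excluded by the 1-Mb distance cap but detectable
  # when the cap is raised
  far <- peaked_matrix(500, cbind(100, 250), seed = 2)
  called_far <- detect_loops(far, max_distance = 1e6)
  expect_false(any(abs(called_far$bin1 - 100) <= 1 &
                     abs(called_far$bin2 - 250) <= 1))
  called_near <- detect_loops(far, max_distance = 1.6e6)
  expect_true(any(abs(called_near$bin1 - 100) <= 1 &
                    abs(called_near$bin2 - 250) <= 1))
})

test_that("loop calling is invariant to global scaling", {
  peaks <- cbind(c(60, 200), c(100, 260))
  m <- peaked_matrix(320, peaks, seed = 3)
  l1 <- detect_loops(m)
  m2 <- contact_matrix(m$counts * 4, m$chrom, m$resolution, m$chrom_length)
  l2 <- detect_loops(m2)
  expect_equal(l1[, c("bin1", "bin2")], l2[, c("bin1", "bin2")])
})

test_that("significant interactions use distance-stratified z-scores", {
  u <- contact_matrix(matrix(6, 100, 100), "chrU", 5000)
  expect_equal(nrow(significant_interactions(u)), 0)

  M <- matrix(10, 200, 200)
  M[50, 60] <- M[60, 50] <- 200   # single inflated pixel at 50 kb
  set.seed(8)
  M <- M + matrix(rpois(200 * 200, 1), 200, 200)
  M <- pmax(M, t(M))
  m <- contact_matrix(M, "chrZ", 5000)
  calls <- significant_interactions(m, min_dist = 20000, max_dist = 1e6)
  expect_true(any(calls$bin1 == 50 & calls$bin2 == 60))
  expect_gte(min(calls$distance), 25000)  # strictly beyond min_dist

  # a pair at 15 kb is excluded by min_dist even if inflated
  M2 <- matrix(10, 100, 100)
  M2[40, 43] <- M2[43, 40] <- 500
  m2 <- contact_matrix(M2, "chrZ", 5000)
  calls2 <- significant_interactions(m2)
  expect_false(any(calls2$bin1 == 40 & calls2$bin2 == 43))
})

test_that("loop classification is an exact partition and swaps on reversal", {
  mk <- function(b1, b2) {
    df <- data.frame(chrom = "chr1", bin1 = b1, bin2 = b2,
                     start1 = (b1 - 1) * 5000, end1 = b1 * 5000,
                     start2 = (b2 - 1) * 5000, end2 = b2 * 5000,
                     distance = (b2 - b1) * 5000, observed = 10,
                     expected = 2, p = 0.001, p_ring = 0.001, q = 0.004,
                     class = NA_character_)
    class(df) <- c("loop_set", "data.frame")
    df
  }
  l1 <- mk(c(10, 30, 50), c(20, 45, 70))
  cls_id <- classify_loops(l1, l1)
  expect_true(all(cls_id$class == "stable"))

  l2 <- mk(c(10, 100), c(20, 200))
  cls <- classify_loops(l1, l2)
  expect_equal(sum(cls$class == "stable"), 1)
  expect_equal(cls$class[cls$bin1 == 100], "gained")
  expect_equal(sum(cls$class == "lost"), 2)
  # partition arithmetic
  expect_equal(sum(cls$class %in% c("stable", "gained")), nrow(l2))
  expect_equal(sum(cls$class %in% c("stable", "lost")), nrow(l1))
  # symmetry: swapping inputs swaps gained and lost
  cls_r <- classify_loops(l2, l1)
  expect_equal(sum(cls_r$class == "gained"), sum(cls$class == "lost"))
  expect_equal(sum(cls_r$class == "lost"), sum(cls$class == "gained"))
})

test_that("APA scores a flat aggregate as 1 and planted peaks above 1.5", {
  u <- contact_matrix(matrix(5, 120, 120), "chrU", 5000)
  one <- data.frame(chrom = "chrU", bin1 = 40, bin2 = 80)
  expect_equal(apa(u, one, flank_bins = 10)$score, 1)

  peaks <- cbind(c(60, 150, 240), c(100, 200, 290))
  m <- peaked_matrix(350, peaks, seed = 5)
  loops <- data.frame(chrom = "chrL", bin1 = peaks[, 1], bin2 = peaks[, 2])
  res <- apa(m, loops, flank_bins = 10)
  expect_gt(res$score, 1.5)
  expect_equal(res$n_loops, 3)

  # loops too close to the diagonal are skipped and tallied
  near <- data.frame(chrom = "chrL", bin1 = 100, bin2 = 110)
  expect_error(apa(m, near), "no usable loops")
})
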