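test_that("metaprofile reproduces constant and step signals exactly", {
  const <- make_track("chr1", seq(0, 99000, 1000), seq(1000, 100000, 1000),
                      rep(2.5, 100))
  centers <- data.frame(chrom = "chr1", start = c(30000, 50000, 70000),
                        end = c(30001, 50001, 70001))
  p <- metaprofile(const, centers, window = 10000, binsize = 1000,
                   chrom_sizes = c(chr1 = 100000))
  expect_equal(p$mean, rep(2.5, 20))
  expect_equal(range(p$positions), c(-9500, 9500))

  # single feature over a step track: profile reproduces the step
  step <- make_track("chr1", c(0, 50000), c(50000, 100000), c(1, 3))
  ps <- metaprofile(step, centers[2, ], window = 10000, binsize = 1000,
                    chrom_sizes = c(chr1 = 100000))
  expect_equal(ps$mean, rep(c(1, 3), each = 10))

  # features truncated by the chromosome end are dropped
  edge <- rbind(centers, data.frame(chrom = "chr1", start = 95000,
                                    end = 95001))
  pe <- metaprofile(const, edge, window = 10000, binsize = 1000,
                    chrom_sizes = c(chr1 = 100000))
  expect_equal(pe$n_features, 3)
  expect_equal(pe$n_dropped, 1)
  expect_error(metaprofile(const, centers[0, ], 10000, 1000), "empty")
})

test_that("metaprofile is linear in the track values", {
  set.seed(23)
  v <- runif(100, 0, 4)
  tr1 <- make_track("chr1", seq(0, 99000, 1000), seq(1000, 100000, 1000), v)
  tr3 <- make_track("chr1", seq(0, 99000, 1000), seq(1000, 100000, 1000),
                    3 * v)
  centers <- data.frame(chrom = "chr1", start = c(40000, 60000),
                        end = c(40001, 60001))
  p1 <- metaprofile(tr1, centers, 20000, 2000, c(chr1 = 1e5))
  p3 <- metaprofile(tr3, centers, 20000, 2000, c(chr1 = 1e5))
  expect_equal(p3$mean, 3 * p1$mean)
})

test_that("gene-body profiles rescale bodies and flip minus-strand genes", {
  const <- make_track("chr1", seq(0, 199000, 1000), seq(1000, 200000, 1000),
                      rep(1.5, 200))
  genes <- expression_table(data.frame(
    gene_id = c("gp", "gm"), chrom = "chr1", start = c(50000, 50000),
    end = c(90000, 90000), strand = c("+", "-"), fpkm1 = 1, fpkm2 = 1,
    log2fc = 0, de = FALSE))
  gp <- genebody_profile(const, genes, flank = 10000, n_body_bins = 20,
                         chrom_sizes = c(chr1 = 2e5))
  expect_equal(gp$n_genes, 2)
  expect_true(all(abs(gp$mean - 1.5) < 1e-9))

  # an asymmetric track: the minus-strand gene mirrors its plus twin
  ramp <- make_track("chr1", seq(0, 199000, 1000), seq(1000, 200000, 1000),
                     seq_len(200))
  gr <- genebody_profile(ramp, genes, flank = 10000, n_body_bins = 20,
                         chrom_sizes = c(chr1 = 2e5))
  expect_equal(gr$matrix[2, ], rev(gr$matrix[1, ]))

  # genes shorter than one body bin are skipped and tallied
  tiny <- expression_table(data.frame(
    gene_id = "t", chrom = "chr1", start = 50000, end = 50010,
    strand = "+", fpkm1 = 1, fpkm2 = 1, log2fc = 0, de = FALSE))
  gt <- genebody_profile(ramp, rbind(genes, tiny), flank = 10000,
                         n_body_bins = 20, chrom_sizes = c(chr1 = 2e5))
  expect_equal(gt$n_skipped, 1)
})

test_that("flanking dips are detected from their geometry, not their scale", {
  # synthetic profile: baseline 2, 40%-deep dips of 20 kb centered at +/-25 kb
  pos <- seq(-49500, 49500, 1000)
  val <- rep(2, length(pos))
  dip <- (abs(pos - 25000) <= 10000) | (abs(pos + 25000) <= 10000)
  val[dip] <- 1.2
  prof <- structure(list(positions = pos, mean = val,
                         matrix = matrix(val, 1), n_features = 1,
                         n_dropped = 0, window = 50000, binsize = 1000),
                    class = "meta_profile")
  rep_ <- detect_flank_dips(prof)
  expect_true(all(rep_$detected))
  expect_lte(max(abs(abs(rep_$center_offset) - 25000)), 5000)
  expect_true(all(abs(rep_$width - 20000) <= 5000))

  # scaling the profile does not change the report
  prof10 <- prof; prof10$mean <- prof$mean * 10
  rep10 <- detect_flank_dips(prof10)
  expect_equal(rep10$detected, rep_$detected)
  expect_equal(rep10$center_offset, rep_$center_offset)

  # flat profile: no dips on either side
  flat <- prof; flat$mean <- rep(3, length(pos))
  expect_false(any(detect_flank_dips(flat)$detected))

  # central peak without flanking dips is not reported as a dip
  peaky <- prof; peaky$mean <- 2 + 3 * exp(-(pos / 4000)^2)
  expect_false(any(detect_flank_dips(peaky)$detected))
})
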