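test_that("read_bed parses, validates and sorts intervals", {
  f <- withr::local_tempfile()
  writeLines(c("chr2\t500\t900\tE2",
               "chr1\t0\t100\tE1",
               "chr1\t50\t200\tE3\t0\t-"), f)
  bed <- read_bed(f)
  expect_equal(bed$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(bed$start, c(0, 50, 500))
  expect_equal(bed$name, c("E1", "E3", "E2"))
  expect_equal(bed$strand, c("*", "-", "*"))

  writeLines("chr1\t50\t50", f)
  expect_error(read_bed(f), "start < end")
  writeLines("chr1\tfifty\t60", f)
  expect_error(read_bed(f), "line 1")
  expect_error(read_bed(file.path(tempdir(), "nope.bed")), "no such file")
})

test_that("read_bedgraph enforces track invariants", {
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t10\t2.5", f)
  tr <- read_bedgraph(f)
  expect_s3_class(tr, "signal_track")
  expect_equal(tr$value, 2.5)

  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"), f)
  expect_error(read_bedgraph(f), "overlapping")
  writeLines("chr1\t0\t10\tx", f)
  expect_error(read_bedgraph(f), "non-numeric")
  writeLines(character(0), f)
  expect_equal(nrow(read_bedgraph(f)), 0)
})

test_that("BEDPE writer normalizes anchors and round-trips", {
  loops <- data.frame(chrom = "chr1", bin1 = 51, bin2 = 11,
                      start1 = 250000, end1 = 255000,
                      start2 = 50000, end2 = 55000,
                      distance = 200000, observed = 12, expected = 3.5,
                      p = 0.001, q = 0.004, class = "gained")
  f <- withr::local_tempfile()
  write_bedpe(loops, f)
  row <- strsplit(readLines(f)[2], "\t")[[1]]
  expect_equal(row[1:6],
               c("chr1", "50000", "55000", "chr1", "250000", "255000"))
  back <- read_bedpe(f, resolution = 5000)
  expect_equal(back$start1, 50000)
  expect_equal(back$bin1, 11)
  expect_equal(back$class, "gained")
  expect_equal(back$p, 0.001)

  write_bedpe(loops[0, ], f)
  expect_equal(nrow(read_bedpe(f)), 0)
})

test_that("interval overlap follows half-open 1-bp semantics", {
  iv <- function(chrom, s, e) data.frame(chrom = chrom, start = s, end = e)
  expect_true(interval_overlap(iv("chr1", 0, 5), iv("chr1", 4, 10)))
  expect_false(interval_overlap(iv("chr1", 0, 5), iv("chr1", 5, 10)))
  expect_false(interval_overlap(iv("chr1", 0, 5), iv("chr2", 0, 5)))
})

test_that("bin index and interval are inverse maps over random positions", {
  bt <- bin_table(c(chrA = 95000, chrB = 40000), 10000)
  expect_equal(bt$n_bins[["chrA"]], 10)
  # last bin short
  expect_equal(bt$bins$end[bt$bins$chrom == "chrA"][10], 95000)
  set.seed(42)
  pos <- sort(sample(0:94999, 200))
  idx <- bin_index(bt, "chrA", pos)
  expect_equal(idx, pos %/% 10000 + 1)
  iv <- bin_interval(bt, "chrA", idx)
  expect_true(all(pos >= iv$start & pos < iv$end))
  expect_error(bin_index(bt, "chrA", 95000), "out of range")
  expect_error(bin_index(bt, "chrC", 0), "unknown chromosome")
})

test_that("bin_pairs conserves the pair count", {
  bt <- bin_table(c(chr1 = 5000), 500)
  m <- bin_pairs(data.frame(p1 = 100, p2 = 600), bt, "chr1")
  expect_equal(m$counts[1, 2], 1)
  expect_equal(m$counts[2, 1], 1)

  m2 <- bin_pairs(cbind(rep(10, 10), rep(400, 10)), bt, "chr1")
  expect_equal(m2$counts[1, 1], 10)
  expect_equal(matrix_mass(m2), 10)

  # brute-force tally oracle on random pairs
  set.seed(7)
  pr <- cbind(sample(0:4999, 1000, replace = TRUE),
              sample(0:4999, 1000, replace = TRUE))
  m3 <- bin_pairs(pr, bt, "chr1")
  expect_equal(matrix_mass(m3), 1000)
  tal <- matrix(0, 10, 10)
  for (k in 1:1000) {
    i <- pr[k, 1] %/% 500 + 1; j <- pr[k, 2] %/% 500 + 1
    tal[min(i, j), max(i, j)] <- tal[min(i, j), max(i, j)] + 1
  }
  expect_equal(m3$counts[upper.tri(m3$counts, diag = TRUE)],
               tal[upper.tri(tal, diag = TRUE)])
})

test_that("expression tables validate and locate the TSS strand-aware", {
  df <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                   start = c(100, 500), end = c(300, 900),
                   strand = c("+", "-"), fpkm1 = c(1, 2), fpkm2 = c(2, 1),
                   log2fc = c(1, -1), de = c(TRUE, FALSE))
  expr <- expression_table(df)
  expect_equal(expr$tss, c(100, 899))
  f <- withr::local_tempfile()
  write_expression(expr, f)
  expect_equal(read_expression(f)$tss, expr$tss)
  df$fpkm1[1] <- -1
  expect_error(expression_table(df), "nonnegative")
  df$fpkm1[1] <- 1
  df$log2fc[1] <- Inf
  expect_error(expression_table(df), "finite")
})
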