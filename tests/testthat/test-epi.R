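mk_loops <- function(b1, b2, class, res = 5000, chrom = "chr1") {
  df <- data.frame(chrom = chrom, bin1 = b1, bin2 = b2,
                   start1 = (b1 - 1) * res, end1 = b1 * res,
                   start2 = (b2 - 1) * res, end2 = b2 * res,
                   distance = (b2 - b1) * res, observed = 10, expected = 2,
                   p = 0.001, p_ring = 0.001, q = 0.004, class = class,
                   stringsAsFactors = FALSE)
  class(df) <- c("loop_set", "data.frame")
  df
}

test_that("the 1-bp overlap rule defines EPI calls", {
  # anchor1 [10000,15000), anchor2 [500000,505000)
  loops <- mk_loops(3, 101, "gained")
  tss <- data.frame(chrom = "chr1", start = 12000, end = 12001, name = "G")
  enh <- data.frame(chrom = "chr1", start = 502000, end = 502500,
                    name = "e1")
  calls <- identify_epis(loops, tss, enh)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$gene_id, "G")
  expect_equal(calls$promoter_anchor, 1L)
  expect_false(calls$ambiguous)

  # a TSS exactly at the half-open anchor end does not overlap
  tss_out <- data.frame(chrom = "chr1", start = 15000, end = 15001,
                        name = "G")
  expect_equal(nrow(identify_epis(loops, tss_out, enh)), 0)

  # both anchors carrying both feature types yield both role assignments
  tss2 <- data.frame(chrom = "chr1", start = c(12000, 502200),
                     end = c(12001, 502201), name = c("G1", "G2"))
  enh2 <- data.frame(chrom = "chr1", start = c(11000, 503000),
                     end = c(11500, 503400), name = c("eA", "eB"))
  both <- identify_epis(loops, tss2, enh2)
  expect_equal(nrow(both), 2)
  expect_setequal(both$promoter_anchor, c(1L, 2L))
  expect_true(all(both$ambiguous))

  expect_warning(out <- identify_epis(loops, tss[0, ], enh), "empty")
  expect_equal(nrow(out), 0)
})

test_that("adding enhancers never removes EPI calls", {
  set.seed(31)
  loops <- mk_loops(c(3, 40, 90), c(101, 140, 260),
                    c("gained", "lost", "stable"))
  tss <- data.frame(chrom = "chr1",
                    start = c(12000, 198000, 447000),
                    end = c(12001, 198001, 447001),
                    name = c("g1", "g2", "g3"))
  enh_small <- data.frame(chrom = "chr1", start = 502000, end = 502400,
                          name = "e1")
  enh_big <- rbind(enh_small,
                   data.frame(chrom = "chr1", start = c(696000, 1296000),
                              end = c(696500, 1296500), name = c("e2", "e3")))
  small <- identify_epis(loops, tss, enh_small)
  big <- identify_epis(loops, tss, enh_big)
  key <- function(df) paste(df$gene_id, df$start1, df$start2,
                            df$promoter_anchor)
  expect_true(all(key(small) %in% key(big)))
})

test_that("differential EPIs deduplicate genes and respect the DE flag", {
  loops <- mk_loops(c(3, 30, 60, 120), c(101, 130, 160, 220),
                    c("gained", "gained", "gained", "lost"))
  # three gained EPIs pointing at two distinct genes
  tss <- data.frame(chrom = "chr1",
                    start = c(12000, 148000, 298000, 598000),
                    end = c(12001, 148001, 298001, 598001),
                    name = c("gA", "gA", "gB", "gC"))
  enh <- data.frame(chrom = "chr1",
                    start = c(502000, 648000, 798000, 1098000),
                    end = c(502400, 648400, 798400, 1098400),
                    name = paste0("e", 1:4))
  epis <- identify_epis(loops, tss, enh)
  expr <- expression_table(data.frame(
    gene_id = c("gA", "gB", "gC"), chrom = "chr1",
    start = c(12000, 298000, 598000), end = c(40000, 330000, 630000),
    strand = "+", fpkm1 = 1, fpkm2 = 2, log2fc = c(1, 2, -1),
    de = c(TRUE, TRUE, TRUE)))
  d <- differential_epis(epis, expr)
  expect_equal(d$n_gained_epis, 3)
  expect_equal(sort(d$gained_degs), c("gA", "gB"))
  expect_equal(d$n_gained_degs, 2)
  expect_equal(d$lost_degs, "gC")
  expect_lte(d$n_gained_degs, d$n_gained_epis)

  none <- differential_epis(epis[0, ], expr)
  expect_equal(none$n_gained_epis + none$n_lost_epis, 0)
})

test_that("EPI expression stats separate planted effects", {
  set.seed(17)
  expr <- expression_table(data.frame(
    gene_id = sprintf("g%02d", 1:70), chrom = "chr1",
    start = seq(1e4, by = 5e4, length.out = 70),
    end = seq(1e4, by = 5e4, length.out = 70) + 2e4,
    strand = "+", fpkm1 = 5, fpkm2 = 5,
    log2fc = c(rnorm(40, 1, 0.4), rnorm(30, -1, 0.4)), de = TRUE))
  st <- epi_expression_stats(expr$gene_id[1:40], expr$gene_id[41:70], expr)
  expect_gt(st$mean_log2fc[st$side == "gained"], 0)
  expect_lt(st$mean_log2fc[st$side == "lost"], 0)
  expect_lt(attr(st, "p"), 1e-6)

  # degenerate single-gene sides report means with p = NA
  st1 <- epi_expression_stats(expr$gene_id[1], expr$gene_id[41], expr)
  expect_true(is.na(attr(st1, "p")))
  expect_equal(st1$n, c(1, 1))
})
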