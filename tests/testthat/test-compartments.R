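# small plaid matrix built from a planted +/-1 block vector
plaid_matrix <- function(e, depth = 200, strength = 0.4, seed = 1,
                         res = 100000) {
  set.seed(seed)
  n <- length(e)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- depth * (D + 1)^-0.7 * (1 + strength * outer(e, e))
  M <- matrix(0, n, n)
  ut <- upper.tri(E, diag = TRUE)
  M[ut] <- rpois(sum(ut), E[ut])
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  contact_matrix(M, "chrP", res)
}

plaid_reference <- function(e, res = 100000) {
  n <- length(e)
  make_track("chrP", (seq_len(n) - 1) * res, seq_len(n) * res,
             ifelse(e > 0, 2, 0.5))
}

test_that("PC1 recovers planted plaid compartments and matches eigen oracle", {
  e <- rep(c(1, -1, 1, -1, 1, -1), each = 10)
  m <- plaid_matrix(e)
  tr <- compartment_pc1(m, plaid_reference(e))
  agree <- mean(tr$label == ifelse(e > 0, "A", "B"), na.rm = TRUE)
  expect_gte(agree, 0.95)

  # independent oracle: leading eigenvector of the O/E correlation matrix
  OE <- oe_matrix(m)
  C <- cor(OE)
  ev <- eigen(C, symmetric = TRUE)$vectors[, 1]
  if (cor(ev, tr$pc1) < 0) ev <- -ev
  expect_gt(abs(cor(ev, tr$pc1)), 0.999)

  # negating the planted vector flips all labels
  m2 <- plaid_matrix(-e)
  tr2 <- compartment_pc1(m2, plaid_reference(-e))
  expect_gte(mean(tr2$label == ifelse(e > 0, "B", "A"), na.rm = TRUE), 0.95)
})

test_that("PC1 is scale-invariant and rejects degenerate input", {
  e <- rep(c(1, -1, 1, -1), each = 10)
  m <- plaid_matrix(e)
  ref <- plaid_reference(e)
  tr <- compartment_pc1(m, ref)
  m5 <- contact_matrix(m$counts * 5, m$chrom, m$resolution, m$chrom_length)
  tr5 <- compartment_pc1(m5, ref)
  expect_equal(tr5$label, tr$label)

  expect_error(compartment_pc1(contact_matrix(matrix(7, 40, 40), "chrP", 1e5),
                               ref), "no compartment signal")
  expect_error(compartment_pc1(contact_matrix(matrix(7, 5, 5), "chrP", 1e5),
                               ref), "insufficient bins")
})

test_that("switch classification maps label pairs and is symmetric", {
  mk <- function(labels) {
    n <- length(labels)
    df <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1e5,
                     end = seq_len(n) * 1e5, bin = seq_len(n),
                     pc1 = ifelse(labels == "A", 1, -1), label = labels)
    class(df) <- c("compartment_track", "data.frame")
    df
  }
  t1 <- mk(c("A", "A", "B", "B"))
  t2 <- mk(c("A", "B", "A", "B"))
  sw <- classify_switches(t1, t2)
  expect_equal(sw$bins$category, c("A->A", "A->B", "B->A", "B->B"))

  # identity: all stable
  swi <- classify_switches(t1, t1)
  expect_equal(sum(swi$summary$pct_non_na[swi$summary$category %in%
                                            c("A->A", "B->B")]), 100)
  expect_equal(sum(swi$summary$n[swi$summary$category %in%
                                   c("A->B", "B->A")]), 0)

  # swapping conditions swaps A->B with B->A exactly
  set.seed(9)
  l1 <- mk(sample(c("A", "B"), 100, replace = TRUE))
  l2 <- mk(sample(c("A", "B"), 100, replace = TRUE))
  s12 <- classify_switches(l1, l2)$summary
  s21 <- classify_switches(l2, l1)$summary
  expect_equal(s12$n[s12$category == "A->B"], s21$n[s21$category == "B->A"])
  expect_equal(s12$n[s12$category == "B->A"], s21$n[s21$category == "A->B"])

  # planted toy: 10 A->B and 10 B->A flips among 100 bins
  base <- rep(c("A", "B"), 50)
  flip <- base
  flip[which(base == "A")[1:10]] <- "B"
  flip[which(base == "B")[1:10]] <- "A"
  sw2 <- classify_switches(mk(base), mk(flip))$summary
  expect_equal(sw2$pct_non_na[sw2$category == "A->B"], 10)
  expect_equal(sw2$pct_non_na[sw2$category == "B->A"], 10)
})

test_that("DE genes are assigned to the switch bin containing their TSS", {
  bins <- data.frame(chrom = "chr1", start = c(0, 1e5, 2e5),
                     end = c(1e5, 2e5, 3e5), bin = 1:3,
                     label1 = c("A", "A", NA), label2 = c("A", "B", NA),
                     category = c("A->A", "A->B", NA))
  sw <- structure(list(bins = bins), class = "switch_table")
  expr <- expression_table(data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(150000, 250000, 10000), end = c(190000, 290000, 60000),
    strand = "+", fpkm1 = 1, fpkm2 = 2,
    log2fc = 1, de = c(TRUE, TRUE, FALSE)))
  res <- genes_by_switch_category(sw, expr)
  expect_equal(res$genes$gene_id, "g1")
  expect_equal(res$genes$category, "A->B")
  expect_equal(res$n_dropped, 1)  # g2 sits on a masked bin; g3 is not DE
})

test_that("expression stats separate planted switch effects", {
  set.seed(21)
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:100),
    log2fc = c(rnorm(50, 1.5, 0.5), rnorm(50, -1.5, 0.5)),
    fpkm1 = rep(10, 100),
    category = rep(c("B->A", "A->B"), each = 50))
  genes$fpkm2 <- genes$fpkm1 * 2^genes$log2fc
  st <- expression_by_category(genes)
  med <- st$per_category$median_log2fc
  names(med) <- st$per_category$category
  expect_gt(med[["B->A"]], 0)
  expect_lt(med[["A->B"]], 0)
  expect_lt(st$pairwise["B->A", "A->B"], 1e-6)

  # two identical groups: median difference zero, p not small
  g0 <- genes; g0$log2fc <- rep(rnorm(50), 2)
  st0 <- expression_by_category(g0)
  expect_equal(diff(st0$per_category$median_log2fc), 0)
  expect_gt(st0$pairwise[1, 2], 0.9)
})

test_that("the Wilcoxon rank-sum p matches exact permutation enumeration", {
  p <- wilcox.test(c(1, 2, 3), c(4, 5, 6), alternative = "less",
                   exact = TRUE)$p.value
  expect_equal(p, 0.05)
  expect_equal(p, wilcox_enum_oracle(c(1, 2, 3), c(4, 5, 6), "less"))
})
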