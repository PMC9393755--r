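#' A/B compartment assignment from PC1 of the O/E correlation matrix
#'
#' Computes the observed/expected matrix, the Pearson correlation matrix of
#' its bin profiles, and the first eigenvector of that correlation matrix.
#' The eigenvector sign is oriented with an external reference signal (ATAC
#' coverage by default): bins in the top quartile of the reference must have a
#' positive mean PC1. Bins with positive PC1 are labeled A (open/active),
#' negative PC1 B (closed/inactive); masked bins and exact zeros are NA.
#'
#' @param m a `contact_matrix` (typically 100-kb resolution, corrected).
#' @param reference a `signal_track` used for sign orientation.
#' @param min_bins minimum number of valid bins (default 10).
#' @return data frame of class `compartment_track`: `chrom`, `start`, `end`,
#'   `bin`, `pc1`, `label`; attribute `flipped` records whether the
#'   orientation rule flipped the raw eigenvector.
#' @export
compartment_pc1 <- function(m, reference, min_bins = 10) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- m$n_bins
  marg <- rowSums(m$counts)
  valid <- marg > 0
  if (!is.null(m$weights)) valid <- valid & !is.na(m$weights)
  if (sum(valid) < min_bins)
    stop("insufficient bins: need >= ", min_bins, " valid bins on ", m$chrom)
  OE <- oe_matrix(m)[valid, valid, drop = FALSE]
  if (stats::sd(as.vector(OE)) < 1e-12)
    stop("no compartment signal: matrix is constant on ", m$chrom)
  C <- suppressWarnings(stats::cor(OE))
  C[!is.finite(C)] <- 0
  ev <- eigen(C, symmetric = TRUE)
  pc1 <- ev$vectors[, 1]
  pos <- (seq_len(n) - 1) * m$resolution
  bins <- data.frame(chrom = m$chrom, start = pos,
                     end = pmin(pos + m$resolution, m$chrom_length),
                     bin = seq_len(n))
  refv <- track_means(reference, bins)
  refv_valid <- refv[valid]
  topq <- refv_valid >= stats::quantile(refv_valid, 0.75)
  flipped <- FALSE
  if (mean(pc1[topq]) < 0) {
    pc1 <- -pc1
    flipped <- TRUE
  }
  full <- rep(NA_real_, n)
  full[valid] <- pc1
  label <- ifelse(is.na(full) | full == 0, NA_character_,
                  ifelse(full > 0, "A", "B"))
  out <- cbind(bins, data.frame(pc1 = full, label = label,
                                stringsAsFactors = FALSE))
  class(out) <- c("compartment_track", "data.frame")
  attr(out, "flipped") <- flipped
  out
}

#' Classify compartment switches between two conditions
#'
#' Per-bin categories from the label pair: `A->A`, `B->B` (stable), `A->B`
#' (open in condition 1, closed in condition 2), `B->A` (the reverse); NA if
#' either label is NA. Genome fractions per category are reported both over
#' non-NA bins (summing to 100%) and over all bins.
#'
#' @param t1,t2 `compartment_track` objects on identical bins (condition 1
#'   and condition 2); each may span several chromosomes when row-bound.
#' @return list of class `switch_table` with `bins` (per-bin data frame with
#'   `category`) and `summary` (per-category n, percent of non-NA bins,
#'   percent of all bins).
#' @export
classify_switches <- function(t1, t2) {
  if (nrow(t1) != nrow(t2) || any(t1$chrom != t2$chrom) ||
      any(t1$start != t2$start))
    stop("compartment tracks are not on the same bins")
  cat_ <- ifelse(is.na(t1$label) | is.na(t2$label), NA_character_,
                 paste0(t1$label, "->", t2$label))
  bins <- data.frame(chrom = t1$chrom, start = t1$start, end = t1$end,
                     bin = t1$bin, label1 = t1$label, label2 = t2$label,
                     category = cat_, stringsAsFactors = FALSE)
  lev <- c("A->A", "B->B", "A->B", "B->A")
  n <- vapply(lev, function(l) sum(!is.na(cat_) & cat_ == l), numeric(1))
  summary <- data.frame(category = lev, n = n,
                        pct_non_na = 100 * n / max(1, sum(!is.na(cat_))),
                        pct_all = 100 * n / nrow(bins))
  structure(list(bins = bins, summary = summary), class = "switch_table")
}

#' Assign DE genes to compartment-switch categories
#'
#' Each DE-flagged gene is assigned the category of the bin containing its
#' TSS (strand-aware 1-bp position). Genes on NA (masked) bins are dropped
#' and tallied.
#'
#' @param switches a `switch_table`.
#' @param expr expression table (see [expression_table()]).
#' @return list with `genes` (DE genes with `category` column) and
#'   `n_dropped` (DE genes on NA bins or outside the binned genome).
#' @export
genes_by_switch_category <- function(switches, expr) {
  bins <- switches$bins
  de <- expr[expr$de, , drop = FALSE]
  tssq <- data.frame(chrom = de$chrom, start = de$tss, end = de$tss + 1)
  hits <- overlap_pairs(tssq, bins)
  category <- rep(NA_character_, nrow(de))
  category[hits$qi] <- bins$category[hits$si]
  keep <- !is.na(category)
  genes <- de[keep, , drop = FALSE]
  genes$category <- category[keep]
  list(genes = genes, n_dropped = sum(!keep))
}

#' Expression statistics by switch category
#'
#' Per category: n, median and mean log2 fold change, median per-condition
#' expression (log2(FPKM+1)); pairwise two-sided Wilcoxon rank-sum p-values on
#' log2FC between categories, and within each category a two-sided Wilcoxon
#' p comparing log2(FPKM+1) between the two conditions. Categories with fewer
#' than 3 genes get NA p-values with a warning.
#'
#' @param genes data frame from [genes_by_switch_category()] (`$genes`).
#' @return list with `per_category` data frame and `pairwise` p-value matrix.
#' @export
expression_by_category <- function(genes) {
  cats <- unique(genes$category)
  if (length(cats) < 2) warning("fewer than 2 non-empty categories")
  per <- do.call(rbind, lapply(cats, function(cc) {
    g <- genes[genes$category == cc, ]
    small <- nrow(g) < 3
    if (small) warning("category ", cc, " has n < 3; p-values set to NA")
    p_cond <- if (small) NA_real_ else
      stats::wilcox.test(log2(g$fpkm1 + 1), log2(g$fpkm2 + 1))$p.value
    data.frame(category = cc, n = nrow(g),
               median_log2fc = stats::median(g$log2fc),
               mean_log2fc = mean(g$log2fc),
               median_log2_fpkm1 = stats::median(log2(g$fpkm1 + 1)),
               median_log2_fpkm2 = stats::median(log2(g$fpkm2 + 1)),
               p_between_conditions = p_cond,
               stringsAsFactors = FALSE)
  }))
  pw <- matrix(NA_real_, length(cats), length(cats),
               dimnames = list(cats, cats))
  for (i in seq_along(cats)) for (j in seq_along(cats)) {
    if (i >= j) next
    x <- genes$log2fc[genes$category == cats[i]]
    y <- genes$log2fc[genes$category == cats[j]]
    if (length(x) >= 3 && length(y) >= 3)
      pw[i, j] <- pw[j, i] <- stats::wilcox.test(x, y)$p.value
  }
  list(per_category = per, pairwise = pw)
}
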