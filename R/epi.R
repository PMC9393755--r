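#' Identify enhancer-promoter interactions from loops
#'
#' An EPI is a loop with one anchor overlapping a gene TSS and the other
#' anchor overlapping at least one enhancer, each by a minimum of 1 bp
#' (half-open coordinates). Both role assignments are tested; a loop whose
#' both anchors carry both feature types yields one call per valid
#' assignment per gene, flagged ambiguous. A single anchor never plays both
#' roles.
#'
#' @param loops a `loop_set` (anchors as genomic intervals at loop
#'   resolution).
#' @param tss data frame of 1-bp TSS intervals with columns `chrom`, `start`,
#'   `end`, `name` (gene id), e.g. from [read_bed()].
#' @param enhancers data frame of enhancer intervals (`chrom`, `start`,
#'   `end`, optionally `name`).
#' @return data frame of class `epi_set`: one row per (loop, role
#'   orientation, gene): loop coordinates and class, `gene_id`,
#'   `promoter_anchor` (1 or 2), `enhancer_ids`, `ambiguous`.
#' @export
identify_epis <- function(loops, tss, enhancers) {
  if (!nrow(tss) || !nrow(enhancers)) {
    warning("empty TSS or enhancer annotation: no EPI calls")
    return(empty_epi_set())
  }
  validate_intervals(tss, "TSS"); validate_intervals(enhancers, "enhancer")
  if (!nrow(loops)) return(empty_epi_set())
  a1 <- data.frame(chrom = loops$chrom, start = loops$start1,
                   end = loops$end1)
  a2 <- data.frame(chrom = loops$chrom, start = loops$start2,
                   end = loops$end2)
  t1 <- overlap_pairs(a1, tss); t2 <- overlap_pairs(a2, tss)
  e1 <- overlap_pairs(a1, enhancers); e2 <- overlap_pairs(a2, enhancers)
  enh_name <- if ("name" %in% names(enhancers)) enhancers$name else
    paste0("enh", seq_len(nrow(enhancers)))
  enh_by_loop <- function(hits) {
    sp <- split(enh_name[hits$si], hits$qi)
    out <- character(nrow(loops))
    out[as.integer(names(sp))] <- vapply(sp, paste, "", collapse = ",")
    out
  }
  enh1 <- enh_by_loop(e1); enh2 <- enh_by_loop(e2)
  has_tss <- function(hits) {
    out <- logical(nrow(loops)); out[unique(hits$qi)] <- TRUE; out
  }
  ht1 <- has_tss(t1); ht2 <- has_tss(t2)
  ambiguous <- (ht1 & nzchar(enh1)) & (ht2 & nzchar(enh2))
  rows <- list()
  add_calls <- function(tss_hits, prom_anchor, enh_other) {
    for (r in seq_len(nrow(tss_hits))) {
      li <- tss_hits$qi[r]
      if (!nzchar(enh_other[li])) next
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = loops$chrom[li],
        start1 = loops$start1[li], end1 = loops$end1[li],
        start2 = loops$start2[li], end2 = loops$end2[li],
        distance = loops$distance[li], class = loops$class[li],
        gene_id = tss$name[tss_hits$si[r]],
        promoter_anchor = prom_anchor,
        enhancer_ids = enh_other[li],
        ambiguous = ambiguous[li],
        stringsAsFactors = FALSE)
    }
  }
  add_calls(t1, 1L, enh2)
  add_calls(t2, 2L, enh1)
  if (!length(rows)) return(empty_epi_set())
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start1, out$start2, out$promoter_anchor,
                   out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("epi_set", "data.frame")
  out
}

empty_epi_set <- function() {
  out <- data.frame(chrom = character(), start1 = numeric(), end1 = numeric(),
                    start2 = numeric(), end2 = numeric(), distance = numeric(),
                    class = character(), gene_id = character(),
                    promoter_anchor = integer(), enhancer_ids = character(),
                    ambiguous = logical(), stringsAsFactors = FALSE)
  class(out) <- c("epi_set", "data.frame")
  out
}

#' Split EPIs into gained and lost sets with unique DEG tallies
#'
#' Partitions EPI calls by the class of their underlying loop and reports the
#' unique DE-flagged genes on each side (a gene linked by several EPIs is
#' counted once).
#'
#' @param epis an `epi_set` whose loops carry classes.
#' @param expr expression table used for the DE flag; if NULL all genes count.
#' @return list with `gained`, `lost` (`epi_set` subsets), `gained_degs`,
#'   `lost_degs` (character vectors of unique DE gene ids) and tallies.
#' @export
differential_epis <- function(epis, expr = NULL) {
  gained <- epis[!is.na(epis$class) & epis$class == "gained", , drop = FALSE]
  lost <- epis[!is.na(epis$class) & epis$class == "lost", , drop = FALSE]
  de_genes <- if (is.null(expr)) NULL else expr$gene_id[expr$de]
  uniq_de <- function(g) {
    u <- unique(g)
    if (is.null(de_genes)) u else intersect(u, de_genes)
  }
  gd <- uniq_de(gained$gene_id); ld <- uniq_de(lost$gene_id)
  list(gained = gained, lost = lost,
       gained_degs = gd, lost_degs = ld,
       n_gained_epis = nrow(gained), n_lost_epis = nrow(lost),
       n_gained_degs = length(gd), n_lost_degs = length(ld))
}

#' Expression statistics for gained vs lost EPI genes
#'
#' Mean and median log2 fold change per side and a two-sided Wilcoxon
#' rank-sum p-value between sides. Sides with fewer than 2 genes report
#' p = NA.
#'
#' @param gained_degs,lost_degs character vectors of gene ids.
#' @param expr expression table.
#' @return data frame with one row per side plus the between-side p-value as
#'   attribute `p` and in the `p_between` column.
#' @export
epi_expression_stats <- function(gained_degs, lost_degs, expr) {
  fc <- function(ids) expr$log2fc[match(ids, expr$gene_id)]
  g <- fc(gained_degs); l <- fc(lost_degs)
  g <- g[!is.na(g)]; l <- l[!is.na(l)]
  p <- if (length(g) >= 2 && length(l) >= 2)
    suppressWarnings(stats::wilcox.test(g, l)$p.value) else NA_real_
  out <- data.frame(
    side = c("gained", "lost"),
    n = c(length(g), length(l)),
    mean_log2fc = c(if (length(g)) mean(g) else NA_real_,
                    if (length(l)) mean(l) else NA_real_),
    median_log2fc = c(if (length(g)) stats::median(g) else NA_real_,
                      if (length(l)) stats::median(l) else NA_real_),
    n_up = c(sum(g > 0), sum(l > 0)),
    n_down = c(sum(g < 0), sum(l < 0)),
    p_between = p)
  attr(out, "p") <- p
  out
}
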