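#' Do two genomic intervals overlap?
#'
#' Overlap requires the same chromosome and an intersection of at least 1 bp
#' under 0-based half-open semantics; abutting intervals do not overlap.
#'
#' @param a,b single-row data frames (or lists) with `chrom`, `start`, `end`.
#' @return `TRUE` or `FALSE`.
#' @export
interval_overlap <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  max(a$start[1], b$start[1]) < min(a$end[1], b$end[1])
}

## Vectorised overlap join between two interval data frames.
## Returns data frame with columns `qi`, `si` (row indices into a and b)
## and `width` of the intersection. Half-open coordinates throughout.
overlap_pairs <- function(a, b) {
  validate_intervals(a, "query"); validate_intervals(b, "subject")
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    # IRanges is closed [start, end]; shift half-open ends down by 1
    qr <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    sr <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    hits <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
    if (length(hits) == 0L) next
    qi <- ia[S4Vectors::queryHits(hits)]
    si <- ib[S4Vectors::subjectHits(hits)]
    w <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
    out[[ch]] <- data.frame(qi = qi, si = si, width = w)
  }
  if (!length(out)) return(data.frame(qi = integer(), si = integer(),
                                      width = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Mean of a piecewise-constant signal track over query intervals.
## Uncovered basepairs contribute value 0 (coverage-track convention).
track_means <- function(track, query) {
  hits <- overlap_pairs(query, track)
  num <- rep(0, nrow(query))
  if (nrow(hits)) {
    contrib <- hits$width * track$value[hits$si]
    agg <- rowsum(contrib, group = hits$qi)
    num[as.integer(rownames(agg))] <- agg[, 1]
  }
  num / (query$end - query$start)
}
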