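#' Genome bin table
#'
#' Partition a genome into fixed-width bins per chromosome. Bins tile each
#' chromosome without gaps or overlaps; the last bin of a chromosome may be
#' shorter than `bin_width`. All coordinates in the package are 0-based,
#' half-open (BED semantics).
#'
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param bin_width bin width in bp (> 0).
#'
#' @return An object of class `bin_table`: a list with `chrom_sizes`,
#'   `bin_width`, `n_bins` (named per chromosome) and a data frame `bins`
#'   with columns `chrom`, `start`, `end`, `bin` (1-based index within the
#'   chromosome).
#' @export
bin_table <- function(chrom_sizes, bin_width) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (length(bin_width) != 1L || !is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be a single positive number")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  chrom_sizes <- round(chrom_sizes)
  bin_width <- as.integer(round(bin_width))
  n_bins <- vapply(chrom_sizes, function(L) as.integer(ceiling(L / bin_width)),
                   integer(1))
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n <- n_bins[[ch]]
    start <- (seq_len(n) - 1L) * bin_width
    end <- pmin(start + bin_width, chrom_sizes[[ch]])
    data.frame(chrom = ch, start = start, end = end, bin = seq_len(n),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  structure(list(chrom_sizes = chrom_sizes, bin_width = bin_width,
                 n_bins = n_bins, bins = bins),
            class = "bin_table")
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("<bin_table> %d chromosome(s), bin width %d bp, %d bins total\n",
              length(x$chrom_sizes), x$bin_width, sum(x$n_bins)))
  invisible(x)
}

#' Bin index of genomic positions
#'
#' Maps 0-based positions to 1-based bin indices within a chromosome:
#' `floor(pos / bin_width) + 1`.
#'
#' @param bt a [bin_table].
#' @param chrom chromosome name.
#' @param pos 0-based positions.
#' @return integer bin indices (1-based).
#' @export
bin_index <- function(bt, chrom, pos) {
  stopifnot(inherits(bt, "bin_table"))
  if (!chrom %in% names(bt$chrom_sizes)) stop("unknown chromosome: ", chrom)
  L <- bt$chrom_sizes[[chrom]]
  if (any(pos < 0 | pos >= L))
    stop(sprintf("position out of range [0,%d) on %s: %s", L, chrom,
                 paste(utils::head(pos[pos < 0 | pos >= L], 3), collapse = ", ")))
  as.integer(pos %/% bt$bin_width) + 1L
}

#' Genomic interval of a bin
#'
#' Inverse of [bin_index()]: returns the half-open interval covered by a bin.
#'
#' @inheritParams bin_index
#' @param bin 1-based bin indices.
#' @return data frame with `chrom`, `start`, `end`.
#' @export
bin_interval <- function(bt, chrom, bin) {
  stopifnot(inherits(bt, "bin_table"))
  n <- bt$n_bins[[chrom]]
  if (any(bin < 1L | bin > n)) stop("bin index out of range on ", chrom)
  start <- (as.integer(bin) - 1L) * bt$bin_width
  data.frame(chrom = chrom, start = start,
             end = pmin(start + bt$bin_width, bt$chrom_sizes[[chrom]]),
             stringsAsFactors = FALSE)
}

## shared validator for interval data frames
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, " table must have columns chrom, start, end")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(sprintf("%s violates 0 <= start < end at row %d (%s:%d-%d)",
                 what, bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  invisible(df)
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}
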