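#' Read a BED file
#'
#' Reads 3-6 column BED (tab-separated, 0-based half-open). Name and strand
#' are captured when present. Intervals are validated (`0 <= start < end`)
#' and returned sorted by (chrom, start, end).
#'
#' @param path file path.
#' @return data frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 columns")
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate")
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = start, end = end,
    name = ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4) f[4] else ".", ""), "."),
    strand = ifelse(nf >= 6L, vapply(fields, function(f) if (length(f) >= 6) f[6] else "*", ""), "*"),
    stringsAsFactors = FALSE)
  validate_intervals(df, "BED")
  res <- sort_intervals(df)
  rownames(res) <- NULL
  res
}

#' Read a bedGraph signal track
#'
#' Four-column bedGraph (chrom, start, end, value). Intervals must be
#' non-overlapping within a chromosome; the result is sorted.
#'
#' @param path file path.
#' @return data frame of class `signal_track` with `chrom`, `start`, `end`,
#'   `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    tr <- data.frame(chrom = character(), start = integer(), end = integer(),
                     value = numeric())
    class(tr) <- c("signal_track", "data.frame")
    return(tr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("malformed bedGraph line ", which(lengths(fields) < 4L)[1])
  value <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  if (anyNA(value))
    stop("malformed bedGraph line ", which(is.na(value))[1],
         ": non-numeric value column")
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = as.numeric(vapply(fields, `[`, "", 2L)),
                   end = as.numeric(vapply(fields, `[`, "", 3L)),
                   value = value, stringsAsFactors = FALSE)
  signal_track(df)
}

#' Construct/validate a signal track
#'
#' @param df data frame with `chrom`, `start`, `end`, `value`; intervals must
#'   be non-overlapping per chromosome.
#' @return the sorted track with class `signal_track`.
#' @export
signal_track <- function(df) {
  validate_intervals(df, "signal track")
  if (!"value" %in% names(df) || !is.numeric(df$value))
    stop("signal track needs a numeric value column")
  df <- sort_intervals(df)
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, ]
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping intervals in signal track on ", ch)
  }
  rownames(df) <- NULL
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Write a signal track as bedGraph
#' @param track a `signal_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("chrom", "start", "end", "value")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write loops as BEDPE
#'
#' Writes one row per loop: the six standard BEDPE columns followed by
#' `distance`, `observed`, `expected`, `p`, `q`, `class`. Anchors are
#' normalized to genome order. A commented header row is included so the file
#' round-trips through [read_bedpe()].
#'
#' @param loops a loop table as produced by [detect_loops()] /
#'   [classify_loops()].
#' @param path output path.
#' @export
write_bedpe <- function(loops, path) {
  cols <- c("chrom", "start1", "end1", "start2", "end2",
            "distance", "observed", "expected", "p", "q", "class")
  for (cc in setdiff(cols, names(loops))) loops[[cc]] <- NA
  if (nrow(loops)) {
    flip <- loops$start1 > loops$start2
    if (any(flip)) {
      tmp <- loops[flip, c("start1", "end1")]
      loops[flip, c("start1", "end1")] <- loops[flip, c("start2", "end2")]
      loops[flip, c("start2", "end2")] <- tmp
      if (all(c("bin1", "bin2") %in% names(loops))) {
        tmpb <- loops$bin1[flip]
        loops$bin1[flip] <- loops$bin2[flip]
        loops$bin2[flip] <- tmpb
      }
    }
  }
  out <- data.frame(chrom1 = loops$chrom, start1 = loops$start1,
                    end1 = loops$end1, chrom2 = loops$chrom,
                    start2 = loops$start2, end2 = loops$end2,
                    distance = loops$distance, observed = loops$observed,
                    expected = loops$expected, p = loops$p, q = loops$q,
                    class = loops$class)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(out), collapse = "\t")), con)
  if (nrow(out))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read loops from BEDPE written by [write_bedpe()]
#' @param path file path.
#' @param resolution bin width in bp used to recover bin indices.
#' @return loop table.
#' @export
read_bedpe <- function(path, resolution = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(chrom = character(), bin1 = integer(), bin2 = integer(),
                      start1 = numeric(), end1 = numeric(), start2 = numeric(),
                      end2 = numeric(), distance = numeric(),
                      observed = numeric(), expected = numeric(),
                      p = numeric(), q = numeric(), class = character())
  if (!length(body)) return(empty)
  df <- utils::read.table(text = body, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start1", "end1", "chrom2", "start2", "end2",
                 "distance", "observed", "expected", "p", "q", "class")
  df$chrom2 <- NULL
  if (!is.null(resolution)) {
    df$bin1 <- as.integer(df$start1 %/% resolution) + 1L
    df$bin2 <- as.integer(df$start2 %/% resolution) + 1L
  } else df$bin1 <- df$bin2 <- NA_integer_
  df[, names(empty)]
}

#' Read an expression table
#'
#' Tab-separated with header; required columns: `gene_id`, `chrom`, `start`,
#' `end`, `strand`, `fpkm1`, `fpkm2`, `log2fc`, `de` (logical/0-1).
#' FPKM values must be nonnegative; `log2fc` must be finite for DE genes.
#'
#' @param path file path.
#' @return validated data frame with an added `tss` column (strand-aware,
#'   0-based position of the transcription start).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  expression_table(df)
}

#' Construct/validate an expression table
#' @param df data frame, see [read_expression()].
#' @return validated expression table with `tss` column.
#' @export
expression_table <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand",
            "fpkm1", "fpkm2", "log2fc", "de")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("expression table missing columns: ",
                         paste(miss, collapse = ", "))
  validate_intervals(df, "gene")
  if (any(df$fpkm1 < 0 | df$fpkm2 < 0)) stop("FPKM must be nonnegative")
  df$de <- as.logical(df$de)
  if (any(df$de & !is.finite(df$log2fc)))
    stop("log2fc must be finite for DE-flagged genes")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  # TSS: 0-based position of the transcription start (strand-aware);
  # for '-' genes the TSS is the last base of the interval.
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  rownames(df) <- NULL
  df
}

#' Write an expression table
#' @param expr expression table.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  cols <- c("gene_id", "chrom", "start", "end", "strand",
            "fpkm1", "fpkm2", "log2fc", "de")
  utils::write.table(expr[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
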