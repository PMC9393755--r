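#' Metaprofile of a signal track around feature centers
#'
#' Samples the mean track value in `binsize` position bins spanning
#' `[-window, +window)` around the midpoint of each feature, then averages
#' across features. Features whose window is truncated by a chromosome end
#' are excluded from the mean. Uncovered basepairs count as signal 0
#' (coverage-track convention).
#'
#' @param track a `signal_track`.
#' @param centers interval data frame (`chrom`, `start`, `end`); the feature
#'   center is the interval midpoint.
#' @param window half-width in bp (must be a multiple of `binsize`).
#' @param binsize position bin width in bp.
#' @param chrom_sizes named vector of chromosome lengths used to drop
#'   truncated features; defaults to the track extent per chromosome.
#' @return list of class `meta_profile`: `positions` (offset of each position
#'   bin center from the feature center), `mean`, `matrix`
#'   (features x positions), `n_features`, `n_dropped`, `window`, `binsize`.
#' @export
metaprofile <- function(track, centers, window = 50000, binsize = 1000,
                        chrom_sizes = NULL) {
  if (!nrow(centers)) stop("empty feature set")
  validate_intervals(centers, "feature")
  if (window %% binsize != 0) stop("window must be a multiple of binsize")
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(split(track$end, track$chrom), max, numeric(1))
  }
  mid <- (centers$start + centers$end) %/% 2
  size <- chrom_sizes[centers$chrom]
  ok <- !is.na(size) & (mid - window >= 0) & (mid + window <= size)
  n_dropped <- sum(!ok)
  centers <- centers[ok, , drop = FALSE]
  mid <- mid[ok]
  if (!nrow(centers)) stop("all features truncated by chromosome ends")
  npos <- as.integer(2 * window / binsize)
  offs <- -window + (seq_len(npos) - 1) * binsize
  nf <- nrow(centers)
  q <- data.frame(chrom = rep(centers$chrom, each = npos),
                  start = rep(mid, each = npos) + rep(offs, nf),
                  end = rep(mid, each = npos) + rep(offs, nf) + binsize)
  v <- track_means(track, q)
  mat <- matrix(v, nrow = nf, ncol = npos, byrow = TRUE)
  structure(list(positions = offs + binsize / 2, mean = colMeans(mat),
                 matrix = mat, n_features = nf, n_dropped = n_dropped,
                 window = window, binsize = binsize),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> %d features, +/-%d bp in %d-bp bins\n",
              x$n_features, x$window, x$binsize))
  invisible(x)
}

#' Gene-body-scaled profile of a signal track
#'
#' Each gene body is rescaled to `n_body_bins` positions; the `flank` bp
#' upstream of the TSS and downstream of the TES are sampled in
#' `flank_binsize` bins. Minus-strand genes are flipped so upstream is always
#' on the left. Genes shorter than one body bin, or with truncated flanks,
#' are skipped and tallied.
#'
#' @param track a `signal_track` (e.g. separation score as bedGraph).
#' @param genes expression table (see [expression_table()]).
#' @param flank flank size in bp (default 10000).
#' @param n_body_bins number of body positions (default 50).
#' @param flank_binsize flank sampling bin in bp (default 1000).
#' @param chrom_sizes named vector of chromosome lengths (defaults to track
#'   extent).
#' @return list of class `genebody_profile`: `mean`, `matrix`, `axis`
#'   (labels: negative bp = upstream flank, 0..1 = scaled body, positive bp =
#'   downstream flank), `n_genes`, `n_skipped`.
#' @export
genebody_profile <- function(track, genes, flank = 10000, n_body_bins = 50,
                             flank_binsize = 1000, chrom_sizes = NULL) {
  if (is.null(chrom_sizes))
    chrom_sizes <- vapply(split(track$end, track$chrom), max, numeric(1))
  nfl <- as.integer(flank / flank_binsize)
  rows <- list(); skipped <- 0L
  for (g in seq_len(nrow(genes))) {
    ch <- genes$chrom[g]
    gs <- genes$start[g]; ge <- genes$end[g]
    L <- chrom_sizes[[ch]]
    if (is.na(L) || gs - flank < 0 || ge + flank > L ||
        (ge - gs) < n_body_bins) {
      skipped <- skipped + 1L
      next
    }
    up <- data.frame(chrom = ch,
                     start = gs - flank + (seq_len(nfl) - 1) * flank_binsize,
                     end = gs - flank + seq_len(nfl) * flank_binsize)
    bodyb <- seq(gs, ge, length.out = n_body_bins + 1)
    body <- data.frame(chrom = ch, start = floor(bodyb[-length(bodyb)]),
                       end = ceiling(bodyb[-1]))
    down <- data.frame(chrom = ch,
                       start = ge + (seq_len(nfl) - 1) * flank_binsize,
                       end = ge + seq_len(nfl) * flank_binsize)
    v <- track_means(track, rbind(up, body, down))
    if (genes$strand[g] == "-") v <- rev(v)
    rows[[length(rows) + 1L]] <- v
  }
  if (!length(rows)) stop("no usable genes for gene-body profile")
  mat <- do.call(rbind, rows)
  axis <- c(-flank + (seq_len(nfl) - 0.5) * flank_binsize,
            (seq_len(n_body_bins) - 0.5) / n_body_bins,
            (seq_len(nfl) - 0.5) * flank_binsize)
  structure(list(mean = colMeans(mat), matrix = mat, axis = axis,
                 n_flank_bins = nfl, n_body_bins = n_body_bins,
                 n_genes = nrow(mat), n_skipped = skipped),
            class = "genebody_profile")
}

#' Detect condensed (dip) regions flanking a profile center
#'
#' Searches each side of a metaprofile (typically ATAC signal around TAD
#' boundaries) for the maximal contiguous run of positions whose signal falls
#' below `(1 - min_depth_frac)` times that side's baseline, the baseline
#' being the median of the outer third of the side. A dip is reported when
#' the run is at least `min_width` wide and lies within `search_window` of
#' the center. The rule is ratio-based, hence invariant to global scaling.
#'
#' @param profile a `meta_profile`.
#' @param search_window search half-width in bp (default 30000).
#' @param min_width minimum dip width in bp (default 10000).
#' @param min_depth_frac minimum fractional depth below baseline
#'   (default 0.25).
#' @return data frame of class `flank_dip_report` with one row per side:
#'   `side`, `detected`, `center_offset` (bp from profile center), `width`
#'   (bp), `depth` (1 - minimum/baseline), `baseline`.
#' @export
detect_flank_dips <- function(profile, search_window = 30000,
                              min_width = 10000, min_depth_frac = 0.25) {
  stopifnot(inherits(profile, "meta_profile"))
  if (profile$window < search_window)
    stop("profile window is narrower than search_window")
  pos <- profile$positions
  val <- profile$mean
  one_side <- function(side) {
    sel <- if (side == "left") pos < 0 else pos > 0
    p <- pos[sel]; v <- val[sel]
    dist <- abs(p)
    outer_third <- dist >= (2 / 3) * profile$window
    baseline <- stats::median(v[outer_third])
    thr <- (1 - min_depth_frac) * baseline
    in_search <- dist <= search_window
    below <- v < thr & in_search
    r <- rle(below)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (!length(runs) || baseline <= 0)
      return(data.frame(side = side, detected = FALSE,
                        center_offset = NA_real_, width = NA_real_,
                        depth = NA_real_, baseline = baseline))
    widths <- (ends[runs] - starts[runs] + 1L) * profile$binsize
    best <- runs[which.max(widths)]
    idx <- starts[best]:ends[best]
    width <- length(idx) * profile$binsize
    det <- width >= min_width
    data.frame(side = side, detected = det,
               center_offset = if (det) mean(p[idx]) else NA_real_,
               width = if (det) width else NA_real_,
               depth = if (det) 1 - min(v[idx]) / baseline else NA_real_,
               baseline = baseline)
  }
  out <- rbind(one_side("left"), one_side("right"))
  class(out) <- c("flank_dip_report", "data.frame")
  out
}
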