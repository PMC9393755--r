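## summed-area table with zero padding; block sums in O(1)
sat <- function(M) {
  n <- nrow(M)
  S <- matrix(0, n + 1L, n + 1L)
  S[-1, -1] <- t(apply(apply(M, 2, cumsum), 1, cumsum))
  S
}

sat_block <- function(S, r1, r2, c1, c2) {
  S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
}

#' TAD-separation (insulation) score
#'
#' For each bin `i` and each window depth `w` (in bins, derived from the bp
#' parameters as `floor(bp / resolution)` with duplicates removed), computes
#' the mean of the inter-block "diamond" submatrix between `(i-w, i]` and
#' `(i, i+w]` — i.e. the contacts crossing the boundary at the left edge of
#' bin `i`. Each window's diamond means are z-scored across the chromosome and
#' the separation score at a bin is the mean z over windows; lower scores mean
#' stronger insulation. The score is defined only where every window fits
#' inside the chromosome.
#'
#' @param m a corrected `contact_matrix`.
#' @param min_depth,max_depth,step window sweep in bp (defaults 15000, 75000,
#'   7500: the values used for 5-kb matrices; scale with resolution).
#' @return data frame of class `separation_track` with `chrom`, `start`,
#'   `end`, `bin`, `score`; attributes `diamonds` (bins x windows raw diamond
#'   means), `windows_bins`, `resolution`.
#' @export
separation_score <- function(m, min_depth = 15000, max_depth = 75000,
                             step = 7500) {
  stopifnot(inherits(m, "contact_matrix"))
  if (max_depth < min_depth) stop("max_depth must be >= min_depth")
  res <- m$resolution
  if (min_depth < 2 * res)
    stop("min_depth must be at least twice the matrix resolution")
  windows <- unique(floor(seq(min_depth, max_depth, by = step) / res))
  windows <- windows[windows >= 1]
  n <- m$n_bins
  wmax <- max(windows)
  track <- data.frame(chrom = m$chrom,
                      start = (seq_len(n) - 1) * res,
                      end = pmin(seq_len(n) * res, m$chrom_length),
                      bin = seq_len(n),
                      score = NA_real_)
  if (n < 2 * wmax + 2) {
    warning("chromosome ", m$chrom, " shorter than twice max_depth; ",
            "empty separation track")
    attr(track, "diamonds") <- matrix(NA_real_, n, length(windows))
    attr(track, "diamonds_z") <- matrix(NA_real_, n, length(windows))
    attr(track, "diamond_pixels") <- matrix(NA_real_, n, 0)
    attr(track, "windows_bins") <- windows
    attr(track, "resolution") <- res
    class(track) <- c("separation_track", "data.frame")
    return(track)
  }
  ## bins masked during balancing (zero or NA weight) are excluded from the
  ## diamond means: their zeroed rows would otherwise fake insulation dips
  valid <- if (is.null(m$weights)) rowSums(m$counts) > 0 else
    !is.na(m$weights)
  cv <- cumsum(c(0, as.numeric(valid)))
  S <- sat(m$counts)
  idx <- (wmax + 1L):(n - wmax + 1L)
  D <- matrix(NA_real_, n, length(windows))
  Z <- matrix(NA_real_, n, length(windows))
  for (k in seq_along(windows)) {
    w <- windows[k]
    v <- vapply(idx, function(i) {
      nr <- cv[i] - cv[i - w]          # valid rows in (i-w, i]
      nc <- cv[i + w] - cv[i]          # valid cols in (i, i+w]
      if (nr * nc < 0.6 * w * w) return(NA_real_)
      sat_block(S, i - w, i - 1L, i, i + w - 1L) / (nr * nc)
    }, numeric(1))
    D[idx, k] <- v
    ok <- !is.na(v)
    sdv <- stats::sd(v[ok])
    Z[idx[ok], k] <- if (!is.finite(sdv) || sdv < 1e-12) 0 else
      (v[ok] - mean(v[ok])) / sdv
  }
  sc <- rowMeans(Z[idx, , drop = FALSE])
  sc[rowSums(is.na(D[idx, , drop = FALSE])) > 0] <- NA
  track$score[idx] <- sc
  ## distance-normalized pixel values of the deepest diamond per bin: the
  ## boundary test needs samples with independent noise, which the per-window
  ## means (near-perfectly correlated within a bin) cannot provide
  expected <- expected_by_distance(m)
  P <- matrix(NA_real_, n, wmax * wmax)
  for (i in idx) {
    if (is.na(track$score[i])) next
    rows <- (i - wmax):(i - 1L); cols <- i:(i + wmax - 1L)
    px <- m$counts[rows, cols]
    ex <- expected[abs(outer(rows, cols, "-")) + 1L]
    vv <- ifelse(outer(valid[rows], valid[cols], "&") & ex > 0, px / ex, NA)
    P[i, ] <- as.vector(vv)
  }
  attr(track, "diamonds") <- D
  attr(track, "diamonds_z") <- Z
  attr(track, "diamond_pixels") <- P
  attr(track, "windows_bins") <- windows
  attr(track, "resolution") <- res
  class(track) <- c("separation_track", "data.frame")
  track
}

## windowed local minima of a numeric series: bins that attain the minimum
## over a +/- window neighborhood; flat ties resolve to the leftmost bin.
## A window of 1 reduces to ordinary strict local minima.
local_minima <- function(x, window = 1L) {
  n <- length(x)
  out <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window); hi <- min(n, i + window)
    win <- x[lo:hi]
    if (i == lo && i == hi) next
    m <- min(win)
    if (x[i] > m) next
    # leftmost representative of a flat minimum
    if (any(x[lo:hi] == m & (lo:hi) < i)) next
    if (i > lo || i < hi) out <- c(out, i)
  }
  out
}

#' Call TAD boundaries from a separation track
#'
#' Candidate boundaries are local minima of the separation score. A minimum is
#' retained if (a) its score lies at least `delta` below the lesser of the two
#' flanking local maxima, and (b) a one-sided Mann-Whitney test comparing the
#' distance-normalized diamond pixel values at the minimum against those
#' pooled from the two flanking maxima gives q < `threshold_comparisons`
#' after Benjamini-Hochberg correction across candidates.
#'
#' @param track a `separation_track`.
#' @param delta minimum score depth relative to flanking maxima (default 0.01).
#' @param threshold_comparisons FDR threshold for the boundary test
#'   (default 0.01).
#' @param extrema_window half-width in bins for local-minimum detection
#'   (default 10): a candidate must attain the score minimum over this
#'   neighborhood, which suppresses noise minima on the shoulders of strong
#'   boundaries.
#' @return data frame of class `boundary_set`: `chrom`, `bin`, `start`, `end`,
#'   `score`, `depth`, `p`, `q`, sorted by position.
#' @export
call_boundaries <- function(track, delta = 0.01, threshold_comparisons = 0.01,
                            extrema_window = 10L) {
  stopifnot(inherits(track, "separation_track"))
  P <- attr(track, "diamond_pixels")
  def <- which(!is.na(track$score))
  empty <- data.frame(chrom = character(), bin = integer(), start = numeric(),
                      end = numeric(), score = numeric(), depth = numeric(),
                      p = numeric(), q = numeric())
  class(empty) <- c("boundary_set", "data.frame")
  if (length(def) < 3) return(empty)
  ## process each contiguous run of defined bins separately (masked bins may
  ## punch holes in the track)
  runs <- split(def, cumsum(c(1L, diff(def) != 1L)))
  cand <- list()
  for (run in runs) {
    if (length(run) < 3) next
    x <- track$score[run]
    mins <- local_minima(x, extrema_window)
    for (k in seq_along(mins)) {
      mi <- mins[k]
      # flanking maxima: highest score between this minimum and its neighbors
      seg_l <- if (k > 1) mins[k - 1] else 1L
      seg_r <- if (k < length(mins)) mins[k + 1] else length(x)
      if (seg_l == mi || seg_r == mi) next
      lmax <- seg_l - 1L + which.max(x[seg_l:mi])
      rmax <- mi - 1L + which.max(x[mi:seg_r])
      if (lmax == mi || rmax == mi) next
      depth <- min(x[lmax], x[rmax]) - x[mi]
      bin <- run[mi]
      pmin_ <- P[bin, ]; pmin_ <- pmin_[!is.na(pmin_)]
      pflank <- c(P[run[lmax], ], P[run[rmax], ])
      pflank <- pflank[!is.na(pflank)]
      p <- if (length(pmin_) >= 5 && length(pflank) >= 5)
        suppressWarnings(stats::wilcox.test(
          pmin_, pflank, alternative = "less", exact = FALSE)$p.value)
      else NA_real_
      cand[[length(cand) + 1L]] <- data.frame(bin = bin, score = x[mi],
                                              depth = depth, p = p)
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand <- cand[!is.na(cand$p), , drop = FALSE]
  cand <- cand[cand$depth >= delta, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand$q <- stats::p.adjust(cand$p, method = "BH")
  cand <- cand[cand$q < threshold_comparisons, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  res <- attr(track, "resolution")
  out <- data.frame(chrom = track$chrom[1], bin = cand$bin,
                    start = track$start[cand$bin], end = track$end[cand$bin],
                    score = cand$score, depth = cand$depth,
                    p = cand$p, q = cand$q)
  out <- out[order(out$bin), ]
  rownames(out) <- NULL
  class(out) <- c("boundary_set", "data.frame")
  out
}

## mean separation score around a bin (+/- window bins); widens the window
## (up to +4 bins) when the whole neighborhood is undefined (masked bins)
score_at <- function(track, chrom, bin, window = 1L) {
  s <- track[track$chrom == chrom, ]
  for (w in window:(window + 4L)) {
    lo <- max(1L, bin - w); hi <- min(nrow(s), bin + w)
    v <- mean(s$score[lo:hi], na.rm = TRUE)
    if (is.finite(v)) return(v)
  }
  NaN
}

#' Classify TAD boundaries between two conditions
#'
#' Boundaries found in both conditions (within `match_tol_bins`) are stable.
#' A boundary found only in condition 2 is gained if its condition-2
#' separation score is lower (stronger insulation) than the condition-1 score
#' at the same position; a boundary found only in condition 1 is lost if the
#' condition-2 score is higher (weaker insulation). Unmatched boundaries
#' failing their score condition are reported as unclassified. Scores are
#' averaged over +/- `avg_window` bins to damp single-bin noise.
#'
#' @param b1,b2 `boundary_set` for conditions 1 and 2 (may span chromosomes).
#' @param t1,t2 the matching `separation_track`s (row-bound across
#'   chromosomes is fine).
#' @param match_tol_bins matching tolerance in bins (default 1).
#' @param avg_window half-width in bins for score averaging (default 1).
#' @return data frame of class `boundary_classification` with one row per
#'   boundary in the union: `chrom`, `bin`, `start`, `end`, `condition`
#'   (`both`/`cond1`/`cond2`), `score1`, `score2`, `class`
#'   (`stable`/`gained`/`lost`/`unclassified`).
#' @export
classify_boundaries <- function(b1, b2, t1, t2, match_tol_bins = 1,
                                avg_window = 1) {
  if (nrow(t1) != nrow(t2) || any(t1$chrom != t2$chrom))
    stop("separation tracks are not on the same bin table")
  out <- list()
  for (ch in union(unique(b1$chrom), unique(b2$chrom))) {
    s1 <- b1[b1$chrom == ch, ]; s2 <- b2[b2$chrom == ch, ]
    used1 <- rep(FALSE, nrow(s1))
    rows <- list()
    for (i in seq_len(nrow(s2))) {
      d <- abs(s1$bin - s2$bin[i])
      d[used1] <- Inf
      j <- if (nrow(s1)) which.min(d) else integer(0)
      sc1 <- score_at(t1, ch, s2$bin[i], avg_window)
      sc2 <- score_at(t2, ch, s2$bin[i], avg_window)
      if (length(j) && is.finite(d[j]) && d[j] <= match_tol_bins) {
        used1[j] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, bin = s2$bin[i], start = s2$start[i], end = s2$end[i],
          condition = "both", score1 = sc1, score2 = sc2, class = "stable")
      } else {
        cls <- if (is.finite(sc1) && is.finite(sc2) && sc2 < sc1)
          "gained" else "unclassified"
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, bin = s2$bin[i], start = s2$start[i], end = s2$end[i],
          condition = "cond2", score1 = sc1, score2 = sc2, class = cls)
      }
    }
    for (j in which(!used1)) {
      sc1 <- score_at(t1, ch, s1$bin[j], avg_window)
      sc2 <- score_at(t2, ch, s1$bin[j], avg_window)
      cls <- if (is.finite(sc1) && is.finite(sc2) && sc2 > sc1)
        "lost" else "unclassified"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, bin = s1$bin[j], start = s1$start[j], end = s1$end[j],
        condition = "cond1", score1 = sc1, score2 = sc2, class = cls)
    }
    if (length(rows)) out[[ch]] <- do.call(rbind, rows)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), bin = integer(), start = numeric(),
               end = numeric(), condition = character(), score1 = numeric(),
               score2 = numeric(), class = character())
  res <- res[order(res$chrom, res$bin), ]
  rownames(res) <- NULL
  class(res) <- c("boundary_classification", "data.frame")
  res
}

#' TAD counts and size distributions from boundary sets
#'
#' TADs are the intervals between consecutive boundaries on a chromosome;
#' the regions before the first and after the last boundary are not counted.
#' Compares the two size distributions with a two-sided rank-sum test.
#'
#' @param b1,b2 `boundary_set` objects for the two conditions.
#' @param resolution bin width in bp.
#' @return list with `tads1`, `tads2` (data frames of TAD intervals with
#'   `size` in bp), `n1`, `n2`, `median1`, `median2`, `p` (two-sided
#'   Wilcoxon rank-sum on sizes).
#' @export
tad_size_stats <- function(b1, b2, resolution) {
  domains <- function(b) {
    out <- list()
    for (ch in unique(b$chrom)) {
      bb <- sort(b$bin[b$chrom == ch])
      if (length(bb) < 2) next
      out[[ch]] <- data.frame(chrom = ch,
                              start = (bb[-length(bb)] - 1) * resolution,
                              end = (bb[-1] - 1) * resolution)
    }
    if (!length(out))
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), size = numeric()))
    d <- do.call(rbind, out)
    d$size <- d$end - d$start
    rownames(d) <- NULL
    d
  }
  t1 <- domains(b1); t2 <- domains(b2)
  p <- if (nrow(t1) >= 2 && nrow(t2) >= 2)
    suppressWarnings(stats::wilcox.test(t1$size, t2$size)$p.value)
  else NA_real_
  list(tads1 = t1, tads2 = t2, n1 = nrow(t1), n2 = nrow(t2),
       median1 = stats::median(t1$size), median2 = stats::median(t2$size),
       p = p)
}
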