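## union-find with path compression for pixel merging
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

## 8-connected component labels for a set of (i, j) pixels
connected_components <- function(ij) {
  k <- nrow(ij)
  if (k == 0L) return(integer(0))
  parent <- seq_len(k)
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_len(k))
    assign(sprintf("%d_%d", ij[t, 1], ij[t, 2]), t, envir = keys)
  for (t in seq_len(k)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      key <- sprintf("%d_%d", ij[t, 1] + di, ij[t, 2] + dj)
      s <- keys[[key]]
      if (!is.null(s)) {
        ra <- uf_find(parent, t); rb <- uf_find(parent, s)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(k), function(t) uf_find(parent, t), integer(1))
  match(roots, unique(roots))
}

#' Detect chromatin loops
#'
#' Three-stage caller on a corrected 5-kb (or comparable) matrix:
#' (1) candidate pixels whose counts are at least `min_enrichment` times the
#' distance-decay expectation and above the `candidate_quantile` of their
#' distance stratum; (2) a right-tail negative-binomial test of the summed
#' peak-window counts against a method-of-moments fit to the distance stratum
#' (`size = mean^2/(var-mean)`), falling back to a Poisson tail when the
#' stratum variance does not exceed its mean; (3) a local-background stage:
#' the peak-window O/E mean must exceed `min_enrichment` times the O/E mean of
#' the surrounding square neighborhood ring (this suppresses TAD corners and
#' compartment blocks, which are enriched against the global distance
#' expectation but not against their own neighborhood; the enrichment is
#' required against both the full ring and its lower-left — shorter-distance,
#' within-domain — quadrant, the latter specifically rejecting domain
#' corners), and a one-sided
#' rank-sum test of the peak-window O/E values against the ring. Candidates
#' are kept when the BH-adjusted negative-binomial p and the raw rank-sum p
#' are both below `p_threshold`; adjacent significant pixels (8-connected)
#' are merged into one loop represented by the pixel with the highest 3x3
#' O/E sum.
#'
#' @param m a corrected `contact_matrix`.
#' @param max_distance maximum loop distance in bp (default 1e6).
#' @param p_threshold significance threshold (default 0.05).
#' @param peak_width peak window radius in bins (default 1: a 3x3 window).
#' @param neighborhood_width neighborhood radius in bins (default 5: an 11x11
#'   window minus the peak).
#' @param min_enrichment minimum observed/expected for candidates (default 2).
#' @param candidate_quantile per-stratum count quantile candidates must
#'   exceed (default 0.95).
#' @param min_pixels strata with fewer pixels are pooled with neighbors
#'   (default 20).
#' @return data frame of class `loop_set`: `chrom`, `bin1`, `bin2`, `start1`,
#'   `end1`, `start2`, `end2`, `distance`, `observed`, `expected`, `p`
#'   (NB, BH-adjusted in `q`), `p_ring`, `q`, `class` (NA). Attribute
#'   `n_candidates` records the candidate count; `poisson_fallback` whether
#'   any stratum used the Poisson tail.
#' @export
detect_loops <- function(m, max_distance = 1e6, p_threshold = 0.05,
                         peak_width = 1, neighborhood_width = 5,
                         min_enrichment = 2, candidate_quantile = 0.95,
                         min_pixels = 20) {
  stopifnot(inherits(m, "contact_matrix"))
  res <- m$resolution
  n <- m$n_bins
  empty <- empty_loop_set()
  if (n == 0 || all(m$counts == 0)) return(empty)
  expected <- expected_by_distance(m)
  OE <- oe_matrix(m, expected)
  dmin <- neighborhood_width + peak_width + 1L
  dmax <- min(n - 1L, as.integer(max_distance %/% res))
  if (dmax < dmin) return(empty)
  M <- m$counts
  pw <- peak_width; nw <- neighborhood_width
  npix <- (2L * pw + 1L)^2

  ## stratum stats
  strata <- vector("list", dmax - dmin + 1L)
  poisson_fallback <- FALSE
  vals_by_d <- lapply(dmin:dmax, function(d) {
    i <- seq_len(max(0L, n - d)); M[cbind(i, i + d)]
  })
  for (k in seq_along(vals_by_d)) {
    v <- vals_by_d[[k]]
    lo <- k; hi <- k
    while (length(v) < min_pixels && (lo > 1 || hi < length(vals_by_d))) {
      if (lo > 1) { lo <- lo - 1; v <- c(v, vals_by_d[[lo]]) }
      if (hi < length(vals_by_d)) { hi <- hi + 1; v <- c(v, vals_by_d[[hi]]) }
    }
    mu <- mean(v); va <- stats::var(v)
    size <- if (is.finite(va) && va > mu) mu^2 / (va - mu) else NA_real_
    if (is.na(size)) poisson_fallback <- TRUE
    strata[[k]] <- list(q = stats::quantile(vals_by_d[[k]], candidate_quantile,
                                            names = FALSE),
                        size = size)
  }
  if (poisson_fallback)
    message("detect_loops: some strata had variance <= mean; Poisson tail used")

  ## candidates
  cand <- list()
  for (k in seq_along(vals_by_d)) {
    d <- dmin + k - 1L
    v <- vals_by_d[[k]]
    i <- seq_len(n - d)
    keep <- v > strata[[k]]$q & v >= min_enrichment * expected[d + 1L] & v > 0
    keep <- keep & (i - nw >= 1L) & (i + d + nw <= n)
    if (any(keep))
      cand[[length(cand) + 1L]] <- cbind(i[keep], i[keep] + d)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  n_cand <- nrow(cand)

  p_nb <- numeric(n_cand)
  p_ring <- rep(NA_real_, n_cand)
  local_ok <- logical(n_cand)
  off <- (-nw):nw
  peak_mask <- outer(abs(off), abs(off), function(a, b) pmax(a, b)) <= pw
  ll_mask <- outer(off, off, function(a, b) a > 0 & b < 0) & !peak_mask
  for (t in seq_len(n_cand)) {
    i <- cand[t, 1]; j <- cand[t, 2]
    d <- j - i
    k <- d - dmin + 1L
    prow <- (i - pw):(i + pw); pcol <- (j - pw):(j + pw)
    obs_sum <- sum(M[prow, pcol])
    mu_sum <- sum(expected[abs(outer(prow, pcol, "-")) + 1L])
    size <- strata[[k]]$size
    p_nb[t] <- if (is.na(size))
      stats::ppois(obs_sum - 1, lambda = mu_sum, lower.tail = FALSE)
    else
      stats::pnbinom(obs_sum - 1, size = npix * size, mu = mu_sum,
                     lower.tail = FALSE)
    W <- OE[(i - nw):(i + nw), (j - nw):(j + nw)]
    x <- W[peak_mask]; y <- W[!peak_mask]
    local_ok[t] <- mean(x) >= min_enrichment * mean(y) &&
      mean(x) >= min_enrichment * mean(W[ll_mask])
    if (local_ok[t])
      p_ring[t] <- suppressWarnings(stats::wilcox.test(
        x, y, alternative = "greater", exact = FALSE)$p.value)
  }
  q_nb <- stats::p.adjust(p_nb, method = "BH")
  sig <- q_nb < p_threshold & local_ok & !is.na(p_ring) &
    p_ring < p_threshold
  if (!any(sig)) {
    attr(empty, "n_candidates") <- n_cand
    attr(empty, "poisson_fallback") <- poisson_fallback
    return(empty)
  }
  sij <- cand[sig, , drop = FALSE]
  comp <- connected_components(sij)
  # representative pixel: maximum 3x3 O/E sum (stable under count noise)
  oe_sum3 <- vapply(seq_len(nrow(sij)), function(t) {
    i <- sij[t, 1]; j <- sij[t, 2]
    sum(OE[(i - 1):(i + 1), (j - 1):(j + 1)])
  }, numeric(1))
  reps <- vapply(split(seq_len(nrow(sij)), comp), function(idx) {
    idx[which.max(oe_sum3[idx])]
  }, integer(1))
  ri <- sij[reps, 1]; rj <- sij[reps, 2]
  out <- data.frame(
    chrom = m$chrom, bin1 = ri, bin2 = rj,
    start1 = (ri - 1) * res, end1 = pmin(ri * res, m$chrom_length),
    start2 = (rj - 1) * res, end2 = pmin(rj * res, m$chrom_length),
    distance = (rj - ri) * res,
    observed = M[cbind(ri, rj)],
    expected = expected[rj - ri + 1L],
    p = p_nb[sig][reps], p_ring = p_ring[sig][reps], q = q_nb[sig][reps],
    class = NA_character_, stringsAsFactors = FALSE)
  out <- out[order(out$bin1, out$bin2), ]
  rownames(out) <- NULL
  class(out) <- c("loop_set", "data.frame")
  attr(out, "n_candidates") <- n_cand
  attr(out, "poisson_fallback") <- poisson_fallback
  out
}

empty_loop_set <- function() {
  out <- data.frame(chrom = character(), bin1 = integer(), bin2 = integer(),
                    start1 = numeric(), end1 = numeric(), start2 = numeric(),
                    end2 = numeric(), distance = numeric(),
                    observed = numeric(), expected = numeric(), p = numeric(),
                    p_ring = numeric(), q = numeric(), class = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("loop_set", "data.frame")
  attr(out, "n_candidates") <- 0L
  attr(out, "poisson_fallback") <- FALSE
  out
}

#' Significant long-range interactions by distance-stratified z-score
#'
#' For each bin pair within the distance range, computes the z-score of the
#' observed count against the per-distance mean and SD, retaining pairs with
#' `z >= z_min` and upper normal-tail p below `p_threshold`; BH-adjusted
#' q-values over all tested pairs are reported.
#'
#' @param m a corrected `contact_matrix`.
#' @param min_dist,max_dist distance range in bp (defaults 20000, 1e6:
#'   contacts of more than 20 kb and at most 1 Mb).
#' @param z_min minimum z-score (default 1).
#' @param p_threshold p-value threshold (default 0.05).
#' @return a `loop_set`-shaped data frame of interaction calls with `z`.
#' @export
significant_interactions <- function(m, min_dist = 20000, max_dist = 1e6,
                                     z_min = 1, p_threshold = 0.05) {
  stopifnot(inherits(m, "contact_matrix"))
  res <- m$resolution
  n <- m$n_bins
  M <- m$counts
  dmin <- max(1L, as.integer(min_dist %/% res) + 1L)  # strictly > min_dist
  dmax <- min(n - 1L, as.integer(max_dist %/% res))
  rows <- list()
  allp <- list()
  for (d in dmin:dmax) {
    i <- seq_len(n - d)
    v <- M[cbind(i, i + d)]
    sdv <- stats::sd(v)
    z <- if (!is.finite(sdv) || sdv < 1e-12) rep(0, length(v))
    else (v - mean(v)) / sdv
    p <- stats::pnorm(z, lower.tail = FALSE)
    allp[[length(allp) + 1L]] <- p
    keep <- z >= z_min & p < p_threshold
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        i = i[keep], j = i[keep] + d, observed = v[keep],
        expected = mean(v), z = z[keep], p = p[keep])
  }
  q_all <- stats::p.adjust(unlist(allp), method = "BH")
  # map q back to retained pairs by recomputing positions
  if (!length(rows)) {
    out <- empty_loop_set(); out$z <- numeric(0); return(out)
  }
  df <- do.call(rbind, rows)
  # q lookup: recompute index of each retained pair in the flattened p vector
  offs <- cumsum(c(0L, vapply(dmin:dmax, function(d) n - d, integer(1))))
  idx <- offs[df$j - df$i - dmin + 1L] + df$i
  df$q <- q_all[idx]
  out <- data.frame(
    chrom = m$chrom, bin1 = df$i, bin2 = df$j,
    start1 = (df$i - 1) * res, end1 = pmin(df$i * res, m$chrom_length),
    start2 = (df$j - 1) * res, end2 = pmin(df$j * res, m$chrom_length),
    distance = (df$j - df$i) * res, observed = df$observed,
    expected = df$expected, p = df$p, p_ring = NA_real_, q = df$q,
    class = NA_character_, z = df$z, stringsAsFactors = FALSE)
  out <- out[order(out$bin1, out$bin2), ]
  rownames(out) <- NULL
  class(out) <- c("loop_set", "data.frame")
  out
}

#' Classify loops between two conditions
#'
#' Loops whose two anchors both match across conditions within
#' `match_tol_bins` are stable; loops present only in condition 2 are gained;
#' only in condition 1, lost. The result is an exact disjoint partition of the
#' two input sets.
#'
#' @param l1,l2 `loop_set` objects for conditions 1 and 2.
#' @param match_tol_bins anchor matching tolerance in bins (default 0: exact
#'   bin identity).
#' @return `loop_set` of the union with `class` filled and a `condition`
#'   column (`both`/`cond1`/`cond2`).
#' @export
classify_loops <- function(l1, l2, match_tol_bins = 0) {
  rows <- list()
  for (ch in union(unique(l1$chrom), unique(l2$chrom))) {
    s1 <- l1[l1$chrom == ch, ]; s2 <- l2[l2$chrom == ch, ]
    used1 <- rep(FALSE, nrow(s1))
    for (i in seq_len(nrow(s2))) {
      j <- NA_integer_
      if (nrow(s1)) {
        d <- pmax(abs(s1$bin1 - s2$bin1[i]), abs(s1$bin2 - s2$bin2[i]))
        d[used1] <- Inf
        jj <- which.min(d)
        if (length(jj) && is.finite(d[jj]) && d[jj] <= match_tol_bins)
          j <- jj
      }
      r <- s2[i, ]
      if (!is.na(j)) {
        used1[j] <- TRUE
        r$class <- "stable"; r$condition <- "both"
      } else {
        r$class <- "gained"; r$condition <- "cond2"
      }
      rows[[length(rows) + 1L]] <- r
    }
    for (j in which(!used1)) {
      r <- s1[j, ]
      r$class <- "lost"; r$condition <- "cond1"
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows)) {
    out <- empty_loop_set(); out$condition <- character(0); return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$bin1, out$bin2), ]
  rownames(out) <- NULL
  class(out) <- c("loop_set", "data.frame")
  out
}

#' Aggregate peak analysis (APA)
#'
#' Stacks O/E-normalized `(2k+1) x (2k+1)` submatrices centered on each loop
#' and scores the aggregate as the center pixel divided by the mean of the
#' `k x k` larger-distance corner block. Loops closer than
#' `min_loop_distance_bins` to the diagonal or within `k` bins of a chromosome
#' edge are skipped and counted.
#'
#' @param m a corrected `contact_matrix`.
#' @param loops a `loop_set` at the matrix resolution (rows on `m$chrom` are
#'   used).
#' @param flank_bins corner/flank half-width `k` (default 10).
#' @param min_loop_distance_bins minimum anchor separation in bins
#'   (default `2 * flank_bins + 1`).
#' @return list of class `apa_result`: `aggregate` matrix, `score`,
#'   `n_loops`, `n_skipped`.
#' @export
apa <- function(m, loops, flank_bins = 10,
                min_loop_distance_bins = 2 * flank_bins + 1) {
  stopifnot(inherits(m, "contact_matrix"))
  k <- as.integer(flank_bins)
  loops <- loops[loops$chrom == m$chrom, , drop = FALSE]
  n <- m$n_bins
  OE <- oe_matrix(m)
  size <- 2L * k + 1L
  agg <- matrix(0, size, size)
  used <- 0L; skipped <- 0L
  for (t in seq_len(nrow(loops))) {
    i <- loops$bin1[t]; j <- loops$bin2[t]
    if (j - i < min_loop_distance_bins || i - k < 1L || j + k > n) {
      skipped <- skipped + 1L
      next
    }
    agg <- agg + OE[(i - k):(i + k), (j - k):(j + k)]
    used <- used + 1L
  }
  if (used == 0L) stop("no usable loops for APA")
  agg <- agg / used
  corner <- agg[1:k, (k + 2L):size]  # rows i-k..i-1, cols j+1..j+k
  score <- agg[k + 1L, k + 1L] / mean(corner)
  structure(list(aggregate = agg, score = score, n_loops = used,
                 n_skipped = skipped), class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("<apa_result> score %.3f over %d loops (%d skipped)\n",
              x$score, x$n_loops, x$n_skipped))
  invisible(x)
}
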