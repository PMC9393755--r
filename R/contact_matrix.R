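#' Contact matrix constructor
#'
#' A per-chromosome symmetric binned Hi-C contact matrix. Counts are stored
#' dense; the "total mass" convention is the sum of the upper triangle
#' including the diagonal (intra-bin pairs counted once).
#'
#' @param counts symmetric nonnegative numeric matrix.
#' @param chrom chromosome name.
#' @param resolution bin width in bp.
#' @param chrom_length chromosome length in bp (default `nrow * resolution`).
#' @param weights optional per-bin balancing weights (NA = masked bin).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom, resolution,
                           chrom_length = nrow(counts) * resolution,
                           weights = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (max(abs(counts - t(counts))) > 1e-8 * (1 + max(counts)))
    stop("counts must be symmetric")
  if (!is.null(weights) && length(weights) != nrow(counts))
    stop("weights length must equal n_bins")
  structure(list(chrom = chrom, resolution = resolution,
                 n_bins = nrow(counts), chrom_length = chrom_length,
                 counts = counts, weights = weights),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %d bp, total mass %.4g%s\n",
              x$chrom, x$n_bins, x$resolution, matrix_mass(x),
              if (is.null(x$weights)) "" else " (balanced)"))
  invisible(x)
}

#' Total contact mass (upper triangle including diagonal)
#' @param m a `contact_matrix`.
#' @return numeric scalar.
#' @export
matrix_mass <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  sum(m$counts[upper.tri(m$counts, diag = TRUE)])
}

#' Bin read pairs into a contact matrix
#'
#' Each pair (pos1, pos2) increments the symmetric cell of the bins containing
#' the two positions; intra-bin pairs are counted once on the diagonal, so the
#' total mass equals the number of pairs.
#'
#' @param pairs data frame or 2-column matrix of 0-based positions on one
#'   chromosome.
#' @param bt a [bin_table].
#' @param chrom chromosome name.
#' @return a `contact_matrix`.
#' @export
bin_pairs <- function(pairs, bt, chrom) {
  pairs <- as.matrix(as.data.frame(pairs)[, 1:2])
  n <- bt$n_bins[[chrom]]
  M <- matrix(0, n, n)
  if (nrow(pairs)) {
    i <- bin_index(bt, chrom, pairs[, 1])
    j <- bin_index(bt, chrom, pairs[, 2])
    lo <- pmin(i, j); hi <- pmax(i, j)
    tab <- table(factor(paste(lo, hi), levels = unique(paste(lo, hi))))
    key <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    li <- as.integer(key[, 1]); hj <- as.integer(key[, 2])
    M[cbind(li, hj)] <- as.numeric(tab)
    M[cbind(hj, li)] <- M[cbind(li, hj)]
  }
  contact_matrix(M, chrom, bt$bin_width, bt$chrom_sizes[[chrom]])
}

#' Sum two contact matrices (replicate merging)
#' @param a,b `contact_matrix` objects on identical bins.
#' @return element-wise sum as a `contact_matrix`.
#' @export
sum_matrices <- function(a, b) {
  check_same_bins(a, b)
  contact_matrix(a$counts + b$counts, a$chrom, a$resolution, a$chrom_length)
}

check_same_bins <- function(a, b) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (a$n_bins != b$n_bins || a$resolution != b$resolution ||
      a$chrom != b$chrom)
    stop("contact matrices are not on the same bin table")
  invisible(TRUE)
}

#' Scale two matrices to a common sequencing depth
#'
#' Both matrices are scaled so their total mass equals the smaller of the two
#' original masses; relative structure within each matrix is unchanged.
#'
#' @param a,b `contact_matrix` objects.
#' @return list of two scaled `contact_matrix` objects.
#' @export
normalize_to_common_depth <- function(a, b) {
  check_same_bins(a, b)
  ma <- matrix_mass(a); mb <- matrix_mass(b)
  if (ma <= 0 || mb <= 0) stop("cannot depth-normalize a zero-mass matrix")
  target <- min(ma, mb)
  a$counts <- a$counts * (target / ma)
  b$counts <- b$counts * (target / mb)
  list(a, b)
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Masks low-coverage bins (marginal equal to zero or deviating from the
#' median marginal by more than `mad_filter` median absolute deviations), then
#' iteratively divides rows and columns by their marginals until the
#' coefficient of variation of the retained marginals falls below `tol`.
#' The corrected matrix is rescaled to the original total mass; the returned
#' per-bin weights satisfy `corrected = raw * w_i * w_j` (NA on masked bins).
#'
#' @param m a `contact_matrix`.
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence tolerance on the marginal CV (default 1e-5).
#' @param mad_filter coverage filter in MAD units (default 3; `Inf` disables
#'   all but the zero-marginal filter).
#' @return a `contact_matrix` with `weights` set.
#' @export
ice_correct <- function(m, max_iter = 200, tol = 1e-5, mad_filter = 3) {
  stopifnot(inherits(m, "contact_matrix"))
  M <- m$counts
  n <- nrow(M)
  marg <- rowSums(M)
  keep <- marg > 0
  if (is.finite(mad_filter) && any(keep)) {
    # filter on log marginals: per-bin biases act multiplicatively, so the
    # linear-scale MAD would flag the legitimate heavy upper tail
    lm <- log(marg[keep])
    med <- stats::median(lm)
    md <- stats::mad(lm)
    if (md > 0)
      keep[keep] <- abs(lm - med) <= mad_filter * md
  }
  if (!any(keep)) stop("matrix too sparse: all bins masked")
  W <- M[keep, keep, drop = FALSE]
  b <- rep(1, sum(keep))
  for (it in seq_len(max_iter)) {
    s <- rowSums(W)
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv)) cv <- 0
    if (cv < tol) break
    s <- s / mean(s)
    W <- W / outer(s, s)
    b <- b * s
  }
  out <- matrix(0, n, n)
  out[keep, keep] <- W
  # rescale to original mass so corrected and raw are comparable
  sc <- matrix_mass(m) / sum(out[upper.tri(out, diag = TRUE)])
  out <- out * sc
  w <- rep(NA_real_, n)
  w[keep] <- sqrt(sc) / b
  res <- contact_matrix(out, m$chrom, m$resolution, m$chrom_length,
                        weights = w)
  res
}

#' Distance-decay expected profile
#'
#' Mean contact value at each bin separation `d = 0 .. n-1`, averaged over all
#' valid bin pairs; bins masked by balancing weights (NA) are excluded.
#'
#' @param m a `contact_matrix`.
#' @return numeric vector of length `n_bins` (index 1 = distance 0).
#' @export
expected_by_distance <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  M <- m$counts
  n <- nrow(M)
  valid <- if (is.null(m$weights)) rep(TRUE, n) else !is.na(m$weights)
  out <- numeric(n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    ok <- valid[i] & valid[i + d]
    out[d + 1L] <- if (any(ok)) mean(M[cbind(i[ok], i[ok] + d)]) else 0
  }
  out
}

#' Observed/expected matrix
#'
#' Divides each cell by the distance-decay expectation; cells with zero
#' expectation become 0.
#'
#' @param m a `contact_matrix`.
#' @param expected optional precomputed [expected_by_distance()] profile.
#' @return numeric matrix of O/E values.
#' @export
oe_matrix <- function(m, expected = expected_by_distance(m)) {
  n <- m$n_bins
  D <- abs(.row(c(n, n)) - .col(c(n, n)))
  E <- matrix(expected[D + 1L], n, n)
  OE <- m$counts / E
  OE[!is.finite(OE)] <- 0
  OE
}

#' Log2 ratio of two contact matrices
#'
#' `R[i,j] = log2((b[i,j] + pseudocount) / (a[i,j] + pseudocount))`, so that
#' positive values mark interactions gained in condition `b`. Antisymmetric
#' under swapping the inputs.
#'
#' @param a,b depth-normalized `contact_matrix` objects on the same bins.
#' @param pseudocount added to both numerator and denominator (default 1).
#' @return numeric matrix.
#' @export
log2_ratio_matrix <- function(a, b, pseudocount = 1) {
  check_same_bins(a, b)
  log2((b$counts + pseudocount) / (a$counts + pseudocount))
}

#' Coarsen a contact matrix to a lower resolution
#'
#' Sums `factor x factor` blocks of bins; used e.g. to derive the 100-kb
#' compartment matrix from the working-resolution matrix.
#'
#' @param m a `contact_matrix`.
#' @param factor integer coarsening factor.
#' @return a `contact_matrix` at `resolution * factor`.
#' @export
coarsen_matrix <- function(m, factor) {
  stopifnot(inherits(m, "contact_matrix"), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(m)
  n <- m$n_bins
  nb <- as.integer(ceiling(n / factor))
  grp <- rep(seq_len(nb), each = factor)[seq_len(n)]
  A <- rowsum(m$counts, grp)
  A <- t(rowsum(t(A), grp))
  contact_matrix(A, m$chrom, m$resolution * factor, m$chrom_length)
}

#' Write a contact matrix as sparse triplet text
#'
#' Upper-triangle nonzero cells as `chrom bin1_start bin2_start count`, with a
#' header comment carrying chromosome, resolution and length.
#'
#' @param m a `contact_matrix`.
#' @param path output path.
#' @export
write_contact_matrix <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  ut <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#chrom=%s resolution=%d length=%d", m$chrom,
                     as.integer(m$resolution), as.integer(m$chrom_length)), con)
  if (nrow(ut)) {
    df <- data.frame(chrom = m$chrom,
                     s1 = (ut[, 1] - 1L) * m$resolution,
                     s2 = (ut[, 2] - 1L) * m$resolution,
                     count = m$counts[ut])
    df <- df[order(df$s1, df$s2), ]
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a sparse triplet contact matrix written by [write_contact_matrix()]
#' @param path file path.
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hd <- lines[startsWith(lines, "#")][1]
  if (is.na(hd)) stop("missing header line in matrix file")
  get <- function(key) {
    mm <- regmatches(hd, regexec(paste0(key, "=([^ ]+)"), hd))[[1]]
    if (length(mm) < 2) stop("header missing ", key)
    mm[2]
  }
  chrom <- get("chrom")
  res <- as.integer(get("resolution"))
  len <- as.integer(get("length"))
  n <- as.integer(ceiling(len / res))
  M <- matrix(0, n, n)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body)) {
    df <- utils::read.table(text = body, sep = "\t")
    i <- as.integer(df[[2]] %/% res) + 1L
    j <- as.integer(df[[3]] %/% res) + 1L
    if (any(i < 1 | i > n | j < 1 | j > n)) stop("bin start out of range")
    M[cbind(i, j)] <- df[[4]]
    M[cbind(j, i)] <- df[[4]]
  }
  contact_matrix(M, chrom, res, len)
}
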