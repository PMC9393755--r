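# Independent oracles and shared fixtures. The heavyweight synthetic bundle
# and demo run are generated once per session and reused.

.cache <- new.env(parent = emptyenv())

acc_bundle <- function() {
  if (is.null(.cache$bundle))
    .cache$bundle <- generate_synthetic(synth_config(seed = 1))
  .cache$bundle
}

acc_demo <- function() {
  if (is.null(.cache$demo))
    .cache$demo <- run_demo(outdir = NULL, seed = 1)
  .cache$demo
}

# Sinkhorn-style balancing run to convergence, independent of ice_correct:
# alternately divide rows and columns by their sums. Returns the balanced
# matrix rescaled to total sum 1 (the balanced form is unique up to scale
# for symmetric matrices with full support).
sinkhorn_oracle <- function(M, iters = 5000, tol = 1e-12) {
  for (it in seq_len(iters)) {
    r <- rowSums(M)
    M <- M / r
    c_ <- colSums(M)
    M <- sweep(M, 2, c_, "/")
    if (max(abs(rowSums(M) - 1)) < tol && max(abs(colSums(M) - 1)) < tol)
      break
  }
  M / sum(M)
}

# Exact one-sided Mann-Whitney p-value by full enumeration of all
# choose(n1+n2, n1) group assignments of the pooled values.
wilcox_enum_oracle <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  pool <- c(x, y)
  n1 <- length(x)
  rk <- rank(pool)
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of x
  combs <- utils::combn(length(pool), n1)
  w_all <- apply(combs, 2, function(idx)
    sum(rk[idx]) - n1 * (n1 + 1) / 2)
  if (alternative == "less") mean(w_all <= w_obs) else mean(w_all >= w_obs)
}

# brute-force per-diagonal means of a matrix (oracle for expected_by_distance)
diag_means_oracle <- function(M) {
  n <- nrow(M)
  vapply(0:(n - 1), function(d)
    mean(M[cbind(seq_len(n - d), seq_len(n - d) + d)]), numeric(1))
}

# small two-block test matrix: two `half`-bin blocks of strong internal
# contact joined with weak inter-block contact
two_block_matrix <- function(half = 100, within = 10, between = 1,
                             chrom = "chrT", res = 5000) {
  n <- 2 * half
  blk <- rep(1:2, each = half)
  M <- matrix(between, n, n)
  M[outer(blk, blk, "==")] <- within
  contact_matrix(M, chrom, res)
}

# distance-decay + Poisson null matrix (no compartments, TADs or loops)
null_matrix <- function(n = 800, depth = 200, alpha = 1, seed = 1,
                        chrom = "chrN", res = 10000) {
  set.seed(seed)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- depth * (D + 1)^(-alpha)
  M <- matrix(0, n, n)
  ut <- upper.tri(E, diag = TRUE)
  M[ut] <- stats::rpois(sum(ut), E[ut])
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  contact_matrix(M, chrom, res)
}

make_track <- function(chrom, starts, ends, values) {
  signal_track(data.frame(chrom = chrom, start = starts, end = ends,
                          value = values))
}
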