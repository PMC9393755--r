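#' Configuration for the synthetic two-condition genome generator
#'
#' Defaults describe a desk-scale genome (2 chromosomes x 20 Mb at 10-kb
#' working resolution) whose planted structure mirrors the statistical
#' features the pipeline assumes: distance decay, plaid compartments aligned
#' to TAD boundaries, insulated TADs, focal loops, boundary-flanking
#' accessibility dips, and switch-correlated expression effects.
#'
#' @param seed RNG seed; the same seed yields identical bundles.
#' @param ... overrides for any default field; unknown keys are rejected.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    chrom_sizes = c(chrS1 = 20e6, chrS2 = 20e6),
    resolution = 10000,            # working Hi-C resolution (bp)
    compartment_resolution = 1e5,  # compartment analysis resolution (bp)
    decay_exponent = 1,            # contact ~ (d+1)^-alpha
    depth = 200,                   # expected contacts at distance 0
    bias_sd = 0.3,                 # log-normal per-bin bias
    poisson_noise = TRUE,          # Poisson counts (FALSE: expected values)
    plaid_strength = 0.3,          # compartment plaid amplitude
    block_tad_range = c(2L, 3L),   # compartment block size in TADs
    n_switch_per_chrom = 2L,       # switched blocks per direction
    tad_size_range = c(40L, 100L), # TAD size in bins
    split_min_size = 50L,          # minimum size of a TAD eligible for a split
    insulation_depth = 0.5,        # cross-TAD contact reduction
    n_split_per_chrom = 12L,       # gained boundaries (TAD splits)
    n_merge_per_chrom = 7L,        # lost boundaries (TAD merges);
    # split:merge ratio ~0.6 mirrors the observed gained:lost boundary ratio
    n_loop_stable = 20L,           # per chromosome
    n_loop_gain = 15L,
    n_loop_loss = 15L,
    loop_enrichment = 5,           # focal center enrichment
    loop_ring_enrichment = 3,      # +/-1-bin shoulder enrichment
    loop_distance_range = c(30L, 85L),  # bins
    n_epi_gain = 12L,              # per chromosome (subset of gained loops)
    n_epi_loss = 12L,
    epi_log2fc_mean = 1, epi_log2fc_sd = 0.4,
    n_deg_per_switch = 25L,        # per chromosome per direction
    switch_log2fc_mean = 1.5, switch_log2fc_sd = 0.5,
    n_stable_deg = 50L,            # per chromosome
    n_background_genes = 100L,     # per chromosome, non-DE
    gene_length_range = c(5000, 50000),
    atac_binsize = 1000,
    atac_base_a = 1.5, atac_base_b = 0.5,
    atac_boundary_peak = 1, atac_peak_halfwidth = 2500,
    dip_width = 20000, dip_offset = 25000, dip_depth = 0.4,
    atac_noise_sd = 0.1,
    enhancer_bonus = 0.8, tss_bonus = 0.5,
    n_decoy_enhancers = 30L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  n_bins <- floor(cfg$chrom_sizes / cfg$resolution)
  if (any(cfg$tad_size_range[2] * 2 > n_bins))
    stop("infeasible planting: TAD size exceeds chromosome size")
  if (cfg$n_epi_gain > cfg$n_loop_gain || cfg$n_epi_loss > cfg$n_loop_loss)
    stop("infeasible planting: more EPI loops than gained/lost loops")
  class(cfg) <- "synth_config"
  cfg
}

## TAD partition of one chromosome: returns boundary bins (first bin of each
## TAD after the first) and per-bin TAD ids
plant_tads <- function(n, size_range) {
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, sample(size_range[1]:size_range[2], 1))
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  if (sizes[length(sizes)] < size_range[1]) {
    sizes[length(sizes) - 1] <- sizes[length(sizes) - 1] + sizes[length(sizes)]
    sizes <- sizes[-length(sizes)]
  }
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  list(sizes = sizes, starts = starts,
       boundaries = starts[-1],
       id = rep(seq_along(sizes), sizes))
}

## expected contact matrix for one chromosome and one condition
expected_matrix <- function(n, cfg, e, tad_id, loops, bias) {
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- cfg$depth * (D + 1)^(-cfg$decay_exponent)
  E <- E * (1 + cfg$plaid_strength * outer(e, e))
  cross <- outer(tad_id, tad_id, "!=")
  E[cross] <- E[cross] * (1 - cfg$insulation_depth)
  E <- E * outer(bias, bias)
  if (nrow(loops)) {
    for (t in seq_len(nrow(loops))) {
      i <- loops$bin1[t]; j <- loops$bin2[t]
      for (di in -1:1) for (dj in -1:1) {
        f <- if (di == 0 && dj == 0) cfg$loop_enrichment else
          cfg$loop_ring_enrichment
        E[i + di, j + dj] <- E[i + di, j + dj] * f
        E[j + dj, i + di] <- E[i + di, j + dj]
      }
    }
  }
  E
}

poissonize <- function(E, noise) {
  if (!noise) return(E)
  n <- nrow(E)
  ut <- upper.tri(E, diag = TRUE)
  M <- matrix(0, n, n)
  M[ut] <- stats::rpois(sum(ut), E[ut])
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

## sample k loop pixels inside host TADs (first-fit over `hosts` with a
## per-host cap, so loops concentrate in the leading hosts and leave later
## TADs untouched). Every planted anchor bin keeps >= 4 bins away from every
## other planted anchor so that no two loops share or abut an anchor (shared
## anchors would entangle loop classification and EPI gene assignment).
## Returns pixels and host ids.
sample_loops <- function(k, hosts, tad, dist_range, taken, cap = 6L) {
  out <- matrix(NA_integer_, 0, 2)
  host_id <- integer(0)
  for (t in seq_len(k)) {
    placed <- FALSE
    for (h in hosts) {
      if (sum(host_id == h) >= cap) next
      lo <- tad$starts[h]; hi <- lo + tad$sizes[h] - 1L
      if (tad$sizes[h] < dist_range[1] + 8L) next
      for (try in 1:80) {
        d <- sample(dist_range[1]:min(dist_range[2], tad$sizes[h] - 6L), 1)
        i <- sample((lo + 2L):(hi - d - 2L), 1)
        j <- i + d
        anchors <- c(taken, out)
        if (length(anchors) &&
            (min(abs(anchors - i)) < 4 || min(abs(anchors - j)) < 4)) next
        out <- rbind(out, c(i, j))
        host_id <- c(host_id, h)
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed) stop("infeasible planting: could not place loops")
  }
  list(pixels = out, hosts = host_id)
}

#' Generate a synthetic two-condition genome bundle
#'
#' Builds Hi-C contact matrices for two conditions with planted compartment
#' switches, TAD splits/merges, loop gains/losses and EPI genes, plus matched
#' ATAC and RNA bedGraph tracks, enhancer/TSS/DAR annotations, an expression
#' table, and a `truth` record of everything planted.
#'
#' @param cfg a [synth_config()].
#' @return list of class `synth_bundle` with elements `config`, `bins`
#'   (working-resolution [bin_table]), `matrices` (per condition, per
#'   chromosome `contact_matrix`), `atac1`, `atac2`, `rna1`, `rna2`
#'   (signal tracks), `enhancers`, `tss`, `dars` (interval data frames),
#'   `expression` (expression table) and `truth`.
#' @export
generate_synthetic <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  res <- cfg$resolution
  bins <- bin_table(cfg$chrom_sizes, res)
  chroms <- names(cfg$chrom_sizes)

  matrices <- list(cond1 = list(), cond2 = list())
  truth <- list(boundaries = list(), loops = list(), switch_blocks = list(),
                compartment_bins = list(), genes = list(), epis = list(),
                bias = list())
  enhancers <- list(); genes_all <- list(); dars <- list()
  atac <- list(cond1 = list(), cond2 = list())

  for (ch in chroms) {
    n <- bins$n_bins[[ch]]
    L <- cfg$chrom_sizes[[ch]]

    ## --- TADs, condition 1 ---
    tad1 <- plant_tads(n, cfg$tad_size_range)
    nt <- length(tad1$sizes)

    ## --- compartment blocks = runs of TADs, alternating A/B ---
    block_sizes <- integer(0)
    while (sum(block_sizes) < nt)
      block_sizes <- c(block_sizes,
                       sample(cfg$block_tad_range[1]:cfg$block_tad_range[2], 1))
    block_sizes[length(block_sizes)] <-
      nt - sum(block_sizes[-length(block_sizes)])
    if (block_sizes[length(block_sizes)] < 1) {
      block_sizes <- block_sizes[-length(block_sizes)]
      block_sizes[length(block_sizes)] <-
        nt - sum(block_sizes[-length(block_sizes)])
    }
    block_of_tad <- rep(seq_along(block_sizes), block_sizes)
    first_type <- sample(c(1, -1), 1)
    block_type1 <- first_type * (-1)^(seq_along(block_sizes) - 1)
    e1 <- block_type1[block_of_tad][tad1$id]

    ## --- compartment switches: flip whole blocks in condition 2 ---
    a_blocks <- which(block_type1 > 0); b_blocks <- which(block_type1 < 0)
    flip_ab <- sample(a_blocks, min(cfg$n_switch_per_chrom, length(a_blocks)))
    flip_ba <- sample(b_blocks, min(cfg$n_switch_per_chrom, length(b_blocks)))
    block_type2 <- block_type1
    block_type2[c(flip_ab, flip_ba)] <- -block_type2[c(flip_ab, flip_ba)]
    e2 <- block_type2[block_of_tad][tad1$id]

    block_bins <- function(bl) {
      tads <- which(block_of_tad == bl)
      lo <- tad1$starts[tads[1]]
      hi <- tad1$starts[tads[length(tads)]] + tad1$sizes[tads[length(tads)]] - 1L
      c(lo, hi)
    }
    sw <- lapply(c(flip_ab, flip_ba), block_bins)
    truth$switch_blocks[[ch]] <- data.frame(
      chrom = ch,
      start = vapply(sw, function(x) (x[1] - 1) * res, numeric(1)),
      end = vapply(sw, function(x) x[2] * res, numeric(1)),
      direction = rep(c("A->B", "B->A"),
                      c(length(flip_ab), length(flip_ba))))

    ## --- loops (planted first so splits can use loop-free TADs) ---
    switch_tads <- which(block_of_tad %in% c(flip_ab, flip_ba))
    size_ok <- which(tad1$sizes >= cfg$loop_distance_range[1] + 8L)
    by_size <- size_ok[order(tad1$sizes[size_ok], decreasing = TRUE)]
    hosts_nonswitch <- by_size[!(by_size %in% switch_tads)]
    gn_s <- sample_loops(cfg$n_loop_gain, hosts_nonswitch, tad1,
                         cfg$loop_distance_range, matrix(NA_integer_, 0, 2))
    ls_s <- sample_loops(cfg$n_loop_loss, hosts_nonswitch, tad1,
                         cfg$loop_distance_range, gn_s$pixels)
    st_s <- sample_loops(cfg$n_loop_stable, by_size, tad1,
                         cfg$loop_distance_range,
                         rbind(gn_s$pixels, ls_s$pixels))
    st <- st_s$pixels; gn <- gn_s$pixels; ls <- ls_s$pixels
    loop_tads <- unique(c(st_s$hosts, gn_s$hosts, ls_s$hosts))
    loops_truth <- data.frame(
      chrom = ch,
      bin1 = c(st[, 1], gn[, 1], ls[, 1]),
      bin2 = c(st[, 2], gn[, 2], ls[, 2]),
      class = rep(c("stable", "gained", "lost"),
                  c(nrow(st), nrow(gn), nrow(ls))))

    ## --- TAD splits (gained) and merges (lost) in condition 2 ---
    splittable <- setdiff(which(tad1$sizes >= cfg$split_min_size), loop_tads)
    split_tads <- sample(splittable,
                         min(cfg$n_split_per_chrom, length(splittable)))
    gained_bins <- vapply(split_tads, function(t)
      tad1$starts[t] + tad1$sizes[t] %/% 2L, integer(1))
    same_block_pairs <- which(block_of_tad[-nt] == block_of_tad[-1])
    mergeable <- setdiff(same_block_pairs,
                         c(split_tads, split_tads - 1L))
    merge_cand <- sample(mergeable,
                         min(cfg$n_merge_per_chrom, length(mergeable)))
    # no two merges may share a TAD
    merge_left <- integer(0)
    for (mt in merge_cand)
      if (!any(abs(merge_left - mt) <= 1)) merge_left <- c(merge_left, mt)
    lost_bins <- tad1$starts[merge_left + 1L]
    b2 <- sort(c(setdiff(tad1$boundaries, lost_bins), gained_bins))
    tad2_id <- cumsum(seq_len(n) %in% c(1L, b2))
    tad2 <- list(id = tad2_id)
    truth$boundaries[[ch]] <- data.frame(
      chrom = ch,
      bin = c(setdiff(tad1$boundaries, lost_bins), gained_bins, lost_bins),
      class = rep(c("stable", "gained", "lost"),
                  c(length(setdiff(tad1$boundaries, lost_bins)),
                    length(gained_bins), length(lost_bins))))
    truth$loops[[ch]] <- loops_truth
    loops1 <- loops_truth[loops_truth$class %in% c("stable", "lost"), ]
    loops2 <- loops_truth[loops_truth$class %in% c("stable", "gained"), ]

    ## --- matrices ---
    bias1 <- exp(stats::rnorm(n, 0, cfg$bias_sd))
    bias2 <- exp(stats::rnorm(n, 0, cfg$bias_sd))
    truth$bias[[ch]] <- list(cond1 = bias1, cond2 = bias2)
    E1 <- expected_matrix(n, cfg, e1, tad1$id, loops1, bias1)
    E2 <- expected_matrix(n, cfg, e2, tad2$id, loops2, bias2)
    matrices$cond1[[ch]] <- contact_matrix(poissonize(E1, cfg$poisson_noise),
                                           ch, res, L)
    matrices$cond2[[ch]] <- contact_matrix(poissonize(E2, cfg$poisson_noise),
                                           ch, res, L)

    ## --- compartment truth at compartment resolution ---
    fac <- as.integer(cfg$compartment_resolution / res)
    nb100 <- ceiling(n / fac)
    grp <- rep(seq_len(nb100), each = fac)[seq_len(n)]
    lab <- function(e) {
      s <- as.vector(rowsum(e, grp))
      ifelse(s > 0, "A", ifelse(s < 0, "B", NA))
    }
    truth$compartment_bins[[ch]] <- data.frame(
      chrom = ch, bin = seq_len(nb100),
      start = (seq_len(nb100) - 1) * cfg$compartment_resolution,
      end = pmin(seq_len(nb100) * cfg$compartment_resolution, L),
      label1 = lab(e1), label2 = lab(e2))

    ## --- genes & expression ---
    in_switch <- function(pos) {
      blk <- truth$switch_blocks[[ch]]
      any(pos >= blk$start & pos < blk$end)
    }
    mk_genes <- function(k, region_fun, fc_mean, fc_sd, de, prefix) {
      if (k == 0) return(NULL)
      out <- vector("list", k)
      for (t in seq_len(k)) {
        repeat {
          tss <- region_fun()
          len <- round(stats::runif(1, cfg$gene_length_range[1],
                                    cfg$gene_length_range[2]))
          strand <- sample(c("+", "-"), 1)
          gs <- if (strand == "+") tss else tss - len + 1
          ge <- gs + len
          if (gs >= 0 && ge <= L) break
        }
        out[[t]] <- data.frame(
          gene_id = sprintf("%s_%s_%03d", prefix, ch, t), chrom = ch,
          start = gs, end = ge, strand = strand,
          log2fc = stats::rnorm(1, fc_mean, fc_sd), de = de,
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    blk <- truth$switch_blocks[[ch]]
    pick_in <- function(direction) {
      b <- blk[blk$direction == direction, ]
      function() {
        r <- b[sample.int(nrow(b), 1), ]
        round(stats::runif(1, r$start + 20000, r$end - 60000))
      }
    }
    pick_out <- function() {
      repeat {
        p <- round(stats::runif(1, 100000, L - 100000))
        if (!in_switch(p)) return(p)
      }
    }
    g_ab <- mk_genes(cfg$n_deg_per_switch, pick_in("A->B"),
                     -cfg$switch_log2fc_mean, cfg$switch_log2fc_sd, TRUE, "gAB")
    g_ba <- mk_genes(cfg$n_deg_per_switch, pick_in("B->A"),
                     cfg$switch_log2fc_mean, cfg$switch_log2fc_sd, TRUE, "gBA")
    g_st <- mk_genes(cfg$n_stable_deg, pick_out, 0, 0.8, TRUE, "gST")
    g_bg <- mk_genes(cfg$n_background_genes, pick_out, 0, 0.2, FALSE, "gBG")

    ## --- EPI genes at gained/lost loop anchors (outside switch blocks) ---
    anchor_pos <- function(bin) (bin - 1) * res + res %/% 2
    mk_epi <- function(loops_cls, k, fc_sign, prefix) {
      cand_rows <- which(!vapply(loops_cls$bin1, function(b)
        in_switch(anchor_pos(b)), logical(1)) &
          !vapply(loops_cls$bin2, function(b)
            in_switch(anchor_pos(b)), logical(1)))
      if (length(cand_rows) < k)
        stop("infeasible planting: not enough non-switch loops for EPIs")
      rows <- sort(cand_rows[seq_len(k)])
      gl <- vector("list", k); el <- vector("list", k)
      for (t in seq_len(k)) {
        r <- loops_cls[rows[t], ]
        tss <- anchor_pos(r$bin1)
        len <- round(stats::runif(1, cfg$gene_length_range[1],
                                  cfg$gene_length_range[2]))
        strand <- "+"
        gl[[t]] <- data.frame(
          gene_id = sprintf("%s_%s_%03d", prefix, ch, t), chrom = ch,
          start = tss, end = min(tss + len, L), strand = strand,
          log2fc = stats::rnorm(1, fc_sign * cfg$epi_log2fc_mean,
                                cfg$epi_log2fc_sd),
          de = TRUE, stringsAsFactors = FALSE)
        el[[t]] <- data.frame(
          chrom = ch, start = anchor_pos(r$bin2) - 250,
          end = anchor_pos(r$bin2) + 250,
          name = sprintf("enh_%s_%s_%03d", prefix, ch, t),
          stringsAsFactors = FALSE)
      }
      list(genes = do.call(rbind, gl), enh = do.call(rbind, el),
           loop_rows = rows)
    }
    gained_loops <- loops_truth[loops_truth$class == "gained", ]
    lost_loops <- loops_truth[loops_truth$class == "lost", ]
    epi_g <- mk_epi(gained_loops, cfg$n_epi_gain, +1, "gEPIg")
    epi_l <- mk_epi(lost_loops, cfg$n_epi_loss, -1, "gEPIl")
    truth$epis[[ch]] <- data.frame(
      chrom = ch,
      gene_id = c(epi_g$genes$gene_id, epi_l$genes$gene_id),
      bin1 = c(gained_loops$bin1[epi_g$loop_rows],
               lost_loops$bin1[epi_l$loop_rows]),
      bin2 = c(gained_loops$bin2[epi_g$loop_rows],
               lost_loops$bin2[epi_l$loop_rows]),
      class = rep(c("gained", "lost"), c(cfg$n_epi_gain, cfg$n_epi_loss)),
      stringsAsFactors = FALSE)

    genes_ch <- rbind(g_ab, g_ba, g_st, g_bg, epi_g$genes, epi_l$genes)
    genes_ch$category <- rep(
      c("A->B", "B->A", "stable", "background", "epi_gained", "epi_lost"),
      c(nrow(g_ab), nrow(g_ba), nrow(g_st), nrow(g_bg),
        nrow(epi_g$genes), nrow(epi_l$genes)))
    genes_all[[ch]] <- genes_ch

    ## decoy enhancers
    dec <- data.frame(
      chrom = ch,
      start = round(stats::runif(cfg$n_decoy_enhancers, 50000, L - 52000)),
      name = sprintf("enh_decoy_%s_%03d", ch, seq_len(cfg$n_decoy_enhancers)),
      stringsAsFactors = FALSE)
    dec$end <- dec$start + round(stats::runif(cfg$n_decoy_enhancers, 500, 2000))
    enhancers[[ch]] <- rbind(epi_g$enh, epi_l$enh,
                             dec[, c("chrom", "start", "end", "name")])

    ## --- DARs: hyper at gained boundaries, hypo at lost ---
    dars[[ch]] <- data.frame(
      chrom = ch,
      start = c(gained_bins, lost_bins) * res - res - 5000,
      end = c(gained_bins, lost_bins) * res - res + 5000,
      name = rep(c("hyper", "hypo"),
                 c(length(gained_bins), length(lost_bins))),
      stringsAsFactors = FALSE)

    ## --- ATAC and RNA tracks (per condition) ---
    bl_bins1 <- sort(tad1$boundaries)
    bl_bins2 <- sort(b2)
    atac_track <- function(e_bins, bl_bins, enh, tssdf) {
      bs <- cfg$atac_binsize
      nb <- as.integer(L / bs)
      pos <- (seq_len(nb) - 1) * bs + bs / 2
      ebin <- e_bins[pmin(floor(pos / res) + 1, n)]
      v <- ifelse(ebin > 0, cfg$atac_base_a, cfg$atac_base_b)
      bpos <- (bl_bins - 1) * res
      for (b in bpos) {
        sel <- abs(pos - b) <= cfg$atac_peak_halfwidth
        v[sel] <- v[sel] + cfg$atac_boundary_peak
      }
      for (eh in seq_len(nrow(enh))) {
        sel <- pos >= enh$start[eh] & pos < enh$end[eh] + bs
        v[sel] <- v[sel] + cfg$enhancer_bonus
      }
      sel <- rep(FALSE, nb)
      for (tpos in tssdf) {
        sel <- sel | abs(pos - tpos) <= 1000
      }
      v[sel] <- v[sel] + cfg$tss_bonus
      dip <- rep(FALSE, nb)
      for (b in bpos) {
        off <- pos - b
        dip <- dip |
          (abs(off - cfg$dip_offset) <= cfg$dip_width / 2) |
          (abs(off + cfg$dip_offset) <= cfg$dip_width / 2)
      }
      v[dip] <- v[dip] * (1 - cfg$dip_depth)
      v <- v * exp(stats::rnorm(nb, 0, cfg$atac_noise_sd))
      signal_track(data.frame(chrom = ch, start = (seq_len(nb) - 1) * bs,
                              end = seq_len(nb) * bs, value = v))
    }
    tss_pos <- ifelse(genes_ch$strand == "+", genes_ch$start,
                      genes_ch$end - 1)
    atac$cond1[[ch]] <- atac_track(e1, bl_bins1, enhancers[[ch]], tss_pos)
    atac$cond2[[ch]] <- atac_track(e2, bl_bins2, enhancers[[ch]], tss_pos)
    genes_all[[ch]]$tss_pos <- tss_pos
  }

  genes <- do.call(rbind, genes_all)
  ## expression levels: baseline log2 FPKM ~ N(3, 1.5), condition 2 shifted
  base <- 2^stats::rnorm(nrow(genes), 3, 1.5)
  genes$fpkm1 <- round(base, 4)
  genes$fpkm2 <- round(base * 2^genes$log2fc, 4)
  genes$log2fc <- round(genes$log2fc, 4)
  expr <- expression_table(genes[, c("gene_id", "chrom", "start", "end",
                                     "strand", "fpkm1", "fpkm2", "log2fc",
                                     "de")])
  expr$category <- genes$category

  ## RNA tracks: gene-body coverage proportional to FPKM
  rna_track <- function(fpkm_col) {
    out <- list()
    for (ch in chroms) {
      bs <- 2000
      L <- cfg$chrom_sizes[[ch]]
      nb <- as.integer(L / bs)
      v <- numeric(nb)
      gch <- which(expr$chrom == ch)
      for (g in gch) {
        b1 <- max(1L, expr$start[g] %/% bs + 1L)
        b2 <- min(nb, (expr$end[g] - 1) %/% bs + 1L)
        v[b1:b2] <- v[b1:b2] + expr[[fpkm_col]][g] / 10
      }
      out[[ch]] <- data.frame(chrom = ch, start = (seq_len(nb) - 1) * bs,
                              end = seq_len(nb) * bs, value = v)
    }
    signal_track(do.call(rbind, out))
  }

  truth$genes <- expr[, c("gene_id", "chrom", "category", "log2fc", "de")]
  bundle <- list(
    config = cfg, bins = bins,
    matrices = matrices,
    atac1 = signal_track(do.call(rbind, lapply(atac$cond1, as.data.frame))),
    atac2 = signal_track(do.call(rbind, lapply(atac$cond2, as.data.frame))),
    rna1 = rna_track("fpkm1"), rna2 = rna_track("fpkm2"),
    enhancers = do.call(rbind, enhancers),
    tss = data.frame(chrom = expr$chrom, start = expr$tss,
                     end = expr$tss + 1, name = expr$gene_id,
                     stringsAsFactors = FALSE),
    dars = do.call(rbind, dars),
    expression = expr,
    truth = list(
      switch_blocks = do.call(rbind, truth$switch_blocks),
      compartment_bins = do.call(rbind, truth$compartment_bins),
      boundaries = do.call(rbind, truth$boundaries),
      loops = do.call(rbind, truth$loops),
      epis = do.call(rbind, truth$epis),
      genes = truth$genes,
      bias = truth$bias))
  for (nm in c("switch_blocks", "compartment_bins", "boundaries", "loops",
               "epis")) rownames(bundle$truth[[nm]]) <- NULL
  class(bundle) <- "synth_bundle"
  bundle
}

#' Write a synthetic bundle to disk
#'
#' Emits triplet contact matrices, bedGraph tracks, BED annotations, the
#' expression TSV and truth TSVs under `dir`.
#'
#' @param bundle a `synth_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_synthetic <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(p) { paths <<- c(paths, p); p }
  for (cond in names(bundle$matrices))
    for (ch in names(bundle$matrices[[cond]]))
      write_contact_matrix(bundle$matrices[[cond]][[ch]],
                           wr(file.path(dir, sprintf("hic_%s_%s.tsv", cond, ch))))
  write_bedgraph(bundle$atac1, wr(file.path(dir, "atac_cond1.bedgraph")))
  write_bedgraph(bundle$atac2, wr(file.path(dir, "atac_cond2.bedgraph")))
  write_bedgraph(bundle$rna1, wr(file.path(dir, "rna_cond1.bedgraph")))
  write_bedgraph(bundle$rna2, wr(file.path(dir, "rna_cond2.bedgraph")))
  bed <- function(df, p) {
    utils::write.table(df, wr(p), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  bed(bundle$enhancers[, c("chrom", "start", "end", "name")],
      file.path(dir, "enhancers.bed"))
  bed(bundle$tss, file.path(dir, "tss.bed"))
  bed(bundle$dars, file.path(dir, "dars.bed"))
  write_expression(bundle$expression, wr(file.path(dir, "expression.tsv")))
  for (nm in c("switch_blocks", "boundaries", "loops", "epis", "genes",
               "compartment_bins"))
    utils::write.table(bundle$truth[[nm]],
                       wr(file.path(dir, sprintf("truth_%s.tsv", nm))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Precision/recall/F1 of called positions against planted truth
#'
#' Greedy one-to-one matching of called features to truth features within a
#' positional tolerance. For 1D features (boundaries) supply `bin` columns;
#' for 2D features (loops) supply `bin1`/`bin2`, matched under Chebyshev
#' distance.
#'
#' @param truth,called data frames with `chrom` and `bin` (or `bin1`,`bin2`).
#' @param tol tolerance in bins (default 1).
#' @return list with `precision`, `recall`, `f1`, `n_truth`, `n_called`,
#'   `n_matched` and logical vectors `truth_matched`, `called_matched`.
#' @export
feature_recovery <- function(truth, called, tol = 1) {
  two_d <- all(c("bin1", "bin2") %in% names(truth))
  tm <- rep(FALSE, nrow(truth)); cm <- rep(FALSE, nrow(called))
  for (i in seq_len(nrow(called))) {
    if (two_d) {
      d <- ifelse(truth$chrom == called$chrom[i],
                  pmax(abs(truth$bin1 - called$bin1[i]),
                       abs(truth$bin2 - called$bin2[i])), Inf)
    } else {
      d <- ifelse(truth$chrom == called$chrom[i],
                  abs(truth$bin - called$bin[i]), Inf)
    }
    d[tm] <- Inf
    j <- if (nrow(truth)) which.min(d) else integer(0)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      tm[j] <- TRUE; cm[i] <- TRUE
    }
  }
  n_matched <- sum(cm)
  precision <- if (nrow(called)) n_matched / nrow(called) else NA_real_
  recall <- if (nrow(truth)) sum(tm) / nrow(truth) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_truth = nrow(truth), n_called = nrow(called), n_matched = n_matched,
       truth_matched = tm, called_matched = cm)
}

#' Compare pipeline outputs against planted truth
#'
#' Computes recovery metrics for every feature class: compartment bin-label
#' agreement and per-switch-block categorization, boundary detection F1 and
#' class confusion, loop recovery and class confusion, EPI gene recovery.
#'
#' @param truth the `truth` element of a `synth_bundle`.
#' @param results named list of pipeline outputs: `compartments1`,
#'   `compartments2` (row-bound `compartment_track`s), `switches`
#'   (`switch_table`), `boundaries` (`boundary_classification`), `loops`
#'   (classified `loop_set`), `epis` (from [differential_epis()]). Any
#'   element may be NULL to skip that section.
#' @param tol_bins positional tolerance in bins (default 1).
#' @return list of per-section recovery reports.
#' @export
truth_compare <- function(truth, results, tol_bins = 1) {
  rep_ <- list()
  if (!is.null(results$compartments1)) {
    tc <- truth$compartment_bins
    agree <- function(track, col) {
      key <- paste(tc$chrom, tc$bin)
      called <- track$label[match(key, paste(track$chrom, track$bin))]
      ok <- !is.na(tc[[col]]) & !is.na(called)
      mean(called[ok] == tc[[col]][ok])
    }
    rep_$compartment_agreement1 <- agree(results$compartments1, "label1")
    rep_$compartment_agreement2 <- agree(results$compartments2, "label2")
  }
  if (!is.null(results$switches)) {
    sb <- truth$switch_blocks
    bins <- results$switches$bins
    blockcat <- character(nrow(sb))
    for (i in seq_len(nrow(sb))) {
      sel <- bins$chrom == sb$chrom[i] & bins$start >= sb$start[i] &
        bins$end <= sb$end[i] & !is.na(bins$category)
      cc <- bins$category[sel]
      blockcat[i] <- if (length(cc)) names(sort(table(cc),
                                                decreasing = TRUE))[1]
      else NA_character_
    }
    rep_$switch_blocks <- data.frame(sb, called = blockcat,
                                     correct = blockcat == sb$direction)
  }
  if (!is.null(results$boundaries)) {
    bc <- results$boundaries
    rep_$boundary_recovery <- feature_recovery(
      truth$boundaries, bc[, c("chrom", "bin")], tol_bins)
    conf <- matrix(0L, 3, 5,
                   dimnames = list(c("stable", "gained", "lost"),
                                   c("stable", "gained", "lost",
                                     "unclassified", "missed")))
    for (i in seq_len(nrow(truth$boundaries))) {
      tb <- truth$boundaries[i, ]
      d <- ifelse(bc$chrom == tb$chrom, abs(bc$bin - tb$bin), Inf)
      j <- which.min(d)
      cls <- if (length(j) && is.finite(d[j]) && d[j] <= tol_bins)
        bc$class[j] else "missed"
      if (!cls %in% colnames(conf)) cls <- "missed"
      conf[tb$class, cls] <- conf[tb$class, cls] + 1L
    }
    rep_$boundary_confusion <- conf
  }
  if (!is.null(results$loops)) {
    lp <- results$loops
    rep_$loop_recovery <- feature_recovery(
      truth$loops, lp[, c("chrom", "bin1", "bin2")], tol_bins)
    conf <- matrix(0L, 3, 4,
                   dimnames = list(c("stable", "gained", "lost"),
                                   c("stable", "gained", "lost", "missed")))
    for (i in seq_len(nrow(truth$loops))) {
      tl <- truth$loops[i, ]
      d <- ifelse(lp$chrom == tl$chrom,
                  pmax(abs(lp$bin1 - tl$bin1), abs(lp$bin2 - tl$bin2)), Inf)
      j <- which.min(d)
      cls <- if (length(j) && is.finite(d[j]) && d[j] <= tol_bins)
        lp$class[j] else "missed"
      if (!cls %in% colnames(conf)) cls <- "missed"
      conf[tl$class, cls] <- conf[tl$class, cls] + 1L
    }
    rep_$loop_confusion <- conf
  }
  if (!is.null(results$epis)) {
    te <- truth$epis
    rep_$epi_recovery <- data.frame(
      class = c("gained", "lost"),
      n_truth = c(sum(te$class == "gained"), sum(te$class == "lost")),
      n_recovered = c(
        length(intersect(te$gene_id[te$class == "gained"],
                         results$epis$gained_degs)),
        length(intersect(te$gene_id[te$class == "lost"],
                         results$epis$lost_degs))))
  }
  rep_
}
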