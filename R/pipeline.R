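#' Pipeline run configuration
#'
#' Defaults follow the analysis parameters used throughout the package:
#' compartments at 100-kb resolution; TAD-separation window sweep scaled to
#' the matrix resolution (at 5-kb matrices the defaults are 15/75/7.5 kb) with
#' delta 0.01 and FDR threshold 0.01; loops up to 1 Mb at p 0.05; EPIs under
#' the minimum 1-bp overlap rule; boundary profiles over +/-50 kb.
#' Unknown keys are rejected.
#'
#' @param ... overrides for any default field.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    outdir = NULL,
    seed = 1,
    stages = c("matrix", "compartments", "tads", "loops", "epi", "profiles"),
    compartment_resolution = 1e5,
    ice_max_iter = 200, ice_tol = 1e-5, ice_mad_filter = 3,
    tad_min_depth = NULL, tad_max_depth = NULL, tad_step = NULL,  # bp; NULL =
    # 3x / 15x / 1.5x the matrix resolution (the 5-kb defaults, rescaled)
    tad_delta = 0.01, tad_threshold = 0.01,
    boundary_match_tol = 1,
    loop_max_distance = 1e6, loop_p = 0.05,
    loop_match_tol = 0,
    interaction_min_dist = 20000, interaction_max_dist = 1e6,
    interaction_z = 1, interaction_p = 0.05,
    run_interactions = TRUE,
    apa_flank = 10,
    profile_window = 50000, profile_binsize = 1000,
    dip_search_window = 30000, dip_min_width = 10000, dip_depth_frac = 0.25)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

apa_by_class <- function(matrices, loops, cls, k) {
  sel <- loops[!is.na(loops$class) & loops$class == cls, , drop = FALSE]
  agg <- NULL; used <- 0L; skipped <- 0L
  for (ch in names(matrices)) {
    sub <- sel[sel$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) next
    r <- tryCatch(apa(matrices[[ch]], sub, flank_bins = k),
                  error = function(e) NULL)
    if (is.null(r)) { skipped <- skipped + nrow(sub); next }
    agg <- if (is.null(agg)) r$aggregate * r$n_loops else
      agg + r$aggregate * r$n_loops
    used <- used + r$n_loops
    skipped <- skipped + r$n_skipped
  }
  if (is.null(agg) || used == 0L) return(NULL)
  agg <- agg / used
  size <- 2L * k + 1L
  corner <- agg[1:k, (k + 2L):size]
  structure(list(aggregate = agg, score = agg[k + 1L, k + 1L] / mean(corner),
                 n_loops = used, n_skipped = skipped), class = "apa_result")
}

#' Run the full two-condition differential-architecture pipeline
#'
#' Chains matrix normalization and correction, compartment calling and
#' switch classification, expression-by-switch statistics, TAD boundary
#' calling and classification, loop detection and classification, APA,
#' EPI identification and expression association, and boundary ATAC
#' metaprofiles with flanking-dip detection. When the input bundle carries a
#' `truth` element a recovery report is added. All stage outputs are written
#' under `config$outdir` (if set) with stable filenames plus a provenance log
#' of the effective parameters and per-stage counts.
#'
#' @param bundle input data: a `synth_bundle` from [generate_synthetic()] or
#'   a list with the same elements (`matrices$cond1/cond2` per chromosome,
#'   `atac1`, `atac2`, `enhancers`, `tss`, `expression`, optional `truth`).
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with all stage outputs.
#' @export
run_pipeline <- function(bundle, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(bundle$matrices) || is.null(bundle$matrices$cond1))
    stop("missing input: bundle$matrices$cond1/cond2 are required")
  chroms <- names(bundle$matrices$cond1)
  res <- list(config = config)
  counts <- list()
  stages <- config$stages

  ## ---- matrix stage: depth normalization + ICE ----
  if (!"matrix" %in% stages)
    stop("the matrix stage cannot be disabled: all later stages depend on it")
  corrected <- list(cond1 = list(), cond2 = list())
  comp_corrected <- list(cond1 = list(), cond2 = list())
  for (ch in chroms) {
    nn <- normalize_to_common_depth(bundle$matrices$cond1[[ch]],
                                    bundle$matrices$cond2[[ch]])
    for (k in 1:2) {
      cond <- paste0("cond", k)
      corrected[[cond]][[ch]] <- ice_correct(
        nn[[k]], max_iter = config$ice_max_iter, tol = config$ice_tol,
        mad_filter = config$ice_mad_filter)
      fac <- config$compartment_resolution / nn[[k]]$resolution
      comp_corrected[[cond]][[ch]] <- ice_correct(
        coarsen_matrix(nn[[k]], fac), max_iter = config$ice_max_iter,
        tol = config$ice_tol, mad_filter = config$ice_mad_filter)
    }
  }
  res$corrected <- corrected
  mres <- bundle$matrices$cond1[[1]]$resolution

  ## ---- compartments ----
  if ("compartments" %in% stages) {
    comp <- list()
    for (cond in c("cond1", "cond2")) {
      ref <- if (cond == "cond1") bundle$atac1 else bundle$atac2
      tr <- lapply(chroms, function(ch)
        compartment_pc1(comp_corrected[[cond]][[ch]], ref))
      comp[[cond]] <- do.call(rbind, lapply(tr, as.data.frame))
      class(comp[[cond]]) <- c("compartment_track", "data.frame")
    }
    res$compartments1 <- comp$cond1
    res$compartments2 <- comp$cond2
    res$switches <- classify_switches(comp$cond1, comp$cond2)
    counts$compartment_bins <- nrow(res$switches$bins)
    if (!is.null(bundle$expression)) {
      gb <- genes_by_switch_category(res$switches, bundle$expression)
      # collapse A->A / B->B into a stable category for the Fig-1F-style stats
      gb$genes$category[gb$genes$category %in% c("A->A", "B->B")] <- "stable"
      res$switch_genes <- gb
      res$switch_expression <- suppressWarnings(
        expression_by_category(gb$genes))
      counts$switch_degs <- nrow(gb$genes)
    }
  }

  ## ---- TADs ----
  if ("tads" %in% stages) {
    md <- config$tad_min_depth %||% (3 * mres)
    xd <- config$tad_max_depth %||% (15 * mres)
    st <- config$tad_step %||% (1.5 * mres)
    sep <- list(); bnd <- list()
    for (cond in c("cond1", "cond2")) {
      sep[[cond]] <- lapply(chroms, function(ch)
        separation_score(corrected[[cond]][[ch]], md, xd, st))
      names(sep[[cond]]) <- chroms
      bl <- lapply(sep[[cond]], call_boundaries,
                   delta = config$tad_delta,
                   threshold_comparisons = config$tad_threshold)
      bnd[[cond]] <- do.call(rbind, lapply(bl, as.data.frame))
      class(bnd[[cond]]) <- c("boundary_set", "data.frame")
    }
    sep_all <- lapply(sep, function(s) {
      d <- do.call(rbind, lapply(s, as.data.frame))
      rownames(d) <- NULL
      d
    })
    res$separation1 <- sep$cond1
    res$separation2 <- sep$cond2
    res$boundaries1 <- bnd$cond1
    res$boundaries2 <- bnd$cond2
    res$boundary_classes <- classify_boundaries(
      bnd$cond1, bnd$cond2, sep_all$cond1, sep_all$cond2,
      match_tol_bins = config$boundary_match_tol)
    res$tad_sizes <- tad_size_stats(bnd$cond1, bnd$cond2, mres)
    counts$boundaries_cond1 <- nrow(bnd$cond1)
    counts$boundaries_cond2 <- nrow(bnd$cond2)
    counts$boundary_classes <- as.list(table(res$boundary_classes$class))
    counts$tads_cond1 <- res$tad_sizes$n1
    counts$tads_cond2 <- res$tad_sizes$n2
  }

  ## ---- loops ----
  if ("loops" %in% stages) {
    lp <- list()
    for (cond in c("cond1", "cond2")) {
      ll <- lapply(chroms, function(ch)
        detect_loops(corrected[[cond]][[ch]],
                     max_distance = config$loop_max_distance,
                     p_threshold = config$loop_p))
      lp[[cond]] <- do.call(rbind, lapply(ll, as.data.frame))
      class(lp[[cond]]) <- c("loop_set", "data.frame")
      attr(lp[[cond]], "n_candidates") <-
        sum(vapply(ll, function(x) attr(x, "n_candidates"), numeric(1)))
    }
    res$loops1 <- lp$cond1
    res$loops2 <- lp$cond2
    res$loop_classes <- classify_loops(lp$cond1, lp$cond2,
                                       match_tol_bins = config$loop_match_tol)
    counts$loops_cond1 <- nrow(lp$cond1)
    counts$loops_cond2 <- nrow(lp$cond2)
    counts$loop_classes <- as.list(table(res$loop_classes$class))
    res$apa <- list(
      stable_cond1 = apa_by_class(corrected$cond1, res$loop_classes,
                                  "stable", config$apa_flank),
      stable_cond2 = apa_by_class(corrected$cond2, res$loop_classes,
                                  "stable", config$apa_flank),
      gained_cond1 = apa_by_class(corrected$cond1, res$loop_classes,
                                  "gained", config$apa_flank),
      gained_cond2 = apa_by_class(corrected$cond2, res$loop_classes,
                                  "gained", config$apa_flank),
      lost_cond1 = apa_by_class(corrected$cond1, res$loop_classes,
                                "lost", config$apa_flank),
      lost_cond2 = apa_by_class(corrected$cond2, res$loop_classes,
                                "lost", config$apa_flank))
    if (isTRUE(config$run_interactions)) {
      si <- lapply(c("cond1", "cond2"), function(cond) {
        x <- lapply(chroms, function(ch)
          significant_interactions(corrected[[cond]][[ch]],
                                   min_dist = config$interaction_min_dist,
                                   max_dist = config$interaction_max_dist,
                                   z_min = config$interaction_z,
                                   p_threshold = config$interaction_p))
        sum(vapply(x, nrow, integer(1)))
      })
      counts$significant_interactions_cond1 <- si[[1]]
      counts$significant_interactions_cond2 <- si[[2]]
    }
  }

  ## ---- EPIs ----
  if ("epi" %in% stages) {
    if (!"loops" %in% stages)
      stop("EPI stage requires loop calls: enable the 'loops' stage")
    if (is.null(bundle$tss) || is.null(bundle$enhancers))
      stop("missing input: EPI stage needs bundle$tss and bundle$enhancers")
    res$epi_calls <- identify_epis(res$loop_classes, bundle$tss,
                                   bundle$enhancers)
    res$epis <- differential_epis(res$epi_calls, bundle$expression)
    res$epi_expression <- epi_expression_stats(
      res$epis$gained_degs, res$epis$lost_degs, bundle$expression)
    counts$epis_gained <- res$epis$n_gained_epis
    counts$epis_lost <- res$epis$n_lost_epis
    counts$epi_degs_gained <- res$epis$n_gained_degs
    counts$epi_degs_lost <- res$epis$n_lost_degs
  }

  ## ---- profiles & flanking dips ----
  if ("profiles" %in% stages && "tads" %in% stages &&
      !is.null(bundle$atac1)) {
    bc <- res$boundary_classes
    # the boundary sits at the left edge of its bin; center profiles there
    centers <- function(cls) {
      sel <- bc[bc$class == cls, , drop = FALSE]
      data.frame(chrom = sel$chrom, start = sel$start, end = sel$start + 1)
    }
    prof <- list()
    for (cls in c("stable", "gained", "lost")) {
      cdf <- centers(cls)
      if (!nrow(cdf)) next
      prof[[paste0(cls, "_cond1")]] <- metaprofile(
        bundle$atac1, cdf, config$profile_window, config$profile_binsize,
        chrom_sizes = bundle$bins$chrom_sizes)
      prof[[paste0(cls, "_cond2")]] <- metaprofile(
        bundle$atac2, cdf, config$profile_window, config$profile_binsize,
        chrom_sizes = bundle$bins$chrom_sizes)
    }
    res$boundary_profiles <- prof
    if (!is.null(prof$stable_cond1))
      res$flank_dips <- list(
        cond1 = detect_flank_dips(prof$stable_cond1,
                                  config$dip_search_window,
                                  config$dip_min_width,
                                  config$dip_depth_frac),
        cond2 = detect_flank_dips(prof$stable_cond2,
                                  config$dip_search_window,
                                  config$dip_min_width,
                                  config$dip_depth_frac))
  }

  ## ---- truth recovery ----
  if (!is.null(bundle$truth)) {
    res$recovery <- truth_compare(
      bundle$truth,
      list(compartments1 = res$compartments1,
           compartments2 = res$compartments2,
           switches = res$switches,
           boundaries = res$boundary_classes,
           loops = res$loop_classes,
           epis = res$epis),
      tol_bins = 1)
  }

  res$counts <- counts
  class(res) <- "pipeline_result"
  if (!is.null(config$outdir)) write_pipeline_outputs(res, config$outdir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## write stage outputs with stable filenames; all files are plain text and
## byte-deterministic for a given input bundle
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name, col.names = TRUE) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  }
  if (!is.null(res$compartments1)) {
    for (k in 1:2) {
      tr <- res[[paste0("compartments", k)]]
      pc1 <- tr[!is.na(tr$pc1), c("chrom", "start", "end", "pc1")]
      tsv(pc1, sprintf("pc1_cond%d.bedgraph", k), col.names = FALSE)
    }
    sw <- res$switches$bins
    sw <- sw[!is.na(sw$category), c("chrom", "start", "end", "category")]
    tsv(sw, "compartment_switches.bed", col.names = FALSE)
    tsv(res$switches$summary, "compartment_switch_summary.tsv")
  }
  if (!is.null(res$switch_expression))
    tsv(res$switch_expression$per_category, "switch_expression_stats.tsv")
  if (!is.null(res$boundary_classes)) {
    tsv(res$boundary_classes, "boundaries_classified.tsv")
    tsv(res$tad_sizes$tads1, "tads_cond1.bed", col.names = FALSE)
    tsv(res$tad_sizes$tads2, "tads_cond2.bed", col.names = FALSE)
  }
  if (!is.null(res$loop_classes))
    write_bedpe(res$loop_classes, file.path(outdir, "loops_classified.bedpe"))
  if (!is.null(res$apa)) {
    sc <- data.frame(
      set = names(res$apa),
      score = vapply(res$apa, function(a)
        if (is.null(a)) NA_real_ else a$score, numeric(1)),
      n_loops = vapply(res$apa, function(a)
        if (is.null(a)) 0L else a$n_loops, integer(1)))
    tsv(sc, "apa_scores.tsv")
  }
  if (!is.null(res$epi_calls)) {
    tsv(res$epi_calls, "epi_calls.tsv")
    tsv(res$epi_expression, "epi_expression_stats.tsv")
  }
  if (!is.null(res$boundary_profiles)) {
    pr <- do.call(rbind, lapply(names(res$boundary_profiles), function(nm) {
      p <- res$boundary_profiles[[nm]]
      data.frame(set = nm, position = p$positions, mean = p$mean)
    }))
    tsv(pr, "boundary_atac_profiles.tsv")
  }
  if (!is.null(res$flank_dips)) {
    fd <- rbind(cbind(condition = "cond1", res$flank_dips$cond1),
                cbind(condition = "cond2", res$flank_dips$cond2))
    tsv(fd, "flank_dips.tsv")
  }
  prov <- list(package = "diffarch",
               version = as.character(utils::packageVersion("diffarch")),
               seed = res$config$seed,
               parameters = res$config[setdiff(names(res$config),
                                               c("outdir", "stages"))],
               stages = res$config$stages,
               counts = res$counts)
  yaml::write_yaml(prov, file.path(outdir, "provenance.yaml"))
  invisible(outdir)
}

#' End-to-end demonstration run on synthetic data
#'
#' Generates the default synthetic two-condition genome with the given seed,
#' runs the full pipeline, and (optionally) writes all outputs plus the
#' planted-truth recovery report under `outdir`.
#'
#' @param outdir output directory, or NULL to skip writing.
#' @param seed RNG seed for the generator (default 1).
#' @param synth overrides passed to [synth_config()].
#' @param run overrides passed to [run_config()].
#' @return a `pipeline_result` (invisibly) with the generator bundle attached
#'   as `$bundle`.
#' @export
run_demo <- function(outdir = NULL, seed = 1, synth = list(), run = list()) {
  scfg <- do.call(synth_config, c(list(seed = seed), synth))
  bundle <- generate_synthetic(scfg)
  rcfg <- do.call(run_config, c(list(outdir = outdir, seed = seed), run))
  res <- run_pipeline(bundle, rcfg)
  res$bundle <- bundle
  if (!is.null(outdir) && !is.null(res$recovery)) {
    rec <- res$recovery
    lines <- c(
      sprintf("compartment_agreement_cond1\t%.6f", rec$compartment_agreement1),
      sprintf("compartment_agreement_cond2\t%.6f", rec$compartment_agreement2),
      sprintf("switch_blocks_correct\t%d/%d",
              sum(rec$switch_blocks$correct), nrow(rec$switch_blocks)),
      sprintf("boundary_f1\t%.6f", rec$boundary_recovery$f1),
      sprintf("loop_recall\t%.6f", rec$loop_recovery$recall),
      sprintf("epi_gained_recovered\t%d/%d", rec$epi_recovery$n_recovered[1],
              rec$epi_recovery$n_truth[1]),
      sprintf("epi_lost_recovered\t%d/%d", rec$epi_recovery$n_recovered[2],
              rec$epi_recovery$n_truth[2]))
    writeLines(lines, file.path(outdir, "recovery_report.tsv"))
  }
  invisible(res)
}
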