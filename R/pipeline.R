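#' Run the full ROI-comparison pipeline
#'
#' End-to-end orchestration: (optionally) simulate a cohort, fit positivity
#' mixtures, define group-level and individualized ROIs, compute annualized
#' change, summarize per analysis group (amyloid-positive CU, MCI, AD), and
#' estimate trial sample sizes with bootstrap reductions versus the temporal
#' meta-ROI and the best-performing group-level staged ROI of each group.
#'
#' @param sim a \code{\link{simulation_config}}; when given, the cohort and
#'   all supporting inputs are generated from it (and a subtype/stage model
#'   is built when the "sustain" method is requested and none is supplied).
#' @param cohort a \code{\link{tau_cohort}} (ignored when \code{sim} given).
#' @param region_sets named list of \code{\link{region_set}} objects; must
#'   include staged sets for the group/highest_dds methods and
#'   \code{reference_roi} for reductions.
#' @param connectivity \code{\link{connectivity_matrix}} (required for
#'   "q1").
#' @param voxel_blocks per-subject list of baseline/followup
#'   \code{\link{voxel_block}}s (required for "overlap").
#' @param sustain_model a \code{\link{sustain_model}} (required for
#'   "sustain" unless simulating).
#' @param methods subset of c("group", "q1", "probability", "overlap",
#'   "highest_dds", "sustain").
#' @param effect_fractions treatment effects for the power analysis.
#' @param alpha,power significance level and power of the trial design.
#' @param n_boot bootstrap replicates for reductions.
#' @param overlap_threshold SUVR threshold of the overlap method.
#' @param reference_roi name of the fixed reference ROI for reductions.
#' @param highest_dds_fallback policy for tau-negative subjects
#'   ("stage1" or "exclude").
#' @param seed master seed (drives mixture restarts and bootstraps).
#' @param outdir optional directory; when given, report tables (TSV), the
#'   manifest (JSON) and serialized mixtures are written there.
#' @return list of class \code{tauroi_report}: \code{changes} (per-subject
#'   per-ROI), \code{group_summaries}, \code{power_table},
#'   \code{reductions}, \code{stage_variation}, \code{positivity}
#'   (mixtures and cutoffs), \code{rois}, \code{exclusions},
#'   \code{manifest}.
#' @export
run_pipeline <- function(sim = NULL, cohort = NULL, region_sets = NULL,
                         connectivity = NULL, voxel_blocks = NULL,
                         sustain_model = NULL,
                         methods = c("group", "highest_dds"),
                         effect_fractions = c(0.2, 0.3, 0.4),
                         alpha = 0.05, power = 0.80, n_boot = 1000L,
                         overlap_threshold = 1.40,
                         reference_roi = "temporal_meta",
                         highest_dds_fallback = "stage1",
                         seed = 1L, outdir = NULL) {
  all_methods <- c("group", "q1", "probability", "overlap", "highest_dds",
                   "sustain")
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  if (!is.null(sim)) {
    gen <- simulate_cohort(sim)
    cohort <- gen$cohort
    region_sets <- gen$region_sets
    connectivity <- gen$connectivity
    if (is.null(voxel_blocks)) voxel_blocks <- gen$voxel_blocks
    if ("sustain" %in% methods && is.null(sustain_model))
      sustain_model <- make_sustain_model(cohort$catalog$region_id,
                                          seed = sim$seed)
  }
  if (is.null(cohort) || is.null(region_sets))
    stop("run_pipeline: a cohort and region sets are required")
  region_sets <- validate_region_sets(region_sets, cohort$catalog)
  staged <- staged_sets_of(region_sets)
  # configuration errors surface before any computation
  if (("q1" %in% methods) && is.null(connectivity))
    stop("run_pipeline: method 'q1' requires a connectivity matrix")
  if (("overlap" %in% methods) && is.null(voxel_blocks))
    stop("run_pipeline: method 'overlap' requires voxel blocks")
  if (("sustain" %in% methods) && is.null(sustain_model))
    stop("run_pipeline: method 'sustain' requires a subtype/stage model")
  if (any(c("group", "highest_dds") %in% methods) && !length(staged))
    stop("run_pipeline: staged region sets required")

  s <- cohort$subjects
  groups <- analysis_groups(cohort)
  analysis_ids <- s$subject_id[Reduce(`|`, groups)]
  exclusions <- list()
  rois <- list()
  changes <- NULL

  if ("group" %in% methods)
    changes <- change_table(cohort, region_sets)

  need_region_gmm <- any(c("q1", "probability") %in% methods)
  mixtures <- NULL
  prob <- NULL
  if (need_region_gmm) {
    mixtures <- fit_gmm_cohort(cohort, level = "region", seed = seed)
    prob <- matrix(0, nrow(s), ncol(cohort$baseline),
                   dimnames = list(s$subject_id, colnames(cohort$baseline)))
    for (r in colnames(prob))
      prob[, r] <- positivity_probability(mixtures[[r]],
                                          cohort$baseline[, r])
  }

  if ("q1" %in% methods) {
    dmat <- connectivity_to_distance(connectivity)
    q1_rois <- lapply(analysis_ids, function(sid) {
      epi <- define_epicenter(prob[sid, ])
      quartile_q1_roi(dmat, epi, subject_id = sid)
    })
    names(q1_rois) <- analysis_ids
    rois$q1 <- q1_rois
    changes <- rbind(changes, change_table(cohort, q1_rois,
                                           roi_name = "q1"))
  }

  if ("probability" %in% methods) {
    prob_rois <- list()
    intervals <- list()
    excluded <- character(0)
    for (g in names(groups)) {
      if (sum(groups[[g]]) == 0L) next
      res <- probability_interval_search(prob, cohort,
                                         subjects = groups[[g]])
      prob_rois <- c(prob_rois, res$rois)
      intervals[[g]] <- res$interval
      excluded <- c(excluded, res$excluded)
    }
    rois$probability <- prob_rois
    exclusions$probability <- excluded
    if (length(prob_rois))
      changes <- rbind(changes, change_table(cohort, prob_rois,
                                             roi_name = "probability"))
  }

  if ("overlap" %in% methods) {
    ov_rois <- list()
    excluded <- character(0)
    for (sid in analysis_ids) {
      vb <- voxel_blocks[[sid]]
      if (is.null(vb)) { excluded <- c(excluded, sid); next }
      roi <- overlap_index_roi(vb$baseline, vb$followup,
                               threshold = overlap_threshold)
      if (is.null(roi)) excluded <- c(excluded, sid)
      else ov_rois[[sid]] <- roi
    }
    rois$overlap <- ov_rois
    exclusions$overlap <- excluded
    if (length(ov_rois))
      changes <- rbind(changes, change_table(cohort, ov_rois,
                                             roi_name = "overlap",
                                             voxel_blocks = voxel_blocks))
  }

  set_mixtures <- NULL
  stage_pos <- NULL
  if (length(staged) && any(c("group", "highest_dds") %in% methods)) {
    set_mixtures <- fit_gmm_cohort(cohort, level = "set", sets = staged,
                                   seed = seed)
    cutoffs <- vapply(set_mixtures, `[[`, numeric(1), "cutoff")
    stage_pos <- t(vapply(s$subject_id, function(sid)
      stage_positivity(cohort$baseline[sid, ], staged, cutoffs,
                       cohort$catalog),
      logical(length(staged))))
  }

  if ("highest_dds" %in% methods) {
    hd_rois <- list()
    excluded <- character(0)
    for (sid in analysis_ids) {
      roi <- highest_positive_dds_roi(stage_pos[sid, ], staged,
                                      subject_id = sid,
                                      fallback = highest_dds_fallback)
      if (is.null(roi)) excluded <- c(excluded, sid)
      else hd_rois[[sid]] <- roi
    }
    rois$highest_dds <- hd_rois
    exclusions$highest_dds <- excluded
    if (length(hd_rois))
      changes <- rbind(changes, change_table(cohort, hd_rois,
                                             roi_name = "highest_dds"))
  }

  if ("sustain" %in% methods) {
    ctrl <- is_control(cohort)
    if (sum(ctrl) < 2L)
      stop("run_pipeline: 'sustain' needs an amyloid-negative control group")
    cm <- colMeans(cohort$baseline[ctrl, , drop = FALSE])
    csd <- apply(cohort$baseline[ctrl, , drop = FALSE], 2, stats::sd)
    su_rois <- list()
    assignments <- list()
    excluded <- character(0)
    for (sid in analysis_ids) {
      z <- zscore_to_controls(cohort$baseline[sid, ], cm, csd)
      a <- sustain_assign(z, sustain_model, subject_id = sid)
      assignments[[sid]] <- a[c("subtype", "stage", "band")]
      if (is.null(a$roi)) excluded <- c(excluded, sid)
      else su_rois[[sid]] <- a$roi
    }
    rois$sustain <- su_rois
    exclusions$sustain <- excluded
    if (length(su_rois))
      changes <- rbind(changes, change_table(cohort, su_rois,
                                             roi_name = "sustain"))
  }

  # group summaries and power ---------------------------------------------
  roi_names <- unique(changes$roi_name)
  summaries <- list()
  power_rows <- list()
  for (g in names(groups)) {
    gids <- s$subject_id[groups[[g]]]
    if (length(gids) < 2L) next
    for (rn in roi_names) {
      vals <- changes$annual_pct_change[changes$roi_name == rn &
                                          changes$subject_id %in% gids]
      if (length(vals) < 2L) next
      summaries[[paste(g, rn)]] <- one_sample_summary(vals, roi = rn,
                                                      group = g)
      for (f in effect_fractions) {
        n_arm <- if (mean(vals) > 0)
          sample_size_per_arm(mean(vals), stats::sd(vals), f, alpha, power)
        else NA_integer_
        power_rows[[paste(g, rn, f)]] <-
          data.frame(group = g, roi = rn, effect_fraction = f,
                     alpha = alpha, power = power, n_per_arm = n_arm,
                     stringsAsFactors = FALSE)
      }
    }
  }
  group_summaries <- do.call(rbind, summaries)
  power_table <- do.call(rbind, power_rows)
  rownames(group_summaries) <- rownames(power_table) <- NULL

  # reductions vs the temporal meta-ROI and the best staged ROI per group --
  reductions <- NULL
  staged_names <- names(staged)
  if (!is.null(group_summaries)) {
    red_rows <- list()
    boot_i <- 0L
    for (g in names(groups)) {
      gs <- group_summaries[group_summaries$group == g, , drop = FALSE]
      if (!nrow(gs)) next
      gstaged <- gs[gs$roi %in% staged_names & gs$mean > 0, , drop = FALSE]
      best_staged <- if (nrow(gstaged))
        gstaged$roi[which.max(gstaged$mean)] else NA_character_
      refs <- c(reference = reference_roi, best_staged = best_staged)
      refs <- refs[!is.na(refs) & refs %in% gs$roi]
      cand <- setdiff(gs$roi[gs$mean > 0], NA)
      gids <- s$subject_id[groups[[g]]]
      get_changes <- function(rn) {
        sub <- changes[changes$roi_name == rn &
                         changes$subject_id %in% gids, ]
        stats::setNames(sub$annual_pct_change, sub$subject_id)
      }
      for (ref_kind in names(refs)) {
        ref_rn <- refs[[ref_kind]]
        ref_ch <- get_changes(ref_rn)
        if (mean(ref_ch) <= 0) next
        for (rn in setdiff(cand, ref_rn)) {
          roi_ch <- get_changes(rn)
          common <- intersect(names(roi_ch), names(ref_ch))
          if (length(common) < 10L) next
          boot_i <- boot_i + 1L
          for (f in effect_fractions) {
            # ROIs with near-zero mean change have no defined trial size;
            # skip them rather than abort the whole report
            pr <- tryCatch(bootstrap_sample_size_reduction(
              roi_ch[common], ref_ch[common], effect_fraction = f,
              alpha = alpha, power = power, n_boot = n_boot,
              seed = seed + boot_i), error = function(e) NULL)
            if (is.null(pr)) next
            red_rows[[paste(g, rn, ref_kind, f)]] <- data.frame(
              group = g, roi = rn, reference_kind = ref_kind,
              reference_roi = ref_rn, effect_fraction = f,
              n_roi = pr$n_roi, n_ref = pr$n_ref,
              reduction_pct = pr$reduction_pct,
              ci_low = pr$ci_low, ci_high = pr$ci_high,
              significant = pr$significant, boot_p = pr$boot_p,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    reductions <- do.call(rbind, red_rows)
    if (!is.null(reductions)) rownames(reductions) <- NULL
  }

  # stage-positivity variation across clinical groups ----------------------
  stage_variation <- NULL
  if (!is.null(stage_pos)) {
    rows <- lapply(names(groups), function(g) {
      gids <- s$subject_id[groups[[g]]]
      if (!length(gids)) return(NULL)
      npos <- rowSums(stage_pos[gids, , drop = FALSE])
      data.frame(group = g, n = length(gids),
                 mean_positive_stages = mean(npos),
                 sd_positive_stages = stats::sd(npos),
                 stringsAsFactors = FALSE)
    })
    stage_variation <- do.call(rbind, rows)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tauroi")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, methods = methods, effect_fractions = effect_fractions,
    alpha = alpha, power = power, n_boot = n_boot,
    overlap_threshold = overlap_threshold, reference_roi = reference_roi,
    highest_dds_fallback = highest_dds_fallback,
    simulated = !is.null(sim),
    sim_config = if (!is.null(sim)) unclass(sim),
    n_subjects = nrow(s),
    n_regions = ncol(cohort$baseline),
    exclusions = exclusions)

  report <- structure(list(changes = changes,
                           group_summaries = group_summaries,
                           power_table = power_table,
                           reductions = reductions,
                           stage_variation = stage_variation,
                           positivity = list(region = mixtures,
                                             set = set_mixtures,
                                             stage_positivity = stage_pos),
                           rois = rois, exclusions = exclusions,
                           manifest = manifest),
                      class = "tauroi_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.tauroi_report <- function(x, ...) {
  cat("tauroi_report:", x$manifest$n_subjects, "subjects,",
      x$manifest$n_regions, "regions; methods:",
      paste(x$manifest$methods, collapse = ", "), "\n")
  if (!is.null(x$group_summaries)) {
    cat("\nGroup mean annual % change (95% CI):\n")
    gs <- x$group_summaries
    for (i in seq_len(nrow(gs)))
      cat(sprintf("  %-4s %-16s %6.2f [%6.2f, %6.2f]  n=%d\n",
                  gs$group[i], gs$roi[i], gs$mean[i], gs$ci95_low[i],
                  gs$ci95_high[i], gs$n[i]))
  }
  invisible(x)
}

#' Write report tables to a directory
#'
#' Emits changes.tsv, group_summaries.tsv, power_table.tsv, reductions.tsv,
#' stage_variation.tsv and manifest.json. Deterministic: identical reports
#' produce byte-identical files.
#'
#' @param report a \code{tauroi_report}.
#' @param outdir output directory (created if absent).
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  emit(report$changes, "changes.tsv")
  emit(report$group_summaries, "group_summaries.tsv")
  emit(report$power_table, "power_table.tsv")
  emit(report$reductions, "reductions.tsv")
  emit(report$stage_variation, "stage_variation.tsv")
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(outdir)
}

#' Compare SUVR-based and tau-extent-based trial outcomes in one ROI
#'
#' For the same ROI (typically the temporal meta-ROI), computes per-subject
#' annual percentage change in (a) the ROI mean SUVR and (b) tau extent (the
#' fraction of ROI voxels above a threshold), then the per-arm sample sizes
#' for both outcome definitions per analysis group and effect fraction,
#' with a paired bootstrap comparison of the two. Subjects with zero
#' baseline extent (percentage change undefined) are excluded and reported.
#'
#' @param cohort a \code{\link{tau_cohort}}.
#' @param voxel_blocks per-subject baseline/followup voxel blocks.
#' @param set the \code{\link{region_set}} to evaluate.
#' @param threshold SUVR threshold for tau extent.
#' @param effect_fractions,alpha,power,n_boot,seed trial parameters.
#' @return list with \code{table} (one row per group x metric x effect
#'   fraction), \code{comparison} (bootstrap reduction of extent vs SUVR
#'   per group x effect), and \code{excluded}.
#' @export
compare_suvr_vs_extent <- function(cohort, voxel_blocks, set,
                                   threshold = 1.40,
                                   effect_fractions = c(0.2, 0.3, 0.4),
                                   alpha = 0.05, power = 0.80,
                                   n_boot = 1000L, seed = 1L) {
  if (is.null(voxel_blocks))
    stop("compare_suvr_vs_extent: voxel blocks required")
  s <- cohort$subjects
  groups <- analysis_groups(cohort)
  analysis_ids <- s$subject_id[Reduce(`|`, groups)]
  excluded <- character(0)
  rows <- list()
  for (sid in analysis_ids) {
    vb <- voxel_blocks[[sid]]
    if (is.null(vb)) { excluded <- c(excluded, sid); next }
    dt <- s$interval_years[s$subject_id == sid]
    bl_suvr <- weighted_roi_mean(cohort$baseline[sid, ], set$region_ids,
                                 cohort$catalog)
    fu_suvr <- weighted_roi_mean(cohort$followup[sid, ], set$region_ids,
                                 cohort$catalog)
    ext_bl <- tau_extent(subset_voxel_block(vb$baseline,
                                            region_ids = set$region_ids),
                         threshold)
    ext_fu <- tau_extent(subset_voxel_block(vb$followup,
                                            region_ids = set$region_ids),
                         threshold)
    if (ext_bl == 0) { excluded <- c(excluded, sid); next }
    rows[[sid]] <- data.frame(
      subject_id = sid,
      suvr_change = annual_pct_change(bl_suvr, fu_suvr, dt),
      extent_change = annual_pct_change(ext_bl, ext_fu, dt),
      stringsAsFactors = FALSE)
  }
  per_subject <- do.call(rbind, rows)
  tab_rows <- list()
  cmp_rows <- list()
  boot_i <- 0L
  for (g in names(groups)) {
    gids <- intersect(s$subject_id[groups[[g]]], per_subject$subject_id)
    if (length(gids) < 10L) next
    sub <- per_subject[match(gids, per_subject$subject_id), ]
    for (f in effect_fractions) {
      for (metric in c("suvr", "extent")) {
        vals <- sub[[paste0(metric, "_change")]]
        n_arm <- if (mean(vals) > 0)
          sample_size_per_arm(mean(vals), stats::sd(vals), f, alpha, power)
        else NA_integer_
        tab_rows[[paste(g, metric, f)]] <-
          data.frame(group = g, metric = metric, effect_fraction = f,
                     mean_change = mean(vals), sd_change = stats::sd(vals),
                     n_per_arm = n_arm, stringsAsFactors = FALSE)
      }
      if (mean(sub$suvr_change) > 0 && mean(sub$extent_change) > 0) {
        boot_i <- boot_i + 1L
        pr <- bootstrap_sample_size_reduction(
          sub$extent_change, sub$suvr_change, effect_fraction = f,
          alpha = alpha, power = power, n_boot = n_boot,
          seed = seed + boot_i)
        cmp_rows[[paste(g, f)]] <- data.frame(
          group = g, effect_fraction = f,
          n_extent = pr$n_roi, n_suvr = pr$n_ref,
          reduction_extent_vs_suvr = pr$reduction_pct,
          ci_low = pr$ci_low, ci_high = pr$ci_high,
          significant = pr$significant, stringsAsFactors = FALSE)
      }
    }
  }
  list(table = do.call(rbind, tab_rows),
       comparison = do.call(rbind, cmp_rows),
       per_subject = per_subject,
       excluded = excluded)
}
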