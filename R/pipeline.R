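# Cohort-level orchestration: rest summaries, balanced task measures
# (TTV / LZC / FS / PS), Kolmogorov-Smirnov group comparisons, task-task
# and rest-task Spearman correlations, per-family FDR control, and a
# manifest sufficient for bit-identical replay.

#' Analysis configuration
#'
#' All tunable constants of the pipeline in one place. Defaults follow
#' the standard session: theta read at Fz, alpha at Pz; resting alpha
#' 8-13 Hz but task alpha 7-13 Hz; broadband 1-40 Hz TTV at Fz; TTV AUC
#' over 0-500 ms; 300-ms LZC windows; the fixed FS/PS AUC window table;
#' 80 standards subsampled to match the deviant count.
#'
#' @param rest_bands,task_bands Named lists of `c(low, high)` Hz bands.
#' @param electrodes Named map band -> electrode label.
#' @param broadband `c(low, high)` Hz for the wide-band task filter.
#' @param broadband_electrode Electrode for broadband TTV / LZC.
#' @param epoch_window `c(tmin, tmax)` ms around onset.
#' @param ttv_window `c(start, end)` ms for the TTV AUC.
#' @param lzc_window_ms One-sided LZC window, ms.
#' @param sliding_windows FS/PS AUC window table ([auc_windows()]).
#' @param n_subsample Standards retained per subject (match the deviant
#'   count).
#' @param subsample_seed Seed for the per-subject standard subsample.
#' @param bh_mode `"per_family"` or `"global"` FDR correction.
#' @param exclude_task_subjects Subject ids dropped from task measures
#'   and correlations (rest summaries keep all subjects).
#' @param transition_fraction,median_order Passed through to the spectral
#'   machinery.
#' @param rest_max_samples Rest truncation length ([resting_summary()]).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(rest_bands = list(theta = c(4, 8),
                                              alpha = c(8, 13)),
                            task_bands = list(theta = c(4, 8),
                                              alpha = c(7, 13)),
                            electrodes = c(theta = "Fz", alpha = "Pz"),
                            broadband = c(1, 40),
                            broadband_electrode = "Fz",
                            epoch_window = c(-500, 800),
                            ttv_window = c(0, 500),
                            lzc_window_ms = 300,
                            sliding_windows = auc_windows(),
                            n_subsample = 80L,
                            subsample_seed = 1L,
                            bh_mode = c("per_family", "global"),
                            exclude_task_subjects = character(),
                            transition_fraction = 0.15,
                            median_order = 10L,
                            rest_max_samples = 85000L) {
  bh_mode <- match.arg(bh_mode)
  if (n_subsample < 2L) stop("`n_subsample` must be >= 2", call. = FALSE)
  if (!(epoch_window[1L] < 0 && epoch_window[2L] > 0)) {
    stop("`epoch_window` must straddle onset", call. = FALSE)
  }
  if (ttv_window[2L] > epoch_window[2L] ||
      lzc_window_ms > -epoch_window[1L] ||
      lzc_window_ms > epoch_window[2L]) {
    stop("analysis windows must fit inside the epoch window", call. = FALSE)
  }
  structure(
    list(rest_bands = rest_bands, task_bands = task_bands,
         electrodes = electrodes, broadband = broadband,
         broadband_electrode = broadband_electrode,
         epoch_window = epoch_window, ttv_window = ttv_window,
         lzc_window_ms = lzc_window_ms, sliding_windows = sliding_windows,
         n_subsample = as.integer(n_subsample),
         subsample_seed = as.integer(subsample_seed), bh_mode = bh_mode,
         exclude_task_subjects = exclude_task_subjects,
         transition_fraction = transition_fraction,
         median_order = as.integer(median_order),
         rest_max_samples = rest_max_samples),
    class = "analysis_config"
  )
}

# ---- per-subject workers ---------------------------------------------------

subject_rest_rows <- function(sub, config) {
  purrr::map_dfr(names(config$rest_bands), function(b) {
    resting_summary(sub$rest, config$electrodes[[b]], config$rest_bands[[b]],
                    transition_fraction = config$transition_fraction,
                    median_order = config$median_order,
                    max_samples = config$rest_max_samples) |>
      dplyr::mutate(subject = sub$id, group = sub$group, band = b,
                    .before = 1L)
  })
}

subject_task_rows <- function(sub, config, subject_index) {
  fs <- sub$task$fs
  tw <- config$epoch_window
  sub_seed <- derive_seed(config$subsample_seed, subject_index)

  # subsample the standards to the deviant count; keep all other trials
  balance <- function(epochs) {
    std <- which(epochs$labels == "standard")
    if (config$n_subsample > length(std)) {
      stop("only ", length(std), " standard trials; cannot subsample ",
           config$n_subsample, call. = FALSE)
    }
    picked <- withr::with_seed(sub_seed, sample(std, config$n_subsample))
    sel <- sort(c(picked, which(epochs$labels != "standard")))
    eeg_epochs(epochs$data[sel, , , drop = FALSE], epochs$fs,
               epochs$t0_index, epochs$labels[sel], epochs$channel_labels)
  }

  rows <- list()
  add <- function(measure, condition, band, value) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      subject = sub$id, group = sub$group, measure = measure,
      condition = condition, band = band, value = value
    )
  }

  # only the analysis channel is carried through each filter
  chan_rec <- function(ch) {
    eeg_recording(sub$task$data[ch, , drop = FALSE], sub$task$fs, ch)
  }

  # broadband: TTV + LZC
  bb <- fir_bandpass(chan_rec(config$broadband_electrode),
                     config$broadband[1L], config$broadband[2L],
                     config$transition_fraction)
  ep <- suppressWarnings(epoch_recording(bb, sub$events, tw[1L], tw[2L]))
  ep <- balance(ep)
  for (cond in unique(ep$labels)) {
    tc <- ttv_curve(filter_epochs(ep, cond), config$broadband_electrode)
    add("ttv_auc", cond, "broadband",
        curve_auc(tc, config$ttv_window[1L], config$ttv_window[2L]))
  }
  lz <- lzc_prepost(ep, config$broadband_electrode, config$lzc_window_ms)
  for (i in seq_len(nrow(lz))) {
    add("lzc_pre", lz$condition[i], "broadband", lz$pre[i])
    add("lzc_post", lz$condition[i], "broadband", lz$post[i])
    add("lzc_diff", lz$condition[i], "broadband", lz$diff[i])
  }

  # narrowband: FS / PS for standard and deviant
  for (b in names(config$task_bands)) {
    nb <- fir_bandpass(chan_rec(config$electrodes[[b]]),
                       config$task_bands[[b]][1L],
                       config$task_bands[[b]][2L],
                       config$transition_fraction)
    epb <- suppressWarnings(epoch_recording(nb, sub$events, tw[1L], tw[2L]))
    epb <- balance(epb)
    for (cond in c("standard", "deviant")) {
      sc <- sliding_curves(filter_epochs(epb, cond),
                           config$task_bands[[b]], config$electrodes[[b]],
                           median_order = config$median_order)
      pct <- sliding_window_auc(sc, config$sliding_windows)
      abs_ <- sliding_absolute_auc(sc, config$sliding_windows)
      add("fs_pct_auc", cond, b, pct$fs_auc)
      add("ps_pct_auc", cond, b, pct$ps_auc)
      add("fs_abs_auc", cond, b, abs_$fs_auc)
      add("ps_abs_auc", cond, b, abs_$ps_auc)
    }
  }

  rt <- sub$reaction_times
  add("mean_rt", "deviant", "broadband",
      if (length(rt)) mean(rt, na.rm = TRUE) else NA_real_)
  dplyr::bind_rows(rows)
}

# Pull one per-subject column out of the long measure table.
measure_vector <- function(task_measures, subjects, measure, condition,
                           band = NULL) {
  tm <- task_measures[task_measures$measure == measure &
                        task_measures$condition == condition, ]
  if (!is.null(band)) tm <- tm[tm$band == band, ]
  tm$value[match(subjects, tm$subject)]
}

# ---- the full analysis -----------------------------------------------------

#' Run the full rest + task analysis on a cohort
#'
#' Computes per-subject rest summaries (theta at Fz, alpha at Pz),
#' balanced task measures (TTV AUC, pre/post LZC, percent-change and
#' absolute FS/PS AUC for standards and deviants; TTV/LZC also for
#' novels), Kolmogorov-Smirnov group comparisons per measure family,
#' and pooled Spearman correlations (task-task including reaction times,
#' and rest-task), with Benjamini-Hochberg adjustment per family.
#'
#' @param cohort An `eeg_cohort` from [simulate_cohort()] (or a list with
#'   the same per-subject structure built from files).
#' @param config An [analysis_config()].
#' @return An `eeg_result_bundle`: tibbles `rest_summaries`,
#'   `task_measures`, `group_tests`, `correlations`, plus a `manifest`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  subjects <- cohort$subjects
  groups <- vapply(subjects, `[[`, character(1L), "group")
  if (any(table(groups) < 2L) || length(unique(groups)) != 2L) {
    stop("need >= 2 subjects in each of two groups", call. = FALSE)
  }

  rest_summaries <- purrr::map_dfr(subjects, subject_rest_rows,
                                   config = config)

  task_subjects <- subjects[!vapply(subjects, `[[`, character(1L), "id") %in%
                              config$exclude_task_subjects]
  task_measures <- purrr::imap_dfr(task_subjects, function(sub, i) {
    tryCatch(subject_task_rows(sub, config, i),
             error = function(e) {
               warning("subject ", sub$id, " skipped: ", conditionMessage(e),
                       call. = FALSE)
               tibble::tibble()
             })
  })

  group_tests <- build_group_tests(rest_summaries, task_measures)
  correlations <- build_correlations(rest_summaries, task_measures)
  group_tests <- adjust_families(group_tests, config$bh_mode)
  correlations <- adjust_families(correlations, config$bh_mode)

  structure(
    list(
      rest_summaries = rest_summaries,
      task_measures = task_measures,
      group_tests = group_tests,
      correlations = correlations,
      manifest = list(
        cohort = cohort$manifest,
        analysis_config = serialize_config(config),
        package_version = as.character(utils::packageVersion("eegdyn"))
      )
    ),
    class = "eeg_result_bundle"
  )
}

# JSON-safe form of an analysis_config (names survive the round trip).
serialize_config <- function(config) {
  out <- unclass(config)
  out$electrodes <- as.list(out$electrodes)
  out
}

split_groups <- function(values, groups) {
  split(values, factor(groups, levels = c("MDD", "CON")))
}

build_group_tests <- function(rest_summaries, task_measures) {
  out <- list()
  push <- function(x) out[[length(out) + 1L]] <<- x

  # rest family: PF / CV / power per band
  for (b in unique(rest_summaries$band)) {
    rs <- rest_summaries[rest_summaries$band == b, ]
    for (m in c("mean_pf", "cv", "mean_power")) {
      g <- split_groups(rs[[m]], rs$group)
      push(ks_two_sample(g$MDD, g$CON,
                         description = paste("rest", b, m, sep = "_"),
                         family = "rest"))
    }
  }
  if (nrow(task_measures) == 0L) {
    return(dplyr::bind_rows(out))
  }
  subs <- unique(task_measures$subject)
  grp <- task_measures$group[match(subs, task_measures$subject)]
  ks_of <- function(measure, condition, band, family, desc) {
    v <- measure_vector(task_measures, subs, measure, condition, band)
    ok <- !is.na(v)
    g <- split_groups(v[ok], grp[ok])
    push(ks_two_sample(g$MDD, g$CON, description = desc, family = family))
  }
  for (cond in c("standard", "deviant", "novel")) {
    ks_of("ttv_auc", cond, "broadband", "ttv", paste0("ttv_auc_", cond))
  }
  for (cond in c("standard", "deviant", "novel")) {
    ks_of("lzc_diff", cond, "broadband", "lzc", paste0("lzc_diff_", cond))
  }
  for (cond in c("standard", "deviant")) {
    ks_of("lzc_pre", cond, "broadband", "lzc", paste0("lzc_prestim_", cond))
  }
  for (b in c("theta", "alpha")) {
    for (cond in c("standard", "deviant")) {
      ks_of("fs_pct_auc", cond, b, "sliding",
            paste("fs_pct", b, cond, sep = "_"))
      ks_of("ps_pct_auc", cond, b, "sliding",
            paste("ps_pct", b, cond, sep = "_"))
      ks_of("fs_abs_auc", cond, b, "sliding_abs",
            paste("fs_abs", b, cond, sep = "_"))
      ks_of("ps_abs_auc", cond, b, "sliding_abs",
            paste("ps_abs", b, cond, sep = "_"))
    }
  }
  dplyr::bind_rows(out)
}

build_correlations <- function(rest_summaries, task_measures) {
  if (nrow(task_measures) == 0L) return(tibble::tibble())
  out <- list()
  push <- function(x) out[[length(out) + 1L]] <<- x
  subs <- unique(task_measures$subject)
  mv <- function(measure, condition, band = NULL) {
    measure_vector(task_measures, subs, measure, condition, band)
  }
  corr <- function(x, y, family, desc) {
    res <- tryCatch(spearman_corr(x, y, description = desc, family = family),
                    error = function(e) NULL)
    if (!is.null(res)) push(res)
  }

  # task-task: TTV AUC vs FS/PS percent-change AUC, per band and condition
  for (cond in c("standard", "deviant")) {
    ttv <- mv("ttv_auc", cond, "broadband")
    for (b in c("theta", "alpha")) {
      corr(ttv, mv("fs_pct_auc", cond, b), "task_task",
           paste("ttv_vs_fs", b, cond, sep = "_"))
      corr(ttv, mv("ps_pct_auc", cond, b), "task_task",
           paste("ttv_vs_ps", b, cond, sep = "_"))
    }
  }
  corr(mv("ttv_auc", "deviant", "broadband"), mv("mean_rt", "deviant"),
       "task_task", "ttv_deviant_vs_mean_rt")

  # rest-task: every rest measure vs the reported task measures
  task_set <- list(
    c("lzc_pre", "standard"), c("lzc_pre", "deviant"),
    c("lzc_post", "standard"), c("lzc_post", "deviant"),
    c("lzc_diff", "deviant"), c("ttv_auc", "deviant"),
    c("fs_pct_auc", "deviant"), c("ps_pct_auc", "deviant")
  )
  for (b in unique(rest_summaries$band)) {
    rs <- rest_summaries[rest_summaries$band == b, ]
    rest_vals <- rs[match(subs, rs$subject), ]
    for (m in c("mean_pf", "cv", "mean_power")) {
      for (tk in task_set) {
        band_arg <- if (tk[1L] %in% c("fs_pct_auc", "ps_pct_auc")) b
                    else "broadband"
        corr(rest_vals[[m]], mv(tk[1L], tk[2L], band_arg), "rest_task",
             paste("rest", b, m, "vs", tk[1L], tk[2L], sep = "_"))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.eeg_result_bundle <- function(x, ...) {
  cat("<eeg_result_bundle>\n")
  cat(sprintf("  rest_summaries: %d rows\n", nrow(x$rest_summaries)))
  cat(sprintf("  task_measures:  %d rows\n", nrow(x$task_measures)))
  cat(sprintf("  group_tests:    %d rows (%d adjusted p < 0.05)\n",
              nrow(x$group_tests),
              sum(x$group_tests$p_adj < 0.05, na.rm = TRUE)))
  cat(sprintf("  correlations:   %d rows (%d adjusted p < 0.05)\n",
              nrow(x$correlations),
              sum(x$correlations$p_adj < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Export a result bundle to a directory
#'
#' Writes `rest_summary.tsv`, `task_measures.tsv`, `group_tests.tsv`,
#' `correlations.tsv` and `manifest.json`. Re-exporting the same bundle
#' is byte-identical.
#'
#' @param bundle An `eeg_result_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "eeg_result_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(bundle$rest_summaries,
                   file.path(out_dir, "rest_summary.tsv"), na = "")
  readr::write_tsv(bundle$task_measures,
                   file.path(out_dir, "task_measures.tsv"), na = "")
  readr::write_tsv(bundle$group_tests,
                   file.path(out_dir, "group_tests.tsv"), na = "")
  readr::write_tsv(bundle$correlations,
                   file.path(out_dir, "correlations.tsv"), na = "")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Re-run an analysis from its manifest
#'
#' Regenerates the cohort from the manifest's generator settings, rebuilds
#' the analysis configuration, and re-runs [run_full_analysis()]. With an
#' unchanged package version the result reproduces the original outputs
#' byte for byte.
#'
#' @param manifest A manifest list, or the path to a `manifest.json`.
#' @return An `eeg_result_bundle`.
#' @export
replay_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  cohort <- cohort_from_manifest(manifest$cohort)
  ac <- manifest$analysis_config
  config <- analysis_config(
    rest_bands = lapply(ac$rest_bands, as.numeric),
    task_bands = lapply(ac$task_bands, as.numeric),
    electrodes = unlist(ac$electrodes),
    broadband = as.numeric(ac$broadband),
    broadband_electrode = ac$broadband_electrode,
    epoch_window = as.numeric(ac$epoch_window),
    ttv_window = as.numeric(ac$ttv_window),
    lzc_window_ms = ac$lzc_window_ms,
    sliding_windows = tibble::as_tibble(ac$sliding_windows),
    n_subsample = ac$n_subsample,
    subsample_seed = ac$subsample_seed,
    bh_mode = ac$bh_mode,
    exclude_task_subjects = as.character(unlist(ac$exclude_task_subjects)),
    transition_fraction = ac$transition_fraction,
    median_order = ac$median_order,
    rest_max_samples = ac$rest_max_samples
  )
  run_full_analysis(cohort, config)
}
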