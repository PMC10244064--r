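#' Analysis run configuration
#'
#' All tunable parameters of the pipeline with their defaults; round-trips
#' losslessly through YAML via \code{\link{write_config}} /
#' \code{\link{read_config}}.
#'
#' @param montage_reduced use the reduced detector-only montage
#' @param delta_band,welch_window_s,welch_overlap slow-oscillation power
#' @param sw_duration_range,sw_amplitude_floor slow-wave detector
#' @param spindle spindle detector parameters (\code{\link{spindle_params}})
#' @param central_stat \code{"median"} or \code{"mean"} per-patient summary
#' @param min_stage_minutes inclusion-rule threshold (minutes)
#' @param n_iter,k classifier repetitions and folds
#' @param seed master seed
#' @return nested list of class \code{"run_config"}
#' @export
run_config <- function(montage_reduced = FALSE,
                       delta_band = c(0.5, 4), welch_window_s = 4,
                       welch_overlap = 0.5,
                       sw_duration_range = c(0.25, 1),
                       sw_amplitude_floor = 0,
                       spindle = spindle_params(),
                       central_stat = "median",
                       min_stage_minutes = 20,
                       n_iter = 5000L, k = 5L, seed = 1L) {
  structure(list(montage_reduced = montage_reduced,
                 delta_band = delta_band,
                 welch_window_s = welch_window_s,
                 welch_overlap = welch_overlap,
                 sw_duration_range = sw_duration_range,
                 sw_amplitude_floor = sw_amplitude_floor,
                 spindle = spindle, central_stat = central_stat,
                 min_stage_minutes = min_stage_minutes,
                 n_iter = as.integer(n_iter), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a \code{\link{run_config}}
#' @param path file path
#' @return \code{read_config}: the \code{run_config}
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  l <- yaml::read_yaml(path)
  do.call(run_config, l)
}

.central_fun <- function(config)
  if (identical(config$central_stat, "mean")) mean else stats::median

#' Extract the nine hemispheric sleep features of one night
#'
#' Runs the full per-night feature chain: bipolar and average-reference
#' derivations, N2/N3 segment extraction, delta power (N2+N3), slow-wave
#' detection on F3-C3/F7-T7/F4-C4/F8-T8 with the average-reference
#' cross-check (N2+N3), spindle detection on C3-FT9/C4-FT10 (N2 only), and
#' spindle-slow oscillation locking (ITC).
#'
#' @param rec referential \code{\link{eeg_recording}}
#' @param hyp \code{\link{hypnogram}}
#' @param config \code{\link{run_config}}
#' @param artifact_mask optional artifact data.frame
#' @return data.frame: \code{feature}, \code{value_left}, \code{value_right}
#' @export
extract_night_features <- function(rec, hyp, config = run_config(),
                                   artifact_mask = NULL) {
  montage <- default_montage(reduced = config$montage_reduced)
  fs <- rec$sampling_rate
  central <- .central_fun(config)
  bip <- derive_bipolar(rec, montage)
  avg <- derive_average_reference(rec)
  n2 <- suppressWarnings(extract_segments(rec, hyp, "N2", artifact_mask,
                                          config$min_stage_minutes))
  n3 <- suppressWarnings(extract_segments(rec, hyp, "N3", artifact_mask,
                                          config$min_stage_minutes))
  nrem <- combine_segments(n2, n3)

  dp <- compute_delta_power(bip, nrem, config$delta_band,
                            config$welch_window_s, config$welch_overlap)

  sw_chan <- intersect(slow_wave_channels(), bip$channel_labels)
  sw_side <- bip$sides[match(sw_chan, bip$channel_labels)]
  sw_events <- do.call(rbind, lapply(seq_along(sw_chan), function(i) {
    ch <- sw_chan[i]
    anode <- sub("-.*$", "", ch)
    ev <- detect_slow_waves(
      bip$signal[match(ch, bip$channel_labels), ],
      avg$signal[match(anode, avg$channel_labels), ],
      fs, nrem, config$sw_duration_range, config$sw_amplitude_floor,
      channel = ch)
    if (nrow(ev)) ev$side <- sw_side[i]
    ev
  }))
  sw <- summarize_slow_waves(sw_events, nrem, channels = sw_chan,
                             sides = sw_side, central = central)
  hemi <- sw$hemisphere
  sw_val <- function(col, side)
    hemi[[col]][hemi$side == side]

  sp_chan <- spindle_channels()
  sp <- lapply(c("left", "right"), function(side) {
    ch <- sp_chan[[side]]
    el <- strsplit(ch, "-", fixed = TRUE)[[1]]
    if (!all(el %in% rec$channel_labels))
      stop("spindle derivation needs electrodes: ",
           paste(el, collapse = ", "))
    tr <- rec$signal[match(el[1], rec$channel_labels), ] -
      rec$signal[match(el[2], rec$channel_labels), ]
    ev <- detect_spindles(tr, fs, n2, config$spindle, channel = ch)
    fe <- spindle_features(ev, tr, fs, n2, config$spindle$band,
                           central = central)
    lock <- if (nrow(ev) > 0) itc(slow_osc_phase_at_troughs(tr, fs, ev))
            else NA_real_
    list(events = ev, features = fe, locking = lock)
  })
  names(sp) <- c("left", "right")

  feat <- function(name, l, r)
    data.frame(feature = name, value_left = l, value_right = r,
               stringsAsFactors = FALSE)
  out <- rbind(
    feat("delta_power", dp$left, dp$right),
    feat("sw_density", sw_val("density_per_min", "left"),
         sw_val("density_per_min", "right")),
    feat("sw_amplitude", sw_val("amplitude_uV", "left"),
         sw_val("amplitude_uV", "right")),
    feat("sw_duration", sw_val("duration_s", "left"),
         sw_val("duration_s", "right")),
    feat("sw_slope", sw_val("slope_uV_s", "left"),
         sw_val("slope_uV_s", "right")),
    feat("sp_density", sp$left$features$density_per_min,
         sp$right$features$density_per_min),
    feat("sp_amplitude", sp$left$features$amplitude_uV,
         sp$right$features$amplitude_uV),
    feat("sp_duration", sp$left$features$duration_s,
         sp$right$features$duration_s),
    feat("sp_locking", sp$left$locking, sp$right$locking))
  attr(out, "quality") <- list(
    n2_minutes = segment_minutes(n2), n3_minutes = segment_minutes(n3),
    below_minimum = attr(n2, "below_minimum") || attr(n3, "below_minimum"))
  out
}

#' Extract pooled hemispheric features across a patient's nights
#'
#' Runs \code{\link{extract_night_features}} per night and pools nights by
#' the per-feature arithmetic mean (\code{\link{pool_nights}}); a patient
#' with a single night passes through flagged \code{single_night}.
#'
#' @param recordings list of referential \code{eeg_recording}s (one per
#'   night)
#' @param hypnograms list of matching \code{\link{hypnogram}}s
#' @param config \code{\link{run_config}}
#' @param patient_id identifier stored on the rows
#' @return data.frame: per-night rows (\code{night} = 1, 2, ...) plus pooled
#'   rows (\code{night} = "pooled")
#' @export
extract_patient_features <- function(recordings, hypnograms,
                                     config = run_config(),
                                     patient_id = "patient") {
  if (!length(recordings)) stop("at least one night is required")
  if (length(recordings) != length(hypnograms))
    stop("recordings and hypnograms must pair up")
  per_night <- lapply(seq_along(recordings), function(k) {
    f <- tryCatch(
      extract_night_features(recordings[[k]], hypnograms[[k]], config),
      error = function(e) stop("patient ", patient_id, ", night ", k, ": ",
                               conditionMessage(e), call. = FALSE))
    f$patient_id <- patient_id
    f$night <- as.character(k)
    f
  })
  tabs <- lapply(per_night, function(f)
    f[c("patient_id", "night", "feature", "value_left", "value_right")])
  pooled <- if (length(tabs) >= 2L) pool_nights(tabs[[1]], tabs[[2]])
            else pool_nights(tabs[[1]])
  nightly <- do.call(rbind, tabs)
  nightly$single_night <- length(tabs) < 2L
  rbind(nightly, pooled)
}

#' Run the full cohort study
#'
#' Per-patient feature extraction (signal level, or the ground-truth fast
#' path), lateralization indices, group statistics (Mann-Whitney for delta
#' power; Kruskal-Wallis + Dunn for the slow-wave and spindle families),
#' two-night stability, the paired epileptic vs non-epileptic hemisphere
#' comparison of spindle density, and the classifier stage: sleep-only run,
#' label-shuffle null, and (when IED counts are available) IED-only and
#' sleep+IED runs with a Sidak-adjusted comparison, Fisher's exact
#' contingency test, predictor importance and the low-IED-asymmetry subset
#' analysis. Statistics use pooled nights; the classifier uses night 1 only.
#'
#' @param cohort a \code{\link{simulate_cohort}} result (with signals when
#'   \code{from_truth = FALSE})
#' @param config \code{\link{run_config}}
#' @param from_truth skip signal processing and take the programmed LIs as
#'   the measured features (fast path)
#' @param with_ied include the IED LI in the classifier stage
#' @return list of class \code{"sleep_study"}: \code{features} (hemispheric
#'   table), \code{li} (long LI table), \code{group_tests},
#'   \code{night_stability}, \code{paired_spindle_density}, \code{runs}
#'   (named \code{sleep_cvrun}s), \code{run_comparison}, \code{fisher_p},
#'   \code{importance}, \code{low_asymmetry}, \code{config}
#' @export
run_full_study <- function(cohort, config = run_config(),
                           from_truth = FALSE, with_ied = TRUE) {
  groups <- vapply(cohort$patients, function(p) p$spec$epileptic_side, "")
  ids <- vapply(cohort$patients, function(p) p$spec$patient_id, "")
  if (min(table(groups)) < 2L) stop("need at least 2 patients per group")

  if (from_truth) {
    tr <- cohort$truth
    tab <- tr
    tab$night <- "pooled"
    night1 <- tr; night1$night <- "1"
    tab <- rbind(tab, night1)
  } else {
    tab <- do.call(rbind, lapply(seq_along(cohort$patients), function(i) {
      p <- cohort$patients[[i]]
      f <- extract_patient_features(
        lapply(p$nights, `[[`, "recording"),
        lapply(p$nights, `[[`, "hypnogram"),
        config, patient_id = ids[i])
      f$group <- groups[i]
      f
    }))
    if (with_ied) {
      ied <- do.call(rbind, lapply(seq_along(cohort$patients), function(i) {
        p <- cohort$patients[[i]]
        cnt <- sapply(p$nights, `[[`, "ied_counts")
        rows <- data.frame(patient_id = ids[i],
                           night = as.character(seq_len(ncol(cnt))),
                           feature = "ied_rate",
                           value_left = cnt["left", ],
                           value_right = cnt["right", ],
                           stringsAsFactors = FALSE)
        pooled <- data.frame(patient_id = ids[i], night = "pooled",
                             feature = "ied_rate",
                             value_left = mean(cnt["left", ]),
                             value_right = mean(cnt["right", ]))
        rows$single_night <- FALSE; pooled$single_night <- FALSE
        rbind(rows, pooled)
      }))
      ied$group <- groups[match(ied$patient_id, ids)]
      common <- intersect(names(tab), names(ied))
      tab <- rbind(tab[common], ied[common])
    }
  }
  tab$group <- groups[match(tab$patient_id, ids)]

  pooled <- tab[tab$night == "pooled", ]
  li_long <- .li_records(pooled)
  li_long$group <- groups[match(li_long$patient_id, ids)]
  sleep_li <- li_long[li_long$feature %in% sleep_features(), ]
  gtests <- group_compare(sleep_li)
  stab <- if (any(tab$night == "2")) night_stability(tab) else NULL
  paired_sp <- paired_hemisphere_compare(pooled, "sp_density")

  # classifier: night 1 only
  n1 <- tab[tab$night == "1", ]
  li1 <- .li_records(n1)
  wide <- function(features) {
    m <- sapply(features, function(f)
      li1$li[match(paste(ids, f), paste(li1$patient_id, li1$feature))])
    as.data.frame(m, row.names = ids)
  }
  sleep_x <- wide(sleep_features())
  runs <- list(sleep = run_repeated_cv(sleep_x, groups,
                                       n_iter = config$n_iter, k = config$k,
                                       seed = config$seed),
               shuffle = run_shuffle_null(sleep_x, groups,
                                          n_iter = config$n_iter,
                                          k = config$k,
                                          seed = config$seed + 1L))
  low_asym <- NULL
  if (with_ied && "ied_rate" %in% li1$feature) {
    both_x <- wide(c(sleep_features(), "ied_rate"))
    ied_x <- wide("ied_rate")
    runs$ied <- run_repeated_cv(ied_x, groups, n_iter = config$n_iter,
                                k = config$k, seed = config$seed + 2L)
    runs$sleep_ied <- run_repeated_cv(both_x, groups,
                                      n_iter = config$n_iter, k = config$k,
                                      seed = config$seed + 3L)
    low_asym <- low_asymmetry_subset(both_x, groups,
                                     n_iter = config$n_iter, k = config$k,
                                     seed = config$seed + 4L)
  }
  cmp <- compare_runs(runs)
  structure(list(features = tab, li = li_long, group_tests = gtests,
                 night_stability = stab,
                 paired_spindle_density = paired_sp,
                 runs = runs, run_comparison = cmp,
                 fisher_p = contingency_significance(runs$sleep),
                 importance = predictor_importance(runs$sleep),
                 low_asymmetry = low_asym, config = config),
            class = "sleep_study")
}

#' @export
print.sleep_study <- function(x, ...) {
  cat("<sleep_study>\n")
  cat("Group LI tests (adjusted):\n")
  print(x$group_tests[c("feature", "test", "p_adj", "es")])
  cat("\nClassification accuracy:\n")
  for (nm in names(x$runs))
    cat(sprintf("  %-10s %.1f%% (SD %.1f%%)\n", nm,
                100 * x$runs[[nm]]$mean_accuracy,
                100 * x$runs[[nm]]$sd_accuracy))
  cat(sprintf("Fisher's exact p (pooled contingency): %.3g\n", x$fisher_p))
  invisible(x)
}

#' Write the tables of a study to TSV files
#' @param study a \code{sleep_study}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  w(study$features, "features.tsv")
  w(study$li, "lateralization.tsv")
  w(study$group_tests, "group_tests.tsv")
  if (!is.null(study$night_stability))
    w(study$night_stability, "night_stability.tsv")
  acc <- data.frame(run = names(study$runs),
                    mean_accuracy = vapply(study$runs, function(r)
                      r$mean_accuracy, 0),
                    sd_accuracy = vapply(study$runs, function(r)
                      r$sd_accuracy, 0))
  w(acc, "classification.tsv")
  write_config(study$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
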