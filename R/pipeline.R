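# End-to-end orchestration: simulate -> extract (clinic, free-living) ->
# correlate -> report, reproducible under a single seed.

#' Canonical in-clinic feature names
#'
#' The 23 in-clinic biosensor and structured-testing features, in their
#' reporting names.
#' @export
TABLE1_FEATURES <- c(
  "Stance time", "Swing time", "Mobility activity time",
  "Turn angle—chest", "Turn duration—chest",
  "Turn velocity (max)—chest", "Turn velocity (mean)—chest",
  "Turn velocity (std)—chest",
  "Turn angle—ankle", "Turn duration—ankle",
  "Turn velocity (max)—ankle", "Turn velocity (mean)—ankle",
  "Turn velocity (std)—ankle",
  "Sway distance left–right", "Sway distance anterior–posterior",
  "Sway displacement left–right",
  "Sway displacement anterior–posterior",
  "Heart rate variability",
  "Mean PVT delay—Total", "Mean PVT delay—1 challenge",
  "Mean PVT delay—3 challenges", "Mean PVT delay—5 challenges",
  "Mean PVT delay—7 challenges")

#' Extract the in-clinic feature vector from one structured session
#'
#' Runs segmentation, the gait/turn/sway extractors, HRV and PVT
#' featurisation on one subject's session and returns the 23 canonical
#' in-clinic features.
#'
#' @param session one element of `simulate_cohort()$sessions` (or an
#'   equivalent list with `annotation`, `recordings`, `sway`, `ibi`,
#'   `pvt`).
#' @param gait_cfg,turn_cfg,sway_cfg extractor configurations.
#' @return one-row tibble: `subject` plus one column per feature (the
#'   names of [TABLE1_FEATURES]).
#' @export
extract_clinic_features <- function(session, gait_cfg = gait_config(),
                                    turn_cfg = turn_config(),
                                    sway_cfg = sway_config()) {
  ann <- session$annotation
  recs <- session$recordings
  subject <- attr(recs[[1]], "subject_id")
  fs <- attr(recs[[1]], "sample_rate_hz")
  windows <- segment_session(recs[[1]], ann)
  mobility <- windows[windows$label %in% c("tug", "walk_2min"), ]
  tug <- windows[windows$label == "tug", ]

  strides <- list()
  for (loc in c("left_ankle", "right_ankle")) {
    rec <- recs[[loc]]
    if (is.null(rec)) next
    foot <- if (grepl("left", loc)) "left" else "right"
    for (i in seq_len(nrow(mobility))) {
      seg <- slice_window(rec, mobility[i, ])
      if (nrow(seg) < 2 * fs) next
      st <- detect_gait_events(tibble::tibble(t = seg$t, gyro = seg$gy),
                               fs, gait_cfg, foot = foot)
      if (nrow(st)) strides[[length(strides) + 1]] <- st
    }
  }
  strides <- dplyr::bind_rows(strides)
  complete <- strides[!is.na(strides$stance_time_s), , drop = FALSE]

  turn_feats <- function(rec_name) {
    rec <- recs[[rec_name]]
    turns <- list()
    for (i in seq_len(nrow(tug))) {
      seg <- slice_window(rec, tug[i, ])
      tu <- detect_turns(tibble::tibble(t = seg$t, yaw = seg$gz), fs,
                         turn_cfg,
                         location = if (rec_name == "chest") "chest"
                                    else "ankle")
      if (nrow(tu)) turns[[length(turns) + 1]] <- tu
    }
    summarize_turns(dplyr::bind_rows(turns))
  }
  tc <- turn_feats("chest")
  ta <- turn_feats(if (!is.null(recs$left_ankle)) "left_ankle" else "chest")

  bal <- windows[windows$label == "balance_30s", ][1, ]
  sw <- compute_sway(session$sway$track, "displacement", window = bal,
                     config = sway_cfg)

  hrv <- tryCatch({
    ep <- hrv_epochs(session$ibi, epoch_s = 360, min_beats = 30)
    mean(ep$rmssd_ms[ep$valid])
  }, error = function(e) NA_real_)

  pvt <- pvt_features(session$pvt)

  out <- tibble::tibble(
    subject = subject,
    `Stance time` = if (nrow(complete)) median(complete$stance_time_s)
                    else NA_real_,
    `Swing time` = if (nrow(strides)) median(strides$swing_time_s)
                   else NA_real_,
    `Mobility activity time` = mean(tug$end_s - tug$start_s),
    `Turn angle—chest` = tc$mean_angle_deg,
    `Turn duration—chest` = tc$mean_duration_s,
    `Turn velocity (max)—chest` = tc$velocity_max_deg_s,
    `Turn velocity (mean)—chest` = tc$velocity_mean_deg_s,
    `Turn velocity (std)—chest` = tc$velocity_std_deg_s,
    `Turn angle—ankle` = ta$mean_angle_deg,
    `Turn duration—ankle` = ta$mean_duration_s,
    `Turn velocity (max)—ankle` = ta$velocity_max_deg_s,
    `Turn velocity (mean)—ankle` = ta$velocity_mean_deg_s,
    `Turn velocity (std)—ankle` = ta$velocity_std_deg_s,
    `Sway distance left–right` = sw$sway_distance_ml_mm,
    `Sway distance anterior–posterior` = sw$sway_distance_ap_mm,
    `Sway displacement left–right` = sw$sway_displacement_ml_mm,
    `Sway displacement anterior–posterior` = sw$sway_displacement_ap_mm,
    `Heart rate variability` = hrv,
    `Mean PVT delay—Total` = pvt$mean_delay_total_ms,
    `Mean PVT delay—1 challenge` = pvt$mean_delay_first_1_ms,
    `Mean PVT delay—3 challenges` = pvt$mean_delay_first_3_ms,
    `Mean PVT delay—5 challenges` = pvt$mean_delay_first_5_ms,
    `Mean PVT delay—7 challenges` = pvt$mean_delay_first_7_ms)
  stopifnot(identical(setdiff(names(out), "subject"), TABLE1_FEATURES))
  out
}

#' Extract free-living daily features for one subject
#'
#' Generates (or accepts) day streams, classifies activity, runs the
#' clinic gait extractor inside walking bouts and aggregates per day.
#'
#' @param profile one row of [subject_profiles()].
#' @param days number of monitored days.
#' @param seed cohort master seed.
#' @param day_minutes,fs passed to [simulate_freeliving_day()].
#' @param fl_cfg a [freeliving_config()].
#' @param gait_cfg a [gait_config()].
#' @return tibble of [daily_features()] rows, one per day, with `subject`.
#' @export
extract_freeliving_subject <- function(profile, days, seed = 1,
                                       day_minutes = 30, fs = 20,
                                       fl_cfg = freeliving_config(),
                                       gait_cfg = gait_config()) {
  out <- vector("list", days)
  for (dday in seq_len(days)) {
    sim <- simulate_freeliving_day(profile, dday, day_minutes = day_minutes,
                                   fs = fs, seed = seed)
    feats <- extract_windows(sim$wrist)
    bouts <- classify_activity(feats, fl_cfg)
    wb <- analyze_walking_bouts(list(ankle = sim$ankle), bouts,
                                gait_cfg = gait_cfg)
    out[[dday]] <- daily_features(bouts, wb$strides, feats, day = dday,
                                  config = fl_cfg)
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(subject = profile$subject_id, .before = 1)
}

#' Stance-time / MSFC-4 composite correlation on a simulated cohort
#'
#' Validation helper for parameter-recovery studies: simulates a cohort,
#' runs segmentation and the gait event detector on both ankle streams of
#' every subject's structured session, takes each subject's median stance
#' time, scores the clinical table, and returns the Spearman correlation
#' between extracted stance time and the MSFC-4 composite. The planted
#' effect makes this correlation negative (longer stance with worse
#' disability).
#'
#' @param seed cohort seed.
#' @param n_subjects cohort size.
#' @param fs clinic sample rate, Hz.
#' @param walk_s walk-test duration, s.
#' @param noise_scale effect-noise multiplier ([effect_config()]); 0 plants
#'   exact monotone maps.
#' @param clinic_noise_sd IMU noise, deg/s.
#' @return Spearman rho (numeric scalar).
#' @export
stance_composite_rho <- function(seed, n_subjects = 23, fs = 40,
                                 walk_s = 15, noise_scale = 1,
                                 clinic_noise_sd = 3) {
  coh <- simulate_cohort(n_subjects, effect_config(noise_scale), seed = seed,
                         fs = fs, walk_s = walk_s,
                         clinic_noise_sd = clinic_noise_sd)
  gait_cfg <- gait_config()
  stance <- vapply(coh$sessions, function(s) {
    win <- segment_session(s$recordings$left_ankle, s$annotation)
    mob <- win[win$label %in% c("tug", "walk_2min"), ]
    st <- list()
    for (loc in c("left_ankle", "right_ankle")) {
      for (i in seq_len(nrow(mob))) {
        seg <- slice_window(s$recordings[[loc]], mob[i, ])
        if (nrow(seg) < 2 * fs) next
        r <- detect_gait_events(tibble::tibble(t = seg$t, gyro = seg$gy),
                                fs, gait_cfg)
        if (nrow(r)) st[[length(st) + 1]] <- r
      }
    }
    st <- dplyr::bind_rows(st)
    median(st$stance_time_s, na.rm = TRUE)
  }, numeric(1))
  scores <- msfc4_scores(coh$clinical)
  as.numeric(spearman_rho(stance, scores$msfc4_composite))
}

#' Pipeline run configuration
#'
#' Every threshold defaults to the documented module default; the config
#' is serialised into the output directory for provenance.
#'
#' @param seed master seed for every source of randomness.
#' @param n_subjects cohort size.
#' @param days free-living days per subject.
#' @param day_minutes monitored minutes per free-living day.
#' @param out_dir output directory.
#' @param fs_clinic,fs_freeliving sample rates, Hz.
#' @param walk_s walk-test duration, s.
#' @param qvalue_pi0 `"smoother"` or `1` (BH mode).
#' @param target_hours weekly wear target for compliance grouping.
#' @param figures write ggplot figures (PNG) into the bundle.
#' @param effect an [effect_config()].
#' @param gait,turn,sway,freeliving extractor configurations.
#' @return config list of class `ms_config`.
#' @export
ms_config <- function(seed = 1, n_subjects = 23, days = 14,
                      day_minutes = 20, out_dir = tempfile("mswear_run_"),
                      fs_clinic = 50, fs_freeliving = 20, walk_s = 60,
                      qvalue_pi0 = "smoother", target_hours = 70,
                      figures = FALSE, effect = effect_config(),
                      gait = gait_config(), turn = turn_config(),
                      sway = sway_config(),
                      freeliving = freeliving_config()) {
  cfg <- as.list(environment())
  class(cfg) <- "ms_config"
  cfg
}

#' Run the full pipeline
#'
#' simulate -> extract (clinic + free-living) -> correlate -> report.
#' Deterministic under the config seed; a failing subject is logged and
#' excluded rather than aborting the run. Outputs: clinic and free-living
#' feature tables, correlation tables, variability curves, compliance
#' groups, the serialised config and a manifest with md5 checksums.
#'
#' @param config an [ms_config()].
#' @return list with the tables (`clinic_features`, `clinic_cortab`,
#'   `freeliving_features`, `freeliving_cortab`, `daily`, `varcurve`,
#'   `compliance`, `clinical_scores`) and `manifest` (output file paths).
#' @export
ms_run <- function(config = ms_config()) {
  if (!inherits(config, "ms_config")) validation_error("invalid config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  log_line("mswear run: seed %d, n = %d, %d free-living days",
           config$seed, config$n_subjects, config$days)

  cohort <- simulate_cohort(config$n_subjects, config$effect,
                            seed = config$seed, fs = config$fs_clinic,
                            walk_s = config$walk_s)
  scores <- msfc4_scores(cohort$clinical)
  clinic_feats <- list()
  for (sid in names(cohort$sessions)) {
    clinic_feats[[sid]] <- tryCatch(
      extract_clinic_features(cohort$sessions[[sid]], config$gait,
                              config$turn, config$sway),
      error = function(e) {
        log_line("subject %s clinic extraction failed: %s", sid,
                 conditionMessage(e))
        NULL
      })
  }
  clinic_features <- dplyr::bind_rows(clinic_feats)
  measures <- c("edss", "msfc4_composite", "z_25fw", "z_9hpt", "z_sdmt",
                "z_lcva")
  clinic_cortab <- correlation_table(
    clinic_features, dplyr::select(scores, "subject",
                                   dplyr::all_of(measures)),
    measures = measures, qvalue_pi0 = config$qvalue_pi0)

  daily <- list()
  for (i in seq_len(nrow(cohort$profiles))) {
    sid <- cohort$profiles$subject_id[i]
    daily[[sid]] <- tryCatch(
      extract_freeliving_subject(cohort$profiles[i, ], config$days,
                                 seed = config$seed,
                                 day_minutes = config$day_minutes,
                                 fs = config$fs_freeliving,
                                 fl_cfg = config$freeliving,
                                 gait_cfg = config$gait),
      error = function(e) {
        log_line("subject %s free-living extraction failed: %s", sid,
                 conditionMessage(e))
        NULL
      })
  }
  daily <- dplyr::bind_rows(daily)
  freeliving_features <- daily |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      `Stance time` = median(.data$median_stance_s, na.rm = TRUE),
      `Swing time` = median(.data$median_swing_s, na.rm = TRUE),
      `Idle minutes` = median(.data$idle_minutes),
      .groups = "drop")
  freeliving_cortab <- correlation_table(
    freeliving_features,
    dplyr::select(scores, "subject", dplyr::all_of(measures)),
    measures = measures, qvalue_pi0 = config$qvalue_pi0)

  k_grid <- unique(pmin(c(1, 2, 4, 7, 14, 28, 49), config$days))
  varcurve <- variability_vs_days(
    dplyr::transmute(daily, subject = .data$subject, day = .data$day,
                     value = .data$median_stance_s),
    k_grid = k_grid, seed = derive_seed(config$seed, 99))

  weekly <- daily |>
    dplyr::mutate(week = (.data$day - 1) %/% 7 + 1) |>
    dplyr::group_by(.data$subject, .data$week) |>
    dplyr::summarise(worn_hours = sum(.data$worn_hours), .groups = "drop")
  # the weekly target cannot exceed the monitored window of a condensed day
  eff_target <- min(config$target_hours, config$day_minutes * 7 / 60)
  comp <- compliance(weekly, target_hours = eff_target)

  paths <- c(
    clinic_features = "clinic_features.csv",
    clinic_cortab = "clinic_correlations.csv",
    freeliving_features = "freeliving_features.csv",
    freeliving_cortab = "freeliving_correlations.csv",
    daily = "daily_features.csv",
    varcurve = "variability_curves.csv",
    compliance = "compliance.csv",
    clinical_scores = "clinical_scores.csv")
  objs <- list(clinic_features = clinic_features,
               clinic_cortab = clinic_cortab,
               freeliving_features = freeliving_features,
               freeliving_cortab = freeliving_cortab,
               daily = daily, varcurve = varcurve, compliance = comp,
               clinical_scores = scores)
  written <- character()
  for (nm in names(paths)) {
    p <- file.path(config$out_dir, paths[[nm]])
    utils::write.csv(as.data.frame(objs[[nm]]), p, row.names = FALSE)
    written <- c(written, p)
  }
  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_ser <- config
  cfg_ser$out_dir <- NULL
  jsonlite::write_json(unclass(cfg_ser), cfg_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  written <- c(written, cfg_path)
  if (isTRUE(config$figures)) {
    figs <- list(correlations = plot_correlation_table(clinic_cortab),
                 variability = plot_variability_curve(varcurve))
    for (nm in names(figs)) {
      p <- file.path(config$out_dir, sprintf("fig_%s.png", nm))
      ggplot2::ggsave(p, figs[[nm]], width = 7, height = 5, dpi = 120)
      written <- c(written, p)
    }
  }
  manifest <- tibble::tibble(file = basename(written),
                             md5 = unname(tools::md5sum(written)))
  utils::write.csv(as.data.frame(manifest),
                   file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  log_line("run complete: %d files", nrow(manifest) + 1)
  c(objs, list(manifest = manifest, out_dir = config$out_dir))
}
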