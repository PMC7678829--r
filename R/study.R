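# End-to-end synthetic study driver and the standard segmentation
# benchmark. The study mirrors the in vivo design -- N participants, 7
# locomotion conditions (3 walking + 4 running speeds), 4 stance phases
# per condition -- but on synthetic recordings with known ground truth, at
# frame counts small enough for routine desk-scale runs.

#' Default synthetic study configuration
#'
#' Seven locomotion conditions with the per-condition stride-frequency
#' high-pass cutoffs 1.3, 1.8, 2.4, 2.6, 2.7, 2.9 and 3.1 Hz (walking 0.7,
#' 1.4, 2.0 m/s and running 2-5 m/s). Across conditions the injected
#' impact frequency and the injected tissue-oscillation frequency increase
#' strictly, emulating the empirical speed effect, so monotonicity of the
#' recovered input frequency and cumulative frequency is a recoverable
#' ground truth. Oscillation amplitudes follow a landmark-velocity cap of
#' ~ 60 mm/s (amplitude proportional to 1/frequency, capped at 2 mm), as
#' displacement spectra fall off with frequency and inter-frame landmark
#' motion at 80 Hz must stay within the tracker's search basin; the gait
#' component is 1 mm so that the oscillation power dominates what the
#' stride-frequency high-pass leaves of the gait motion. Stance durations
#' shorten from walking to fast running; frame counts per stance follow
#' from the 80 Hz frame rate.
#'
#' @param n_participants number of synthetic participants (default 3).
#' @param seed base seed; all per-participant / per-condition seeds derive
#'   from it.
#' @return list with `conditions` (data frame), `n_participants`,
#'   `n_stances`, `seed`, image geometry and scene texture parameters.
#' @export
default_study_config <- function(n_participants = 3L, seed = 20260101L) {
  conditions <- data.frame(
    label = c("walk_0.7", "walk_1.4", "walk_2.0",
              "run_2.0", "run_3.0", "run_4.0", "run_5.0"),
    gait = c("walking", "walking", "walking",
             "running", "running", "running", "running"),
    speed_m_s = c(0.7, 1.4, 2.0, 2.0, 3.0, 4.0, 5.0),
    stride_frequency_hz = c(1.3, 1.8, 2.4, 2.6, 2.7, 2.9, 3.1),
    stance_duration_s = c(0.75, 0.70, 0.65, 0.40, 0.38, 0.36, 0.35),
    impact_frequency_hz = c(8, 10, 12, 14, 16, 18, 20),
    oscillation_frequency_hz = c(5, 7.5, 10, 12.5, 15, 17.5, 20),
    oscillation_amplitude_mm = c(2.0, 1.6, 1.2, 0.96, 0.8, 0.69, 0.6),
    gait_amplitude_mm = rep(1, 7))
  list(conditions = conditions,
       n_participants = as.integer(n_participants),
       n_stances = 4L,
       seed = as.integer(seed),
       frame_rate_hz = 80,
       width_px = 608L, height_px = 288L,
       mm_per_px_y = 50 / 512,
       superficial = list(c0 = 95, c1 = 0.01, c2 = 0),
       deep = list(c0 = 195, c1 = 0.015, c2 = -5e-6),
       impact_amplitude_N = 600, active_peak_N = 1500,
       training_frames = 80L, training_label_every = 10L)
}

study_scene <- function(config, cond, phase = 0, n_frames) {
  scene_spec(width_px = config$width_px, height_px = config$height_px,
             n_frames = n_frames, frame_rate_hz = config$frame_rate_hz,
             mm_per_px_y = config$mm_per_px_y,
             superficial = config$superficial, deep = config$deep,
             gait = list(frequency_hz = cond$stride_frequency_hz,
                         amplitude_mm = cond$gait_amplitude_mm, phase_rad = phase),
             oscillations = list(list(frequency_hz = cond$oscillation_frequency_hz,
                                      amplitude_mm = cond$oscillation_amplitude_mm,
                                      phase_rad = phase / 2)))
}

train_participant_model <- function(config, participant_seed) {
  # train on the widest-motion condition so the PDM spans every condition
  conds <- config$conditions
  widest <- conds[which.max(conds$gait_amplitude_mm + conds$oscillation_amplitude_mm), ]
  spec <- study_scene(config, widest, phase = 0, n_frames = config$training_frames)
  gen <- generate_image_sequence(spec, seed = participant_seed)
  lab_idx <- seq(0L, config$training_frames - 1L, by = config$training_label_every)
  models <- lapply(c("superficial", "deep"), function(side) {
    labels <- lapply(lab_idx, function(f) {
      landmark_shape(gen$scene$landmark_truth[[side]][f + 1L, ], frame_index = f)
    })
    train_shape_model(gen$images, labels,
                      source_id = sprintf("participant_%d_%s", participant_seed, side))
  })
  names(models) <- c("superficial", "deep")
  models
}

standing_reference <- function(config, participant_seed, models) {
  spec <- scene_spec(width_px = config$width_px, height_px = config$height_px,
                     n_frames = 3L, frame_rate_hz = config$frame_rate_hz,
                     mm_per_px_y = config$mm_per_px_y,
                     superficial = config$superficial, deep = config$deep,
                     gait = list(frequency_hz = 1, amplitude_mm = 0, phase_rad = 0),
                     oscillations = list())
  gen <- generate_image_sequence(spec, seed = participant_seed + 7L)
  trajs <- segment_sequence(models, gen$images)
  stats::setNames(lapply(trajs, function(tr) {
    landmark_shape(colMeans(tr$y), x_columns = tr$x_columns)
  }), names(models))
}

#' Run the full synthetic study
#'
#' Simulates `n_participants` x 7 conditions x 4 stance phases: per
#' participant an ASM is trained on ground-truth labels of a synthetic
#' training sequence (both aponeuroses); per condition and stance a fresh
#' speckle scene is generated and segmented, landmark displacement
#' (relative to a segmented quiet-standing reference) is high-passed at
#' the condition's stride frequency and turned into 0-40 Hz spectra;
#' matching force traces give the impact input frequency, and EMG traces
#' the normalised wavelet intensity. The statistical layer then runs the
#' one-way (input frequency) and two-way (region x condition, per
#' aponeurosis) repeated-measures ANOVAs, Bonferroni post-hocs where main
#' effects are significant, and linear / quadratic trend fits of peak
#' power against input frequency.
#'
#' @param config a [default_study_config()] (possibly modified).
#' @param out_dir optional directory for CSV tables and the run log.
#' @return list: `input_frequency` (participant x condition data frame),
#'   `spectra` (per participant / condition / aponeurosis / region
#'   metrics), `condition_summary`, `anova`, `posthoc`, `trends`, `emg`,
#'   `log`. Identical configs (same seed) give identical reports.
#' @export
run_synthetic_study <- function(config = default_study_config(), out_dir = NULL) {
  conds <- config$conditions
  nc <- nrow(conds)
  np <- config$n_participants
  ns <- config$n_stances
  log_lines <- c(sprintf("synthetic study: %d participants x %d conditions x %d stances, base seed %d",
                         np, nc, ns, config$seed))
  input_rows <- list(); spec_rows <- list(); emg_rows <- list()

  for (p in seq_len(np)) {
    pseed <- config$seed + 1009L * p
    log_lines <- c(log_lines, sprintf("participant %d: seed %d", p, pseed))
    models <- train_participant_model(config, pseed)
    standing <- standing_reference(config, pseed, models)

    for (ci in seq_len(nc)) {
      cond <- conds[ci, ]
      n_frames <- as.integer(round(cond$stance_duration_s * config$frame_rate_hz))

      # --- kinetics: one trace holding all stances of this condition ---
      ftr <- generate_force_trace(gait = cond$gait,
                                  stance_duration_s = cond$stance_duration_s,
                                  impact_frequency_hz = cond$impact_frequency_hz,
                                  impact_amplitude_N = config$impact_amplitude_N,
                                  active_peak_N = config$active_peak_N,
                                  n_stances = ns,
                                  seed = pseed + 17L * ci)
      st <- detect_stance(lowpass_force(ftr))
      # traces are noiseless, so timing is read from the raw samples
      ifq <- input_frequency_per_stance(ftr, st)
      input_rows[[length(input_rows) + 1L]] <-
        data.frame(participant = p, condition = cond$label,
                   input_frequency_hz = mean(ifq$input_frequency_hz))

      # --- imaging: one fresh scene per stance phase ---
      per_stance <- vector("list", ns)
      for (s in seq_len(ns)) {
        sc_seed <- pseed + 101L * ci + s
        # stances start at a seeded random gait phase
        phase <- withr::with_seed(sc_seed, runif(1, 0, 2 * pi))
        spec <- study_scene(config, cond, phase = phase, n_frames = n_frames)
        gen <- generate_image_sequence(spec, seed = sc_seed)
        trajs <- segment_sequence(models, gen$images)
        names(trajs) <- c("superficial", "deep")
        per_stance[[s]] <- lapply(c("superficial", "deep"), function(side) {
          d <- transverse_displacement(trajs[[side]], standing[[side]],
                                       stance_metadata = list(condition = cond$label))
          d <- highpass_stride(d, cond$stride_frequency_hz)
          assign_regions(landmark_spectra(d))$regions
        })
      }
      for (side_i in 1:2) {
        side <- c("superficial", "deep")[side_i]
        regs <- do.call(rbind, lapply(per_stance, function(x) x[[side_i]]))
        agg <- stats::aggregate(cbind(peak_power_mm2, cumulative_frequency_hz) ~ region,
                                data = regs, FUN = mean)
        spec_rows[[length(spec_rows) + 1L]] <-
          cbind(data.frame(participant = p, condition = cond$label,
                           aponeurosis = side), agg)
      }

      # --- EMG: burst centred in stance, amplitude growing with speed ---
      etr <- generate_emg_trace(duration_s = max(1, cond$stance_duration_s + 0.4),
                                burst_windows = list(c(0.1, 0.1 + cond$stance_duration_s)),
                                burst_amplitude = 0.5 + 0.25 * ci,
                                seed = pseed + 31L * ci)
      emg_rows[[length(emg_rows) + 1L]] <-
        data.frame(participant = p, condition = cond$label,
                   key = sprintf("p%d_%s", p, cond$label),
                   peak_total_intensity = max(emg_intensity(etr)$total))
    }
  }

  input_df <- do.call(rbind, input_rows)
  spectra_df <- do.call(rbind, spec_rows)
  emg_df <- do.call(rbind, emg_rows)
  # normalise EMG peaks to the maximum across all conditions per participant
  emg_df$normalised_peak <- unlist(lapply(split(emg_df$peak_total_intensity, emg_df$participant),
                                          function(v) v / max(v)), use.names = FALSE)

  cond_levels <- conds$label
  input_mat <- matrix(input_df$input_frequency_hz, nrow = np, byrow = TRUE,
                      dimnames = list(NULL, cond_levels))
  condition_summary <- data.frame(condition = cond_levels,
                                  input_frequency_hz = colMeans(input_mat))
  for (side in c("superficial", "deep")) {
    sd_ <- spectra_df[spectra_df$aponeurosis == side, ]
    agg <- stats::aggregate(cbind(peak_power_mm2, cumulative_frequency_hz) ~ condition,
                            data = sd_, FUN = mean)
    agg <- agg[match(cond_levels, agg$condition), ]
    condition_summary[[paste0("peak_power_", side)]] <- agg$peak_power_mm2
    condition_summary[[paste0("cumulative_frequency_", side)]] <- agg$cumulative_frequency_hz
  }

  anova <- list(); posthoc <- list(); trends <- list()
  if (np >= 2 && nc >= 2) {
    anova$input_frequency <- rm_anova_one_way(input_mat)
    if (anova$input_frequency$effects$p[1] < 0.05) {
      posthoc$input_frequency <- bonferroni_posthoc(input_mat)
    }
    regions <- c("distal", "mid", "proximal")
    for (side in c("superficial", "deep")) {
      for (metric in c("peak_power_mm2", "cumulative_frequency_hz")) {
        arr <- array(NA_real_, dim = c(np, length(regions), nc),
                     dimnames = list(NULL, regions, cond_levels))
        sub <- spectra_df[spectra_df$aponeurosis == side, ]
        arr[cbind(sub$participant, match(sub$region, regions),
                  match(sub$condition, cond_levels))] <- sub[[metric]]
        anova[[paste(side, metric, sep = "_")]] <- rm_anova_two_way(arr)
      }
    }
  } else {
    log_lines <- c(log_lines,
                   "ANOVA skipped: needs >= 2 participants and >= 2 conditions; metrics still reported")
  }
  if (nc >= 4) {
    x <- condition_summary$input_frequency_hz
    for (side in c("superficial", "deep")) {
      y <- condition_summary[[paste0("peak_power_", side)]]
      trends[[paste0("peak_power_", side, "_linear")]] <- fit_trend(x, y, 1L)
      trends[[paste0("peak_power_", side, "_quadratic")]] <- fit_trend(x, y, 2L)
    }
  }

  report <- list(input_frequency = input_df, spectra = spectra_df,
                 condition_summary = condition_summary,
                 anova = anova, posthoc = posthoc, trends = trends,
                 emg = emg_df[, c("participant", "condition", "peak_total_intensity",
                                  "normalised_peak")],
                 log = log_lines, config = config)
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Write a study report to CSV tables plus a run log
#'
#' @param report a [run_synthetic_study()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$input_frequency, file.path(out_dir, "input_frequency.csv"),
            row.names = FALSE)
  write.csv(report$spectra, file.path(out_dir, "spectra_by_region.csv"),
            row.names = FALSE)
  write.csv(report$condition_summary, file.path(out_dir, "condition_summary.csv"),
            row.names = FALSE)
  write.csv(report$emg, file.path(out_dir, "emg_intensity.csv"), row.names = FALSE)
  if (length(report$anova)) {
    anova_df <- do.call(rbind, lapply(names(report$anova), function(nm) {
      cbind(analysis = nm, report$anova[[nm]]$effects)
    }))
    write.csv(anova_df, file.path(out_dir, "anova.csv"), row.names = FALSE)
  }
  if (length(report$trends)) {
    tr <- do.call(rbind, lapply(names(report$trends), function(nm) {
      t <- report$trends[[nm]]
      data.frame(fit = nm, degree = t$degree, r_squared = t$r_squared,
                 c0 = t$coefficients[1], c1 = t$coefficients[2],
                 c2 = if (t$degree == 2) t$coefficients[3] else NA_real_)
    }))
    write.csv(tr, file.path(out_dir, "trend_fits.csv"), row.names = FALSE)
  }
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Standard synthetic segmentation benchmark
#'
#' Generates the reference speckle scene (608 x 512 px, 50/512 mm/px depth
#' scale, 100 frames at 80 Hz; 1.3 Hz / 3 mm gait trajectory plus 8 Hz /
#' 1.5 mm and 13 Hz / 0.5 mm oscillation components), trains the ASM on
#' ground-truth labels of every 20th frame, segments the whole sequence
#' for both aponeuroses, and reports the mean absolute transverse landmark
#' error on the held-out frames in mm.
#'
#' @param seed scene seed (default 42).
#' @param n_frames number of frames (default 100).
#' @param label_every training-label cadence in frames (default 20).
#' @return list: `mean_abs_error_mm` (held-out frames, both aponeuroses),
#'   `per_side_mm`, `n_eval` (held-out frame x landmark comparisons),
#'   `trajectories`, `scene`.
#' @export
run_segmentation_benchmark <- function(seed = 42L, n_frames = 100L,
                                       label_every = 20L) {
  spec <- scene_spec(n_frames = n_frames,
                     gait = list(frequency_hz = 1.3, amplitude_mm = 3, phase_rad = 0),
                     oscillations = list(
                       list(frequency_hz = 8, amplitude_mm = 1.5, phase_rad = 0),
                       list(frequency_hz = 13, amplitude_mm = 0.5, phase_rad = 1)))
  gen <- generate_image_sequence(spec, seed = seed)
  lab_idx <- seq(0L, n_frames - 1L, by = label_every)
  models <- lapply(c("superficial", "deep"), function(side) {
    labels <- lapply(lab_idx, function(f) {
      landmark_shape(gen$scene$landmark_truth[[side]][f + 1L, ], frame_index = f)
    })
    train_shape_model(gen$images, labels, source_id = paste0("benchmark_", side))
  })
  trajs <- segment_sequence(models, gen$images)
  names(trajs) <- c("superficial", "deep")
  held_out <- setdiff(seq_len(n_frames), lab_idx + 1L)
  errs <- vapply(c("superficial", "deep"), function(side) {
    truth <- gen$scene$landmark_truth[[side]][held_out, , drop = FALSE]
    fit <- trajs[[side]]$y[held_out, , drop = FALSE]
    mean(abs(fit - truth)) * gen$images$mm_per_px_y
  }, numeric(1))
  list(mean_abs_error_mm = mean(errs), per_side_mm = errs,
       n_eval = length(held_out) * ncol(trajs$superficial$y) * 2L,
       trajectories = trajs, scene = gen$scene)
}
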