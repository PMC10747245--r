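# End-to-end orchestration: simulate a cohort, process both measurement
# streams per trial, segment cycles from force, extract parameters, and
# assemble the agreement report (MAE, CMC, ICC, Pearson, paired t-tests).

#' Analysis configuration
#'
#' @param cutoff_hz Low-pass cutoff for coordinate trajectories (Hz);
#'   `NULL` disables filtering.
#' @param filter_order Effective Butterworth order (default 4).
#' @param filter_convention `"effective"` (half-order design run
#'   forward-backward; biomechanics convention) or `"design"`.
#' @param max_gap Longest interpolatable keypoint gap, frames.
#' @param threshold_n GRF contact threshold, newtons.
#' @param min_contact_s,quiet_s Event-detection debounce windows, seconds.
#' @param min_cycle_frames Minimum gait-cycle length, video frames.
#' @param confidence_gate Keypoints at or below this confidence are missing.
#' @param mae_granularity `"waveform"` (MAE over the 101 normalized points;
#'   default) or `"parameters"` (MAE over the 12 discrete parameters).
#' @param offset_calibration Subtract each trial's mean AI-minus-reference
#'   angle offset before comparison (off by default).
#' @return A `run_config` list.
#' @export
run_config <- function(cutoff_hz = 6, filter_order = 4,
                       filter_convention = c("effective", "design"),
                       max_gap = 10, threshold_n = 20,
                       min_contact_s = 0.1, quiet_s = 0.05,
                       min_cycle_frames = 20, confidence_gate = 0,
                       mae_granularity = c("waveform", "parameters"),
                       offset_calibration = FALSE) {
  cfg <- list(
    cutoff_hz = cutoff_hz,
    filter_order = filter_order,
    filter_convention = match.arg(filter_convention),
    max_gap = max_gap,
    threshold_n = threshold_n,
    min_contact_s = min_contact_s,
    quiet_s = quiet_s,
    min_cycle_frames = min_cycle_frames,
    confidence_gate = confidence_gate,
    mae_granularity = match.arg(mae_granularity),
    offset_calibration = offset_calibration
  )
  class(cfg) <- "run_config"
  cfg
}

#' Simulate a cohort of participants with repeated gait trials
#'
#' Draws one profile per participant around `base_profile`: peak angles from
#' normal distributions with between-subject standard deviations near adult
#' normative spreads (hip flexion 6.0, hip extension 5.0, knee
#' loading-response flexion 8.6, knee swing flexion 7.6, ankle dorsiflexion
#' 4.2, plantarflexion 6.1 degrees), cycle duration N(base, 0.07 s), stance
#' fraction N(base, 0.015) and body mass N(base, 12 kg), all clamped to
#' physiologic ranges. Within a participant, trials re-jitter the peaks with
#' standard deviation `trial_sd` (trial-to-trial variability) and receive
#' fresh corruption seeds. The noise and dropout knobs are taken from
#' `base_profile` and applied to every trial.
#'
#' @param n_participants Number of participants (>= 3; reproducibility and
#'   ICC statistics need several subjects).
#' @param n_trials Trials per participant (default 3).
#' @param base_profile Center [gait_profile()].
#' @param seed Integer seed for all cohort-level randomness.
#' @param trial_sd Within-participant peak-angle jitter, degrees.
#' @return A `gait_cohort`: list of participants, each holding `profile`
#'   draws and a list of `gait_trial`s.
#' @export
simulate_cohort <- function(n_participants, n_trials = 3,
                            base_profile = gait_profile(), seed = 1,
                            trial_sd = 1.5) {
  if (n_participants < 3) stop("need at least 3 participants")
  if (n_trials < 1) stop("need at least 1 trial per participant")
  stopifnot(inherits(base_profile, "gait_profile"))
  set.seed(seed)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  participants <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    subj <- list(
      hip_peak_flex = clamp(stats::rnorm(1, base_profile$hip_peak_flex, 6.0),
                            15, 45),
      hip_peak_ext = clamp(stats::rnorm(1, base_profile$hip_peak_ext, 5.0),
                           3, 25),
      knee_stance_peak_flex = clamp(
        stats::rnorm(1, base_profile$knee_stance_peak_flex, 8.6), 6, 30),
      knee_swing_peak_flex = clamp(
        stats::rnorm(1, base_profile$knee_swing_peak_flex, 7.6), 45, 75),
      ankle_peak_dorsi = clamp(
        stats::rnorm(1, base_profile$ankle_peak_dorsi, 4.2), 6, 25),
      ankle_peak_plantar = clamp(
        stats::rnorm(1, base_profile$ankle_peak_plantar, 6.1), 5, 28),
      cycle_duration = clamp(
        stats::rnorm(1, base_profile$cycle_duration, 0.07), 0.9, 1.4),
      stance_fraction = clamp(
        stats::rnorm(1, base_profile$stance_fraction, 0.015), 0.55, 0.65),
      body_mass = clamp(stats::rnorm(1, base_profile$body_mass, 12), 40, 90)
    )
    trials <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      jit <- function(v, lo) max(v + stats::rnorm(1, 0, trial_sd), lo)
      prof <- gait_profile(
        cycle_duration = subj$cycle_duration,
        n_cycles = base_profile$n_cycles,
        sample_rate_video = base_profile$sample_rate_video,
        sample_rate_force = base_profile$sample_rate_force,
        hip_peak_flex = jit(subj$hip_peak_flex, 10),
        hip_peak_ext = jit(subj$hip_peak_ext, 1),
        knee_stance_peak_flex = jit(subj$knee_stance_peak_flex, 4),
        knee_swing_peak_flex = jit(subj$knee_swing_peak_flex, 40),
        ankle_peak_dorsi = jit(subj$ankle_peak_dorsi, 4),
        ankle_peak_plantar = jit(subj$ankle_peak_plantar, 3),
        stance_fraction = subj$stance_fraction,
        segment_lengths = base_profile$segment_lengths,
        pixel_scale = base_profile$pixel_scale,
        noise_sd = base_profile$noise_sd,
        dropout_prob_crossing = base_profile$dropout_prob_crossing,
        body_mass = subj$body_mass,
        speed = base_profile$speed,
        seed = sample.int(.Machine$integer.max, 1)
      )
      trials[[tr]] <- simulate_trial(prof)
    }
    participants[[p]] <- list(id = p, draws = subj, trials = trials)
  }
  cohort <- list(participants = participants, seed = seed,
                 n_trials = n_trials, base_profile = base_profile)
  class(cohort) <- "gait_cohort"
  cohort
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d participants x %d trials (seed %s)\n",
              length(x$participants), x$n_trials, format(x$seed)))
  invisible(x)
}

# Per-trial processing shared by run_validation(): preprocess both streams,
# derive cycle bounds from force, and collect per-cycle waveform agreement
# and parameters.
.analyze_trial <- function(trial, config, participant = NA, trial_id = NA) {
  prof <- trial$profile
  ai <- fill_gaps(trial$pose, max_gap = config$max_gap)
  ref <- trial$reference
  if (!is.null(config$cutoff_hz)) {
    ai <- lowpass(ai, cutoff_hz = config$cutoff_hz,
                  order = config$filter_order,
                  convention = config$filter_convention)
    ref <- lowpass(ref, cutoff_hz = config$cutoff_hz,
                   order = config$filter_order,
                   convention = config$filter_convention)
  }
  ang_ai <- joint_angles(ai, confidence_gate = config$confidence_gate)
  ang_ref <- joint_angles(ref, confidence_gate = config$confidence_gate)

  nfr <- n_frames(ref)
  wave_rows <- list()
  par_rows <- list()
  exclusions <- character(0)
  for (side in c("right", "left")) {
    if (side %in% ai$unusable_sides) {
      exclusions <- c(exclusions, sprintf(
        "participant %s trial %s: %s side unusable (long keypoint gap)",
        participant, trial_id, side))
      next
    }
    ev <- detect_events(trial$grf[[side]], threshold_n = config$threshold_n,
                        min_contact_s = config$min_contact_s,
                        quiet_s = config$quiet_s)
    fr <- prof$sample_rate_force
    vr <- prof$sample_rate_video
    ic_f <- to_video_frames(ev$ic, fr, vr)
    to_f <- ev$toe_off * vr / fr  # keep toe-off at force resolution
    bc <- build_cycles(ic_f, to_f, nfr,
                       min_cycle_frames = config$min_cycle_frames)
    exclusions <- c(exclusions, bc$excluded)
    if (!nrow(bc$cycles)) next
    for (ci in seq_len(nrow(bc$cycles))) {
      cyc <- bc$cycles[ci, ]
      norm_ai <- list()
      norm_ref <- list()
      bad <- FALSE
      for (joint in c("hip", "knee", "ankle")) {
        va <- ang_ai$angles[[side]][[joint]]
        va[ang_ai$flagged[[side]][[joint]]] <- NA_real_
        vr2 <- ang_ref$angles[[side]][[joint]]
        vr2[ang_ref$flagged[[side]][[joint]]] <- NA_real_
        na <- normalize_cycle(va, cyc$ic, cyc$next_ic,
                              min_cycle_frames = config$min_cycle_frames)
        nr <- normalize_cycle(vr2, cyc$ic, cyc$next_ic,
                              min_cycle_frames = config$min_cycle_frames)
        if (is.null(na) || is.null(nr)) {
          bad <- TRUE
          break
        }
        if (config$offset_calibration) na <- na - mean(na) + mean(nr)
        norm_ai[[joint]] <- na
        norm_ref[[joint]] <- nr
      }
      if (bad) {
        exclusions <- c(exclusions, sprintf(
          "participant %s trial %s: %s cycle at frame %d excluded (flagged frames)",
          participant, trial_id, side, cyc$ic))
        next
      }
      pa <- extract_parameters(norm_ai, cyc$stance_pct)
      pr <- extract_parameters(norm_ref, cyc$stance_pct)
      for (joint in c("hip", "knee", "ankle")) {
        wave_rows[[length(wave_rows) + 1L]] <- data.frame(
          participant = participant, trial = trial_id, side = side,
          cycle = ci, joint = joint,
          mae = mae(norm_ai[[joint]], norm_ref[[joint]]),
          cmc = cmc(rbind(norm_ai[[joint]], norm_ref[[joint]]))
        )
      }
      par_rows[[length(par_rows) + 1L]] <- data.frame(
        participant = participant, trial = trial_id, side = side,
        cycle = ci,
        source = rep(c("ai", "reference"), each = length(pa)),
        parameter = rep(names(pa), 2), value = c(pa, pr)
      )
    }
  }
  list(
    waveforms = if (length(wave_rows)) do.call(rbind, wave_rows) else NULL,
    parameters = if (length(par_rows)) do.call(rbind, par_rows) else NULL,
    exclusions = exclusions
  )
}

#' Run the full agreement validation over a cohort
#'
#' Processes every trial of every participant (gap filling and optional
#' zero-lag low-pass filtering of both streams, joint angles, force-derived
#' gait cycles applied identically to the pose and reference streams,
#' 101-point normalization, parameter extraction) and assembles the
#' agreement battery:
#'
#' * `mae_table` — per joint x side: mean MAE across participants with
#'   parametric 95% CI, accuracy band, and the right-vs-left paired t-test;
#' * `cmc_table` — per joint x side: mean (SD) CMC across participants,
#'   waveform-similarity band, undefined-cycle counts, right-vs-left test;
#' * `icc_table` — per parameter x side x source: ICC(1,k) across
#'   participants with 95% CI and reproducibility band;
#' * `parameter_table` — per parameter x side: AI and reference mean (SD)
#'   with the AI-vs-reference paired t-test;
#' * `pearson_table` — per parameter x side: Pearson r and p between
#'   participant-level AI and reference values;
#'
#' plus per-cycle intermediates and the exclusion log.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param config A [run_config()].
#' @return An `agreement_report` list.
#' @export
run_validation <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "gait_cohort"))
  if (!inherits(config, "run_config")) stop("config must be a run_config()")
  waves <- list()
  pars <- list()
  exclusions <- character(0)
  for (p in cohort$participants) {
    for (tr in seq_along(p$trials)) {
      res <- .analyze_trial(p$trials[[tr]], config, participant = p$id,
                            trial_id = tr)
      if (!is.null(res$waveforms)) waves[[length(waves) + 1L]] <- res$waveforms
      if (!is.null(res$parameters)) pars[[length(pars) + 1L]] <- res$parameters
      exclusions <- c(exclusions, res$exclusions)
    }
  }
  if (!length(waves)) stop("no analyzable cycles in the cohort")
  waves <- do.call(rbind, waves)
  pars <- do.call(rbind, pars)

  # --- waveform agreement: participant-level MAE and CMC per joint/side ---
  if (config$mae_granularity == "parameters") {
    pw <- stats::reshape(
      pars, direction = "wide", timevar = "source",
      idvar = c("participant", "trial", "side", "cycle", "parameter"))
    pw$joint <- sub("_.*$", "", pw$parameter)
    pw$abs_err <- abs(pw$value.ai - pw$value.reference)
    part_mae <- stats::aggregate(
      abs_err ~ participant + side + joint, data = pw, FUN = mean)
    names(part_mae)[names(part_mae) == "abs_err"] <- "mae"
  } else {
    part_mae <- stats::aggregate(mae ~ participant + side + joint,
                                 data = waves, FUN = mean)
  }
  part_cmc <- stats::aggregate(
    cmc ~ participant + side + joint, data = waves,
    FUN = function(z) mean(z, na.rm = TRUE), na.action = stats::na.pass)
  cmc_undef <- stats::aggregate(
    cmc ~ participant + side + joint, data = waves,
    FUN = function(z) sum(is.na(z)), na.action = stats::na.pass)
  names(cmc_undef)[names(cmc_undef) == "cmc"] <- "n_undefined"

  mae_rows <- list()
  cmc_rows <- list()
  for (joint in c("ankle", "knee", "hip")) {
    lr_t <- NA_real_
    jm <- part_mae[part_mae$joint == joint, ]
    jw <- stats::reshape(jm, direction = "wide", timevar = "side",
                         idvar = "participant")
    if (all(c("mae.right", "mae.left") %in% names(jw)) &&
        sum(stats::complete.cases(jw[, c("mae.right", "mae.left")])) >= 3) {
      cc <- stats::complete.cases(jw[, c("mae.right", "mae.left")])
      lr_t <- unname(paired_t(jw$mae.right[cc], jw$mae.left[cc])["p"])
    }
    for (side in c("right", "left")) {
      v <- jm$mae[jm$side == side]
      if (length(v) < 2) next
      ci <- mae_ci(v)
      mae_rows[[paste(joint, side)]] <- data.frame(
        joint = joint, side = side, n = length(v),
        mae = ci[["mean"]], ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
        band = interpret_band("AE", ci[["mean"]]),
        p_right_vs_left = lr_t
      )
    }
    jc <- part_cmc[part_cmc$joint == joint, ]
    ju <- cmc_undef[cmc_undef$joint == joint, ]
    lrc_t <- NA_real_
    jcw <- stats::reshape(jc, direction = "wide", timevar = "side",
                          idvar = "participant")
    if (all(c("cmc.right", "cmc.left") %in% names(jcw)) &&
        sum(stats::complete.cases(jcw[, c("cmc.right", "cmc.left")])) >= 3) {
      cc <- stats::complete.cases(jcw[, c("cmc.right", "cmc.left")])
      lrc_t <- unname(paired_t(jcw$cmc.right[cc], jcw$cmc.left[cc])["p"])
    }
    for (side in c("right", "left")) {
      v <- jc$cmc[jc$side == side]
      v <- v[is.finite(v)]
      if (!length(v)) next
      cmc_rows[[paste(joint, side)]] <- data.frame(
        joint = joint, side = side, n = length(v),
        cmc_mean = mean(v), cmc_sd = stats::sd(v),
        band = interpret_band("CMC", mean(v)),
        n_undefined_cycles = sum(ju$n_undefined[ju$side == side]),
        p_right_vs_left = lrc_t
      )
    }
  }

  # --- parameters: trial-level means feed ICC; participant means feed the
  # Pearson and fixed-error comparisons ---
  trial_par <- stats::aggregate(
    value ~ participant + trial + side + source + parameter, data = pars,
    FUN = mean)
  part_par <- aggregate_parameters(trial_par)

  icc_rows <- list()
  par_rows <- list()
  pear_rows <- list()
  for (side in c("right", "left")) {
    for (pname in PARAMETER_NAMES) {
      for (src in c("ai", "reference")) {
        sub <- trial_par[trial_par$side == side & trial_par$source == src &
                           trial_par$parameter == pname, ]
        m <- stats::reshape(sub[, c("participant", "trial", "value")],
                            direction = "wide", timevar = "trial",
                            idvar = "participant")
        m <- as.matrix(m[, -1, drop = FALSE])
        m <- m[stats::complete.cases(m), , drop = FALSE]
        if (nrow(m) >= 3 && ncol(m) >= 2) {
          ic <- icc_1_3(m)
          icc_rows[[paste(side, pname, src)]] <- data.frame(
            side = side, parameter = pname, source = src,
            icc = ic$icc, ci_low = ic$ci_low, ci_high = ic$ci_high,
            p_value = ic$p_value, n = ic$n, k = ic$k,
            band = interpret_band("ICC", ic$icc)
          )
        }
      }
      pp <- part_par[part_par$side == side & part_par$parameter == pname, ]
      ppw <- stats::reshape(pp[, c("participant", "source", "value")],
                            direction = "wide", timevar = "source",
                            idvar = "participant")
      if (all(c("value.ai", "value.reference") %in% names(ppw))) {
        cc <- stats::complete.cases(ppw[, c("value.ai", "value.reference")])
        va <- ppw$value.ai[cc]
        vrf <- ppw$value.reference[cc]
        if (length(va) >= 3) {
          tt <- paired_t(va, vrf)
          par_rows[[paste(side, pname)]] <- data.frame(
            side = side, parameter = pname, n = length(va),
            ai_mean = mean(va), ai_sd = stats::sd(va),
            ref_mean = mean(vrf), ref_sd = stats::sd(vrf),
            p_ai_vs_ref = tt[["p"]]
          )
          pr <- if (stats::sd(va) == 0 || stats::sd(vrf) == 0) {
            c(r = NA_real_, p = NA_real_)
          } else {
            pearson_r(va, vrf)
          }
          pear_rows[[paste(side, pname)]] <- data.frame(
            side = side, parameter = pname, n = length(va),
            r = pr[["r"]], p = pr[["p"]]
          )
        }
      }
    }
  }

  report <- list(
    mae_table = do.call(rbind, mae_rows),
    cmc_table = do.call(rbind, cmc_rows),
    icc_table = do.call(rbind, icc_rows),
    parameter_table = do.call(rbind, par_rows),
    pearson_table = do.call(rbind, pear_rows),
    waveforms = waves,
    parameters = pars,
    exclusions = exclusions,
    config = config,
    n_participants = length(cohort$participants),
    seed = cohort$seed
  )
  for (nm in c("mae_table", "cmc_table", "icc_table", "parameter_table",
               "pearson_table")) {
    if (!is.null(report[[nm]])) rownames(report[[nm]]) <- NULL
  }
  class(report) <- "agreement_report"
  report
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d participants, %d analyzed cycles, %d exclusions\n",
              x$n_participants, nrow(x$waveforms) / 3, length(x$exclusions)))
  if (!is.null(x$mae_table)) {
    cat("\nMAE (deg), mean (95% CI):\n")
    print(x$mae_table[, c("joint", "side", "mae", "ci_low", "ci_high",
                          "band")], digits = 3, row.names = FALSE)
  }
  if (!is.null(x$cmc_table)) {
    cat("\nCMC, mean (SD):\n")
    print(x$cmc_table[, c("joint", "side", "cmc_mean", "cmc_sd", "band")],
          digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write an agreement report to CSV files
#'
#' Emits the five summary tables, the per-cycle intermediates, the exclusion
#' log and a manifest (configuration, seed, package version) into a
#' directory. Outputs are deterministic for a fixed cohort and
#' configuration.
#'
#' @param report An [run_validation()] result.
#' @param path Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  tabs <- c("mae_table", "cmc_table", "icc_table", "parameter_table",
            "pearson_table", "waveforms", "parameters")
  for (nm in tabs) {
    if (is.null(report[[nm]])) next
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], f, row.names = FALSE)
    out <- c(out, f)
  }
  writeLines(report$exclusions, file.path(path, "exclusions.log"))
  manifest <- list(
    config = unclass(report$config),
    n_participants = report$n_participants,
    seed = report$seed,
    package_version = as.character(utils::packageVersion("planargait"))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(out, file.path(path, c("exclusions.log", "manifest.json"))))
}
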