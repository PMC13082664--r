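# Synthetic bilateral gait generator.
#
# Emulates the structure of multi-subject overground walking recordings:
# periodic bilateral gait with ~60% stance duty cycle, a half-cycle
# left/right offset, phase-dependent signal morphology on 12 shank IMU
# channels (3-axis acceleration + 3-axis angular velocity per shank),
# subject-level amplitude/cadence variability, and additive Gaussian noise.
# Ground-truth events and phase labels are carried alongside the signals so
# every downstream stage can be verified exactly.

imu_channel_names <- function() {
  as.vector(t(outer(c("left", "right"),
                    c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z"),
                    paste, sep = "_")))
}

default_template_amplitudes <- function() {
  amp <- matrix(0.4, nrow = 12L, ncol = 4L,
                dimnames = list(imu_channel_names(), phase_names))
  for (ch in 1:12) {
    amp[ch, ((ch - 1L) %% 4L) + 1L] <- 2.0   # dominant phase for this channel
    amp[ch, (ch %% 4L) + 1L] <- 1.0          # secondary phase
  }
  amp
}

#' Parameters of the synthetic bilateral gait generator
#'
#' @param n_subjects,trials_per_subject dataset shape.
#' @param trial_duration trial length in seconds.
#' @param fs sampling rate in Hz (default 200, matching the recording rate
#'   the pipeline expects before resampling to 100 Hz).
#' @param cycle_mean mean gait-cycle (stride) duration in seconds
#'   (default 1.1, typical of comfortable level walking).
#' @param cycle_cv coefficient of variation of per-cycle duration
#'   (default 0.03, healthy stride-time variability).
#' @param stance_fraction fraction of the cycle the foot is on the ground
#'   (default 0.60).
#' @param contralateral_offset phase lag of the left leg relative to the
#'   right, as a fraction of the cycle (default 0.50).
#' @param start_offset time of the first right heel strike in seconds
#'   (default 0.1); keeping it positive makes every rendered event
#'   recoverable from the contact channels (a stance already in progress at
#'   sample 0 has no detectable heel strike).
#' @param template_amplitudes 12 x 4 matrix of per-channel per-phase bump
#'   amplitudes (rows = IMU channels, columns = LR, LS, PSw, Sw). Default:
#'   each channel has one dominant and one secondary phase so the four
#'   phases are linearly discriminative from the channel profile.
#' @param noise_sigma additive Gaussian noise sd in signal units
#'   (default 0.3).
#' @param subject_amp_sd,subject_cadence_sd sd of the log-normal
#'   subject-level amplitude and cadence multipliers (defaults 0.10, 0.03).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the parameters and this seed.
#' @return object of class `gait_sim_params`.
#' @export
gait_sim_params <- function(n_subjects = 12L, trials_per_subject = 2L,
                            trial_duration = 60, fs = 200,
                            cycle_mean = 1.1, cycle_cv = 0.03,
                            stance_fraction = 0.60,
                            contralateral_offset = 0.50,
                            start_offset = 0.1,
                            template_amplitudes = default_template_amplitudes(),
                            noise_sigma = 0.3,
                            subject_amp_sd = 0.10, subject_cadence_sd = 0.03,
                            seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects),
            trials_per_subject = as.integer(trials_per_subject),
            trial_duration = trial_duration, fs = fs,
            cycle_mean = cycle_mean, cycle_cv = cycle_cv,
            stance_fraction = stance_fraction,
            contralateral_offset = contralateral_offset,
            start_offset = start_offset,
            template_amplitudes = template_amplitudes,
            noise_sigma = noise_sigma,
            subject_amp_sd = subject_amp_sd,
            subject_cadence_sd = subject_cadence_sd,
            seed = as.integer(seed))
  class(p) <- "gait_sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_msg(p$stance_fraction > 0 && p$stance_fraction < 1,
                "stance_fraction must be in (0, 1)")
  stopifnot_msg(p$contralateral_offset >= 0 && p$contralateral_offset < 1,
                "contralateral_offset must be in [0, 1)")
  stopifnot_msg(p$fs > 0, "fs must be positive")
  stopifnot_msg(p$cycle_mean > 0, "cycle_mean must be positive")
  stopifnot_msg(p$cycle_cv >= 0, "cycle_cv must be nonnegative")
  stopifnot_msg(p$noise_sigma >= 0, "noise_sigma must be nonnegative")
  stopifnot_msg(p$start_offset >= 0, "start_offset must be nonnegative")
  stopifnot_msg(all(dim(p$template_amplitudes) == c(12L, 4L)),
                "template_amplitudes must be a 12 x 4 matrix")
  invisible(p)
}

new_gait_trial <- function(imu, contact_left, contact_right, fs,
                           subject_id, trial_id,
                           events = NULL, phases = NULL,
                           reference_side = "right") {
  structure(list(imu = imu,
                 contact_left = as.integer(contact_left),
                 contact_right = as.integer(contact_right),
                 fs = fs, subject_id = subject_id, trial_id = trial_id,
                 events = events, phases = phases,
                 reference_side = reference_side),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  n <- nrow(x$imu)
  cat(sprintf("<gait_trial> subject %s trial %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$trial_id, n, x$fs, n / x$fs))
  if (!is.null(x$phases)) {
    lab <- sum(x$phases >= 0)
    cat(sprintf("  labeled: %d/%d samples, reference side %s\n", lab, n, x$reference_side))
  }
  invisible(x)
}

#' Draw a bilateral heel-strike / toe-off schedule for one trial
#'
#' Right-leg heel strikes are `start_offset` plus the cumulative sum of
#' per-cycle durations drawn around `cycle_mean * cadence_factor` with
#' coefficient of variation `cycle_cv`; each right toe off follows its heel
#' strike by `stance_fraction` of that cycle, and left events are the right
#' events shifted by `contralateral_offset` of the cycle. Events at or
#' beyond the trial end are dropped.
#'
#' @param params a [gait_sim_params()] object.
#' @param cadence_factor subject-level multiplier on cycle duration.
#' @return list with `gait_events` elements `left` and `right` (0-based
#'   sample indices, strictly increasing, HS/TO alternating).
#' @export
simulate_subject_cycles <- function(params, cadence_factor = 1) {
  validate_sim_params(params)
  if (params$trial_duration < 2 * params$cycle_mean) {
    stop("trial_duration must cover at least two mean cycles", call. = FALSE)
  }
  n_samples <- round(params$trial_duration * params$fs)
  mean_cyc <- params$cycle_mean * cadence_factor
  n_cyc <- ceiling(params$trial_duration / mean_cyc) + 3L
  dur <- mean_cyc * (1 + params$cycle_cv * stats::rnorm(n_cyc))
  dur <- pmax(dur, 0.2 * mean_cyc)
  hs_t <- params$start_offset + cumsum(c(0, dur[-n_cyc]))
  to_t <- hs_t + params$stance_fraction * dur
  shift <- params$contralateral_offset * dur
  build <- function(hs, to) {
    ev <- rbind(data.frame(type = "HS", index = round(hs * params$fs)),
                data.frame(type = "TO", index = round(to * params$fs)))
    ev <- ev[order(ev$index), , drop = FALSE]
    ev <- ev[ev$index < n_samples, , drop = FALSE]
    ev
  }
  right <- build(hs_t, to_t)
  left <- build(hs_t + shift, to_t + shift)
  out <- list(
    left = new_gait_events(left$type, left$index, side = "left"),
    right = new_gait_events(right$type, right$index, side = "right")
  )
  validate_events(out$left, "simulated left events")
  validate_events(out$right, "simulated right events")
  out
}

contact_from_events <- function(events, n_samples) {
  x <- integer(n_samples)
  ev <- events
  # pair HS -> TO; a leading TO means stance from sample 0, a trailing HS
  # means stance to the end of the trial
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  if (nrow(ev) > 0L && ev$type[1L] == "TO") {
    starts <- 0L; ends <- ev$index[1L]; i <- 2L
  }
  while (i <= nrow(ev)) {
    s <- ev$index[i]
    e <- if (i + 1L <= nrow(ev)) ev$index[i + 1L] else n_samples
    starts <- c(starts, s); ends <- c(ends, e)
    i <- i + 2L
  }
  for (j in seq_along(starts)) {
    if (ends[j] > starts[j]) x[(starts[j] + 1L):ends[j]] <- 1L
  }
  x
}

#' Render IMU and contact signals for a given event schedule
#'
#' Contact channels are 1 exactly on each \[HS, TO) stance interval. Each
#' IMU channel is a sum of smooth Gaussian bumps, one per occurrence of each
#' phase (centered at the phase-run midpoint, width a quarter of the run),
#' scaled by `template_amplitudes[channel, phase] * amp_factor`, plus
#' additive Gaussian noise of sd `noise_sigma`. Ground-truth phases come
#' from [label_phases()] applied to the schedule.
#'
#' @param events list with `left`/`right` `gait_events`.
#' @param params a [gait_sim_params()] object.
#' @param amp_factor subject-level amplitude multiplier.
#' @param subject_id,trial_id identifiers stored on the trial.
#' @return a `gait_trial` with `imu` (n x 12 matrix), `contact_left`,
#'   `contact_right`, ground-truth `events` and `phases`.
#' @export
render_trial <- function(events, params, amp_factor = 1,
                         subject_id = "S01", trial_id = "T1") {
  validate_sim_params(params)
  n <- round(params$trial_duration * params$fs)
  phases <- label_phases(events$left, events$right, n, reference_side = "right")
  imu <- matrix(0, n, 12L, dimnames = list(NULL, imu_channel_names()))
  r <- rle(as.integer(phases))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  t_all <- seq_len(n)
  for (k in seq_along(r$values)) {
    ph <- r$values[k]
    if (ph < 0L) next
    center <- (starts[k] + ends[k]) / 2
    sdw <- max(r$lengths[k] / 4, 1)
    lo <- max(1L, floor(center - 4 * sdw))
    hi <- min(n, ceiling(center + 4 * sdw))
    bump <- exp(-((t_all[lo:hi] - center)^2) / (2 * sdw^2))
    amps <- params$template_amplitudes[, ph + 1L] * amp_factor
    imu[lo:hi, ] <- imu[lo:hi, ] + outer(bump, amps)
  }
  if (params$noise_sigma > 0) {
    imu <- imu + matrix(stats::rnorm(n * 12L, sd = params$noise_sigma), n, 12L)
  }
  new_gait_trial(imu,
                 contact_from_events(events$left, n),
                 contact_from_events(events$right, n),
                 fs = params$fs, subject_id = subject_id, trial_id = trial_id,
                 events = events, phases = phases)
}

#' Generate a full synthetic dataset
#'
#' Draws one amplitude multiplier and one cadence multiplier per subject
#' (log-normal, sd `subject_amp_sd` / `subject_cadence_sd`) so trials of the
#' same subject are correlated, then simulates and renders
#' `n_subjects * trials_per_subject` trials. Fully reproducible from
#' `params$seed`.
#'
#' @param params a [gait_sim_params()] object.
#' @return list of `gait_trial` objects.
#' @export
generate_dataset <- function(params) {
  validate_sim_params(params)
  with_seed(child_seed(params$seed, "simulate"), {
    trials <- vector("list", params$n_subjects * params$trials_per_subject)
    k <- 0L
    for (s in seq_len(params$n_subjects)) {
      sid <- sprintf("S%02d", s)
      amp_factor <- exp(stats::rnorm(1, sd = params$subject_amp_sd))
      cadence <- exp(stats::rnorm(1, sd = params$subject_cadence_sd))
      for (tr in seq_len(params$trials_per_subject)) {
        k <- k + 1L
        ev <- simulate_subject_cycles(params, cadence_factor = cadence)
        trials[[k]] <- render_trial(ev, params, amp_factor = amp_factor,
                                    subject_id = sid,
                                    trial_id = sprintf("T%d", tr))
      }
    }
    trials
  })
}
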