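# Synthetic fNIRS generator: seeded recordings with task-evoked hemodynamics,
# hemispheric lateralization and physiological noise. Everything downstream
# (filtering, epoching, GASF encoding, GAN training) is testable on its output.

#' Simulation configuration for the synthetic fNIRS generator
#'
#' Bundles every knob of [generate_recording()]. Defaults emulate a
#' finger/foot-tapping block design: trials roughly every 30 s (uniformly
#' jittered by +/- 5 s), a canonical double-gamma hemodynamic response
#' peaking at 6 s, and physiological nuisance components at cardiac
#' (1-1.5 Hz), respiratory (0.2-0.5 Hz) and Mayer-wave (~0.1 Hz)
#' frequencies plus a per-channel DC offset, slow drift and white noise.
#'
#' @param n_trials_per_class trials per task class (RHT/LHT/FT); >= 1.
#' @param sampling_rate sampling rate in Hz. 10 Hz keeps a 30 s epoch at
#'   300 samples and satisfies Nyquist for cardiac noise.
#' @param n_channels number of measurement channels; the first half is
#'   tagged left hemisphere, the second half right.
#' @param inter_trial_interval mean onset-to-onset spacing, seconds.
#' @param iti_jitter half-width of the uniform onset jitter, seconds.
#' @param task_duration tapping-block duration, seconds.
#' @param hrf_peak_time time-to-peak of the hemodynamic response, seconds.
#' @param undershoot_ratio post-stimulus undershoot depth relative to peak.
#' @param effect_amplitude peak evoked amplitude of the contralateral
#'   \eqn{\Delta}HbO response, in the recording's (micromolar-scaled) units.
#' @param noise_amplitudes named numeric vector with entries `cardiac`,
#'   `respiration`, `mayer`, `drift`, `white` (all >= 0).
#' @param cardiac_freq,respiration_freq,mayer_freq nuisance frequencies in
#'   Hz; must lie in 1-1.5, 0.2-0.5 and 0.05-0.15 respectively.
#' @param seed integer seed; [generate_recording()] is a pure function of
#'   the full configuration including this seed.
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [generate_recording()]
#' @export
#' @examples
#' cfg <- sim_config(n_trials_per_class = 2, seed = 7)
#' rec <- generate_recording(cfg)
#' rec
sim_config <- function(n_trials_per_class = 10,
                       sampling_rate = 10,
                       n_channels = 20,
                       inter_trial_interval = 30,
                       iti_jitter = 5,
                       task_duration = 10,
                       hrf_peak_time = 6,
                       undershoot_ratio = 1 / 6,
                       effect_amplitude = 1,
                       noise_amplitudes = c(cardiac = 0.2, respiration = 0.15,
                                            mayer = 0.25, drift = 0.2,
                                            white = 0.1),
                       cardiac_freq = 1.2,
                       respiration_freq = 0.3,
                       mayer_freq = 0.1,
                       seed = 1L) {
  req <- c("cardiac", "respiration", "mayer", "drift", "white")
  if (!all(req %in% names(noise_amplitudes))) {
    stop_invalid("noise_amplitudes must name: ", paste(req, collapse = ", "))
  }
  noise_amplitudes <- noise_amplitudes[req]
  if (any(noise_amplitudes < 0)) stop_invalid("noise amplitudes must be >= 0")
  if (n_trials_per_class < 1) stop_invalid("n_trials_per_class must be >= 1")
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be positive")
  if (cardiac_freq < 1 || cardiac_freq > 1.5)
    stop_invalid("cardiac_freq must lie in [1, 1.5] Hz")
  if (respiration_freq < 0.2 || respiration_freq > 0.5)
    stop_invalid("respiration_freq must lie in [0.2, 0.5] Hz")
  if (mayer_freq < 0.05 || mayer_freq > 0.15)
    stop_invalid("mayer_freq must lie in [0.05, 0.15] Hz")
  if (n_channels < 2 || n_channels %% 2 != 0)
    stop_invalid("n_channels must be an even number >= 2")
  structure(list(
    n_trials_per_class = as.integer(n_trials_per_class),
    sampling_rate = sampling_rate,
    n_channels = as.integer(n_channels),
    inter_trial_interval = inter_trial_interval,
    iti_jitter = iti_jitter,
    task_duration = task_duration,
    hrf_peak_time = hrf_peak_time,
    undershoot_ratio = undershoot_ratio,
    effect_amplitude = effect_amplitude,
    noise_amplitudes = noise_amplitudes,
    cardiac_freq = cardiac_freq,
    respiration_freq = respiration_freq,
    mayer_freq = mayer_freq,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' The response is a difference of two gamma densities: a main lobe with
#' mode at `peak_time` and an undershoot lobe peaking 10 s later, scaled by
#' `undershoot_ratio`. The kernel is zero at t = 0 and normalized so its
#' maximum is 1.
#'
#' @param time_grid non-negative, strictly increasing time points (seconds).
#' @param peak_time time-to-peak in seconds.
#' @param undershoot_ratio undershoot amplitude relative to the main lobe;
#'   0 gives a non-negative kernel.
#' @return numeric vector of kernel values on `time_grid`.
#' @export
#' @examples
#' t <- seq(0, 30, by = 0.1)
#' h <- hrf_kernel(t, peak_time = 6)
#' t[which.max(h)]
hrf_kernel <- function(time_grid, peak_time = 6, undershoot_ratio = 1 / 6) {
  if (length(time_grid) == 0) stop_invalid("time_grid must be non-empty")
  if (any(time_grid < 0)) stop_invalid("time_grid must be non-negative")
  if (length(time_grid) > 1 && any(diff(time_grid) <= 0))
    stop_invalid("time_grid must be strictly increasing")
  if (peak_time <= 0) stop_invalid("peak_time must be positive")
  # gamma density with unit scale has its mode at shape - 1
  main <- dgamma(time_grid, shape = peak_time + 1, scale = 1)
  under <- dgamma(time_grid, shape = peak_time + 11, scale = 1)
  h <- main / max(dgamma(peak_time, shape = peak_time + 1, scale = 1)) -
    undershoot_ratio * under / dgamma(peak_time + 10, shape = peak_time + 11, scale = 1)
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

# Evoked regressor: task boxcar convolved with the HRF, sampled on the full
# recording grid, normalized to unit peak. delay shifts the onset; widen
# stretches the response (used for the weaker, later ipsilateral response).
evoked_course <- function(n_samples, fs, onset, duration, cfg,
                          delay = 0, widen = 1) {
  kern_t <- seq(0, 32 * widen, by = 1 / fs)
  kern <- hrf_kernel(kern_t / widen, cfg$hrf_peak_time, cfg$undershoot_ratio)
  box <- rep(1, max(1L, round(duration * fs)))
  resp <- stats::convolve(box, rev(kern), type = "open")
  m <- max(abs(resp))
  if (m > 0) resp <- resp / m
  out <- numeric(n_samples)
  i0 <- round((onset + delay) * fs) + 1L
  span <- i0:min(i0 + length(resp) - 1L, n_samples)
  out[span] <- resp[seq_along(span)]
  out
}

#' Generate a synthetic multichannel fNIRS recording
#'
#' Produces a `nirs_recording` with `3 * n_trials_per_class` task events in
#' randomized order. Evoked responses follow the classic motor lateralization
#' pattern: hand taps raise \eqn{\Delta}HbO contralaterally (with a weaker,
#' delayed and broadened ipsilateral response) and lower \eqn{\Delta}HbR;
#' foot taps lower \eqn{\Delta}HbO and raise \eqn{\Delta}HbR bilaterally.
#' Physiological noise is injected as sinusoids with per-channel random
#' phase at the cardiac, respiratory and Mayer-wave frequencies, plus a DC
#' offset, a slow linear drift and white noise. The output is a pure
#' function of `cfg` (bit-identical for identical configurations).
#'
#' @param cfg a [sim_config()].
#' @return object of class `nirs_recording`: list with channels x samples
#'   matrices `hbo` and `hbr`, `sampling_rate`, `channel_side`, and an
#'   `events` tibble (`onset`, `duration`, `label`).
#' @export
generate_recording <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_invalid("cfg must be a sim_config")
  if (cfg$sampling_rate < 2 * cfg$cardiac_freq) {
    stop_invalid("sampling_rate ", cfg$sampling_rate,
                 " Hz aliases cardiac noise at ", cfg$cardiac_freq,
                 " Hz (need >= 2x)")
  }
  fs <- cfg$sampling_rate
  nc <- cfg$n_channels
  n_ev <- 3L * cfg$n_trials_per_class
  with_seed(cfg$seed, {
    labels <- task_label(sample(rep(0:2, cfg$n_trials_per_class)))
    gaps <- cfg$inter_trial_interval +
      runif(n_ev - 1, -cfg$iti_jitter, cfg$iti_jitter)
    onsets <- cumsum(c(20, gaps))
    onsets <- round(onsets * fs) / fs  # snap to the sample grid
    total_s <- onsets[n_ev] + cfg$task_duration + 35
    ns <- as.integer(round(total_s * fs))

    side <- rep(c("left", "right"), each = nc / 2)
    gain <- runif(nc, 0.8, 1.2)  # per-channel optode coupling variation

    hbo <- matrix(0, nc, ns)
    hbr <- matrix(0, nc, ns)
    amp <- cfg$effect_amplitude
    for (i in seq_len(n_ev)) {
      contra <- evoked_course(ns, fs, onsets[i], cfg$task_duration, cfg)
      if (labels[i] == "FT") {
        # bilateral: HbO decreases, HbR increases; the foot response seen by
        # lateral optodes is brisker and narrower than the hand responses,
        # which keeps the three classes separable in shape as well as sign
        # (the GASF encoding is invariant to a global sign flip, so sign
        # alone cannot carry class identity on a single channel)
        ft <- evoked_course(ns, fs, onsets[i], cfg$task_duration, cfg,
                            widen = 0.55)
        hbo <- hbo + gain %o% (-0.6 * amp * ft)
        hbr <- hbr + gain %o% (0.3 * amp * ft)
      } else {
        ipsi <- evoked_course(ns, fs, onsets[i], cfg$task_duration, cfg,
                              delay = 2.5, widen = 1.8)
        contra_side <- if (labels[i] == "RHT") "left" else "right"
        g_con <- gain * (side == contra_side)
        g_ips <- gain * (side != contra_side)
        hbo <- hbo + g_con %o% (amp * contra) + g_ips %o% (0.45 * amp * ipsi)
        hbr <- hbr - g_con %o% (amp / 3 * contra) - g_ips %o% (0.15 * amp * ipsi)
      }
    }

    t <- (seq_len(ns) - 1) / fs
    na <- cfg$noise_amplitudes
    for (ch in seq_len(nc)) {
      for (chrom in c("hbo", "hbr")) {
        physio <-
          na[["cardiac"]] * sin(2 * pi * cfg$cardiac_freq * t + runif(1, 0, 2 * pi)) +
          na[["respiration"]] * sin(2 * pi * cfg$respiration_freq * t + runif(1, 0, 2 * pi)) +
          na[["mayer"]] * sin(2 * pi * cfg$mayer_freq * t + runif(1, 0, 2 * pi))
        dc <- na[["drift"]] * rnorm(1)
        slope <- na[["drift"]] * rnorm(1, sd = 0.5) / max(t)
        white <- rnorm(ns, sd = na[["white"]])
        add <- physio + dc + slope * t + white
        if (chrom == "hbo") hbo[ch, ] <- hbo[ch, ] + add
        else hbr[ch, ] <- hbr[ch, ] + add
      }
    }
    dimnames(hbo) <- dimnames(hbr) <-
      list(sprintf("CH%02d", seq_len(nc)), NULL)

    structure(list(
      hbo = hbo,
      hbr = hbr,
      sampling_rate = fs,
      channel_side = side,
      events = tibble::tibble(onset = onsets,
                              duration = rep(cfg$task_duration, n_ev),
                              label = labels)
    ), class = "nirs_recording")
  })
}

#' Event labels of a recording, in event order
#'
#' @param recording a `nirs_recording`.
#' @return factor of task labels, one per event.
#' @export
true_labels <- function(recording) {
  stopifnot(inherits(recording, "nirs_recording"))
  if (nrow(recording$events) < 1) stop_invalid("recording has no events")
  recording$events$label
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat("<nirs_recording> ", nrow(x$hbo), " channels x ", ncol(x$hbo),
      " samples @ ", x$sampling_rate, " Hz (",
      round(ncol(x$hbo) / x$sampling_rate), " s), ",
      nrow(x$events), " events\n", sep = "")
  print(table(x$events$label))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_trials_per_class, " trials/class, ",
      x$n_channels, " channels @ ", x$sampling_rate,
      " Hz, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
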