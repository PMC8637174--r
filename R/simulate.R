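#' Sample an auditory-probe event train
#'
#' Draws probe onsets for one block with inter-probe intervals i.i.d.
#' continuous-uniform on the configured ITI range. The first onset sits at
#' 1 s plus the pre-stimulus epoch window after block start; the last onset
#' leaves at least 0.8 s plus a 5-s tail before block end, so every ERP
#' epoch and a trailing spectral epoch fit inside the recording.
#'
#' @param config an `mwl_config`.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return data.frame with columns `onset_sample` (integer) and `onset_s`.
#' @export
sample_event_train <- function(config, seed = NULL) {
  draw <- function() {
    lo <- config$iti_range_s[1]; hi <- config$iti_range_s[2]
    first <- 1 + abs(erp_epoch_span()[1])
    limit <- config$block_duration_s - (erp_epoch_span()[2] + 5)
    if (limit < first + lo)
      stop("block too short to hold at least 2 probe events")
    onsets <- first
    repeat {
      nxt <- onsets[length(onsets)] + stats::runif(1, lo, hi)
      if (nxt > limit) break
      onsets <- c(onsets, nxt)
    }
    if (length(onsets) < 2L)
      stop("block too short to hold at least 2 probe events")
    data.frame(onset_sample = as.integer(round(onsets * config$sampling_rate_hz)),
               onset_s = onsets)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Render the noiseless template of one evoked component
#'
#' The forward model of a component: a temporal Gaussian at the peak
#' latency, scaled by polarity, base amplitude, the condition's effect
#' factor and the spatial topography.
#'
#' @param spec an `mwl_component`.
#' @param task `"nback"` or `"matb"`; @param difficulty `"easy"` or `"hard"`.
#' @param time_axis_s numeric vector of times (s) relative to probe onset.
#' @param difficulty condition level.
#' @return channel x time matrix in microvolts.
#' @export
render_component <- function(spec, task, difficulty, time_axis_s) {
  nch <- length(spec$topography)
  eff <- effect_factor(spec, task, difficulty, nch)
  bump <- exp(-(time_axis_s - spec$peak_latency_s)^2 / (2 * spec$width_s^2))
  amp <- spec$polarity * spec$base_amplitude_uV * eff * spec$topography
  outer(amp, bump)
}

# Background synthesis happens in the frequency domain: white Gaussian
# noise is shaped by the amplitude spectrum of each constituent process
# (1/f^a broadband plus four band-limited processes) and returned to the
# time domain with one inverse FFT per process. Each band's slow power
# drift (vigilance-like nonstationarity) multiplies its time course;
# per-channel block variance is then rescaled to its exact target
# (empirical calibration).

# Squared magnitude response of an order-`ord` analog Butterworth
# band-pass, evaluated at frequencies f (Hz).
butter_bandpass_gain2 <- function(f, low_hz, high_hz, ord = 4) {
  xi <- ifelse(f > 0, (f^2 - low_hz * high_hz) / (f * (high_hz - low_hz)), Inf)
  1 / (1 + xi^(2 * ord))
}

# Spectrally shaped Gaussian noise: n_samples x n_channels columns of
# white noise filtered by amplitude gain `g` (length n_samples), each
# column rescaled to unit SD.
shaped_noise <- function(n_samples, n_channels, g) {
  w <- matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels)
  x <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / n_samples
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sds[sds == 0] <- 1
  x / rep(sds, each = n_samples)
}

# Slow unit-variance Gaussian processes (one per column) used as band
# power drifts; Gaussian spectral envelope with the given cutoff (Hz).
slow_envelopes <- function(n_samples, n_cols, fs, cutoff_hz) {
  k <- seq_len(n_samples) - 1
  f <- pmin(k, n_samples - k) * fs / n_samples
  shaped_noise(n_samples, n_cols, exp(-(f / cutoff_hz)^2 / 2))
}

#' Render ongoing background activity for one condition
#'
#' Sum of a 1/f^a broadband process at `noise_scale_uV` RMS and, for each
#' band, band-limited noise with a 4th-order Butterworth band-pass
#' spectral shape whose per-channel block variance is `base_power *
#' effect(task, difficulty) * topography^2 * subject_scale` (exact, by
#' empirical calibration). Each band additionally carries a slow
#' log-normal power drift (`band_power_drift_sd` on the log scale,
#' `drift_cutoff_hz` bandwidth), shared across channels but independent
#' between bands, emulating the nonstationarity of real ongoing EEG.
#' Channels are otherwise mutually independent.
#'
#' @param config an `mwl_config`.
#' @param task,difficulty condition labels.
#' @param n_samples number of samples to render.
#' @param seed optional integer seed.
#' @param subject_scale per-subject power scaling (default 1).
#' @return scalp-channel x sample matrix in microvolts.
#' @export
render_background <- function(config, task, difficulty, n_samples,
                              seed = NULL, subject_scale = 1) {
  draw <- function() {
    nch <- n_channels(config$montage)
    fs <- config$sampling_rate_hz
    k <- seq_len(n_samples) - 1
    f <- pmin(k, n_samples - k) * fs / n_samples
    x <- matrix(0, n_samples, nch)
    if (config$noise_scale_uV > 0) {
      gp <- sqrt(c(0, f[-1]^(-config$noise_1f_exponent)))
      x <- x + shaped_noise(n_samples, nch, gp) * config$noise_scale_uV
    }
    drift_sd <- config$band_power_drift_sd
    env <- if (drift_sd > 0)
      slow_envelopes(n_samples, length(config$bands), fs,
                     config$drift_cutoff_hz)
    for (bi in seq_along(config$bands)) {
      bs <- config$bands[[bi]]
      eff <- effect_factor(bs, task, difficulty, nch)
      sds <- sqrt(bs$base_power * eff * subject_scale) * bs$topography
      if (all(sds == 0)) next
      gb <- sqrt(butter_bandpass_gain2(f, bs$low_hz, bs$high_hz))
      y <- shaped_noise(n_samples, nch, gb)
      if (drift_sd > 0) {
        amp <- exp(drift_sd * env[, bi] / 2)     # sqrt of power drift
        y <- y * amp
        ss <- sqrt(colMeans(y^2) - colMeans(y)^2)
        ss[ss == 0] <- 1
        y <- y / rep(ss, each = n_samples)
      }
      x <- x + y * rep(sds, each = n_samples)
    }
    x <- t(x)
    rownames(x) <- config$montage$channel_labels
    x
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate one recording block
#'
#' Assembles background activity, evoked-component templates added at each
#' probe onset, and low-amplitude mastoid reference channels into a
#' continuous labelled recording.
#'
#' @param config an `mwl_config`.
#' @param subject_id character subject identifier.
#' @param task,difficulty,block_index condition labels.
#' @param seed optional integer seed; default derives a substream from the
#'   config master seed and the condition labels.
#' @param subject_scale per-subject log-normal scaling of amplitudes and
#'   band powers.
#' @return an object of class `mwl_recording` with elements `data`
#'   (channel x sample matrix, scalp channels then the two mastoids),
#'   `sampling_rate_hz`, `events`, `labels`, and `montage`.
#' @export
simulate_block <- function(config, subject_id, task, difficulty, block_index,
                           seed = NULL, subject_scale = 1) {
  task <- match.arg(task, c("nback", "matb"))
  difficulty <- match.arg(difficulty, c("easy", "hard"))
  if (is.null(seed))
    seed <- substream_seed(config$seed, sprintf("sim/%s/%s.%s.b%d",
                                                subject_id, task, difficulty,
                                                block_index))
  fs <- config$sampling_rate_hz
  n <- round(config$block_duration_s * fs)
  with_seed(seed, {
    events <- sample_event_train(config)
    data <- render_background(config, task, difficulty, n,
                              subject_scale = subject_scale)
    post <- seq(0, round(0.8 * fs)) / fs
    jit <- config$latency_jitter_sd_s
    if (jit == 0) {
      tpl <- matrix(0, n_channels(config$montage), length(post))
      for (cs in config$components)
        tpl <- tpl + render_component(cs, task, difficulty, post)
      tpl <- tpl * subject_scale
      for (on in events$onset_sample) {
        idx <- on + seq_along(post)            # onset sample is t = 0
        data[, idx] <- data[, idx] + tpl
      }
    } else {
      for (on in events$onset_sample) {
        shift <- stats::rnorm(1, 0, jit)
        tpl <- matrix(0, n_channels(config$montage), length(post))
        for (cs in config$components)
          tpl <- tpl + render_component(cs, task, difficulty, post - shift)
        idx <- on + seq_along(post)
        data[, idx] <- data[, idx] + tpl * subject_scale
      }
    }
    mast <- matrix(stats::rnorm(2 * n, sd = 0.1 * config$noise_scale_uV), 2, n)
    rownames(mast) <- config$montage$reference_labels
    structure(
      list(data = rbind(data, mast), sampling_rate_hz = fs, events = events,
           labels = list(subject = subject_id, task = task,
                         difficulty = difficulty, block = block_index),
           montage = config$montage),
      class = "mwl_recording")
  })
}

#' Simulate a full multi-subject study
#'
#' Produces the 2 task x 2 difficulty x 2 block design (8 blocks) for each
#' subject. A per-subject log-normal scaling of all component amplitudes
#' and band powers (SD = `subject_variability` on the log scale) is drawn
#' once per subject from its own substream, so any subject can be
#' regenerated independently.
#'
#' @param config an `mwl_config`.
#' @param apply_fn optional function applied to each `mwl_recording` as it
#'   is produced; when given, its return values are stored instead of the
#'   raw recordings (keeps memory bounded for large studies).
#' @return list of `n_subjects * 8` recordings (or `apply_fn` results),
#'   ordered subject, task (nback, matb), difficulty (easy, hard), block.
#' @export
simulate_study <- function(config, apply_fn = NULL) {
  if (config$n_subjects < 2L)
    warning("fewer than 2 subjects: group statistics will not be possible")
  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  scales <- vapply(subjects, function(sid) {
    with_seed(substream_seed(config$seed, paste0("subject_scale/", sid)),
              exp(stats::rnorm(1, 0, config$subject_variability)))
  }, numeric(1))
  out <- list()
  for (si in seq_along(subjects)) {
    for (task in c("nback", "matb")) {
      for (difficulty in c("easy", "hard")) {
        for (b in 1:2) {
          rec <- simulate_block(config, subjects[si], task, difficulty, b,
                                subject_scale = scales[si])
          key <- sprintf("%s.%s.%s.b%d", subjects[si], task, difficulty, b)
          out[[key]] <- if (is.null(apply_fn)) rec else apply_fn(rec)
        }
      }
    }
  }
  out
}

#' @export
print.mwl_recording <- function(x, ...) {
  cat(sprintf("<mwl_recording> %s %s/%s block %d: %d ch x %d samples @ %g Hz, %d events\n",
              x$labels$subject, x$labels$task, x$labels$difficulty,
              x$labels$block, nrow(x$data), ncol(x$data),
              x$sampling_rate_hz, nrow(x$events)))
  invisible(x)
}
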