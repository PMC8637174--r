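#' Specification of an evoked component injected by the simulator
#'
#' Each auditory probe evokes four successive components (N1, eP3a, lP3a,
#' RON). A component is modelled as a Gaussian bump in time, scaled by a
#' spatial topography and a condition-dependent amplitude factor.
#'
#' @param name one of "N1", "eP3a", "lP3a", "RON".
#' @param peak_latency_s peak latency in seconds post-stimulus; must fall
#'   inside the component's analysis window (see [component_windows()]).
#' @param width_s temporal Gaussian SD in seconds (> 0).
#' @param polarity +1 (positivity) or -1 (negativity).
#' @param topography per-channel gain in \[0, 1\].
#' @param base_amplitude_uV peak amplitude in microvolts before scaling.
#' @param effect named list mapping `"<task>.<difficulty>"` (tasks `nback`,
#'   `matb`; difficulties `easy`, `hard`) to a non-negative multiplicative
#'   amplitude factor; each entry is a scalar or a per-channel vector.
#' @return an object of class `mwl_component`.
#' @export
component_spec <- function(name, peak_latency_s, width_s, polarity,
                           topography, base_amplitude_uV,
                           effect = uniform_effect(1)) {
  name <- match.arg(name, c("N1", "eP3a", "lP3a", "RON"))
  win <- component_windows()[[name]] / 1000
  if (peak_latency_s < win[1] || peak_latency_s > win[2])
    stop(sprintf("%s peak latency %.3f s outside its analysis window [%.3f, %.3f] s",
                 name, peak_latency_s, win[1], win[2]))
  stopifnot(width_s > 0, polarity %in% c(-1, 1),
            all(topography >= 0), all(topography <= 1),
            base_amplitude_uV >= 0)
  check_effect_map(effect)
  structure(list(name = name, peak_latency_s = peak_latency_s,
                 width_s = width_s, polarity = polarity,
                 topography = topography,
                 base_amplitude_uV = base_amplitude_uV,
                 effect = effect),
            class = "mwl_component")
}

#' Specification of an oscillatory band injected by the simulator
#'
#' Ongoing activity carries band-limited noise in the four analysis bands
#' (theta 4-8, alpha 8-13, beta1 13-20, beta2 20-30 Hz); the per-channel
#' variance of each band is `base_power * effect(task, difficulty) *
#' topography^2` so relative band power carries the condition effects.
#'
#' @param name one of "theta", "alpha", "beta1", "beta2".
#' @param low_hz,high_hz band edges, 0 < low < high <= 45.
#' @param base_power band variance in microvolts squared at unit gain.
#' @param topography per-channel gain in \[0, 1\].
#' @param effect as in [component_spec()]; factors scale the band variance.
#' @return an object of class `mwl_band`.
#' @export
band_spec <- function(name, low_hz, high_hz, base_power, topography,
                      effect = uniform_effect(1)) {
  name <- match.arg(name, c("theta", "alpha", "beta1", "beta2"))
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz <= 45, base_power >= 0,
            all(topography >= 0), all(topography <= 1))
  check_effect_map(effect)
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz,
                 base_power = base_power, topography = topography,
                 effect = effect),
            class = "mwl_band")
}

#' Constant effect map (same factor in every condition)
#' @param factor non-negative scalar applied to all four cells.
#' @export
uniform_effect <- function(factor = 1) {
  cells <- c("nback.easy", "nback.hard", "matb.easy", "matb.hard")
  stats::setNames(rep(list(factor), 4), cells)
}

check_effect_map <- function(effect) {
  cells <- c("nback.easy", "nback.hard", "matb.easy", "matb.hard")
  if (!is.list(effect) || !all(cells %in% names(effect)))
    stop("effect map must name all four task x difficulty cells")
  ok <- vapply(effect, function(v) is.numeric(v) && all(v >= 0), logical(1))
  if (!all(ok)) stop("effect factors must be non-negative numerics")
  invisible(TRUE)
}

# Per-channel effect vector for one condition; scalars are recycled.
effect_factor <- function(spec, task, difficulty, nch) {
  key <- paste(task, difficulty, sep = ".")
  v <- spec$effect[[key]]
  if (is.null(v)) stop("unknown task/difficulty cell: ", key)
  if (length(v) == 1L) rep(v, nch)
  else if (length(v) == nch) as.numeric(v)
  else stop("effect vector length must be 1 or the channel count")
}

#' Simulation configuration for the probe-in-task study
#'
#' Bundles the montage, the four component and four band specifications,
#' the noise model and the study design into one validated object. The
#' defaults reproduce the recorded study's conditions: 10-minute blocks,
#' probes every 8-22 s, 500 Hz sampling, a 2 task x 2 difficulty x 2 block
#' design per subject.
#'
#' @param montage an `mwl_montage` (default: 60-channel layout).
#' @param scenario preset name: `"paper_like"` (ERP amplitude effects
#'   identical across tasks, band-power effects with task-dependent
#'   topographies and offsets), `"null"` (no condition effects anywhere),
#'   or `"psd_consistent"` (control: band effects identical across tasks).
#' @param n_subjects number of simulated subjects.
#' @param block_duration_s block length in seconds (default 600).
#' @param iti_range_s inter-probe interval range in seconds (default 8-22).
#' @param sampling_rate_hz sampling rate (default 500; must exceed 90 Hz).
#' @param noise_1f_exponent spectral exponent of the 1/f background.
#' @param noise_scale_uV RMS of the 1/f background in microvolts.
#' @param subject_variability fractional SD of the log-normal per-subject
#'   scaling applied to all component amplitudes and band powers.
#' @param band_power_drift_sd SD (log scale) of the slow within-block
#'   band-power drift; 0 disables the drift.
#' @param drift_cutoff_hz spectral cutoff (Hz) of the drift process
#'   (default 0.1, i.e. fluctuations on the ~10-second scale).
#' @param latency_jitter_sd_s optional SD (s) of trial-to-trial latency
#'   jitter of the evoked templates; 0 (default) keeps the averaging
#'   oracle exact.
#' @param seed master seed; every stage derives named substreams from it.
#' @param components,bands optional overrides of the scenario presets.
#' @return an object of class `mwl_config`.
#' @export
sim_config <- function(montage = default_montage(),
                       scenario = c("paper_like", "null", "psd_consistent"),
                       n_subjects = 17,
                       block_duration_s = 600,
                       iti_range_s = c(8, 22),
                       sampling_rate_hz = 500,
                       noise_1f_exponent = 1,
                       noise_scale_uV = 10,
                       subject_variability = 0.2,
                       band_power_drift_sd = 0.5,
                       drift_cutoff_hz = 0.1,
                       latency_jitter_sd_s = 0,
                       seed = 1L,
                       components = NULL,
                       bands = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(montage, "mwl_montage"))
  if (is.null(components)) components <- scenario_components(montage, scenario)
  if (is.null(bands)) bands <- scenario_bands(montage, scenario)
  cfg <- structure(
    list(montage = montage, scenario = scenario,
         components = components, bands = bands,
         n_subjects = as.integer(n_subjects),
         block_duration_s = block_duration_s,
         iti_range_s = as.numeric(iti_range_s),
         sampling_rate_hz = sampling_rate_hz,
         noise_1f_exponent = noise_1f_exponent,
         noise_scale_uV = noise_scale_uV,
         subject_variability = subject_variability,
         band_power_drift_sd = band_power_drift_sd,
         drift_cutoff_hz = drift_cutoff_hz,
         latency_jitter_sd_s = latency_jitter_sd_s,
         seed = as.integer(seed)),
    class = "mwl_config")
  validate_config(cfg)
  cfg
}

# ERP epoch span relative to probe onset, in seconds.
erp_epoch_span <- function() c(-0.5, 0.8)

validate_config <- function(cfg) {
  span <- erp_epoch_span()
  epoch_len <- span[2] - span[1]
  if (length(cfg$iti_range_s) != 2L || cfg$iti_range_s[1] > cfg$iti_range_s[2])
    stop("iti_range_s must be (low, high) with low <= high")
  if (cfg$iti_range_s[1] < epoch_len)
    stop("ITI lower bound must be at least the ERP epoch span (",
         epoch_len, " s) so consecutive epochs never overlap")
  mean_iti <- mean(cfg$iti_range_s)
  if (cfg$block_duration_s / mean_iti < 20)
    stop("block too short: block_duration_s / mean ITI must be >= 20")
  if (cfg$sampling_rate_hz <= 2 * 45)
    stop("sampling rate must exceed 90 Hz (twice the 45 Hz analysis edge)")
  if (length(cfg$components) != 4L || length(cfg$bands) != 4L)
    stop("config requires exactly 4 components and 4 bands")
  nch <- n_channels(cfg$montage)
  for (cs in cfg$components)
    if (length(cs$topography) != nch)
      stop("component topography length must match the montage")
  for (bs in cfg$bands)
    if (length(bs$topography) != nch)
      stop("band topography length must match the montage")
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  invisible(cfg)
}

# ---- scenario presets -----------------------------------------------------
# Effect directions follow the recorded findings: component amplitudes
# shrink in magnitude under high workload, identically in both tasks except
# lP3a (workload-sensitive only in MATB); theta power rises and alpha falls
# under high workload with task-dependent topographies, and MATB carries a
# global theta-up / alpha-down offset relative to N-back.

scenario_components <- function(montage, scenario) {
  topo_fc <- gaussian_topography(montage, c(0, 0.30), 0.55)  # frontocentral
  topo_f  <- gaussian_topography(montage, c(0, 0.45), 0.55)  # frontal
  topo_c  <- gaussian_topography(montage, c(0, 0.05), 0.60)  # central
  eff_mwl <- list(nback.easy = 1, nback.hard = 0.6,
                  matb.easy = 1, matb.hard = 0.6)
  eff_lp3a <- switch(scenario,
    paper_like = list(nback.easy = 1, nback.hard = 1,
                      matb.easy = 1, matb.hard = 0.6),
    psd_consistent = eff_mwl,
    null = uniform_effect(1))
  eff <- if (scenario == "null") uniform_effect(1) else eff_mwl
  list(
    component_spec("N1",   0.150, 0.012, -1, topo_fc, 6.0, eff),
    component_spec("eP3a", 0.245, 0.018, +1, topo_fc, 8.0, eff),
    component_spec("lP3a", 0.315, 0.025, +1, topo_c,  6.0, eff_lp3a),
    component_spec("RON",  0.445, 0.035, -1, topo_f,  5.0, eff))
}

scenario_bands <- function(montage, scenario) {
  nch <- n_channels(montage)
  g_front    <- gaussian_topography(montage, c(0, 0.45), 0.45)
  g_parietal <- gaussian_topography(montage, c(0, -0.45), 0.45)
  g_post     <- gaussian_topography(montage, c(0, -0.60), 0.50)
  g_fc       <- gaussian_topography(montage, c(0, 0.15), 0.50)
  g_fp       <- pmin(g_front + g_parietal, 1)

  topo_theta <- pmin(0.4 + 0.6 * g_front, 1)
  topo_alpha <- pmin(0.4 + 0.6 * g_post, 1)
  topo_beta1 <- pmin(0.5 + 0.5 * g_fc, 1)
  topo_beta2 <- rep(0.7, nch)

  if (scenario == "null") {
    e_theta <- e_alpha <- e_beta1 <- e_beta2 <- uniform_effect(1)
  } else {
    # theta: rises with workload, mainly in N-back (fronto-parietal);
    # barely workload-sensitive in MATB (weak parietal); MATB carries a
    # global theta-up offset (strong task effect, weak MWL effect)
    th_nb_e <- 1 - 0.12 * g_fp; th_nb_h <- 1 + 0.30 * g_fp
    th_mb_e <- 1 - 0.02 * g_parietal; th_mb_h <- 1 + 0.04 * g_parietal
    # alpha: falls with workload; posterior mask in N-back,
    # fronto-central in MATB (disjoint topographies); MATB alpha-down
    # offset
    al_nb_e <- 1 + 0.18 * g_post; al_nb_h <- 1 - 0.13 * g_post
    al_mb_e <- 1 + 0.18 * g_fc; al_mb_h <- 1 - 0.13 * g_fc
    b1_nb_e <- 1 + 0.10 * g_fc; b1_nb_h <- 1 - 0.08 * g_fc
    if (scenario == "psd_consistent") {
      e_theta <- list(nback.easy = th_nb_e, nback.hard = th_nb_h,
                      matb.easy = th_nb_e, matb.hard = th_nb_h)
      e_alpha <- list(nback.easy = al_nb_e, nback.hard = al_nb_h,
                      matb.easy = al_nb_e, matb.hard = al_nb_h)
      e_beta1 <- list(nback.easy = b1_nb_e, nback.hard = b1_nb_h,
                      matb.easy = b1_nb_e, matb.hard = b1_nb_h)
    } else {
      e_theta <- list(nback.easy = th_nb_e, nback.hard = th_nb_h,
                      matb.easy = 1.4 * th_mb_e, matb.hard = 1.4 * th_mb_h)
      e_alpha <- list(nback.easy = al_nb_e, nback.hard = al_nb_h,
                      matb.easy = 0.65 * al_mb_e, matb.hard = 0.65 * al_mb_h)
      e_beta1 <- list(nback.easy = b1_nb_e, nback.hard = b1_nb_h,
                      matb.easy = 1, matb.hard = 1)
    }
    e_beta2 <- uniform_effect(1)
  }
  list(
    band_spec("theta", 4, 8,  25, topo_theta, e_theta),
    band_spec("alpha", 8, 13, 36, topo_alpha, e_alpha),
    band_spec("beta1", 13, 20, 16, topo_beta1, e_beta1),
    band_spec("beta2", 20, 30, 9,  topo_beta2, e_beta2))
}

#' @export
print.mwl_config <- function(x, ...) {
  cat(sprintf(paste0("<mwl_config> scenario=%s, %d subjects, %d channels, ",
                     "%g s blocks @ %g Hz, ITI %g-%g s, seed %d\n"),
              x$scenario, x$n_subjects, n_channels(x$montage),
              x$block_duration_s, x$sampling_rate_hz,
              x$iti_range_s[1], x$iti_range_s[2], x$seed))
  invisible(x)
}
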