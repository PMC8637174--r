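# Single forward pass of a normalized IIR filter (a[1] = 1) using the
# compiled convolution/recursive engines in stats::filter.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)[(nb - 1) + seq_along(x)]
  if (length(a) > 1L)
    v <- stats::filter(v, -a[-1], method = "recursive")
  as.numeric(v)
}

# Forward-backward (zero-phase) application with odd-reflection padding
# at both ends, matching the usual filtfilt edge treatment.
zero_phase_filter <- function(filt, x) {
  b <- filt$b; a <- filt$a
  n <- length(x)
  p <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 2L)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[p + seq_len(n)]
}

#' Zero-phase band-pass filtering of a continuous recording
#'
#' High-pass (default 0.5 Hz) then low-pass (default 45 Hz) 4th-order
#' Butterworth filters, each applied forward-backward (zero phase) to every
#' channel. Length is preserved; DC is removed by the high-pass.
#'
#' @param rec an `mwl_recording`.
#' @param hp_hz high-pass cutoff in Hz.
#' @param lp_hz low-pass cutoff in Hz; must be below Nyquist.
#' @return the filtered `mwl_recording`.
#' @export
filter_continuous <- function(rec, hp_hz = 0.5, lp_hz = 45) {
  fs <- rec$sampling_rate_hz
  if (lp_hz >= fs / 2) stop("low-pass cutoff must be below Nyquist")
  if (hp_hz <= 0 || hp_hz >= lp_hz) stop("require 0 < hp_hz < lp_hz")
  hp <- signal::butter(4, hp_hz / (fs / 2), type = "high")
  lp <- signal::butter(4, lp_hz / (fs / 2), type = "low")
  for (ch in seq_len(nrow(rec$data))) {
    x <- zero_phase_filter(hp, rec$data[ch, ])
    rec$data[ch, ] <- zero_phase_filter(lp, x)
  }
  rec$filtered <- TRUE
  rec
}

#' Re-reference scalp channels to the average bilateral mastoid
#'
#' Subtracts the mean of the two mastoid channels from every scalp channel
#' and drops the mastoids from the output.
#'
#' @param rec an `mwl_recording` containing the montage's mastoid labels.
#' @return the re-referenced `mwl_recording` (scalp channels only).
#' @export
rereference_mastoids <- function(rec) {
  refs <- rec$montage$reference_labels
  if (!all(refs %in% rownames(rec$data)))
    stop("mastoid channels ", paste(refs, collapse = ", "),
         " not present in the recording")
  ref_mean <- colMeans(rec$data[refs, , drop = FALSE])
  scalp <- rec$montage$channel_labels
  rec$data <- sweep(rec$data[scalp, , drop = FALSE], 2, ref_mean)
  rec$rereferenced <- TRUE
  rec
}

new_epoch_set <- function(data, time_axis_s, provenance, kind) {
  stopifnot(dim(data)[1] == nrow(provenance), kind %in% c("erp", "spectral"))
  structure(list(data = data, time_axis_s = time_axis_s,
                 provenance = provenance, kind = kind),
            class = "mwl_epochs")
}

block_provenance <- function(rec, n_trials) {
  data.frame(subject = rec$labels$subject, task = rec$labels$task,
             difficulty = rec$labels$difficulty, block = rec$labels$block,
             trial = seq_len(n_trials), stringsAsFactors = FALSE)
}

#' Extract event-related potential epochs
#'
#' One epoch per probe event spanning -0.5 to +0.8 s around onset
#' (half-open sample range, onset sample on the post-stimulus side; 650
#' samples at 500 Hz). Events whose full span does not fit inside the
#' recording are dropped and counted.
#'
#' @param rec an `mwl_recording` (scalp channels; re-reference first).
#' @return an `mwl_epochs` object of kind `"erp"` with a trial x channel x
#'   time array; attribute `n_dropped` counts boundary-dropped events.
#' @export
extract_erp_epochs <- function(rec) {
  fs <- rec$sampling_rate_hz
  span <- erp_epoch_span()
  pre <- round(-span[1] * fs); post <- round(span[2] * fs)
  n_len <- pre + post
  n_samp <- ncol(rec$data)
  on <- rec$events$onset_sample
  keep <- (on - pre + 1) >= 1 & (on + post) <= n_samp
  if (!any(keep)) stop("no probe event fits fully inside the recording")
  on <- on[keep]
  nch <- nrow(rec$data)
  arr <- array(NA_real_, c(length(on), nch, n_len),
               dimnames = list(NULL, rownames(rec$data), NULL))
  for (i in seq_along(on))
    arr[i, , ] <- rec$data[, (on[i] - pre + 1):(on[i] + post)]
  es <- new_epoch_set(arr, seq(span[1], by = 1 / fs, length.out = n_len),
                      block_provenance(rec, length(on)), "erp")
  attr(es, "n_dropped") <- sum(!keep)
  es
}

#' Baseline-correct ERP epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus window
#' (-0.5 to 0 s) so every corrected epoch has exactly zero pre-stimulus
#' mean.
#'
#' @param epochs an `mwl_epochs` of kind `"erp"`.
#' @return the corrected `mwl_epochs`.
#' @export
baseline_correct <- function(epochs) {
  if (epochs$kind != "erp") stop("baseline correction applies to ERP epochs only")
  pre <- which(epochs$time_axis_s < 0)
  base <- apply(epochs$data[, , pre, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)   # recycles over time (3rd dim)
  epochs
}

#' Extract 5-s spectral epochs from inter-probe intervals
#'
#' For each pair of consecutive probes, the evoked-free interval
#' `[onset_i + 0.8 s, onset_(i+1) - 0.5 s]` is located; if it is at least
#' 5 s long (closed boundary) one 5-s epoch centered in the interval is
#' extracted. At most one epoch per interval; shorter intervals are
#' skipped and counted.
#'
#' @param rec a filtered, re-referenced `mwl_recording`.
#' @return an `mwl_epochs` of kind `"spectral"` (5 s exactly); attribute
#'   `n_skipped` counts intervals shorter than 5 s.
#' @export
extract_spectral_epochs <- function(rec) {
  fs <- rec$sampling_rate_hz
  n_len <- round(5 * fs)
  on_s <- rec$events$onset_s
  if (length(on_s) < 2L) stop("need at least two probe events")
  lo <- on_s[-length(on_s)] + erp_epoch_span()[2]
  hi <- on_s[-1] + erp_epoch_span()[1]
  len <- hi - lo
  ok <- which(len >= 5 - 1e-9)
  if (!length(ok)) stop("no inter-probe interval is long enough for a 5-s epoch")
  starts <- round(((lo[ok] + hi[ok]) / 2 - 2.5) * fs)
  nch <- nrow(rec$data)
  arr <- array(NA_real_, c(length(ok), nch, n_len),
               dimnames = list(NULL, rownames(rec$data), NULL))
  for (i in seq_along(ok))
    arr[i, , ] <- rec$data[, (starts[i] + 1):(starts[i] + n_len)]
  es <- new_epoch_set(arr, seq(0, by = 1 / fs, length.out = n_len),
                      block_provenance(rec, length(ok)), "spectral")
  attr(es, "n_skipped") <- length(len) - length(ok)
  es
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Automated stand-in for manual artifact screening: any trial containing
#' a sample with absolute amplitude above the threshold is removed.
#'
#' @param epochs an `mwl_epochs`.
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @return the cleaned `mwl_epochs`; attribute `rejected_fraction` records
#'   the fraction removed.
#' @export
reject_amplitude <- function(epochs, threshold_uv = 100) {
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= threshold_uv
  if (!any(keep)) stop("all trials exceed the amplitude threshold")
  frac <- mean(!keep)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$provenance <- epochs$provenance[keep, , drop = FALSE]
  attr(epochs, "rejected_fraction") <- frac
  epochs
}

#' Full preprocessing of one raw block
#'
#' Convenience chain: band-pass filter, mastoid re-reference, then extract
#' baseline-corrected ERP epochs and 5-s spectral epochs with amplitude
#' rejection.
#'
#' @param rec a raw `mwl_recording` (scalp + mastoid channels).
#' @param threshold_uv amplitude-rejection threshold.
#' @return list with elements `erp` and `spectral` (`mwl_epochs`).
#' @export
preprocess_block <- function(rec, threshold_uv = 100) {
  rec <- filter_continuous(rec)
  rec <- rereference_mastoids(rec)
  erp <- reject_amplitude(baseline_correct(extract_erp_epochs(rec)),
                          threshold_uv)
  spec <- reject_amplitude(extract_spectral_epochs(rec), threshold_uv)
  list(erp = erp, spectral = spec)
}

#' @export
print.mwl_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mwl_epochs kind=%s> %d trials x %d channels x %d samples\n",
              x$kind, d[1], d[2], d[3]))
  invisible(x)
}
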