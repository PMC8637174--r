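#' Band definitions for relative power features
#'
#' Analysis bands theta (4-8), alpha (8-13), beta1 (13-20), beta2
#' (20-30 Hz); relative power is normalized over 4-45 Hz. Shared edges are
#' assigned half-open, `low <= f < high`, so no bin is double-counted; the
#' 45 Hz bin is included in the normalization range (closed at the top).
#'
#' @return list with `bands` (named list of `(low, high)` pairs) and
#'   `normalization_range` `(4, 45)`.
#' @export
band_definitions <- function() {
  list(bands = list(theta = c(4, 8), alpha = c(8, 13),
                    beta1 = c(13, 20), beta2 = c(20, 30)),
       normalization_range = c(4, 45))
}

#' Welch power spectral density of one 5-s epoch
#'
#' Welch's method with 1-s Hamming-windowed segments and 50% overlap
#' (9 segments for a 5-s epoch), giving a 1 Hz frequency grid; one-sided
#' estimate in microvolts squared per Hz.
#'
#' @param epoch channel x sample matrix spanning exactly 5 s.
#' @param rate sampling rate in Hz.
#' @return list with `freq_hz` (0 to Nyquist, 1 Hz steps) and `psd`
#'   (channel x frequency matrix).
#' @export
welch_psd <- function(epoch, rate) {
  if (is.null(dim(epoch))) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  if (n != round(5 * rate))
    stop("welch_psd expects an epoch of exactly 5 s")
  nseg <- round(rate)                      # 1-s segments
  step <- nseg %/% 2L                      # 50% overlap
  starts <- seq(1, n - nseg + 1, by = step)
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hamming
  u <- sum(win^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- matrix(0, nrow(epoch), nfreq)
  for (s in starts) {
    seg <- epoch[, s:(s + nseg - 1), drop = FALSE] * rep(win, each = nrow(epoch))
    sp <- stats::mvfft(t(seg))[seq_len(nfreq), , drop = FALSE]
    acc <- acc + t(Mod(sp)^2)
  }
  psd <- acc / (length(starts) * u * rate)
  # one-sided: double everything except DC (and Nyquist when nseg even)
  inner <- 2:(nfreq - if (nseg %% 2L == 0L) 1L else 0L)
  psd[, inner] <- 2 * psd[, inner]
  freq <- seq(0, nfreq - 1) * rate / nseg
  rownames(psd) <- rownames(epoch)
  list(freq_hz = freq, psd = psd)
}

#' Relative power spectrum over the 4-45 Hz range
#'
#' Each retained bin is divided by the channel's total power in 4-45 Hz;
#' bins outside the range are dropped. Every output row sums to one.
#'
#' @param psd list as returned by [welch_psd()] (or the same shape after
#'   condition averaging).
#' @return list with `freq_hz` (retained grid) and `rel` (channel x
#'   frequency matrix of relative power).
#' @export
relative_psd <- function(psd) {
  rng <- band_definitions()$normalization_range
  keep <- psd$freq_hz >= rng[1] - 1e-9 & psd$freq_hz <= rng[2] + 1e-9
  p <- psd$psd[, keep, drop = FALSE]
  tot <- rowSums(p)
  if (any(tot <= 0)) stop("zero total power in the normalization range")
  list(freq_hz = psd$freq_hz[keep], rel = p / tot)
}

#' Relative band power
#'
#' Sums relative power over the bins of each band, half-open at shared
#' edges (`low <= f < high`).
#'
#' @param rel list as from [relative_psd()].
#' @return channel x band matrix with columns theta, alpha, beta1, beta2;
#'   values in \[0, 1\], jointly at most 1.
#' @export
band_power <- function(rel) {
  bands <- band_definitions()$bands
  out <- sapply(bands, function(b) {
    idx <- rel$freq_hz >= b[1] - 1e-9 & rel$freq_hz < b[2] - 1e-9
    rowSums(rel$rel[, idx, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(bands)))
  rownames(out) <- rownames(rel$rel)
  out
}

#' Single-trial relative band-power feature table
#'
#' Welch PSD, 4-45 Hz relative normalization and band summation applied to
#' every 5-s epoch (`trial` mode: each trial normalized on its own).
#'
#' @param epochs an `mwl_epochs` of kind `"spectral"`.
#' @return an `mwl_features` table (family `"psd"`), one column per
#'   channel x band (e.g. `Pz.alpha`).
#' @export
psd_feature_table <- function(epochs) {
  if (epochs$kind != "spectral") stop("psd_feature_table expects spectral epochs")
  rate <- 1 / diff(epochs$time_axis_s[1:2])
  nt <- dim(epochs$data)[1]
  ch <- dimnames(epochs$data)[[2]]
  bands <- names(band_definitions()$bands)
  feats <- matrix(NA_real_, nt, length(ch) * length(bands))
  for (i in seq_len(nt)) {
    trial <- matrix(epochs$data[i, , ], nrow = length(ch),
                    dimnames = list(ch, NULL))
    bp <- band_power(relative_psd(welch_psd(trial, rate)))
    feats[i, ] <- as.vector(bp)
  }
  colnames(feats) <- as.vector(outer(ch, bands, paste, sep = "."))
  new_feature_table(epochs$provenance, feats, "psd")
}

#' Condition-average relative spectra
#'
#' The statistical-map path: Welch PSDs are averaged within each group
#' (default subject x task x difficulty) and the averaged spectrum is then
#' normalized over 4-45 Hz (`condition` mode).
#'
#' @param epochs an `mwl_epochs` of kind `"spectral"`.
#' @param group_by provenance columns defining the groups.
#' @return named list of lists as from [relative_psd()], one per group.
#' @export
condition_relative_psd <- function(epochs,
                                   group_by = c("subject", "task", "difficulty")) {
  if (epochs$kind != "spectral") stop("expects spectral epochs")
  rate <- 1 / diff(epochs$time_axis_s[1:2])
  key <- interaction(epochs$provenance[group_by], drop = TRUE, sep = ".")
  groups <- split(seq_len(dim(epochs$data)[1]), key)
  nch <- dim(epochs$data)[2]
  lapply(groups, function(idx) {
    acc <- NULL
    for (i in idx) {
      trial <- matrix(epochs$data[i, , ], nrow = nch,
                      dimnames = list(dimnames(epochs$data)[[2]], NULL))
      w <- welch_psd(trial, rate)
      if (is.null(acc)) { acc <- w } else { acc$psd <- acc$psd + w$psd }
    }
    acc$psd <- acc$psd / length(idx)
    relative_psd(acc)
  })
}
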