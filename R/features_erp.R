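#' Component analysis windows
#'
#' Post-stimulus time windows (ms) over which each component's amplitude
#' is averaged: N1 130-170, eP3a 220-270, lP3a 280-350, RON 390-500.
#'
#' @return named list of `(start_ms, end_ms)` pairs.
#' @export
component_windows <- function() {
  list(N1 = c(130, 170), eP3a = c(220, 270),
       lP3a = c(280, 350), RON = c(390, 500))
}

#' Average ERP waveforms per group
#'
#' Arithmetic mean of baseline-corrected epochs within each group
#' (default: subject x task x difficulty).
#'
#' @param epochs an `mwl_epochs` of kind `"erp"`.
#' @param group_by provenance columns defining the groups.
#' @return named list of channel x time matrices; attribute `n_trials`
#'   gives the trial count per group.
#' @export
average_erp <- function(epochs, group_by = c("subject", "task", "difficulty")) {
  if (epochs$kind != "erp") stop("average_erp expects ERP epochs")
  key <- interaction(epochs$provenance[group_by], drop = TRUE, sep = ".")
  groups <- split(seq_len(dim(epochs$data)[1]), key)
  if (any(lengths(groups) == 0L)) stop("empty group")
  out <- lapply(groups, function(idx) {
    m <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    dimnames(m) <- list(dimnames(epochs$data)[[2]], NULL)
    m
  })
  attr(out, "n_trials") <- lengths(groups)
  attr(out, "time_axis_s") <- epochs$time_axis_s
  out
}

#' Mean amplitude in each component window
#'
#' Averages a waveform (or single trial) over the samples whose time falls
#' inside each component window (closed interval, times at the recording
#' rate).
#'
#' @param waveform channel x time matrix (microvolts).
#' @param time_axis_s times (s) of the waveform columns.
#' @param windows component windows as from [component_windows()].
#' @return channel x component matrix of mean amplitudes (microvolts).
#' @export
window_amplitude <- function(waveform, time_axis_s,
                             windows = component_windows()) {
  t_ms <- time_axis_s * 1000
  out <- vapply(windows, function(w) {
    if (w[1] < min(t_ms) || w[2] > max(t_ms))
      stop("component window outside the epoch span")
    idx <- which(t_ms >= w[1] - 1e-9 & t_ms <= w[2] + 1e-9)
    rowMeans(waveform[, idx, drop = FALSE])
  }, numeric(nrow(waveform)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(windows)))
  rownames(out) <- rownames(waveform)
  out
}

#' Single-trial ERP feature table
#'
#' Applies [window_amplitude()] to every trial, producing one row per
#' trial and one column per channel x component (e.g. `Fz.eP3a`),
#' 240 columns for the 60-channel montage.
#'
#' @param epochs baseline-corrected `mwl_epochs` of kind `"erp"`.
#' @return an `mwl_features` data.frame: label columns (subject, task,
#'   difficulty, block, trial) followed by the feature columns; attribute
#'   `family` is `"erp"`.
#' @export
erp_feature_table <- function(epochs) {
  if (epochs$kind != "erp") stop("erp_feature_table expects ERP epochs")
  nt <- dim(epochs$data)[1]
  ch <- dimnames(epochs$data)[[2]]
  comp <- names(component_windows())
  feats <- matrix(NA_real_, nt, length(ch) * length(comp))
  for (i in seq_len(nt)) {
    trial <- matrix(epochs$data[i, , ], nrow = length(ch),
                    dimnames = list(ch, NULL))
    feats[i, ] <- as.vector(window_amplitude(trial, epochs$time_axis_s))
  }
  colnames(feats) <- as.vector(outer(ch, comp, paste, sep = "."))
  new_feature_table(epochs$provenance, feats, "erp")
}

new_feature_table <- function(provenance, feats, family) {
  stopifnot(!anyNA(feats))
  df <- cbind(provenance, as.data.frame(feats, check.names = FALSE))
  attr(df, "family") <- family
  attr(df, "feature_names") <- colnames(feats)
  class(df) <- c("mwl_features", "data.frame")
  df
}

#' Feature columns of a feature table
#' @param table an `mwl_features` table.
#' @return numeric matrix of the feature columns only.
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, attr(table, "feature_names"), drop = FALSE])
}

#' Bind feature tables by row
#' @param tables list of `mwl_features` with identical feature columns.
#' @return one combined `mwl_features` table.
#' @export
bind_features <- function(tables) {
  fam <- unique(vapply(tables, attr, character(1), "family"))
  fn <- attr(tables[[1]], "feature_names")
  stopifnot(length(fam) == 1L,
            all(vapply(tables, function(t)
              identical(attr(t, "feature_names"), fn), logical(1))))
  out <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(out) <- NULL
  attr(out, "family") <- fam
  attr(out, "feature_names") <- fn
  class(out) <- c("mwl_features", "data.frame")
  out
}
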