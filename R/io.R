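# External interfaces: EDF recordings with BIDS-style events tables,
# feature-table CSVs, YAML simulation configs.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)
}

#' Write a recording to EDF
#'
#' Minimal continuous EDF: 16-bit samples in 1-second data records,
#' physical units microvolts, symmetric per-channel physical range. Any
#' trailing partial second is truncated. The start date/time fields are
#' fixed so that repeated writes of the same recording are byte-identical.
#'
#' @param rec an `mwl_recording`.
#' @param path output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate_hz
  stopifnot(fs == round(fs))
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1L) stop("recording shorter than one EDF data record")
  labels <- rownames(rec$data)
  pmax_ <- apply(abs(rec$data), 1, max)
  pmax_ <- ifelse(pmax_ > 0, ceiling(pmax_ * 10) / 10, 1)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8)
  wr(sprintf("subject %s", rec$labels$subject), 80)
  wr(sprintf("task %s difficulty %s block %s", rec$labels$task,
             rec$labels$difficulty, rec$labels$block), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (lab in labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(formatC(-pmax_[i], format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wr(formatC(pmax_[i], format = "g", digits = 6), 8)
  for (i in seq_len(ns)) wr("-32767", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  scalef <- 32767 / pmax_
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round(rec$data[, idx, drop = FALSE] * scalef)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads continuous EDF files as written by [write_edf()] (16-bit,
#' uniform sampling rate across signals).
#'
#' @param path EDF file path.
#' @return list with `data` (channel x sample matrix, rows named by
#'   signal label), `sampling_rate_hz`, and the patient/recording id
#'   strings.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  patient <- rd(80); recording <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates are not supported")
  fs <- spr[1] / dur
  data <- matrix(NA_real_, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t((block - rep(dmin_, each = spr[1])) *
                       rep(gain, each = spr[1]) + rep(pmin_, each = spr[1]))
  }
  list(data = data, sampling_rate_hz = fs,
       patient = patient, recording = recording)
}

#' Write the events table of a recording
#'
#' Tab-separated table with columns `onset`, `duration`, `trial_type`
#' (onset in seconds; probe duration 0.35 s).
#'
#' @param rec an `mwl_recording`.
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(rec, path) {
  df <- data.frame(onset = rec$events$onset_s, duration = 0.35,
                   trial_type = "auditory_probe")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events table
#' @param path `.tsv` path with columns onset, duration, trial_type.
#' @param sampling_rate_hz rate used to derive `onset_sample`.
#' @return data.frame with `onset_sample` and `onset_s`.
#' @export
read_events_tsv <- function(path, sampling_rate_hz) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  data.frame(onset_sample = as.integer(round(df$onset * sampling_rate_hz)),
             onset_s = df$onset)
}

#' Export one block: EDF + events + JSON sidecar
#'
#' @param rec an `mwl_recording`.
#' @param dir output directory; @param stem file stem.
#' @param config_hash optional config hash recorded in the sidecar.
#' @param dir output directory.
#' @param stem basename stem for the three files.
#' @return character vector of the three paths, invisibly.
#' @export
write_block <- function(rec, dir, stem, config_hash = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_edf <- file.path(dir, paste0(stem, ".edf"))
  p_tsv <- file.path(dir, paste0(stem, "_events.tsv"))
  p_json <- file.path(dir, paste0(stem, ".json"))
  write_edf(rec, p_edf)
  write_events_tsv(rec, p_tsv)
  side <- c(rec$labels,
            list(sampling_rate_hz = rec$sampling_rate_hz,
                 n_channels = nrow(rec$data)))
  if (!is.null(config_hash)) side$config_hash <- config_hash
  jsonlite::write_json(side, p_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p_edf, p_tsv, p_json))
}

#' Load a block written by [write_block()] back into a recording
#' @param dir directory; @param stem file stem; @param montage the montage
#'   describing the scalp/mastoid labels.
#' @param dir,stem location written by [write_block()].
#' @param montage an `mwl_montage`.
#' @return an `mwl_recording`.
#' @export
read_block <- function(dir, stem, montage) {
  e <- read_edf(file.path(dir, paste0(stem, ".edf")))
  side <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                              simplifyVector = TRUE)
  events <- read_events_tsv(file.path(dir, paste0(stem, "_events.tsv")),
                            e$sampling_rate_hz)
  structure(list(data = e$data, sampling_rate_hz = e$sampling_rate_hz,
                 events = events,
                 labels = list(subject = side$subject, task = side$task,
                               difficulty = side$difficulty,
                               block = side$block),
                 montage = montage),
            class = "mwl_recording")
}

#' Write a feature table to CSV
#' @param table an `mwl_features` table.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  df <- as.data.frame(table)
  attr(df, "family") <- NULL; attr(df, "feature_names") <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path `.csv` path written by [write_feature_csv()].
#' @param family feature family label (`"erp"` or `"psd"`).
#' @return an `mwl_features` table.
#' @export
read_feature_csv <- function(path, family) {
  df <- utils::read.csv(path, check.names = FALSE)
  label_cols <- c("subject", "task", "difficulty", "block", "trial")
  stopifnot(all(label_cols %in% names(df)))
  fn <- setdiff(names(df), label_cols)
  new_feature_table(df[label_cols], as.matrix(df[fn]), family)
}

#' Build a simulation config from a YAML file
#'
#' The YAML mirrors the scalar fields of [sim_config()] plus
#' `montage_size` (4, 8, 16 or 60); scenario presets supply the component
#' and band specifications.
#'
#' @param path YAML file path.
#' @return an `mwl_config`.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    montage = small_montage(if (is.null(y$montage_size)) 60 else y$montage_size))
  for (f in c("scenario", "n_subjects", "block_duration_s", "iti_range_s",
              "sampling_rate_hz", "noise_1f_exponent", "noise_scale_uV",
              "subject_variability", "band_power_drift_sd",
              "drift_cutoff_hz", "latency_jitter_sd_s", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(sim_config, args)
}

# 32-bit FNV-1a over the serialized config (environment-free fields only),
# used to content-address pipeline outputs.
config_hash <- function(config) {
  raw <- serialize(config[c("scenario", "n_subjects", "block_duration_s",
                            "iti_range_s", "sampling_rate_hz",
                            "noise_1f_exponent", "noise_scale_uV",
                            "subject_variability", "band_power_drift_sd",
                            "drift_cutoff_hz", "latency_jitter_sd_s",
                            "seed")], NULL, version = 2)
  raw <- c(raw, serialize(config$montage$channel_labels, NULL, version = 2))
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
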