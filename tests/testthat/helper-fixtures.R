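# Shared fixtures: small configs, hand-built recordings and feature
# tables, and a session cache so expensive simulated studies are built
# once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small, fast simulation config (4-channel montage, 100 Hz, 300-s blocks).
tiny_config <- function(scenario = "paper_like", n_subjects = 2, seed = 7,
                        n_channels = 4, fs = 100, block_s = 300, ...) {
  sim_config(montage = small_montage(n_channels), scenario = scenario,
             n_subjects = n_subjects, block_duration_s = block_s,
             sampling_rate_hz = fs, seed = seed, ...)
}

# A silent recording with hand-placed events, for epoching tests.
manual_recording <- function(n_channels = 4, fs = 500, dur_s = 60,
                             onsets_s = c(10, 20, 30), data = NULL,
                             task = "nback", difficulty = "easy") {
  montage <- small_montage(n_channels)
  labels <- c(montage$channel_labels, montage$reference_labels)
  if (is.null(data))
    data <- matrix(0, length(labels), round(dur_s * fs))
  rownames(data) <- labels
  structure(list(
    data = data, sampling_rate_hz = fs,
    events = data.frame(onset_sample = as.integer(round(onsets_s * fs)),
                        onset_s = onsets_s),
    labels = list(subject = "s01", task = task, difficulty = difficulty,
                  block = 1L),
    montage = montage), class = "mwl_recording")
}

# Feature table built directly from a matrix (bypassing the signal chain).
manual_features <- function(x, difficulty, family = "erp", subject = "s01",
                            task = "nback", block = 1L) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  prov <- data.frame(subject = subject, task = task, difficulty = difficulty,
                     block = block, trial = seq_len(nrow(x)),
                     stringsAsFactors = FALSE)
  probemwl:::new_feature_table(prov, x, family)
}

# Gaussian two-class feature tables for one subject covering the full
# task x difficulty x block design; `shift` moves the hard class along
# every feature in the given task (named vector, e.g. c(nback = 1)).
toy_study_table <- function(n_per_cell = 20, d = 4, shift = c(nback = 2, matb = 2),
                            family = "erp", subject = "s01", sd = 1,
                            seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    rows <- list()
    for (task in c("nback", "matb"))
      for (difficulty in c("easy", "hard"))
        for (block in 1:2) {
          mu <- if (difficulty == "hard") shift[[task]] else 0
          x <- matrix(stats::rnorm(n_per_cell * d, mean = mu, sd = sd),
                      n_per_cell, d)
          colnames(x) <- paste0("f", seq_len(d))
          rows[[paste(task, difficulty, block)]] <-
            probemwl:::new_feature_table(
              data.frame(subject = subject, task = task,
                         difficulty = difficulty, block = block,
                         trial = seq_len(n_per_cell),
                         stringsAsFactors = FALSE),
              x, family)
        }
    bind_features(rows)
  })
}

# Concatenate ERP epoch sets along the trial axis.
abind_trials <- function(...) {
  sets <- list(...)
  nts <- vapply(sets, function(s) dim(s$data)[1], integer(1))
  d <- dim(sets[[1]]$data)
  out <- array(NA_real_, c(sum(nts), d[2], d[3]),
               dimnames = c(list(NULL), dimnames(sets[[1]]$data)[2:3]))
  at <- 0L
  for (s in sets) {
    out[at + seq_len(dim(s$data)[1]), , ] <- s$data
    at <- at + dim(s$data)[1]
  }
  probemwl:::new_epoch_set(out, sets[[1]]$time_axis_s,
                           do.call(rbind, lapply(sets, `[[`, "provenance")),
                           sets[[1]]$kind)
}
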