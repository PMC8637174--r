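test_that("band-pass keeps 10 Hz, removes 60 Hz and DC", {
  fs <- 200
  tt <- seq(0, 20, by = 1 / fs)
  rec <- manual_recording(4, fs = fs, dur_s = 20, onsets_s = c(5, 15))
  rec$data[1, ] <- sin(2 * pi * 60 * tt)[seq_len(ncol(rec$data))]
  rec$data[2, ] <- sin(2 * pi * 10 * tt)[seq_len(ncol(rec$data))]
  rec$data[3, ] <- 7
  f <- filter_continuous(rec)
  rms <- function(v) sqrt(mean(v^2))
  mid <- 500:3500   # away from edges
  expect_lt(rms(f$data[1, mid]) / rms(rec$data[1, mid]), 0.05)
  expect_equal(rms(f$data[2, mid]) / rms(rec$data[2, mid]), 1,
               tolerance = 0.05)
  expect_lt(rms(f$data[3, mid]), 0.05)
  expect_equal(ncol(f$data), ncol(rec$data))
  expect_error(filter_continuous(rec, lp_hz = 120), "Nyquist")
})

test_that("zero-phase realization matches signal::filtfilt away from edges", {
  set.seed(4)
  x <- stats::rnorm(4000)
  for (ft in list(signal::butter(4, 0.2, type = "low"),
                  signal::butter(4, 0.01, type = "high"))) {
    a <- probemwl:::zero_phase_filter(ft, x)
    b <- signal::filtfilt(ft, x)
    expect_equal(a[200:3800], b[200:3800], tolerance = 1e-2)
  }
})

test_that("double filtering barely changes passband energy", {
  cfg <- tiny_config(fs = 200)
  rec <- simulate_block(cfg, "s01", "nback", "easy", 1)
  f1 <- filter_continuous(rec)
  f2 <- filter_continuous(f1)
  band_rms <- function(r) {
    w <- welch_psd(r$data[1, 1:(5 * 200), drop = FALSE], 200)
    sel <- w$freq_hz >= 4 & w$freq_hz <= 45
    sqrt(sum(w$psd[1, sel]))
  }
  expect_equal(band_rms(f2) / band_rms(f1), 1, tolerance = 0.02)
})

test_that("mastoid re-referencing subtracts the mastoid mean and drops it", {
  rec <- manual_recording(4, fs = 100, dur_s = 10, onsets_s = c(5))
  set.seed(2)
  rec$data[] <- stats::rnorm(length(rec$data))
  out <- rereference_mastoids(rec)
  expect_identical(rownames(out$data), small_montage(4)$channel_labels)
  ref <- (rec$data["M1", ] + rec$data["M2", ]) / 2
  for (ch in rownames(out$data))
    expect_equal(out$data[ch, ], rec$data[ch, ] - ref, tolerance = 1e-12)
  # zero mastoids leave data unchanged; mastoid = channel cancels it
  rec2 <- rec; rec2$data[c("M1", "M2"), ] <- 0
  expect_equal(rereference_mastoids(rec2)$data,
               rec2$data[small_montage(4)$channel_labels, ])
  rec3 <- rec; rec3$data["M1", ] <- rec3$data["M2", ] <- rec3$data["Cz", ]
  expect_equal(max(abs(rereference_mastoids(rec3)$data["Cz", ])), 0)
  rec4 <- rec; rownames(rec4$data)[5] <- "X1"
  expect_error(rereference_mastoids(rec4), "mastoid")
})

test_that("ERP epochs span -0.5 to 0.8 s and drop edge events", {
  rec <- manual_recording(4, fs = 500, dur_s = 60,
                          onsets_s = c(0.2, 10, 20, 30, 59.9))
  rec$data <- rec$data[small_montage(4)$channel_labels, ]
  ep <- extract_erp_epochs(rec)
  expect_equal(dim(ep$data), c(3, 4, 650))
  expect_equal(attr(ep, "n_dropped"), 2)
  expect_equal(ep$time_axis_s[1], -0.5)
  expect_equal(ep$time_axis_s[650], 0.8 - 1 / 500)
  expect_equal(ep$provenance$trial, 1:3)
})

test_that("epochs reproduce injected content at the event", {
  rec <- manual_recording(4, fs = 500, dur_s = 30, onsets_s = 10)
  rec$data <- rec$data[small_montage(4)$channel_labels, ]
  on <- round(10 * 500)
  rec$data[1, on + 1] <- 3    # the onset sample itself (t = 0)
  ep <- extract_erp_epochs(rec)
  i0 <- which(abs(ep$time_axis_s) < 1e-9)
  expect_equal(as.numeric(ep$data[1, 1, i0]), 3)
  expect_equal(sum(ep$data != 0), 1)
})

test_that("baseline correction zeroes the pre-stimulus mean exactly", {
  rec <- manual_recording(4, fs = 500, dur_s = 30, onsets_s = c(10, 20))
  rec$data <- rec$data[small_montage(4)$channel_labels, ]
  rec$data[] <- 7
  ep <- baseline_correct(extract_erp_epochs(rec))
  expect_equal(max(abs(ep$data)), 0)
  set.seed(9)
  rec$data[] <- stats::rnorm(length(rec$data))
  ep2 <- baseline_correct(extract_erp_epochs(rec))
  pre <- ep2$time_axis_s < 0
  premeans <- apply(ep2$data[, , pre, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(premeans)), 1e-12)
  sp <- extract_spectral_epochs(rec)
  expect_error(baseline_correct(sp), "ERP")
})

test_that("baseline correction shifts but never reshapes the post-stimulus", {
  rec <- manual_recording(4, fs = 500, dur_s = 30, onsets_s = c(10, 20))
  rec$data <- rec$data[small_montage(4)$channel_labels, ]
  set.seed(10)
  rec$data[] <- stats::rnorm(length(rec$data))
  raw <- extract_erp_epochs(rec)
  cor <- baseline_correct(raw)
  d <- raw$data - cor$data
  # per trial and channel the difference is a constant over time
  spread <- apply(d, c(1, 2), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-12)
})

test_that("spectral epochs sit centered between probes, 5 s exactly", {
  # ITI 8 s: free interval 6.7 s -> one epoch
  rec <- manual_recording(4, fs = 500, dur_s = 40, onsets_s = c(10, 18))
  rec$data <- rec$data[small_montage(4)$channel_labels, ]
  sp <- extract_spectral_epochs(rec)
  expect_equal(dim(sp$data), c(1, 4, 2500))
  expect_equal(attr(sp, "n_skipped"), 0)
  # ITI exactly 6.3 s: interval exactly 5 s, retained (closed boundary)
  rec2 <- manual_recording(4, fs = 500, dur_s = 40, onsets_s = c(10, 16.3))
  rec2$data <- rec2$data[small_montage(4)$channel_labels, ]
  expect_equal(dim(extract_spectral_epochs(rec2)$data)[1], 1)
  # ITI 6.2 s: interval 4.9 s, skipped
  rec3 <- manual_recording(4, fs = 500, dur_s = 40,
                           onsets_s = c(10, 16.2, 30))
  rec3$data <- rec3$data[small_montage(4)$channel_labels, ]
  sp3 <- extract_spectral_epochs(rec3)
  expect_equal(dim(sp3$data)[1], 1)
  expect_equal(attr(sp3, "n_skipped"), 1)
})

test_that("spectral epochs avoid evoked windows and count at most n-1", {
  cfg <- tiny_config(fs = 100)
  rec <- simulate_block(cfg, "s01", "nback", "easy", 1)
  rec <- rereference_mastoids(rec)
  sp <- extract_spectral_epochs(rec)
  n_ev <- nrow(rec$events)
  expect_lte(dim(sp$data)[1], n_ev - 1)
  # reconstruct the epoch windows and check the separation rule
  on <- rec$events$onset_s
  lo <- on[-length(on)] + 0.8; hi <- on[-1] - 0.5
  centers <- (lo + hi)[(hi - lo) >= 5 - 1e-9] / 2
  expect_equal(dim(sp$data)[1], length(centers))
})

test_that("amplitude rejection removes exactly the offending trials", {
  rec <- manual_recording(4, fs = 500, dur_s = 60,
                          onsets_s = c(10, 20, 30, 40))
  rec$data <- rec$data[small_montage(4)$channel_labels, ]
  set.seed(3)
  rec$data[] <- stats::rnorm(length(rec$data))
  rec$data[2, round(20.1 * 500)] <- 500   # spike inside trial 2 only
  ep <- extract_erp_epochs(rec)
  clean <- reject_amplitude(ep, 100)
  expect_equal(dim(clean$data)[1], 3)
  expect_equal(clean$provenance$trial, c(1L, 3L, 4L))
  expect_equal(attr(clean, "rejected_fraction"), 0.25)
  expect_equal(dim(reject_amplitude(ep, 1000)$data)[1], 4)
  expect_error(reject_amplitude(ep, 0), "all trials")
})

test_that("re-referencing and epoching commute", {
  cfg <- tiny_config(fs = 100)
  rec <- simulate_block(cfg, "s01", "matb", "easy", 1)
  a <- extract_erp_epochs(rereference_mastoids(rec))
  # epoch first (keeping mastoids), then re-reference epoch-wise
  ep <- extract_erp_epochs(rec)
  refs <- rec$montage$reference_labels
  ref_mean <- apply(ep$data[, refs, , drop = FALSE], c(1, 3), mean)
  manual <- ep$data[, rec$montage$channel_labels, , drop = FALSE]
  for (ch in seq_along(rec$montage$channel_labels))
    manual[, ch, ] <- manual[, ch, ] - ref_mean
  expect_equal(a$data, manual, tolerance = 1e-12)
})
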