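test_that("probe event gaps stay inside the configured ITI range", {
  cfg <- tiny_config()
  ev <- sample_event_train(cfg, seed = 1)
  gaps <- diff(ev$onset_s)
  expect_true(all(gaps >= 8 & gaps <= 22))
  expect_equal(ev$onset_sample, as.integer(round(ev$onset_s * 100)))
  # epoch and tail margins
  expect_gte(ev$onset_s[1], 1.5)
  expect_lte(ev$onset_s[nrow(ev)], 300 - 5.8)
})

test_that("degenerate constant ITI gives an arithmetic event train", {
  cfg <- tiny_config(iti_range_s = c(10, 10))
  ev <- sample_event_train(cfg, seed = 1)
  expect_equal(diff(ev$onset_s), rep(10, nrow(ev) - 1), tolerance = 1e-12)
  # first at 1.5 s, last <= 294.2 s: floor(span / 10) + 1 events
  expect_equal(nrow(ev), floor((300 - 5.8 - 1.5) / 10) + 1)
})

test_that("sampled ITIs behave as U(8, 22): mean and KS law", {
  # one very long block yields >= 10,000 gaps in a single stream
  cfg <- tiny_config(block_s = 160000)
  ev <- sample_event_train(cfg, seed = 1)
  gaps <- diff(ev$onset_s)
  expect_gte(length(gaps), 10000)
  gaps <- gaps[1:10000]
  expect_equal(mean(gaps), 15, tolerance = 0.2 / 15)
  ks <- suppressWarnings(stats::ks.test(gaps, "punif", 8, 22))
  expect_gt(ks$p.value, 0.01)
})

test_that("a too-short block is a configuration error", {
  cfg <- tiny_config()
  cfg$block_duration_s <- 12   # below the >= 2 events requirement
  expect_error(sample_event_train(cfg, seed = 1), "too short")
})

test_that("component templates follow the product model", {
  m <- small_montage(4)
  topo <- c(Fz = 1, Cz = 0.5, Pz = 0.2, Oz = 0)
  tt <- seq(0, 0.8, by = 1 / 500)
  cs <- component_spec("eP3a", 0.245, 0.018, +1, topo, 5,
                       effect = list(nback.easy = 0.5, nback.hard = 0,
                                     matb.easy = 1, matb.hard = 1))
  tpl <- render_component(cs, "nback", "easy", tt)
  # peak = base * factor * topography at the sample nearest peak latency
  expect_equal(max(tpl), 5 * 0.5, tolerance = 2e-3)
  expect_equal(unname(which.max(apply(tpl, 1, max))), 1)
  expect_lte(abs(tt[which.max(tpl[1, ])] - 0.245), 1 / 500)
  # zero effect factor silences the template
  expect_equal(max(abs(render_component(cs, "nback", "hard", tt))), 0)
  expect_error(render_component(cs, "flight", "easy", tt), "unknown")
})

test_that("template energy matches the closed-form Gaussian integral", {
  m <- small_montage(4)
  cs <- component_spec("eP3a", 0.245, 0.018, +1, c(1, 0, 0, 0), 5)
  fs <- 500
  tt <- seq(0, 0.8, by = 1 / fs)
  tpl <- render_component(cs, "nback", "easy", tt)
  num <- sum(tpl[1, ]^2) / fs
  analytic <- 5^2 * cs$width_s * sqrt(pi)   # integral of A^2 exp(-t^2/w^2)
  expect_equal(num, analytic, tolerance = 0.01)
})

test_that("background is 1/f when bands are silenced", {
  zero_bands <- lapply(band_definitions()$bands, function(b) NULL)
  m <- small_montage(4)
  bands <- list(band_spec("theta", 4, 8, 0, rep(0, 4)),
                band_spec("alpha", 8, 13, 0, rep(0, 4)),
                band_spec("beta1", 13, 20, 0, rep(0, 4)),
                band_spec("beta2", 20, 30, 0, rep(0, 4)))
  cfg <- tiny_config(noise_scale_uV = 1, bands = bands, fs = 200)
  bg <- render_background(cfg, "nback", "easy", 60000, seed = 2)
  sp <- stats::spec.pgram(stats::ts(bg[1, ], frequency = 200), plot = FALSE,
                          spans = 31)
  sel <- sp$freq >= 4 & sp$freq <= 45
  slope <- unname(stats::coef(stats::lm(log(sp$spec[sel]) ~
                                          log(sp$freq[sel])))[2])
  expect_equal(slope, -1, tolerance = 0.1)
})

test_that("single-band variance matches its configured target", {
  bands <- list(band_spec("theta", 4, 8, 0, rep(0, 4)),
                band_spec("alpha", 8, 13, 25, rep(1, 4)),
                band_spec("beta1", 13, 20, 0, rep(0, 4)),
                band_spec("beta2", 20, 30, 0, rep(0, 4)))
  cfg <- tiny_config(noise_scale_uV = 0, bands = bands, fs = 200)
  bg <- render_background(cfg, "nback", "easy", 60000, seed = 5)
  expect_equal(stats::var(bg[1, ]), 25, tolerance = 0.05)
})

test_that("a planted alpha difference surfaces in Welch relative power", {
  m <- small_montage(4)
  eff <- list(nback.easy = 1.2, nback.hard = 0.8,
              matb.easy = 1, matb.hard = 1)
  bands <- list(band_spec("theta", 4, 8, 10, rep(1, 4)),
                band_spec("alpha", 8, 13, 20, rep(1, 4), effect = eff),
                band_spec("beta1", 13, 20, 8, rep(1, 4)),
                band_spec("beta2", 20, 30, 5, rep(1, 4)))
  cfg <- tiny_config(bands = bands, fs = 200, noise_scale_uV = 5,
                     band_power_drift_sd = 0)
  alpha_of <- function(task, difficulty, seed) {
    bg <- render_background(cfg, task, difficulty, 200 * 30, seed = seed)
    acc <- 0   # average the PSD over all six 5-s stretches (long signal)
    for (k in 0:5)
      acc <- acc + welch_psd(bg[, k * 1000 + 1:1000, drop = FALSE], 200)$psd
    band_power(relative_psd(list(freq_hz = seq(0, 100),
                                 psd = acc / 6)))[1, "alpha"]
  }
  wins <- vapply(1:100, function(s)
    alpha_of("nback", "easy", s) > alpha_of("nback", "hard", 1000 + s),
    logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("an all-silent configuration renders exact zeros", {
  m <- small_montage(4)
  comps <- lapply(scenario_components_silent <- list(
    c("N1", 0.150, 0.012, -1), c("eP3a", 0.245, 0.018, 1),
    c("lP3a", 0.315, 0.025, 1), c("RON", 0.445, 0.035, -1)),
    function(p) component_spec(p[[1]], as.numeric(p[[2]]),
                               as.numeric(p[[3]]), as.numeric(p[[4]]),
                               rep(0, 4), 0))
  bands <- lapply(list(c("theta", 4, 8), c("alpha", 8, 13),
                       c("beta1", 13, 20), c("beta2", 20, 30)),
    function(p) band_spec(p[[1]], as.numeric(p[[2]]), as.numeric(p[[3]]),
                          0, rep(0, 4)))
  cfg <- tiny_config(noise_scale_uV = 0, components = comps, bands = bands)
  rec <- simulate_block(cfg, "s01", "nback", "easy", 1)
  expect_equal(max(abs(rec$data)), 0)
})

test_that("the default 10-min design yields about 40 probes per block", {
  cfg <- sim_config(montage = small_montage(4), n_subjects = 1)
  ev <- sample_event_train(cfg, seed = 3)
  expect_gte(nrow(ev), 30)
  expect_lte(nrow(ev), 50)
})

test_that("identical seeds reproduce a block exactly", {
  cfg <- tiny_config()
  r1 <- simulate_block(cfg, "s01", "matb", "hard", 2)
  r2 <- simulate_block(cfg, "s01", "matb", "hard", 2)
  expect_identical(r1, r2)
  r3 <- simulate_block(cfg, "s01", "matb", "hard", 1)
  expect_false(identical(r1$data, r3$data))
})

test_that("simulate_study covers the full design with per-cell balance", {
  cfg <- tiny_config(n_subjects = 3, block_s = 300)
  recs <- cached("tiny_study_recs", simulate_study(cfg))
  expect_length(recs, 24)
  lab <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r$labels, stringsAsFactors = FALSE)))
  expect_equal(as.vector(table(lab$task, lab$difficulty)), rep(6L, 4))
  expect_equal(length(unique(lab$subject)), 3)
  # ERP epochs fit inside every recording
  for (r in recs[1:3]) {
    expect_true(all(r$events$onset_s >= 0.5))
    expect_true(all(r$events$onset_s <= cfg$block_duration_s - 0.8))
    expect_true(all(is.finite(r$data)))
  }
})

test_that("scenario presets encode the intended effect structure", {
  m <- small_montage(16)
  pl <- sim_config(montage = m, scenario = "paper_like", n_subjects = 2,
                   block_duration_s = 300, sampling_rate_hz = 100)
  # ERP effects identical across tasks for all components except lP3a
  for (cs in pl$components) {
    if (cs$name == "lP3a") {
      expect_equal(cs$effect$matb.hard, 0.6)
      expect_equal(cs$effect$nback.hard, 1)
    } else {
      expect_identical(cs$effect$nback.easy, cs$effect$matb.easy)
      expect_identical(cs$effect$nback.hard, cs$effect$matb.hard)
    }
  }
  # band effects differ between tasks
  alpha <- pl$bands[[2]]
  expect_false(isTRUE(all.equal(alpha$effect$nback.hard,
                                alpha$effect$matb.hard)))
  # null scenario: every factor is exactly 1
  nl <- sim_config(montage = m, scenario = "null", n_subjects = 2,
                   block_duration_s = 300, sampling_rate_hz = 100)
  for (sp in c(nl$components, nl$bands))
    for (v in sp$effect) expect_true(all(v == 1))
  # psd_consistent: band effects identical across tasks
  pc <- sim_config(montage = m, scenario = "psd_consistent", n_subjects = 2,
                   block_duration_s = 300, sampling_rate_hz = 100)
  for (bs in pc$bands) {
    expect_identical(bs$effect$nback.easy, bs$effect$matb.easy)
    expect_identical(bs$effect$nback.hard, bs$effect$matb.hard)
  }
})
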