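test_that("roc_auc equals the Mann-Whitney statistic on hand examples", {
  # perfectly ordered
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1),
                       c("hard", "hard", "easy", "easy")), 1.0)
  # move one hard decision below one easy: 3 of 4 pairs ordered
  expect_equal(roc_auc(c(0.9, 0.4, 0.7, 0.1),
                       c("hard", "hard", "easy", "easy")), 0.75)
  # ties contribute one half
  expect_equal(roc_auc(c(1, 1), c("hard", "easy")), 0.5)
  expect_error(roc_auc(1:3, c("hard", "hard", "hard")), "both classes")
})

test_that("roc_auc agrees with pROC and is ~0.5 under independence", {
  skip_if_not_installed("pROC")
  set.seed(14)
  d <- stats::rnorm(300)
  lab <- sample(c("easy", "hard"), 300, replace = TRUE)
  ours <- roc_auc(d, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(lab, levels = c("easy", "hard")), predictor = d,
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  set.seed(15)
  d2 <- stats::rnorm(2000)
  lab2 <- rep(c("easy", "hard"), 1000)
  expect_equal(roc_auc(d2, lab2), 0.5, tolerance = 0.05)
})

test_that("decision averaging groups consecutive same-condition trials", {
  dec <- data.frame(subject = "s01", task = "nback",
                    difficulty = rep(c("easy", "hard"), each = 10),
                    block = 1L, trial = c(1:10, 1:10),
                    decision = c(1:10, 101:110))
  a1 <- average_decisions(dec, 1)
  expect_equal(a1$decision, dec$decision)
  a5 <- average_decisions(dec, 5)
  expect_equal(nrow(a5), 4)
  expect_equal(sort(a5$decision), c(mean(1:5), mean(6:10),
                                    mean(101:105), mean(106:110)))
  expect_true(all(a5$group_size == 5))
  # groups never mix conditions
  expect_equal(as.vector(table(a5$difficulty)), c(2L, 2L))
  expect_error(average_decisions(dec, 0), ">= 1")
})

test_that("trailing remainder groups follow the ceiling(n/2) rule", {
  mk <- function(k) data.frame(subject = "s01", task = "nback",
                               difficulty = "easy", block = 1L,
                               trial = seq_len(k), decision = seq_len(k))
  # 7 trials, n = 5: remainder 2 < 3 -> dropped
  expect_equal(nrow(average_decisions(mk(7), 5)), 1)
  # 8 trials, n = 5: remainder 3 >= 3 -> kept
  a <- average_decisions(mk(8), 5)
  expect_equal(nrow(a), 2)
  expect_equal(a$decision[2], mean(6:8))
  expect_equal(a$group_size, c(5L, 3L))
})

test_that("decision ordering is chronological regardless of row order", {
  dec <- data.frame(subject = "s01", task = "nback", difficulty = "easy",
                    block = 1L, trial = 1:6, decision = c(10, 20, 30, 40, 50, 60))
  shuffled <- dec[c(3, 1, 6, 2, 5, 4), ]
  expect_equal(average_decisions(shuffled, 3)$decision, c(20, 50))
})

test_that("the SVM separates a separable toy problem and orients to hard", {
  set.seed(16)
  x_easy <- matrix(stats::rnorm(40, mean = -3, sd = 0.3), 20, 2)
  x_hard <- matrix(stats::rnorm(40, mean = +3, sd = 0.3), 20, 2)
  tr <- manual_features(rbind(x_easy, x_hard),
                        rep(c("easy", "hard"), each = 20))
  te <- manual_features(rbind(x_easy + 0.1, x_hard - 0.1),
                        rep(c("easy", "hard"), each = 20))
  dec <- fit_predict_decision(tr, te)
  expect_true(all(dec$decision[te$difficulty == "hard"] > 0))
  expect_true(all(dec$decision[te$difficulty == "easy"] < 0))
  expect_equal(roc_auc(dec$decision, dec$difficulty), 1.0)
  # train = test stays perfectly separable
  dec2 <- fit_predict_decision(tr, tr)
  expect_equal(roc_auc(dec2$decision, dec2$difficulty), 1.0)
})

test_that("label-swapped training negates the oriented decisions", {
  set.seed(17)
  x <- matrix(stats::rnorm(60 * 3), 60, 3)
  x[31:60, 1] <- x[31:60, 1] + 1.5
  tr <- manual_features(x, rep(c("easy", "hard"), each = 30))
  te <- manual_features(matrix(stats::rnorm(20 * 3), 20, 3),
                        rep(c("easy", "hard"), 10))
  swapped <- tr
  swapped$difficulty <- ifelse(tr$difficulty == "easy", "hard", "easy")
  d1 <- fit_predict_decision(tr, te)$decision
  d2 <- fit_predict_decision(swapped, te)$decision
  expect_equal(d1, -d2, tolerance = 1e-9)
  # single-class training refuses to fit
  expect_error(fit_predict_decision(tr[tr$difficulty == "easy", ], te),
               "single class")
})

test_that("run_suite enforces disjoint folds and fills the result grid", {
  tabs <- list(erp = toy_study_table(n_per_cell = 12, d = 4,
                                     shift = c(nback = 3, matb = 3)))
  res <- run_suite(tabs, n_set = c(1, 5))
  expect_equal(nrow(res), 4 * 2)        # 4 schemes x 2 averaging counts
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  # a strongly separable table classifies perfectly in all schemes
  expect_true(all(res$auc == 1))
  # n = 1 equals raw-trial AUC (identity averaging)
  expect_equal(res$auc[res$n_avg == 1], rep(1, 4))
})

test_that("run_suite stays at chance under label-independent features", {
  set.seed(18)
  tabs <- list(psd = toy_study_table(n_per_cell = 25, d = 6,
                                     shift = c(nback = 0, matb = 0),
                                     family = "psd"))
  res <- run_suite(tabs, n_set = 1)
  expect_true(all(res$auc > 0.2 & res$auc < 0.8))
  expect_equal(mean(res$auc), 0.5, tolerance = 0.15)
})
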