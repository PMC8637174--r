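#' Fit an RBF-kernel SVM and return test decision values
#'
#' Features are z-scored with training-set statistics only; the kernel
#' width is `gamma = 1 / (d * median feature variance of the standardized
#' training set)` and the cost is fixed at `C = 1`. Decision values are
#' oriented so that positive means "hard".
#'
#' @param train_table,test_table `mwl_features` tables; the training table
#'   must contain both difficulty classes.
#' @param cost SVM cost parameter.
#' @param gamma optional kernel width override.
#' @return data.frame: the test provenance columns plus `decision`.
#' @export
fit_predict_decision <- function(train_table, test_table, cost = 1,
                                 gamma = NULL) {
  ytr <- factor(train_table$difficulty, levels = c("easy", "hard"))
  if (length(unique(ytr)) < 2L) stop("training set has a single class")
  xtr <- feature_matrix(train_table)
  xte <- feature_matrix(test_table)
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xtr <- scale(xtr, center = mu, scale = sdv)
  xte <- scale(xte, center = mu, scale = sdv)
  if (is.null(gamma)) {
    medvar <- stats::median(apply(xtr, 2, stats::var))
    if (!is.finite(medvar) || medvar <= 0) medvar <- 1
    gamma <- 1 / (ncol(xtr) * medvar)
  }
  fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  dtr <- as.numeric(attr(stats::predict(fit, xtr, decision.values = TRUE),
                         "decision.values"))
  flip <- mean(dtr[ytr == "hard"]) < mean(dtr[ytr == "easy"])
  dte <- as.numeric(attr(stats::predict(fit, xte, decision.values = TRUE),
                         "decision.values"))
  if (flip) dte <- -dte
  out <- test_table[, c("subject", "task", "difficulty", "block", "trial")]
  out$decision <- dte
  out
}

#' Average decision values over consecutive trials
#'
#' Within each (subject, task, difficulty, block) cell, chronologically
#' ordered decisions are partitioned into non-overlapping consecutive
#' groups of size `n` and averaged; a trailing remainder group is kept if
#' it has at least `ceiling(n / 2)` trials, otherwise dropped. Groups
#' never mix conditions.
#'
#' @param decisions data.frame as returned by [fit_predict_decision()].
#' @param n group size (`n = 1` is the identity).
#' @return data.frame with one row per group: cell labels, `decision`
#'   (group mean) and `group_size`.
#' @export
average_decisions <- function(decisions, n) {
  if (n < 1L) stop("n must be >= 1")
  if (n == 1L) {
    decisions$group_size <- 1L
    return(decisions[, c("subject", "task", "difficulty", "block",
                         "decision", "group_size")])
  }
  key <- interaction(decisions$subject, decisions$task,
                     decisions$difficulty, decisions$block, drop = TRUE)
  parts <- split(decisions, key)
  rows <- lapply(parts, function(d) {
    d <- d[order(d$trial), , drop = FALSE]
    grp <- (seq_len(nrow(d)) - 1L) %/% n + 1L
    sizes <- tabulate(grp)
    keep_last <- sizes[length(sizes)] >= ceiling(n / 2)
    means <- tapply(d$decision, grp, mean)
    if (!keep_last && length(means) > 1L) {
      means <- means[-length(means)]
      sizes <- sizes[-length(sizes)]
    } else if (!keep_last) {
      return(NULL)
    }
    data.frame(subject = d$subject[1], task = d$task[1],
               difficulty = d$difficulty[1], block = d$block[1],
               decision = as.numeric(means), group_size = sizes[seq_along(means)])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random "hard"
#' decision value exceeds a random "easy" one, with ties counting one
#' half.
#'
#' @param decisions numeric decision values (positive-oriented to "hard").
#' @param labels difficulty labels (`"easy"` / `"hard"`) per decision.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(decisions, labels) {
  pos <- labels == "hard"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes required for ROC-AUC")
  r <- rank(decisions, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

scheme_table <- function() {
  data.frame(
    scheme = c("within_nback", "within_matb",
               "nback_train_matb_test", "matb_train_nback_test"),
    train_task = c("nback", "matb", "nback", "matb"),
    test_task = c("nback", "matb", "matb", "nback"),
    within = c(TRUE, TRUE, FALSE, FALSE))
}

#' Run the full classification suite
#'
#' For every subject, feature family, scheme and trial-averaging count:
#' within-task schemes use block-wise 2-fold cross-validation (train block
#' 1, test block 2 and the reverse; the two fold AUCs are averaged);
#' cross-task schemes train on all blocks of the training task and test on
#' all blocks of the other task. Decisions are averaged over `n`
#' consecutive same-condition trials before ROC scoring.
#'
#' @param tables named list of `mwl_features` tables (e.g. `erp`, `psd`).
#' @param n_set trial-averaging counts (default 1, 5, 10).
#' @param cost SVM cost.
#' @return data.frame: subject, family, scheme, n_avg, auc, n_test_groups.
#' @export
run_suite <- function(tables, n_set = c(1, 5, 10), cost = 1) {
  schemes <- scheme_table()
  res <- list()
  for (family in names(tables)) {
    tab <- tables[[family]]
    for (sid in unique(tab$subject)) {
      st <- tab[tab$subject == sid, , drop = FALSE]
      for (k in seq_len(nrow(schemes))) {
        sc <- schemes[k, ]
        folds <- if (sc$within) list(c(1, 2), c(2, 1)) else list(NA)
        dec_by_fold <- lapply(folds, function(fold) {
          if (sc$within) {
            tr <- st[st$task == sc$train_task & st$block == fold[1], ]
            te <- st[st$task == sc$test_task & st$block == fold[2], ]
          } else {
            tr <- st[st$task == sc$train_task, ]
            te <- st[st$task == sc$test_task, ]
          }
          stopifnot(nrow(merge(tr[c("task", "block", "trial")],
                               te[c("task", "block", "trial")])) == 0L)
          fit_predict_decision(tr, te, cost = cost)
        })
        for (n in n_set) {
          aucs <- vapply(dec_by_fold, function(dec) {
            avg <- average_decisions(dec, n)
            roc_auc(avg$decision, avg$difficulty)
          }, numeric(1))
          ngrp <- sum(vapply(dec_by_fold, function(dec)
            nrow(average_decisions(dec, n)), integer(1)))
          res[[length(res) + 1L]] <- data.frame(
            subject = sid, family = family, scheme = sc$scheme,
            n_avg = n, auc = mean(aucs), n_test_groups = ngrp)
        }
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
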