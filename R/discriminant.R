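#' Signed Fisher discriminant ratio
#'
#' For one feature, `(mean_easy - mean_hard) / sqrt(var_easy + var_hard)`
#' with unbiased (n-1) sample variances. The magnitude measures easy/hard
#' separability; the sign is positive when the feature is larger in the
#' easy condition.
#'
#' @param values_easy,values_hard numeric samples (single-trial feature
#'   values), each of length at least 2.
#' @return a single numeric value. Degenerate cases: if both variances are
#'   zero the result is signed infinity (means differ) or 0 (means equal),
#'   with a warning either way.
#' @export
f_signed <- function(values_easy, values_hard) {
  if (length(values_easy) < 2L || length(values_hard) < 2L)
    stop("each condition needs at least 2 values")
  num <- mean(values_easy) - mean(values_hard)
  den <- sqrt(stats::var(values_easy) + stats::var(values_hard))
  if (den == 0) {
    warning("zero pooled variance in f_signed")
    return(if (num == 0) 0 else sign(num) * Inf)
  }
  num / den
}

# Vectorized over feature columns: easy/hard are trial x feature matrices.
f_signed_cols <- function(easy, hard) {
  m <- colMeans(easy) - colMeans(hard)
  v <- apply(easy, 2, stats::var) + apply(hard, 2, stats::var)
  out <- ifelse(v > 0, m / sqrt(v), ifelse(m == 0, 0, sign(m) * Inf))
  out
}

#' Per-feature cross-task discriminant difference
#'
#' Elementwise `|f_nback - f_matb|` between the two tasks' signed Fisher
#' ratios over the same feature set.
#'
#' @param f_nback,f_matb named numeric vectors over identical features.
#' @return named numeric vector of absolute differences.
#' @export
delta_f <- function(f_nback, f_matb) {
  if (!identical(names(f_nback), names(f_matb)))
    stop("feature sets differ between tasks")
  abs(f_nback - f_matb)
}

#' Per-subject discriminant map for one feature family
#'
#' For every subject and feature: the signed Fisher ratio within each task
#' (easy vs hard trials pooled over the two blocks), their absolute
#' difference, and the per-subject mean of the absolute differences over
#' all finite features.
#'
#' @param table an `mwl_features` table covering both tasks.
#' @return list with `per_feature` (data.frame: subject, feature, f_nback,
#'   f_matb, delta_abs) and `per_subject` (data.frame: subject,
#'   mean_delta_abs, n_excluded).
#' @export
discriminant_map <- function(table) {
  fn <- attr(table, "feature_names")
  subjects <- unique(table$subject)
  pf <- list(); ps <- list()
  for (sid in subjects) {
    fs <- lapply(c("nback", "matb"), function(task) {
      easy <- feature_matrix(table[table$subject == sid & table$task == task &
                                     table$difficulty == "easy", ])
      hard <- feature_matrix(table[table$subject == sid & table$task == task &
                                     table$difficulty == "hard", ])
      if (nrow(easy) < 2L || nrow(hard) < 2L)
        stop("subject ", sid, " lacks trials in task ", task)
      f <- f_signed_cols(easy, hard)
      names(f) <- fn
      f
    })
    d <- delta_f(fs[[1]], fs[[2]])
    finite <- is.finite(d)
    pf[[sid]] <- data.frame(subject = sid, feature = fn,
                            f_nback = fs[[1]], f_matb = fs[[2]],
                            delta_abs = d, row.names = NULL)
    ps[[sid]] <- data.frame(subject = sid,
                            mean_delta_abs = mean(d[finite]),
                            n_excluded = sum(!finite))
  }
  list(per_feature = do.call(rbind, pf), per_subject = do.call(rbind, ps))
}

#' Cross-task consistency comparison between feature families
#'
#' Computes per-subject mean `|deltaF|` for the ERP and PSD families and
#' compares them with a bootstrap paired t-test. Lower mean `|deltaF|`
#' means higher cross-task consistency of the family's discriminability.
#'
#' @param tables named list with `mwl_features` elements `erp` and `psd`
#'   covering the same subjects.
#' @param n_boot bootstrap iterations for the paired test.
#' @param seed integer seed for the bootstrap.
#' @return list with `per_subject` (subject, mean_delta_erp,
#'   mean_delta_psd), `maps` (both discriminant maps), and `test`
#'   (t statistic, bootstrap p, n subjects).
#' @export
consistency_summary <- function(tables, n_boot = 1000, seed = 1L) {
  stopifnot(all(c("erp", "psd") %in% names(tables)))
  m_erp <- discriminant_map(tables$erp)
  m_psd <- discriminant_map(tables$psd)
  stopifnot(identical(m_erp$per_subject$subject, m_psd$per_subject$subject))
  if (nrow(m_erp$per_subject) < 3L)
    stop("group comparison needs at least 3 subjects")
  per_subject <- data.frame(
    subject = m_erp$per_subject$subject,
    mean_delta_erp = m_erp$per_subject$mean_delta_abs,
    mean_delta_psd = m_psd$per_subject$mean_delta_abs)
  test <- boot_paired_ttest(per_subject$mean_delta_erp,
                            per_subject$mean_delta_psd,
                            n_boot = n_boot, seed = seed)
  list(per_subject = per_subject,
       maps = list(erp = m_erp, psd = m_psd),
       test = test)
}
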