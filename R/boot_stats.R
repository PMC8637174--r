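# Vectorized bootstrap engine for one-sample t statistics.
# D: n x m matrix, each column one dataset of paired differences (or
# within-subject contrasts). The null sample for each column is built by
# resampling its mean-centered values with replacement, with independent
# resample indices per column. Returns t_obs and two-sided bootstrap p per
# column, both with the +1 correction so p is always in (0, 1].
boot_t_engine <- function(D, n_boot, two_sided = TRUE) {
  D <- as.matrix(D)
  n <- nrow(D); m <- ncol(D)
  cm <- colMeans(D)
  cv <- colMeans(D^2) - cm^2
  cv <- cv * n / (n - 1)
  t_obs <- ifelse(cv > 0, cm / sqrt(cv / n),
                  ifelse(cm == 0, 0, sign(cm) * Inf))
  Dc <- sweep(D, 2, cm)                       # centered null population
  exceed <- numeric(m)
  ref <- if (two_sided) abs(t_obs) else t_obs
  for (b in seq_len(n_boot)) {
    idx <- matrix(sample.int(n, n * m, replace = TRUE), n, m)
    Db <- matrix(Dc[cbind(as.vector(idx), rep(seq_len(m), each = n))], n, m)
    bm <- colMeans(Db)
    bv <- (colMeans(Db^2) - bm^2) * n / (n - 1)
    tb <- ifelse(bv > 0, bm / sqrt(bv / n), 0)
    exceed <- exceed + if (two_sided) (abs(tb) >= ref) else (tb >= ref)
  }
  p <- (1 + exceed) / (n_boot + 1)
  list(t_obs = t_obs, p = p)
}

#' Bootstrap paired t-test
#'
#' Paired t statistic on `d = x - y`; the null distribution is built by
#' resampling the mean-centered differences with replacement `n_boot`
#' times and recomputing t. Two-sided p uses the +1 correction,
#' `(1 + #(|t*| >= |t_obs|)) / (n_boot + 1)`, so p is never zero.
#'
#' @param x,y paired per-subject values, equal length of at least 3.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed optional integer seed.
#' @return list with `t`, `p`, `n`, and `degenerate` (TRUE when the
#'   differences have zero variance).
#' @export
boot_paired_ttest <- function(x, y, n_boot = 1000, seed = NULL) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must be paired with length >= 3")
  d <- x - y
  if (stats::var(d) == 0) {
    return(list(t = if (all(d == 0)) 0 else sign(d[1]) * Inf,
                p = 1, n = length(d), degenerate = TRUE))
  }
  run <- function() boot_t_engine(matrix(d, ncol = 1), n_boot)
  r <- if (is.null(seed)) run() else with_seed(seed, run())
  list(t = r$t_obs[1], p = r$p[1], n = length(d), degenerate = FALSE)
}

# Per-subject effect contrasts of the 2 x 2 within-subject design.
# values: n x 2 x 2 array, dims subject x task (nback, matb) x
# difficulty (easy, hard).
rm2x2_contrasts <- function(values) {
  stopifnot(length(dim(values)) == 3L, all(dim(values)[2:3] == 2L))
  mwl  <- (values[, 1, 1] + values[, 2, 1] - values[, 1, 2] - values[, 2, 2]) / 2
  task <- (values[, 1, 1] + values[, 1, 2] - values[, 2, 1] - values[, 2, 2]) / 2
  ixn  <- (values[, 1, 1] - values[, 1, 2] - values[, 2, 1] + values[, 2, 2]) / 2
  cbind(mwl = mwl, task = task, interaction = ixn)
}

#' Bootstrap two-way (MWL x task) repeated-measures ANOVA
#'
#' For a 2 x 2 within-subject design each effect (workload, task,
#' interaction) has one degree of freedom and its F statistic -- effect
#' mean square over the subject-by-effect interaction mean square --
#' equals `n * mean(c)^2 / var(c)` where `c` is the per-subject effect
#' contrast. The null distribution of each effect is built by resampling
#' subjects' mean-centered contrasts with replacement.
#'
#' @param values numeric array subject x task(2: nback, matb) x
#'   difficulty(2: easy, hard); no empty cells.
#' @param n_boot bootstrap iterations.
#' @param seed optional integer seed.
#' @return data.frame with rows mwl, task, interaction and columns
#'   `effect`, `F`, `p`.
#' @export
boot_rm_anova2 <- function(values, n_boot = 1000, seed = NULL) {
  if (anyNA(values)) stop("empty or missing design cells")
  C <- rm2x2_contrasts(values)
  run <- function() boot_t_engine(C, n_boot)
  r <- if (is.null(seed)) run() else with_seed(seed, run())
  data.frame(effect = colnames(C), F = r$t_obs^2, p = r$p, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up BH over one family of p values.
#'
#' @param p_values numeric vector of raw p values.
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` (BH-adjusted p values) and `mask`
#'   (logical, `adjusted <= q`).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value family")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, mask = adj <= q)
}

#' Cell-wise bootstrap statistical map
#'
#' Applies the bootstrap paired t-test (`test = "paired_t"`) or the
#' bootstrap 2 x 2 repeated-measures ANOVA (`test = "rm_anova"`) to every
#' cell of a channel x bin grid, then corrects the whole map as one FDR
#' family and zeroes non-significant cells in the display copy.
#'
#' For `"paired_t"`, `values` is subject x cell x condition(2: easy,
#' hard) and the map statistic is t(easy - hard). For `"rm_anova"`,
#' `values` is subject x cell x task(2) x difficulty(2) and one map per
#' effect is returned.
#'
#' @param values numeric array as above; the cell dimension may carry a
#'   `dim` attribute `cell_dims = c(n_channels, n_bins)`.
#' @param test `"paired_t"` or `"rm_anova"`.
#' @param n_boot bootstrap iterations per cell.
#' @param q FDR level.
#' @param seed optional integer seed.
#' @param channels,bins optional dimension labels for the long-format
#'   export.
#' @return for `"paired_t"` an `mwl_statmap` (list: statistic, p_raw,
#'   p_fdr, mask, display, channels, bins); for `"rm_anova"` a named list
#'   of three `mwl_statmap`s (mwl, task, interaction).
#' @export
stat_map <- function(values, test = c("paired_t", "rm_anova"),
                     n_boot = 1000, q = 0.05, seed = NULL,
                     channels = NULL, bins = NULL) {
  test <- match.arg(test)
  run <- function() {
    if (test == "paired_t") {
      stopifnot(length(dim(values)) == 3L, dim(values)[3] == 2L)
      D <- values[, , 1] - values[, , 2]
      r <- boot_t_engine(as.matrix(D), n_boot)
      finish_map(r$t_obs, r$p, q, channels, bins, dim(values)[2])
    } else {
      stopifnot(length(dim(values)) == 4L, all(dim(values)[3:4] == 2L))
      m <- dim(values)[2]
      Cs <- lapply(seq_len(m), function(j)
        rm2x2_contrasts(values[, j, , , drop = TRUE]))
      effects <- c("mwl", "task", "interaction")
      out <- list()
      for (e in seq_along(effects)) {
        D <- vapply(Cs, function(C) C[, e], numeric(dim(values)[1]))
        r <- boot_t_engine(as.matrix(D), n_boot)
        out[[effects[e]]] <- finish_map(r$t_obs^2, r$p, q, channels, bins, m)
      }
      out
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

finish_map <- function(statistic, p_raw, q, channels, bins, m) {
  fdr <- fdr_correct(p_raw, q)
  structure(list(statistic = statistic, p_raw = p_raw,
                 p_fdr = fdr$adjusted, mask = fdr$mask,
                 display = statistic * fdr$mask,
                 channels = channels, bins = bins, n_cells = m),
            class = "mwl_statmap")
}

#' Long-format export of a statistical map
#'
#' @param map an `mwl_statmap`.
#' @return data.frame with columns channel, bin, statistic, p_raw, p_fdr,
#'   significant.
#' @export
statmap_to_df <- function(map) {
  stopifnot(inherits(map, "mwl_statmap"))
  nch <- if (is.null(map$channels)) map$n_cells else length(map$channels)
  nb <- max(1L, map$n_cells %/% nch)
  data.frame(
    channel = rep(if (is.null(map$channels)) seq_len(nch) else map$channels,
                  times = nb),
    bin = rep(if (is.null(map$bins)) seq_len(nb) else map$bins, each = nch),
    statistic = map$statistic, p_raw = map$p_raw, p_fdr = map$p_fdr,
    significant = map$mask)
}
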