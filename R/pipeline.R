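#' Run the full study pipeline
#'
#' Simulate (or stream) every block of the configured study, preprocess,
#' extract single-trial ERP and relative band-power features, compute the
#' cross-task discriminant consistency comparison, run the classification
#' suite, build channel x component and channel x band statistical maps,
#' and write all artifacts plus a machine-readable report. Fully
#' deterministic given the config (including its master seed): running
#' twice produces byte-identical files.
#'
#' @param config an `mwl_config`, or the path to a YAML file for
#'   [config_from_yaml()].
#' @param out_dir output directory (created if needed).
#' @param n_boot bootstrap iterations for all tests.
#' @param n_set trial-averaging counts for classification.
#' @return the study report (also written to `report.json`), a list with
#'   the config hash, per-stage counts, the consistency test, the
#'   classification summary, and the artifact paths.
#' @export
run_study <- function(config, out_dir, n_boot = 1000, n_set = c(1, 5, 10)) {
  if (is.character(config)) config <- config_from_yaml(config)
  stopifnot(inherits(config, "mwl_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  counts <- new.env()
  counts$events <- 0L; counts$erp_kept <- 0L; counts$erp_rejected <- 0L
  counts$spectral_kept <- 0L; counts$spectral_skipped <- 0L
  results <- simulate_study(config, apply_fn = function(rec) {
    pp <- preprocess_block(rec)
    counts$events <- counts$events + nrow(rec$events)
    counts$erp_kept <- counts$erp_kept + nrow(pp$erp$provenance)
    counts$erp_rejected <- counts$erp_rejected +
      round(attr(pp$erp, "rejected_fraction") * nrow(rec$events))
    counts$spectral_kept <- counts$spectral_kept + nrow(pp$spectral$provenance)
    counts$spectral_skipped <- counts$spectral_skipped +
      attr(pp$spectral, "n_skipped")
    list(erp = erp_feature_table(pp$erp),
         psd = psd_feature_table(pp$spectral))
  })
  tables <- list(erp = bind_features(lapply(results, `[[`, "erp")),
                 psd = bind_features(lapply(results, `[[`, "psd")))
  paths <- c(features_erp = file.path(out_dir, "features_erp.csv"),
             features_psd = file.path(out_dir, "features_psd.csv"))
  write_feature_csv(tables$erp, paths[["features_erp"]])
  write_feature_csv(tables$psd, paths[["features_psd"]])

  # discriminant consistency
  consistency <- NULL
  if (config$n_subjects >= 3L) {
    consistency <- consistency_summary(
      tables, n_boot = n_boot,
      seed = substream_seed(config$seed, "boot/consistency"))
    p <- file.path(out_dir, c("discriminant_erp.csv", "discriminant_psd.csv",
                              "consistency_subjects.csv",
                              "consistency_test.json"))
    utils::write.csv(consistency$maps$erp$per_feature, p[1], row.names = FALSE)
    utils::write.csv(consistency$maps$psd$per_feature, p[2], row.names = FALSE)
    utils::write.csv(consistency$per_subject, p[3], row.names = FALSE)
    jsonlite::write_json(consistency$test, p[4], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, discriminant_erp = p[1], discriminant_psd = p[2],
               consistency_subjects = p[3], consistency_test = p[4])
  } else {
    warning("fewer than 3 subjects: group consistency test skipped")
    m <- discriminant_map(tables$erp); mp <- discriminant_map(tables$psd)
    p <- file.path(out_dir, c("discriminant_erp.csv", "discriminant_psd.csv"))
    utils::write.csv(m$per_feature, p[1], row.names = FALSE)
    utils::write.csv(mp$per_feature, p[2], row.names = FALSE)
    paths <- c(paths, discriminant_erp = p[1], discriminant_psd = p[2])
  }

  # classification
  cls <- run_suite(tables, n_set = n_set)
  p_cls <- file.path(out_dir, "classification.csv")
  utils::write.csv(cls, p_cls, row.names = FALSE)
  summ <- stats::aggregate(auc ~ family + scheme + n_avg, cls,
                           function(a) c(mean = mean(a), sd = stats::sd(a)))
  cls_summary <- data.frame(summ[1:3], auc_mean = summ$auc[, "mean"],
                            auc_sd = summ$auc[, "sd"])
  p_clss <- file.path(out_dir, "classification_summary.json")
  jsonlite::write_json(cls_summary, p_clss, digits = NA, pretty = TRUE)
  paths <- c(paths, classification = p_cls, classification_summary = p_clss)

  # channel x component / channel x band statistical maps
  if (config$n_subjects >= 3L) {
    for (family in c("erp", "psd")) {
      arr <- condition_mean_array(tables[[family]])
      map <- stat_map(arr$anova, test = "rm_anova", n_boot = n_boot,
                      seed = substream_seed(config$seed,
                                            paste0("boot/map_", family)),
                      channels = arr$channels, bins = arr$bins)
      for (eff in names(map)) {
        pm <- file.path(out_dir, sprintf("statmap_%s_%s.csv", family, eff))
        utils::write.csv(statmap_to_df(map[[eff]]), pm, row.names = FALSE)
        paths <- c(paths, stats::setNames(pm, sprintf("statmap_%s_%s",
                                                      family, eff)))
      }
    }
  }

  report <- list(
    config_hash = hash,
    scenario = config$scenario,
    n_subjects = config$n_subjects,
    n_recordings = config$n_subjects * 8L,
    counts = list(events = counts$events,
                  erp_epochs_kept = counts$erp_kept,
                  erp_epochs_rejected = counts$erp_rejected,
                  spectral_epochs_kept = counts$spectral_kept,
                  spectral_intervals_skipped = counts$spectral_skipped),
    consistency_test = if (is.null(consistency)) NULL else consistency$test,
    seed_registry = list(master = config$seed,
                         consistency = substream_seed(config$seed,
                                                      "boot/consistency")),
    artifacts = as.list(paths))
  on_disk <- report
  on_disk$artifacts <- as.list(vapply(paths, basename, character(1)))
  jsonlite::write_json(on_disk, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# Per-subject condition means of every feature, arranged for stat_map:
# subject x feature x task x difficulty.
condition_mean_array <- function(table) {
  fn <- attr(table, "feature_names")
  subjects <- sort(unique(table$subject))
  arr <- array(NA_real_, c(length(subjects), length(fn), 2, 2),
               dimnames = list(subjects, fn, c("nback", "matb"),
                               c("easy", "hard")))
  for (si in seq_along(subjects))
    for (ti in 1:2)
      for (di in 1:2) {
        sel <- table$subject == subjects[si] &
          table$task == c("nback", "matb")[ti] &
          table$difficulty == c("easy", "hard")[di]
        arr[si, , ti, di] <- colMeans(feature_matrix(table[sel, , drop = FALSE]))
      }
  if (anyNA(arr)) stop("empty design cell for a subject")
  channels <- unique(sub("\\.[^.]+$", "", fn))
  bins <- unique(sub("^.*\\.", "", fn))
  list(anova = arr, channels = channels, bins = bins)
}
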