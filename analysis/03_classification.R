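#!/usr/bin/env Rscript

# Workload classification: RBF-SVM with block-wise within-task
# cross-validation and both cross-task transfer directions, decision
# values averaged over n = 1, 5, 10 consecutive trials before ROC-AUC
# scoring.
#
# Reads results/features_{erp,psd}.csv; writes results/classification.csv
# and results/classification_summary.csv.

library(probemwl)

tabs <- list(erp = read_feature_csv("results/features_erp.csv", "erp"),
             psd = read_feature_csv("results/features_psd.csv", "psd"))
cls <- run_suite(tabs, n_set = c(1, 5, 10))
write.csv(cls, "results/classification.csv", row.names = FALSE)

agg <- aggregate(auc ~ family + scheme + n_avg, cls, mean)
sdv <- aggregate(auc ~ family + scheme + n_avg, cls, sd)
summary_df <- data.frame(agg[1:3], auc_mean = agg$auc, auc_sd = sdv$auc)
write.csv(summary_df, "results/classification_summary.csv", row.names = FALSE)

for (sch in c("nback_train_matb_test", "matb_train_nback_test")) {
  e <- summary_df[summary_df$scheme == sch & summary_df$n_avg == 10, ]
  message(sprintf("%s, n = 10: AUC ERP %.3f vs PSD %.3f", sch,
                  e$auc_mean[e$family == "erp"],
                  e$auc_mean[e$family == "psd"]))
}
message("full grid written to results/classification_summary.csv")
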