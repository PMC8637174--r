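#!/usr/bin/env Rscript

# Channel x component and channel x band statistical maps: bootstrap 2x2
# (workload x task) repeated-measures ANOVAs on per-subject condition
# means, plus per-task bootstrap paired t-tests (easy vs hard), all
# FDR-corrected over each map with non-significant cells zeroed in the
# display copy.
#
# Reads results/features_{erp,psd}.csv; writes
# results/statmap_<family>_<effect>.csv and
# results/statmap_<family>_ttest_<task>.csv.

library(probemwl)

for (family in c("erp", "psd")) {
  tab <- read_feature_csv(sprintf("results/features_%s.csv", family), family)
  arr <- probemwl:::condition_mean_array(tab)
  maps <- stat_map(arr$anova, test = "rm_anova", n_boot = 1000,
                   seed = substream_seed(2, paste0("maps/", family)),
                   channels = arr$channels, bins = arr$bins)
  for (eff in names(maps)) {
    f <- sprintf("results/statmap_%s_%s.csv", family, eff)
    write.csv(statmap_to_df(maps[[eff]]), f, row.names = FALSE)
    message(sprintf("%s %s effect: %d/%d cells significant (FDR 0.05)",
                    family, eff, sum(maps[[eff]]$mask),
                    length(maps[[eff]]$mask)))
  }
  for (ti in 1:2) {
    task <- c("nback", "matb")[ti]
    tmap <- stat_map(arr$anova[, , ti, ], test = "paired_t", n_boot = 1000,
                     seed = substream_seed(2, paste0("maps/", family, task)),
                     channels = arr$channels, bins = arr$bins)
    f <- sprintf("results/statmap_%s_ttest_%s.csv", family, task)
    write.csv(statmap_to_df(tmap), f, row.names = FALSE)
    message(sprintf("%s easy-hard t-map (%s): %d/%d cells significant",
                    family, task, sum(tmap$mask), length(tmap$mask)))
  }
}
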