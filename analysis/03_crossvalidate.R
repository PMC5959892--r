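#!/usr/bin/env Rscript
# Leave-one-patient-out cross-validation of the 25-component PC-LDA
# recognition model on the simulated cohort, with sample-level majority
# voting and 75% reliability thresholding. Writes confusion tables and a
# recognition summary.

library(reims)

cohort <- read_peaklists("scratch/cohort_peaks.csv", "scratch/cohort_meta.csv")
cohort <- filter_low_tumour(cohort, min_content = 50)
cv <- lopocv(cohort, n_pcs = 25, threshold = 0.75)

ms <- metrics(cv$confusion_sample)
mx <- metrics(cv$confusion_spectrum)
cat(sprintf("LOPOCV: %d folds. Sample-level correct classification %.1f%%, spectrum-level %.1f%%.\n",
            length(unique(cv$assignments$fold)), ms$overall_pct, mx$overall_pct))
print(cv$confusion_sample)
print(ms$per_class)

rec <- recognition_summary(cv$assignments, threshold = 0.75)
cat(sprintf("Recognition at 75%% reliability: %d/%d burns reported (%.1f%%), %.1f%% of reported correct.\n",
            rec$n_reported, rec$n_total, rec$reported_pct, rec$accuracy_pct))

write.csv(as.data.frame(cv$confusion_sample),
          "results/lopocv_confusion_sample.csv", row.names = FALSE)
write.csv(as.data.frame(cv$confusion_spectrum),
          "results/lopocv_confusion_spectrum.csv", row.names = FALSE)
write.csv(cbind(ms$per_class, overall_pct = ms$overall_pct),
          "results/lopocv_metrics.csv", row.names = FALSE)
write.csv(data.frame(n_total = rec$n_total, n_reported = rec$n_reported,
                     n_correct = rec$n_correct,
                     reported_pct = rec$reported_pct,
                     accuracy_pct = rec$accuracy_pct),
          "results/recognition_summary.csv", row.names = FALSE)
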