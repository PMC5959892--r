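#!/usr/bin/env Rscript
# Simulate the reference cohort: 3 tissue classes (normal, borderline,
# cancer) x 10 patients x 2 samples x 3 burns, five discriminant lipid
# peaks planted at 673.481, 685.517, 699.497, 742.539 and 744.555 m/z
# (fold change 4), patient effect SD 0.2, burn noise SD 0.1, calibration
# drift SD 0.02 Da around the 699.497 lock mass.
# Intermediate peak lists go to scratch/ (regenerable); a small design
# summary goes to results/.

library(reims)

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(seed = 20180419)
cohort <- generate_cohort(cfg)
write_peaklists(cohort, "scratch/cohort_peaks.csv", "scratch/cohort_meta.csv")

gt <- ground_truth(cfg, "cancer", "normal")
gt_bot <- ground_truth(cfg, "cancer", "borderline")
truth <- data.frame(mz = gt$mz, bin = gt$bin,
                    log2fc_cancer_vs_normal = gt$log2fc,
                    log2fc_cancer_vs_borderline = gt_bot$log2fc)
write.csv(truth[truth$log2fc_cancer_vs_normal != 0 |
                truth$log2fc_cancer_vs_borderline != 0, ],
          "results/simulated_ground_truth.csv", row.names = FALSE)

m <- cohort_meta(cohort)
cat(sprintf("Simulated %d spectra (%d patients, %d samples).\n",
            nrow(m), length(unique(m$patient_id)),
            length(unique(m$sample_id))))
cat("Planted discriminant bins:",
    paste(sort(unique(gt$bin[gt$discriminant | gt_bot$log2fc != 0])),
          collapse = ", "), "\n")
cat("Peak lists written to scratch/cohort_peaks.csv\n")
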