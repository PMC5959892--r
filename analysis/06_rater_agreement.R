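#!/usr/bin/env Rscript
# Inter-rater agreement on simulated metastatic sampling points: the
# recognition model's calls vs ground-truth histology, and a simulated
# surgeon who misses small deposits (visual assessment is insensitive to
# microscopic tumour), compared with Cohen's kappa.

library(reims)

set.seed(20180419)

cohort <- read_peaklists("scratch/cohort_peaks.csv", "scratch/cohort_meta.csv")
cv <- lopocv(cohort)
asg <- cv$assignments
# one rated site per sample: histology = truth, iknife = model call
sites <- unique(asg[, c("sample_id", "truth", "sample_call")])
# surgeon: correct on obvious sites, miscalls ~20% of non-normal ones
surgeon <- sites$truth
vis_miss <- runif(nrow(sites)) < 0.2 & sites$truth != "normal"
surgeon[vis_miss] <- "normal"

ratings <- data.frame(surgeon = surgeon, iknife = sites$sample_call,
                      histology = sites$truth)
out <- rater_agreement(ratings)
print(out, row.names = FALSE)

ik <- cohens_kappa(ratings$iknife, ratings$histology)
sg <- cohens_kappa(ratings$surgeon, ratings$histology)
cat(sprintf("\niKnife vs histology: kappa = %.2f (%s), z = %.2f, P = %.3g\n",
            ik$kappa, ik$band, ik$z, ik$p_value))
cat(sprintf("Surgeon vs histology: kappa = %.2f (%s), z = %.2f, P = %.3g\n",
            sg$kappa, sg$band, sg$z, sg$p_value))
write.csv(out, "results/rater_agreement.csv", row.names = FALSE)
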