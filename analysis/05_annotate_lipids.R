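#!/usr/bin/env Rscript
# Annotate the shortlisted discriminant bins with in-silico negative-mode
# glycerophospholipid and fatty-acid ions ([M-H]-, [M-NH3]-, [M+Cl]-)
# within +/- 0.1 m/z, even chains only.

library(reims)

db <- lipid_database()
cat(sprintf("In-silico ion database: %d ions over %d species.\n",
            nrow(db), length(unique(db$species))))
write.csv(db, "scratch/lipid_ion_database.csv", row.names = FALSE)

short <- read.csv("results/univariate_shortlist.csv")
queries <- short$bin + 0.05  # bin centre of the 0.1 Da bin
ann <- do.call(rbind, lapply(queries, function(q) {
  hits <- annotate_mz(q, tolerance = 0.1, database = db)
  if (nrow(hits)) head(hits, 3) else NULL
}))
write.csv(ann, "results/shortlist_annotation.csv", row.names = FALSE)

cat("\nBest annotations for the planted discriminant masses:\n")
for (q in c(673.481, 685.517, 699.497, 742.539, 744.555)) {
  hits <- annotate_mz(q, 0.1, db)
  cat(sprintf("  %.3f -> %s\n", q,
              paste(sprintf("%s %s (%+.4f)", hits$species[1:min(2, nrow(hits))],
                            hits$adduct[1:min(2, nrow(hits))],
                            hits$error[1:min(2, nrow(hits))]),
                    collapse = "; ")))
}
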