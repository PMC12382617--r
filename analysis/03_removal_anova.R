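#!/usr/bin/env Rscript
# Stage 3: removal percentages and their factorial analysis.
#
# Summarizes per-dose removal (mean and 95% Student-t CI over triplicates)
# for each antibiotic in the noisy campaign, then asks whether removal
# differs between antibiotics and doses with a balanced two-factor ANOVA,
# followed by Tukey pairwise comparisons between antibiotics.

library(ebikin)

tab <- read_peak_table("results/peak_table_cv10.csv")
coefs <- reference_coefficients()
antibiotics <- coefs$analyte[coefs$role == "antibiotic"]

removal <- do.call(rbind, lapply(antibiotics, removal_table, table = tab))
write.csv(removal[, c("antibiotic", "dose_kGy", "n", "mean_removal",
                      "ci_halfwidth")],
          "results/removal_table.csv", row.names = FALSE)

long <- do.call(rbind, lapply(antibiotics, function(a) {
  sub <- tab[tab$analyte == a, ]
  baseline <- mean(sub$area[sub$dose_kGy == 0 & !sub$censored])
  data.frame(antibiotic = a, dose_kGy = sub$dose_kGy,
             replicate = sub$replicate,
             removal_percent = 100 * (1 - sub$area / baseline))
}))
fit <- removal_anova(long)   # dose-0 cells dropped (removal there is 0 by construction)
write.csv(as.data.frame(fit$table), "results/anova.csv", row.names = FALSE)
print(fit)

hsd <- tukey_hsd(fit)
write.csv(hsd, "results/tukey.csv", row.names = FALSE)
insig <- hsd[!hsd$significant, c("level_i", "level_j", "p")]
cat("\nantibiotic pairs with statistically indistinguishable removal:\n")
print(as.data.frame(insig), row.names = FALSE)
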