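#!/usr/bin/env Rscript
# Stage 1: simulate the measurement campaign.
#
# Builds the bundled kinetic registry (seven antibiotics, thirteen
# degradation products) and writes two synthetic peak tables: a noiseless
# forward evaluation of every model on the campaign dose grid, and a noisy
# triplicate campaign with 10% multiplicative noise and ND-censoring below
# the detection limit. Later stages fit these tables.

library(ebikin)

seed <- 1L
dir.create("results", showWarnings = FALSE)

models <- reference_models()
doses <- c(0, 0.1, 1, 3, 7)

noiseless <- simulate_noiseless(models, seq(0, 7, by = 0.25))
write_peak_table(noiseless, "results/peak_table_noiseless.csv")

cfg <- generator_config(models = models, doses = doses, replicates = 3L,
                        cv = 0.10, lod_fraction = 0.001, seed = seed)
noisy <- generate_peak_table(cfg)
write_peak_table(noisy, "results/peak_table_cv10.csv")

cat(sprintf("noiseless table: %d observations (%d analytes x 29 doses)\n",
            nrow(noiseless), length(models)))
cat(sprintf("noisy table:     %d observations (%d censored as ND)\n",
            nrow(noisy), sum(noisy$censored)))
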