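#!/usr/bin/env Rscript
# Stage 4: dosimetry control.
#
# Computes absorbed dose from a Fricke ferrous-sulfate reading and
# calibrates the linear charge-to-dose conversion from the bundled
# irradiation-session log, holding out the highest-dose session group to
# check the extrapolation.

library(ebikin)

dose_example <- fricke_dose(fricke_params(deltaS = 0.05))
cat(sprintf("Fricke example: deltaS = 0.05 -> %.2f Gy\n", dose_example))

sessions <- read_sessions()
cal_all <- calibrate_charge_to_dose(sessions)
cal_holdout <- calibrate_charge_to_dose(sessions[1:3, ])
pred <- predict_dose(sessions$charge_nC[4], cal_holdout$slope_Gy_per_nC)

cat(sprintf("charge->dose slope (all sessions):  %.6f Gy/nC\n",
            cal_all$slope_Gy_per_nC))
cat(sprintf("slope from the three lower-dose groups: %.6f Gy/nC\n",
            cal_holdout$slope_Gy_per_nC))
cat(sprintf("held-out high-dose group: predicted %.1f Gy vs measured %.1f Gy (%.3f%% off)\n",
            pred, sessions$dose_Gy[4],
            100 * abs(pred - sessions$dose_Gy[4]) / sessions$dose_Gy[4]))
cat(sprintf("max relative spread of session dose/charge ratios: %.4f%%\n",
            100 * cal_all$max_rel_dev))

jsonlite::write_json(
  list(fricke_example_Gy = dose_example,
       slope_all_Gy_per_nC = cal_all$slope_Gy_per_nC,
       slope_holdout_Gy_per_nC = cal_holdout$slope_Gy_per_nC,
       holdout_predicted_Gy = pred,
       holdout_measured_Gy = sessions$dose_Gy[4],
       max_rel_dev = cal_all$max_rel_dev),
  "results/dosimetry.json", auto_unbox = TRUE, digits = NA)
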