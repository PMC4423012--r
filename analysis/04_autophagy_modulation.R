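#!/usr/bin/env Rscript
# Autophagy strength sets the apoptosis threshold.
#
# Lowering the sensor-driven autophagy activation constant (kaau_p = 0.2,
# a 3-MA-like inhibition) pulls the apoptosis threshold to lower stress;
# raising it (kaau_p = 0.7, metyrapone-like activation) pushes the
# threshold up and delays apoptosis activation at a fixed stress level.
# Writes results/modulation/.

library(erfate)

out <- "results/modulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
params <- er_params()

thr <- threshold_vs_kaau(params, c(0.2, params$kaau_p, 0.7))
utils::write.csv(thr, file.path(out, "threshold_vs_kaau.csv"), row.names = FALSE)
print(thr, digits = 3)

# with weakened autophagy even S0 = 1 becomes lethal within 240 min
p_weak <- modulate_autophagy(params, 0.2)
tr <- integrate_protocol(p_weak, constant_stress(1, 240))
end <- tr[nrow(tr), ]
message(sprintf("kaau_p = 0.2, S0 = 1: fate at 240 min = %s (APO_act = %.2f)",
                classify(end, p_weak), end[[paste0("APO_", params$n_steps)]]))

# activation delay under strengthened autophagy at S0 = 5
delay <- sapply(c(base = params$kaau_p, strong = 0.7), function(k) {
  ens <- simulate_ensemble(modulate_autophagy(params, k), constant_stress(5, 240),
                           n_cells = 50, master_seed = 401)
  atd <- activation_time_distribution(ens)
  stats::median(atd$time)
})
utils::write.csv(data.frame(kaau_p = c(params$kaau_p, 0.7),
                            median_activation_min = delay),
                 file.path(out, "activation_delay.csv"), row.names = FALSE)
message(sprintf(
  "Median apoptosis activation at S0 = 5: %.0f min (baseline) vs %.0f min (kaau_p = 0.7)",
  delay["base"], delay["strong"]))
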