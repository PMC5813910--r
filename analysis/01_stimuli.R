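#!/usr/bin/env Rscript
# Stimulus registry: build every stimulus set used across the three
# experiments and the size-discrimination task, check the derived
# densities against their printed (rounded) values, and export the
# registry for downstream scripts.

library(swimodel)

dir.create("results", showWarnings = FALSE)

sets <- build_standard_sets()
write_stimulus_sets(sets, "results/stimulus_registry.csv")
stimulus_registry_json(sets, "results/stimulus_registry.json")

heav <- sets[sets$set %in% c("small", "big", "equal_density"), ]
message("heaviness stimuli: ", nrow(heav), " cans in 3 density sets")
message("big set densities (g/cm^3): ",
        paste(round(heav$density_g_cm3[heav$set == "big"], 2),
              collapse = ", "))
message("small set densities (g/cm^3): ",
        paste(round(heav$density_g_cm3[heav$set == "small"], 2),
              collapse = ", "))
message("equal-density set: constant at ",
        unique(round(heav$density_g_cm3[heav$set == "equal_density"], 2)),
        " g/cm^3 -- the big 230 g can shares this density")

vols <- data.frame(
  set = rep(c("small", "big"), each = 8),
  standard_cm3 = rep(c(31.8, 596), each = 8),
  comparison_cm3 = c(comparison_volumes(31.8), comparison_volumes(596))
)
utils::write.csv(vols, "results/sizedisc_volumes.csv", row.names = FALSE)
message("size-task comparisons span ",
        paste(range(vols$comparison_cm3[vols$set == "small"]),
              collapse = "-"),
        " cm^3 (small) and ",
        paste(range(vols$comparison_cm3[vols$set == "big"]),
              collapse = "-"), " cm^3 (big)")
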