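#!/usr/bin/env Rscript
# Simulate the study cohort: 19 high-risk and 48 low-risk women, each
# walking a ~400 m hallway course (320 s at ~1.25 m/s) with a hip-worn
# 30 Hz triaxial accelerometer. Writes the cohort table and ground
# truth; the raw tracings are regenerated deterministically by later
# stages (seed 20260921), so the bulky per-sample CSVs are not kept.

library(gaitrisk)

seed <- 20260921
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

spec <- cohort_spec(n_high = 19, n_low = 48, duration_s = 320,
                    rate_hz = 30, seed = seed)
sim <- simulate_cohort(spec)

write_cohort_csv(sim$cohort, "results/cohort.csv")
write_ground_truth_json(sim$truths, "scratch/ground_truth.json")

cat(sprintf("simulated %d subjects (%d high / %d low risk)\n",
            nrow(sim$cohort), sum(sim$cohort$label == "high"),
            sum(sim$cohort$label == "low")))
cat(sprintf("high-risk SPPB mean %.1f, low-risk %.1f\n",
            mean(sim$cohort$sppb_total[sim$cohort$label == "high"]),
            mean(sim$cohort$sppb_total[sim$cohort$label == "low"])))
cat(sprintf("mean vertical acceleration: high %.3f g, low %.3f g\n",
            mean(vapply(sim$tracings[sim$cohort$label == "high"],
                        function(tr) mean(tr$data$ay_g), numeric(1))),
            mean(vapply(sim$tracings[sim$cohort$label == "low"],
                        function(tr) mean(tr$data$ay_g), numeric(1)))))
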