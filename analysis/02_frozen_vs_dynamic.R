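#!/usr/bin/env Rscript
# Stage 2: the frozen-gradient experiment. Simulate the ground-truth circuit
# with time-variable maternal inputs and with inputs clamped to their early
# blastoderm values, then quantify where and when the two runs diverge:
# late over-expression, posterior boundary overshoot, and the slow-down of
# domain shift rates under gradient decay.

library(gapdyn)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
gt <- ground_truth_dataset(cfg)
at <- cfg$schedule$analysis_times
frozen <- simulate_circuit(gt$params, cfg$schedule, gt$profiles, gt$init,
                           mode = "frozen")

cmp <- compare_runs(gt$trajectory, frozen)
write_profiles(
  data.frame(time_min = cmp$table$time_min,
             position_pct = cmp$table$position_pct,
             species = cmp$table$species,
             concentration = abs(cmp$table$difference)),
  "results/frozen_dynamic_absdiff.tsv")
write.table(cmp$summary, "results/frozen_dynamic_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Maximum |frozen - dynamic| per gene and time class:\n")
for (lb in c("T2", "T4", "T8")) {
  s <- cmp$summary[cmp$summary$time_class == lb, ]
  cat(sprintf("  %s: %s\n", lb,
              paste(sprintf("%s=%.1f", s$species, s$max_abs_diff),
                    collapse = "  ")))
}

rows <- list()
for (g in c("kni", "gt")) {
  bd <- boundary_timecourse(gt$trajectory, g, side = "anterior", times = at)
  bf <- boundary_timecourse(frozen, g, side = "anterior", times = at)
  main <- as.integer(names(which.max(table(bd$domain))))
  b <- bd[bd$domain == main & bd$time >= at[["T1"]] - 1e-9 &
            bd$time <= at[["T8"]] + 1e-9, ]
  sr <- shift_rate(b)
  ov <- overshoot(bd, bf)
  t8 <- ov$table$difference[abs(ov$table$time - at[["T8"]]) < 1e-9]
  cat(sprintf(
    "%s anterior boundary: %.1f%% (T1) -> %.1f%% (T8); rate %.3f -> %.3f %%/min; frozen-run overshoot at T8 = %+.2f%%\n",
    g, b$position[1], b$position[nrow(b)],
    sr$intervals$rate[1], sr$intervals$rate[nrow(sr$intervals)], t8))
  rows[[g]] <- data.frame(gene = g, sr$intervals,
                          overshoot_T8 = t8)
}
write.table(do.call(rbind, rows), "results/shift_rates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_manifest("results/02_manifest.json", "frozen_vs_dynamic", seed = seed,
               params = gt$params,
               outputs = c("results/frozen_dynamic_absdiff.tsv",
                           "results/frozen_dynamic_summary.tsv",
                           "results/shift_rates.tsv"))
cat("Interpretation: with the gradients clamped at their early values the\n")
cat("posterior kni and gt domains keep shifting and over-accumulate product\n")
cat("late; gradient decay caps expression and decelerates the shifts.\n")
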