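#!/usr/bin/env Rscript
# Exercises the simulation arm: draws a cohort with the reference
# group structure, pushes it through classification and statistics,
# and validates the image pipeline end to end by rendering canonical
# objects as voxel phantoms and re-measuring them.

suppressPackageStartupMessages(library(mcmorph))
seed <- 1

res <- run_pipeline(pipeline_config("simulate", seed = seed),
                    output_dir = "results/synthetic")
cat(sprintf("Simulated cohort (seed %d): %d samples, %d objects\n",
            seed, nrow(res$samples), nrow(res$objects)))
cat("\nChi-square tests on simulated morphology flags:\n")
print(res$stats$chisq[, c("flag", "statistic", "p_value", "p_adjusted")],
      row.names = FALSE)
cat("(NA rows: flag absent in every group, test undefined)\n")

cat("\nEnd-to-end phantom recovery (render -> segment -> measure):\n")
targets <- data.frame(class = c("sphere", "rod", "plate"),
                      V_um3 = c(4.5e6, 1.145e7, 3.0e6),
                      SMI = c(4.0, 3.0, 0.2),
                      ideal = c(4, 3, 0))
rec <- lapply(seq_len(nrow(targets)), function(i) {
  rs <- render_sample_volume(targets[i, c("V_um3", "SMI")], spacing = 9,
                             noise_sigma = 50, seed = seed + i)
  lab <- label_components(threshold_volume(rs$volume, "fixed",
                                           fixed_value = 500,
                                           verbose = FALSE))
  m <- measure_objects(lab)
  data.frame(class = targets$class[i], V_target = targets$V_um3[i],
             V_measured = m$V_um3,
             V_err_pct = 100 * (m$V_um3 / targets$V_um3[i] - 1),
             SMI_ideal = targets$ideal[i], SMI_measured = m$SMI)
})
rec <- do.call(rbind, rec)
write.csv(rec, "results/synthetic/phantom_recovery.csv", row.names = FALSE)
for (i in seq_len(nrow(rec)))
  cat(sprintf("  %-7s volume %+.2f%%, SMI %.3f (ideal %g)\n",
              rec$class[i], rec$V_err_pct[i], rec$SMI_measured[i],
              rec$SMI_ideal[i]))
cat("written: results/synthetic/\n")
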