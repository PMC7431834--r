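#!/usr/bin/env Rscript
# Step 5: clonal-mosaic statistics.
#
# Three simulated genotypes: a mock mosaic (symmetric lineages -- the
# null), a fusion-deficient-like clone (slower division, higher loss
# hazard), and a fission-deficient-like clone (normal division, neighbour
# displacement modelled as a higher hazard on the marker-positive
# lineage). Division rate, maintenance and partial/full clone composition
# are summarized per week.

suppressPackageStartupMessages(library(mitodynamics))

out <- "results/05_clonal"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genotypes <- list(
  mock = mosaic_config(n_germaria = 500L, gsc_neg = 1L, gsc_pos = 2L,
                       rate_neg = 5, rate_pos = 5,
                       hazard_neg = 0.024, hazard_pos = 0.024,
                       weeks = 3L, seed = 61L),
  fusion_deficient = mosaic_config(n_germaria = 500L, gsc_neg = 1L,
                                   gsc_pos = 2L, rate_neg = 2.5,
                                   rate_pos = 5, hazard_neg = 0.27,
                                   hazard_pos = 0.024, weeks = 3L,
                                   seed = 62L),
  fission_deficient = mosaic_config(n_germaria = 500L, gsc_neg = 1L,
                                    gsc_pos = 2L, rate_neg = 5,
                                    rate_pos = 5, hazard_neg = 0.024,
                                    hazard_pos = 0.3, weeks = 3L,
                                    seed = 63L))

all_summaries <- list()
for (g in names(genotypes)) {
  d <- simulate_mosaic(genotypes[[g]])
  s <- clonal_summary(d)
  s$genotype <- g
  all_summaries[[g]] <- s
  cat("\n--", g, "--\n")
  cat("pooled relative division rate by week:",
      round(s$pooled_rate, 3), "\n")
  cat("per-germarium mean rate (+/- SEM):",
      paste0(round(s$mean_rate, 2), " (", round(s$sem_rate, 3), ")"), "\n")
  cat("maintenance % (>= 1 marked GSC):", round(s$maintenance_pct, 1), "\n")
  cat("partial / full clone % at week 3:", round(s$partial_pct[3], 1), "/",
      round(s$full_pct[3], 1), "\n")
}

cat("\nReadout: the mock mosaic sits at a division rate of ~1.0 and high",
    "maintenance;\nthe fusion-deficient clone divides at ~0.5 and is lost",
    "(maintenance falls with week);\nthe fission-deficient clone keeps a",
    "~1.0 division rate while its full-clone share rises\nas",
    "marker-positive neighbours vacate the niche.\n")

write.csv(do.call(rbind, all_summaries),
          file.path(out, "clonal_summary.csv"), row.names = FALSE)
cat("Wrote per-genotype summaries to", out, "\n")
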