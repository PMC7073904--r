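#!/usr/bin/env Rscript
# Generate the synthetic experimental inputs for the analysis: growth
# curves for the thymidine and thymidine+methionine conditions (three
# replicates each, matching the plate layout of the growth experiments),
# formaldehyde time courses in the growing and non-growing regimes, and
# Nash-assay calibration standards. Everything downstream reads these
# delimited files, so the whole chain runs without any external data.

suppressPackageStartupMessages(library(c1flux))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed0 <- 20200212L

curves <- list()
for (scen in c("thy", "thy_met")) {
  mu <- if (scen == "thy") 0.036 else 0.047
  for (rep in 1:3) {
    g <- gen_growth_curve(mu = mu, noise_cv = 0.03,
                          seed = seed0 + 10L * match(scen, c("thy", "thy_met")) + rep)
    curves[[length(curves) + 1L]] <-
      data.frame(scenario = scen, replicate = rep, g)
  }
}
growth_tab <- do.call(rbind, curves)
write.table(growth_tab, file.path(out, "growth_curves.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

fald <- rbind(
  data.frame(mode = "growing_plateau",
             gen_formaldehyde_series("growing_plateau", seed = seed0)),
  data.frame(mode = "non_growing_accumulation",
             gen_formaldehyde_series("non_growing_accumulation",
                                     seed = seed0 + 1L)))
write.table(fald, file.path(out, "formaldehyde_series.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

standards <- gen_nash_standards(seed = seed0 + 2L)
write.table(standards, file.path(out, "nash_standards.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("growth curves:     ", nrow(growth_tab), "rows,",
    length(unique(growth_tab$scenario)), "scenarios x 3 replicates\n")
cat("formaldehyde rows: ", nrow(fald), "\n")
cat("nash standards:    ", nrow(standards), "points on 0-1 mM\n")
cat("written under", out, "\n")
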