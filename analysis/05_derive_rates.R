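#!/usr/bin/env Rscript
# The complete inference chain: intersect the phase planes with the
# measured growth rates to obtain the in vivo condensation flux, check the
# two conditions agree, bound the growth of a hypothetical serine-cycle
# methylotroph living off the spontaneous condensation, and compare the in
# vivo flux with the in vitro rate law.

suppressPackageStartupMessages(library(c1flux))

report <- run_c1_analysis(c1_config(out_dir = "results/report"))
print(report)

cat("\nfiles: results/report/report.json + phase-plane TSVs\n")
stopifnot(report$flux_consistency$consistent)
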