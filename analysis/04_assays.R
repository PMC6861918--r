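#!/usr/bin/env Rscript
# Analyse the simulated co-culture plate: percent of control, Mann-Whitney
# significance versus untreated wells, dose dependence and banded points.
library(tbitriage)

dir.create("results", showWarnings = FALSE)
plate <- read_plate_table("results/synthetic/plate.tsv")
res <- analyze_plate(plate)
cat("per-cell results:\n")
print(res$results, row.names = FALSE, digits = 3)
cat("\nper-compound banded points (strongest significant dose):\n")
print(res$points, row.names = FALSE, digits = 3)
write.table(res$results, "results/assay_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$points, "results/assay_points.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# dose dependence of the planted inhibition (1 uM stronger than 0.1 uM)
tn <- plate[plate$analyte == "TNFa" & plate$treatment == "cmpdA", ]
dd <- dose_dependence(tn$value[tn$concentration_uM == 0.1],
                      tn$value[tn$concentration_uM == 1], 0.1, 1)
cat(sprintf("\ncmpdA TNFa dose dependence: p = %.4g, more effective at 1 uM: %s\n",
            dd$p, dd$more_effective))
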