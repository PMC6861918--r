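#!/usr/bin/env Rscript
# Convert concordance scores into percentile-band points, for both the
# bundled published table (four candidate compounds) and the synthetic one.
library(tbitriage)

dir.create("results", showWarnings = FALSE)
pub <- read_concordance_table(system.file("extdata", "ilincs_concordance.tsv",
                                          package = "tbitriage"))
for (tp in c("acute", "chronic")) {
  sc <- score_concordance(pub, tp)
  cat(sprintf("published, %s:\n", tp))
  print(sc, row.names = FALSE)
  write.table(sc, file.path("results", paste0("concordance_", tp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("note: percentiles here are within the supplied candidate list, not the",
    "full perturbagen library the published points were banded against\n")

sim <- read_concordance_table("results/synthetic/concordance.tsv")
cat("synthetic, acute:\n")
print(score_concordance(sim, "acute"), row.names = FALSE)
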