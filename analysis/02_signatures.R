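#!/usr/bin/env Rscript
# Build the acute and chronic transcriptomic signatures from the bundled
# perilesional-cortex differential-expression tables (fold change > 1.5,
# BH FDR < 0.05) and report the effect sizes of the Nrf2 target genes on
# the percent-of-control scale.
library(tbitriage)

dir.create("results", showWarnings = FALSE)
for (tp in c("32h", "3mo")) {
  de <- read_de_table(system.file("extdata", paste0("tbi_de_", tp, ".tsv"),
                                  package = "tbitriage"))
  sig <- build_signature(de, label = paste0("cortex-", tp))
  write_signature(sig, file.path("results", paste0("signature_", tp, ".tsv")))
  cat(sprintf("%s: %d of %d genes enter the signature (%d up, %d down)\n",
              attr(sig, "label"), nrow(sig), nrow(de),
              sum(sig$direction == "up"), sum(sig$direction == "down")))
}

de32 <- read_de_table(system.file("extdata", "tbi_de_32h.tsv",
                                  package = "tbitriage"))
for (g in c("Hmox1", "Nqo1")) {
  lfc <- de32$log2fc[de32$gene_id == g]
  cat(sprintf("acute %s: log2FC %.3f -> %d%% of control\n",
              g, lfc, fold_change_percent(lfc)))
}

# simulated acute table from stage 01, for the synthetic end-to-end run
sim <- read_de_table("results/synthetic/de_acute.tsv")
sim_sig <- build_signature(sim, label = "synthetic-acute")
cat(sprintf("synthetic table: %d signal genes recovered\n", nrow(sim_sig)))
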