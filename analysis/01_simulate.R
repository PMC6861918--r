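#!/usr/bin/env Rscript
# Generate the synthetic inputs for every downstream stage (seed 1) under
# results/synthetic/. Each generator draws from its own substream, so the
# stages can be regenerated independently.
library(tbitriage)

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L
w <- function(df, name) {
  write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("  %-18s %5d rows\n", name, nrow(df)))
}

cat("Simulating pipeline inputs (seed", seed, ")\n")
w(simulate_de_table(n_genes = 500, n_signal = 40, seed = seed), "de_acute.tsv")

w(simulate_concordance(
  c("cmpdA", "cmpdB", "cmpdC", "cmpdD"),
  strong_compounds = "cmpdA", no_score = "cmpdD", seed = seed),
  "concordance.tsv")

# planted percent-of-control effects: cmpdA strongly anti-inflammatory and
# anti-oxidant at the higher dose, cmpdB inert
effects <- rbind(
  expand.grid(treatment = "cmpdA", concentration_uM = c(0.1, 1),
              analyte = c("TNFa", "nitrite"), stringsAsFactors = FALSE),
  expand.grid(treatment = "cmpdA", concentration_uM = c(0.1, 1),
              analyte = "viability", stringsAsFactors = FALSE),
  expand.grid(treatment = "cmpdB", concentration_uM = c(0.1, 1),
              analyte = c("TNFa", "nitrite", "viability"),
              stringsAsFactors = FALSE))
effects$effect <- c(70, 40, 75, 45, 100, 100, rep(100, 6))
w(simulate_coculture_plate(effects, cv = 0.08, seed = seed), "plate.tsv")

w(simulate_qpcr(
  data.frame(gene = rep(c("Nfe2l2", "Gclm", "Hmox1", "Nqo1"), 2),
             condition = rep(c("inflammatory", "non_inflammatory"), each = 4),
             log2fc = c(1, 0, 0, 0, 1, 0, 0, 0)),
  treatment = "cmpdA", sigma = 0.15, seed = seed), "qpcr.tsv")

w(simulate_cytokine_panel(n_vehicle = 15, n_treated = 11,
                          group_effect_day28 = 2, seed = seed), "panel.tsv")

ev <- data.frame(
  compound = rep(c("cmpdA", "cmpdB"), each = 2),
  component = rep(c("bbb", "water_solubility"), 2),
  points = c(5, 5, 0, 0))
w(ev, "evidence.tsv")
cat("done\n")
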