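# Per-stage substreams of the master seed: each generator seeds its own
# stream, so adding or re-running one stage never perturbs another's output.
stage_seed <- function(seed, stage) {
  offsets <- c(de_table = 101L, concordance = 202L, plate = 303L,
               qpcr = 404L, panel = 505L)
  if (!stage %in% names(offsets)) stop("unknown simulation stage: ", stage)
  (as.integer(seed) %% 2000000000L) + offsets[[stage]]
}

#' Simulate a differential-expression table
#'
#' Null genes draw log2FC ~ Normal(0, 0.1) and FDR ~ Uniform(0.05, 1), so
#' they fail the default FDR filter by construction; signal genes draw
#' |log2FC| uniformly from `signal_log2fc_range` (with random sign) and
#' FDR ~ Uniform(0, 0.05), so exactly `n_signal` rows survive
#' [build_signature()]'s default thresholds.
#'
#' @param n_genes total genes.
#' @param n_signal number of signal genes (<= n_genes).
#' @param signal_log2fc_range range of |log2FC| for signal genes; the lower
#'   end must exceed log2(1.5).
#' @param seed master seed.
#' @return data.frame `gene_id`, `log2fc`, `fdr`.
#' @export
simulate_de_table <- function(n_genes, n_signal,
                              signal_log2fc_range = c(1, 3), seed = 1L) {
  if (n_signal > n_genes) stop("n_signal must be <= n_genes")
  if (signal_log2fc_range[1] <= log2(1.5)) {
    stop("signal |log2FC| range must start above log2(1.5)")
  }
  set.seed(stage_seed(seed, "de_table"))
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  log2fc <- stats::rnorm(n_genes, 0, 0.1)
  fdr <- stats::runif(n_genes, 0.05, 1)
  if (n_signal > 0L) {
    idx <- seq_len(n_signal)
    mag <- stats::runif(n_signal, signal_log2fc_range[1],
                        signal_log2fc_range[2])
    log2fc[idx] <- mag * sample(c(-1, 1), n_signal, replace = TRUE)
    fdr[idx] <- stats::runif(n_signal, 0, 0.05 - 1e-9)
  }
  data.frame(gene_id = gene_id, log2fc = log2fc, fdr = fdr,
             stringsAsFactors = FALSE)
}

#' Simulate a compound-concordance table
#'
#' Compounds draw signed concordance scores uniformly from (-1, 1) at both
#' timepoints; `strong_compounds` names compounds forced to the top of the
#' absolute ranking (|concordance| in (0.85, 1)); `no_score` names compounds
#' with an absent score at a random timepoint.
#'
#' @param compounds character vector of compound names.
#' @param strong_compounds subset forced to high |concordance|.
#' @param no_score subset with a missing score at one timepoint.
#' @param seed master seed.
#' @return data.frame `compound`, `timepoint`, `concordance`, `cell_line`,
#'   `signature_id`.
#' @export
simulate_concordance <- function(compounds, strong_compounds = character(0),
                                 no_score = character(0), seed = 1L) {
  set.seed(stage_seed(seed, "concordance"))
  out <- expand.grid(compound = compounds,
                     timepoint = c("acute", "chronic"),
                     stringsAsFactors = FALSE)
  out$concordance <- stats::runif(nrow(out), -1, 1)
  strong <- out$compound %in% strong_compounds
  out$concordance[strong] <- stats::runif(sum(strong), 0.85, 1) *
    sign(out$concordance[strong])
  for (cmp in no_score) {
    tp <- sample(c("acute", "chronic"), 1L)
    out$concordance[out$compound == cmp & out$timepoint == tp] <- NA
  }
  out$cell_line <- "NEU"
  out$signature_id <- sprintf("SIM_%04d", seq_len(nrow(out)))
  out
}

#' Simulate a co-culture plate table
#'
#' Control wells draw LogNormal(mu0, cv) per analyte; wells of a treatment
#' cell with planted effect e (true percent of control) draw
#' LogNormal(mu0 + ln(e/100), cv). Each (treatment, concentration, analyte)
#' cell gets `wells_per_cell` wells in each of `experiments` runs, mirroring
#' duplicated quadruplicate plates.
#'
#' @param treatment_effects data.frame `treatment`, `concentration_uM`,
#'   `analyte`, `effect` (true percent of control, > 0).
#' @param cv log-scale coefficient of variation of well noise, in (0, 1).
#' @param wells_per_cell wells per cell per experiment (default 4).
#' @param experiments independent runs (default 2).
#' @param seed master seed.
#' @return plate data.frame `experiment_id`, `well_id`, `treatment`,
#'   `concentration_uM`, `analyte`, `value`, including control wells.
#' @export
simulate_coculture_plate <- function(treatment_effects, cv = 0.1,
                                     wells_per_cell = 4L, experiments = 2L,
                                     seed = 1L) {
  stopifnot(all(c("treatment", "concentration_uM", "analyte", "effect")
                %in% names(treatment_effects)))
  if (cv <= 0 || cv >= 1) stop("cv must be in (0, 1)")
  if (any(treatment_effects$effect <= 0)) stop("effects must be > 0")
  set.seed(stage_seed(seed, "plate"))
  mu0 <- c(TNFa = log(800), nitrite = log(12), viability = log(1))
  analytes <- unique(treatment_effects$analyte)
  if (!all(analytes %in% names(mu0))) {
    stop("unknown analyte(s): ",
         paste(setdiff(analytes, names(mu0)), collapse = ", "))
  }
  rows <- list()
  well <- 0L
  for (ex in seq_len(experiments)) {
    for (an in analytes) {
      for (w in seq_len(wells_per_cell)) {
        well <- well + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          experiment_id = paste0("exp", ex), well_id = sprintf("W%04d", well),
          treatment = "control", concentration_uM = 0, analyte = an,
          value = stats::rlnorm(1L, mu0[[an]], cv), stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(treatment_effects))) {
      te <- treatment_effects[i, ]
      for (w in seq_len(wells_per_cell)) {
        well <- well + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          experiment_id = paste0("exp", ex), well_id = sprintf("W%04d", well),
          treatment = te$treatment, concentration_uM = te$concentration_uM,
          analyte = te$analyte,
          value = stats::rlnorm(1L, mu0[[te$analyte]] + log(te$effect / 100), cv),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a qPCR Ct table
#'
#' Ct = gene baseline - planted_log2fc (treated samples only)
#' + batch_shift_ct (second and later batches) + Normal(0, sigma). The
#' Gapdh reference is unaffected by treatment but carries the batch shift,
#' so the batch-adjusted regression of -delta-Ct must absorb it.
#'
#' @param planted_log2fc data.frame `gene`, `condition`, `log2fc`.
#' @param batch_shift_ct constant Ct shift of batches after the first.
#' @param n_per_group samples per treatment group per condition per batch.
#' @param batches number of experiment replicates (default 2).
#' @param sigma Ct noise SD.
#' @param treatment treated-group label.
#' @param seed master seed.
#' @return Ct data.frame `sample_id`, `gene`, `ct`, `batch`, `condition`,
#'   `treatment`, including Gapdh rows for every sample.
#' @export
simulate_qpcr <- function(planted_log2fc, batch_shift_ct = 0.5,
                          n_per_group = 4L, batches = 2L, sigma = 0.3,
                          treatment = "compound", seed = 1L) {
  stopifnot(all(c("gene", "condition", "log2fc") %in% names(planted_log2fc)))
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  set.seed(stage_seed(seed, "qpcr"))
  baseline <- c(Nfe2l2 = 24, Gclm = 23, Hmox1 = 22, Nqo1 = 25, Gapdh = 18)
  rows <- list()
  sid <- 0L
  for (cond in unique(planted_log2fc$condition)) {
    genes <- planted_log2fc$gene[planted_log2fc$condition == cond]
    for (b in seq_len(batches)) {
      shift <- if (b > 1L) batch_shift_ct else 0
      for (trt in c(treatment, "control")) {
        for (s in seq_len(n_per_group)) {
          sid <- sid + 1L
          sample_id <- sprintf("S%04d", sid)
          for (g in c(genes, "Gapdh")) {
            base <- if (g %in% names(baseline)) baseline[[g]] else 24
            lfc <- if (g != "Gapdh" && trt == treatment) {
              planted_log2fc$log2fc[planted_log2fc$gene == g &
                                    planted_log2fc$condition == cond]
            } else 0
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sample_id, gene = g,
              ct = base - lfc + shift + stats::rnorm(1L, 0, sigma),
              batch = paste0("batch", b), condition = cond, treatment = trt,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a longitudinal plasma cytokine panel
#'
#' Log-concentrations are cytokine baseline + day effect (declining towards
#' day 28 in the vehicle group, mirroring the post-injury decay of the
#' cytokine response) + animal random intercept + a multiplicative treated-
#' group shift at the final day + well noise. Group sizes default to the 15
#' vehicle / 11 treated animals of the in vivo trial.
#'
#' @param n_vehicle,n_treated group sizes.
#' @param days sampling days (default 7, 14, 28).
#' @param group_effect_day28 multiplicative shift of treated-group
#'   concentrations at the last day (1 = null).
#' @param affected_cytokines cytokines receiving the shift (default all 12).
#' @param within_animal_sd SD of the per-animal random intercept (log
#'   scale).
#' @param noise_sd residual SD (log scale).
#' @param seed master seed.
#' @return long data.frame `animal_id`, `group`, `day`, `cytokine`,
#'   `concentration` (pg/mL).
#' @export
simulate_cytokine_panel <- function(n_vehicle = 15L, n_treated = 11L,
                                    days = c(7, 14, 28),
                                    group_effect_day28 = 1,
                                    affected_cytokines = NULL,
                                    within_animal_sd = 0.3, noise_sd = 0.2,
                                    seed = 1L) {
  if (group_effect_day28 < 1) stop("group_effect_day28 must be >= 1")
  if (within_animal_sd <= 0 || noise_sd <= 0) stop("noise scales must be > 0")
  set.seed(stage_seed(seed, "panel"))
  cytokines <- c("GM-CSF", "IFNy", "IL-1a", "IL-1b", "IL-2", "IL-4", "IL-5",
                 "IL-6", "IL-10", "IL-12p70", "IL-13", "TNFa")
  if (is.null(affected_cytokines)) affected_cytokines <- cytokines
  baseline <- stats::setNames(log(stats::runif(length(cytokines), 20, 400)),
                              cytokines)
  # post-injury decay: elevated at days 7 and 14, settled by day 28
  day_effect <- stats::setNames(seq(0.6, 0, length.out = length(days)),
                                paste0("d", sort(days)))
  groups <- c(rep("vehicle", n_vehicle), rep("treated", n_treated))
  animals <- sprintf("animal%02d", seq_along(groups))
  intercepts <- stats::rnorm(length(animals), 0, within_animal_sd)
  last_day <- max(days)
  rows <- expand.grid(animal_id = animals, day = sort(days),
                      cytokine = cytokines, stringsAsFactors = FALSE)
  ai <- match(rows$animal_id, animals)
  rows$group <- groups[ai]
  logc <- baseline[rows$cytokine] + day_effect[paste0("d", rows$day)] +
    intercepts[ai] +
    ifelse(rows$group == "treated" & rows$day == last_day &
             rows$cytokine %in% affected_cytokines,
           log(group_effect_day28), 0) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  rows$concentration <- exp(unname(logc))
  rows[, c("animal_id", "group", "day", "cytokine", "concentration")]
}
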