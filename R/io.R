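# Shared TSV conventions: UTF-8, tab-separated, "#"-prefixed header
# comments, "NA"/"No score"/empty as missing.

read_tsv_checked <- function(path, required_cols, numeric_cols = character(0),
                             na_strings = c("NA", "No score", "")) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("malformed table ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (cl in numeric_cols) {
    raw <- df[[cl]]
    raw[raw %in% na_strings] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0L) {
      stop("malformed table ", path, ": non-numeric value '", raw[bad[1L]],
           "' in column '", cl, "', data line ", bad[1L])
    }
    df[[cl]] <- num
  }
  for (cl in setdiff(names(df), numeric_cols)) {
    df[[cl]][df[[cl]] %in% na_strings] <- NA
  }
  df
}

write_stage_tsv <- function(df, path, stage, seed = NULL, extra = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  header <- sprintf("# stage: %s; package: tbitriage %s%s%s", stage,
                    as.character(utils::packageVersion("tbitriage")),
                    if (!is.null(seed)) sprintf("; seed: %d", seed) else "",
                    if (!is.null(extra)) paste0("; ", extra) else "")
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with header `gene_id  log2fc  fdr`; "NA" permitted in `fdr`.
#' @param path file path.
#' @return data.frame ready for [build_signature()].
#' @export
read_de_table <- function(path) {
  read_tsv_checked(path, c("gene_id", "log2fc", "fdr"), c("log2fc", "fdr"))
}

#' Read a compound-concordance table
#'
#' TSV `compound  timepoint  concordance  cell_line  signature_id`;
#' "No score" or an empty cell marks an absent concordance.
#' @param path file path.
#' @return data.frame ready for [score_concordance()].
#' @export
read_concordance_table <- function(path) {
  read_tsv_checked(path, c("compound", "timepoint", "concordance"),
                   "concordance")
}

#' Read a co-culture plate table
#'
#' TSV `experiment_id  well_id  treatment  concentration_uM  analyte  value`.
#' @param path file path.
#' @return data.frame ready for [analyze_plate()].
#' @export
read_plate_table <- function(path) {
  read_tsv_checked(path, c("experiment_id", "well_id", "treatment",
                           "concentration_uM", "analyte", "value"),
                   c("concentration_uM", "value"))
}

#' Read a qPCR Ct table
#'
#' TSV `sample_id  gene  ct  batch  condition  treatment`.
#' @param path file path.
#' @return data.frame ready for [engagement_report()].
#' @export
read_ct_table <- function(path) {
  read_tsv_checked(path, c("sample_id", "gene", "ct", "batch", "condition",
                           "treatment"), "ct")
}

#' Read a longitudinal cytokine panel
#'
#' TSV `animal_id  group  day  cytokine  concentration` (long format).
#' @param path file path.
#' @return data.frame ready for [build_features()].
#' @export
read_panel_table <- function(path) {
  read_tsv_checked(path, c("animal_id", "group", "day", "cytokine",
                           "concentration"), c("day", "concentration"))
}

#' Read a component-evidence table
#'
#' TSV `compound  component  points` of per-compound integer points for
#' scheme components, e.g. user-supplied pharmacokinetic judgments or the
#' published scorecard profiles bundled with the package.
#' @param path file path.
#' @return data.frame ready for [weighted_score()] assembly.
#' @export
read_evidence_table <- function(path) {
  read_tsv_checked(path, c("compound", "component", "points"), "points")
}

#' Write an expression signature
#'
#' TSV `gene_id  direction  log2fc` with a one-line header comment carrying
#' the label and filter thresholds.
#' @param sig an `expression_signature`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "expression_signature"))
  extra <- sprintf("label: %s; fc_threshold: %g; fdr_threshold: %g",
                   attr(sig, "label"), attr(sig, "fc_threshold"),
                   attr(sig, "fdr_threshold"))
  write_stage_tsv(as.data.frame(sig), path, "build-sig", extra = extra)
}

#' Run the triage pipeline end to end
#'
#' Executes, in order: signature building, concordance scoring, plate-assay
#' analysis, target engagement, composite scoring and (optionally) the
#' cytokine ML evaluation, skipping stages whose inputs are `NULL`. Stage
#' outputs are written as TSV under `out_dir` and listed in the returned
#' manifest. Pharmacokinetic points (blood-brain barrier, water solubility)
#' are user-supplied literature judgments via the `evidence` table.
#'
#' @param out_dir output directory (created if needed).
#' @param de_acute,de_chronic differential-expression TSV paths.
#' @param concordance concordance TSV path.
#' @param plate plate TSV path.
#' @param ct qPCR Ct TSV path.
#' @param panel longitudinal cytokine TSV path.
#' @param evidence TSV `compound  component  points` of user-supplied
#'   component points (e.g. bbb, water_solubility).
#' @param scheme scoring scheme (default [default_scheme()]).
#' @param ml a [cv_config()] for the ML stage.
#' @param ml_feature_sets list of [feature_set()]s to evaluate (default:
#'   all cytokines at the last sampled day, unaugmented).
#' @param seed recorded in output headers and used for the ML stage.
#' @return list: `manifest` (stage, output, n_rows), `scorecards`,
#'   `ranking`, `ml` (per-feature-set outcomes), plus the per-stage tables.
#' @export
run_pipeline <- function(out_dir, de_acute = NULL, de_chronic = NULL,
                         concordance = NULL, plate = NULL, ct = NULL,
                         panel = NULL, evidence = NULL,
                         scheme = default_scheme(), ml = cv_config(seed = seed),
                         ml_feature_sets = NULL, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  note <- function(stage, file, n) {
    manifest <<- rbind(manifest, data.frame(stage = stage, output = file,
                                            n_rows = n,
                                            stringsAsFactors = FALSE))
  }
  out <- list()
  emit <- function(df, name, stage) {
    path <- file.path(out_dir, name)
    write_stage_tsv(df, path, stage, seed = seed)
    note(stage, name, nrow(df))
  }

  for (tp in c("acute", "chronic")) {
    path <- if (tp == "acute") de_acute else de_chronic
    if (is.null(path)) next
    sig <- build_signature(read_de_table(path), label = paste0(tp, "-sig"))
    out[[paste0("signature_", tp)]] <- sig
    write_signature(sig, file.path(out_dir, paste0("signature_", tp, ".tsv")))
    note("build-sig", paste0("signature_", tp, ".tsv"), nrow(sig))
  }

  conc_points <- NULL
  if (!is.null(concordance)) {
    tab <- read_concordance_table(concordance)
    for (tp in intersect(c("acute", "chronic"), unique(tab$timepoint))) {
      sc <- score_concordance(tab, tp)
      sc$timepoint <- tp
      conc_points <- rbind(conc_points, sc)
    }
    out$concordance <- conc_points
    emit(conc_points, "concordance_points.tsv", "score-concordance")
  }

  assay <- NULL
  if (!is.null(plate)) {
    assay <- analyze_plate(read_plate_table(plate))
    out$assays <- assay
    emit(assay$results, "assay_results.tsv", "analyze-assays")
    emit(assay$points, "assay_points.tsv", "analyze-assays")
  }

  engagement <- NULL
  if (!is.null(ct)) {
    ct_tab <- read_ct_table(ct)
    treatments <- setdiff(unique(ct_tab$treatment), "control")
    for (trt in treatments) {
      rep_tab <- engagement_report(ct_tab, trt)
      rep_tab$treatment <- trt
      engagement <- rbind(engagement, rep_tab)
    }
    out$engagement <- engagement
    emit(engagement, "engagement.tsv", "engagement")
  } else {
    message("no Ct table supplied; engagement stage skipped, ",
            "scoring will use 0 engagement points")
  }

  extra_evidence <- if (!is.null(evidence)) read_evidence_table(evidence)
  else NULL

  compounds <- sort(unique(c(conc_points$compound, assay$points$treatment,
                             engagement$treatment, extra_evidence$compound)))
  compounds <- setdiff(compounds, c("1400W", "IL-10"))  # positive controls
  scorecards <- list()
  if (length(compounds) > 0L) {
    analyte_component <- c(TNFa = "tnfa", nitrite = "nitrite",
                           viability = "viability")
    for (cmp in compounds) {
      pts <- c()
      if (!is.null(conc_points)) {
        for (tp in c("acute", "chronic")) {
          row <- conc_points[conc_points$compound == cmp &
                               conc_points$timepoint == tp, ]
          if (nrow(row) == 1L) {
            pts[paste0("concordance_", tp)] <- row$points
          }
        }
      }
      if (!is.null(assay)) {
        rows <- assay$points[assay$points$treatment == cmp, ]
        for (i in seq_len(nrow(rows))) {
          pts[analyte_component[[rows$analyte[i]]]] <- rows$points[i]
        }
      }
      if (!is.null(engagement)) {
        rows <- engagement[engagement$treatment == cmp, ]
        for (i in seq_len(nrow(rows))) {
          pts[paste0("engagement_", rows$gene[i], "_", rows$condition[i])] <-
            rows$point[i]
        }
      }
      if (!is.null(extra_evidence)) {
        rows <- extra_evidence[extra_evidence$compound == cmp, ]
        for (i in seq_len(nrow(rows))) pts[rows$component[i]] <- rows$points[i]
      }
      scorecards[[cmp]] <- suppressWarnings(
        weighted_score(pts, scheme, compound = cmp))
    }
    out$scorecards <- scorecards
    out$ranking <- rank_compounds(scorecards)
    emit(out$ranking, "ranking.tsv", "score")
    card_tab <- do.call(rbind, lapply(scorecards, function(cd) {
      cbind(compound = cd$compound, cd$table)
    }))
    rownames(card_tab) <- NULL
    emit(card_tab, "scorecards.tsv", "score")
  }

  if (!is.null(panel)) {
    pan <- read_panel_table(panel)
    if (is.null(ml_feature_sets)) {
      ml_feature_sets <- list(feature_set(
        paste0("cytokines_day", max(pan$day)), days = max(pan$day)))
    }
    ml_out <- list()
    report <- NULL
    for (fs in ml_feature_sets) {
      feats <- build_features(pan, fs)
      res <- nested_cv_evaluate(feats$X, feats$y, ml)
      ml_out[[fs$name]] <- res
      report <- rbind(report, data.frame(
        feature_set = fs$name, n_features = ncol(feats$X),
        mean_auc = res$mean_auc, gate = res$gate_passed,
        stringsAsFactors = FALSE))
    }
    out$ml <- ml_out
    emit(report, "ml_report.tsv", "ml-evaluate")
  }

  out$manifest <- manifest
  out
}
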