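#' Relative expression by the delta-Ct method
#'
#' `2^-(ct_gene - ct_reference)`: one extra quantitation cycle on the target
#' relative to the reference (Gapdh) halves the relative expression.
#'
#' @param ct_gene,ct_reference quantitation cycles (finite, > 0); vectorised.
#' @return relative expression (unitless).
#' @examples
#' relative_expression(22.0, 18.5)  # 2^-3.5
#' @export
relative_expression <- function(ct_gene, ct_reference) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_reference)) ||
      any(ct_gene <= 0) || any(ct_reference <= 0)) {
    stop("Ct values must be finite and > 0")
  }
  2^(-(ct_gene - ct_reference))
}

# -delta-Ct (log2 expression relative to Gapdh) per sample of one gene.
# Rejects samples without a reference measurement, naming them.
neg_delta_ct <- function(measurements, gene, reference = "Gapdh") {
  g <- measurements[measurements$gene == gene, , drop = FALSE]
  ref <- measurements[measurements$gene == reference, , drop = FALSE]
  idx <- match(g$sample_id, ref$sample_id)
  if (anyNA(idx)) {
    stop("missing ", reference, " Ct for sample(s): ",
         paste(g$sample_id[is.na(idx)], collapse = ", "))
  }
  data.frame(sample_id = g$sample_id,
             y = -(g$ct - ref$ct[idx]),
             batch = g$batch,
             stringsAsFactors = FALSE)
}

#' Batch-adjusted treatment effect on qPCR expression
#'
#' Estimates the treatment effect on the log2 expression scale. The response
#' is -delta-Ct (target Ct minus Gapdh Ct, negated), so the fitted treatment
#' coefficient is directly a log2 fold change; the model is
#' `-dCt ~ treatment + batch`, with batch as fixed-effect indicator(s)
#' absorbing constant between-run shifts. The p-value is the two-sided t
#' test of the treatment coefficient.
#'
#' @param treated,control data.frames of qPCR measurements with columns
#'   `sample_id`, `gene`, `ct`, `batch` (each group needs >= 2 samples of
#'   the target gene, plus matching Gapdh rows).
#' @param gene target gene name.
#' @param reference reference gene name (default "Gapdh").
#' @return list with `log2fc`, `p`, `n_treated`, `n_control`.
#' @export
engagement_effect <- function(treated, control, gene, reference = "Gapdh") {
  dt <- neg_delta_ct(treated, gene, reference)
  dc <- neg_delta_ct(control, gene, reference)
  if (nrow(dt) < 2L || nrow(dc) < 2L) {
    stop("need >= 2 samples per group for gene ", gene)
  }
  dat <- rbind(cbind(dt, trt = 1), cbind(dc, trt = 0))
  dat$batch <- factor(dat$batch)
  if (nlevels(dat$batch) > 1L) {
    # treatment must not be confounded with batch
    tab <- table(dat$batch, dat$trt)
    if (all(rowSums(tab > 0) == 1L)) {
      stop("treatment is confounded with batch; effect is inestimable")
    }
    fit <- stats::lm(y ~ trt + batch, data = dat)
  } else {
    fit <- stats::lm(y ~ trt, data = dat)
  }
  cf <- summary(fit)$coefficients
  list(log2fc = unname(cf["trt", "Estimate"]),
       p = unname(cf["trt", "Pr(>|t|)"]),
       n_treated = nrow(dt), n_control = nrow(dc))
}

#' Engagement call from an estimated effect
#'
#' An effect significant at `alpha` (two-sided, no multiplicity correction)
#' is called "up" or "down" by the sign of its log2 fold change; otherwise
#' "none".
#'
#' @param log2fc estimated log2 fold change.
#' @param p its two-sided p-value.
#' @param alpha significance threshold (default 0.05).
#' @return "up", "down" or "none".
#' @export
engagement_call <- function(log2fc, p, alpha = 0.05) {
  if (is.na(p) || p >= alpha) "none" else if (log2fc > 0) "up" else "down"
}

#' Points for an engagement call
#'
#' Significant upregulation of a predicted target gene earns +1, significant
#' downregulation -1, no effect 0.
#'
#' @param call "up", "down" or "none".
#' @return integer point in {-1, 0, +1} (vectorised).
#' @export
engagement_points <- function(call) {
  vapply(call, function(cl) {
    switch(cl, up = 1L, down = -1L, none = 0L,
           stop("invalid engagement call: ", cl))
  }, integer(1), USE.NAMES = FALSE)
}

#' Engagement report for a Ct table
#'
#' Runs [engagement_effect()] for every target gene x condition of one
#' treatment versus the untreated control, and attaches call and point.
#'
#' @param ct_table data.frame `sample_id`, `gene`, `ct`, `batch`,
#'   `condition`, `treatment`.
#' @param treatment treatment label to test.
#' @param control_treatment control label (default "control").
#' @param genes target genes; default: all non-reference genes present.
#' @param reference reference gene (default "Gapdh").
#' @param alpha significance threshold.
#' @return data.frame `gene`, `condition`, `log2fc`, `p`, `call`, `point`.
#' @export
engagement_report <- function(ct_table, treatment,
                              control_treatment = "control",
                              genes = NULL, reference = "Gapdh",
                              alpha = 0.05) {
  stopifnot(all(c("sample_id", "gene", "ct", "batch", "condition",
                  "treatment") %in% names(ct_table)))
  if (is.null(genes)) genes <- setdiff(unique(ct_table$gene), reference)
  out <- NULL
  for (cond in unique(ct_table$condition)) {
    sub <- ct_table[ct_table$condition == cond, , drop = FALSE]
    trt <- sub[sub$treatment == treatment, , drop = FALSE]
    ctl <- sub[sub$treatment == control_treatment, , drop = FALSE]
    for (g in genes) {
      eff <- engagement_effect(trt, ctl, g, reference)
      call <- engagement_call(eff$log2fc, eff$p, alpha)
      out <- rbind(out, data.frame(
        gene = g, condition = cond, log2fc = eff$log2fc, p = eff$p,
        call = call, point = engagement_points(call),
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  out
}
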