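#' Build a directioned expression signature from a differential-expression table
#'
#' Filters a table of per-gene log2 fold changes and Benjamini-Hochberg
#' adjusted p-values (FDR) down to the genes that define a transcriptomic
#' injury signature: a gene enters the signature iff its linear fold change
#' exceeds `fc_threshold` in either direction (strictly, i.e.
#' `|log2fc| > log2(fc_threshold)`) and its FDR is present and strictly below
#' `fdr_threshold`. Genes with missing FDR (undetected expression) are
#' excluded.
#'
#' @param records data.frame with columns `gene_id`, `log2fc`, `fdr`
#'   (`fdr` may contain `NA`).
#' @param fc_threshold linear fold-change threshold (>= 1); default 1.5.
#' @param fdr_threshold FDR threshold in (0, 1]; default 0.05.
#' @param label free-text label for the signature (e.g. "acute-32h").
#' @return An object of class `expression_signature`: a data.frame with
#'   columns `gene_id`, `direction` ("up"/"down") and `log2fc`, with
#'   attributes `label`, `fc_threshold`, `fdr_threshold` and `n_input`.
#' @examples
#' de <- data.frame(gene_id = c("Hmox1", "Nfe2l2"),
#'                  log2fc = c(2.860, 0.094),
#'                  fdr = c(1.69e-9, 0.641))
#' build_signature(de, label = "acute-32h")
#' @export
build_signature <- function(records, fc_threshold = 1.5, fdr_threshold = 0.05,
                            label = "signature") {
  stopifnot(is.data.frame(records))
  required <- c("gene_id", "log2fc", "fdr")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("differential-expression table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (fc_threshold < 1) stop("fc_threshold must be >= 1 (linear scale)")
  if (fdr_threshold <= 0 || fdr_threshold > 1) {
    stop("fdr_threshold must be in (0, 1]")
  }
  if (nrow(records) > 0L) {
    if (any(!nzchar(records$gene_id) | is.na(records$gene_id))) {
      stop("empty or missing gene_id in differential-expression table")
    }
    dup <- unique(records$gene_id[duplicated(records$gene_id)])
    if (length(dup) > 0L) {
      stop("duplicate gene_id in differential-expression table: ",
           paste(dup, collapse = ", "))
    }
    bad_fdr <- !is.na(records$fdr) & (records$fdr < 0 | records$fdr > 1)
    if (any(bad_fdr)) {
      stop("fdr outside [0, 1] for gene(s): ",
           paste(records$gene_id[bad_fdr], collapse = ", "))
    }
  }
  keep <- !is.na(records$log2fc) &
    abs(records$log2fc) > log2(fc_threshold) &
    !is.na(records$fdr) &
    records$fdr < fdr_threshold
  sig <- data.frame(
    gene_id = records$gene_id[keep],
    direction = ifelse(records$log2fc[keep] > 0, "up", "down"),
    log2fc = records$log2fc[keep],
    stringsAsFactors = FALSE
  )
  structure(sig,
            label = label,
            fc_threshold = fc_threshold,
            fdr_threshold = fdr_threshold,
            n_input = nrow(records),
            class = c("expression_signature", "data.frame"))
}

#' Translate signature gene identifiers through a mapping table
#'
#' Re-keys a signature from one identifier space to another (e.g. rat probe
#' or Ensembl IDs to human NCBI IDs). Unmapped genes are dropped and counted;
#' a source mapping to several targets expands to all of them, carrying the
#' source's direction and effect size. If two different sources map onto the
#' same target, the entry from the source with the larger |log2fc| is kept
#' (ties broken by source gene_id, lexicographically) when their directions
#' agree; conflicting directions on the same target are an error.
#'
#' @param sig an `expression_signature` from [build_signature()].
#' @param map data.frame with columns `source_id`, `target_id`.
#' @return A translated `expression_signature`; attribute `n_dropped` counts
#'   source entries without any mapping.
#' @export
translate_ids <- function(sig, map) {
  stopifnot(inherits(sig, "expression_signature"), is.data.frame(map))
  if (!all(c("source_id", "target_id") %in% names(map))) {
    stop("mapping table needs columns source_id and target_id")
  }
  if (nrow(map) == 0L) stop("mapping table is empty")
  map <- unique(map[, c("source_id", "target_id")])
  idx <- match(map$source_id, sig$gene_id)
  hit <- !is.na(idx)
  mapped_sources <- unique(map$source_id[hit])
  n_dropped <- sum(!(sig$gene_id %in% mapped_sources))
  out <- data.frame(
    gene_id = map$target_id[hit],
    direction = sig$direction[idx[hit]],
    log2fc = sig$log2fc[idx[hit]],
    source_id = map$source_id[hit],
    stringsAsFactors = FALSE
  )
  # many-to-one collisions: conflicting directions reject, else keep the
  # strongest effect (tie-break by source id so the result is deterministic)
  if (anyDuplicated(out$gene_id)) {
    for (tgt in unique(out$gene_id[duplicated(out$gene_id)])) {
      rows <- out[out$gene_id == tgt, ]
      if (length(unique(rows$direction)) > 1L) {
        stop("mapping collision with conflicting directions on target ", tgt,
             " (sources: ", paste(sort(rows$source_id), collapse = ", "), ")")
      }
    }
    ord <- order(out$gene_id, -abs(out$log2fc), out$source_id)
    out <- out[ord, ]
    out <- out[!duplicated(out$gene_id), ]
  }
  out <- out[order(out$gene_id), c("gene_id", "direction", "log2fc")]
  rownames(out) <- NULL
  structure(out,
            label = attr(sig, "label"),
            fc_threshold = attr(sig, "fc_threshold"),
            fdr_threshold = attr(sig, "fdr_threshold"),
            n_input = attr(sig, "n_input"),
            n_dropped = n_dropped,
            class = c("expression_signature", "data.frame"))
}

#' Convert a log2 fold change to percent of control
#'
#' `2^log2fc * 100`: a log2FC of 0 is 100% of control, 1 is 200%, and the
#' acute Hmox1 effect of 2.860 is 726%. Rounding, when requested, is half-up
#' to the nearest integer (so reported percentages match the convention of
#' printed effect sizes).
#'
#' @param log2fc numeric vector of log2 fold changes (finite).
#' @param round_to_integer round half-up to whole percent? Default `TRUE`.
#' @return percent-of-control value(s).
#' @examples
#' fold_change_percent(2.860)  # 726
#' fold_change_percent(0)      # 100
#' @export
fold_change_percent <- function(log2fc, round_to_integer = TRUE) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  pct <- 2^log2fc * 100
  if (round_to_integer) floor(pct + 0.5) else pct
}

#' @export
print.expression_signature <- function(x, ...) {
  cat(sprintf("Expression signature '%s': %d genes (%d up, %d down)\n",
              attr(x, "label"), nrow(x),
              sum(x$direction == "up"), sum(x$direction == "down")))
  cat(sprintf("  filters: fold change > %.3g, FDR < %.3g; %d input records\n",
              attr(x, "fc_threshold"), attr(x, "fdr_threshold"),
              attr(x, "n_input")))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
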