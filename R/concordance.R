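#' Percentile ranks of compounds by absolute concordance
#'
#' Compounds are arranged by the absolute value of their concordance score
#' with the injury signature at the given timepoint (strongest first); each
#' compound's percentile is `rank / N` with rank 1 the strongest, so the
#' percentile lies in (0, 1]. Ties share the worst (largest) percentile of
#' their tied block. Compounds with no concordance score at the timepoint
#' get no percentile.
#'
#' @param records data.frame with columns `compound`, `timepoint`,
#'   `concordance` (NA = no score); extra columns ignored.
#' @param timepoint "acute" or "chronic".
#' @return named numeric vector, percentile per scored compound.
#' @export
percentile_rank <- function(records, timepoint) {
  stopifnot(is.data.frame(records),
            all(c("compound", "timepoint", "concordance") %in% names(records)))
  rec <- records[records$timepoint == timepoint, , drop = FALSE]
  dup <- unique(rec$compound[duplicated(rec$compound)])
  if (length(dup) > 0L) {
    stop("duplicate (compound, timepoint) rows for: ",
         paste(dup, collapse = ", "))
  }
  rec <- rec[!is.na(rec$concordance), , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("no record with a concordance score at timepoint '", timepoint, "'")
  }
  if (any(abs(rec$concordance) > 1)) stop("|concordance| must be <= 1")
  n <- nrow(rec)
  # max-rank within tied |concordance| blocks -> shared worst percentile
  r <- rank(-abs(rec$concordance), ties.method = "max")
  stats::setNames(r / n, rec$compound)
}

#' Convert a concordance percentile to 0-5 band points
#'
#' The banded scale gives 5 points to the top 10% of the absolute-concordance
#' ranking, 4 to the top 20%, down to 1 for the top 50%; anything weaker, or
#' an absent score, earns 0 points.
#'
#' @param percentile fraction in (0, 1], or `NA` for "no score".
#' @return integer points in 0..5 (vectorised).
#' @examples
#' concordance_points(0.07)  # 5
#' concordance_points(0.25)  # 3
#' concordance_points(NA)    # 0
#' @export
concordance_points <- function(percentile) {
  bad <- !is.na(percentile) & (percentile <= 0 | percentile > 1)
  if (any(bad)) stop("percentile must be in (0, 1] or NA")
  pts <- function(p) {
    if (is.na(p)) return(0L)
    if (p <= 0.10) 5L else if (p <= 0.20) 4L else if (p <= 0.30) 3L
    else if (p <= 0.40) 2L else if (p <= 0.50) 1L else 0L
  }
  vapply(percentile, pts, integer(1))
}

#' Score all compounds of a concordance table at one timepoint
#'
#' Combines [percentile_rank()] and [concordance_points()]. By default a
#' negative concordance, however strong in absolute value, earns 0 points
#' (`negative_scores_eligible = FALSE`): the ranking footnote uses absolute
#' values but the published scorecard gave a strongly negative chronic
#' concordance no credit. Set the flag to `TRUE` to let negative scores
#' compete on |concordance| alone.
#'
#' @param records concordance table (see [percentile_rank()]).
#' @param timepoint "acute" or "chronic".
#' @param negative_scores_eligible logical, default `FALSE`.
#' @return data.frame `compound`, `concordance`, `percentile`, `points`,
#'   covering every compound present at the timepoint (unscored compounds
#'   have NA percentile and 0 points).
#' @export
score_concordance <- function(records, timepoint,
                              negative_scores_eligible = FALSE) {
  rec <- records[records$timepoint == timepoint, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records at timepoint '", timepoint, "'")
  pct <- percentile_rank(records, timepoint)
  out <- data.frame(
    compound = rec$compound,
    concordance = rec$concordance,
    percentile = unname(pct[rec$compound]),
    stringsAsFactors = FALSE
  )
  out$points <- concordance_points(out$percentile)
  if (!negative_scores_eligible) {
    neg <- !is.na(out$concordance) & out$concordance < 0
    out$points[neg] <- 0L
  }
  out[order(-abs(ifelse(is.na(out$concordance), -Inf, out$concordance))), ,
      drop = FALSE]
}
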