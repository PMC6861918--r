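#' The default weighted go/no-go scoring scheme
#'
#' Fifteen components in four blocks: the in-silico therapeutic time window
#' (acute and chronic concordance bands, 10% each), pharmacokinetics
#' (blood-brain barrier penetration and water solubility, 10% each, points
#' -5/0/+5 for no/unknown/yes), the co-culture outcome (TNFa inhibition 15%,
#' nitrite inhibition 15%, MAP2 neuronal viability 20%, banded -5..5), and
#' target engagement of Nfe2l2/Gclm/Hmox1/Nqo1 under inflammatory and
#' non-inflammatory conditions (1.25% each, points -1/0/+1). Weights sum to
#' 100%; the best achievable total is 4.6 and the worst -3.6.
#'
#' @return A `scoring_scheme`: data.frame with columns `component`, `block`,
#'   `weight`, `min_points`, `max_points`.
#' @export
default_scheme <- function() {
  eng <- function(cond) paste0("engagement_", c("Nfe2l2", "Gclm", "Hmox1", "Nqo1"),
                               "_", cond)
  scheme <- data.frame(
    component = c("concordance_acute", "concordance_chronic",
                  "bbb", "water_solubility",
                  "tnfa", "nitrite", "viability",
                  eng("inflammatory"), eng("non_inflammatory")),
    block = c(rep("in_silico", 2), rep("pharmacokinetics", 2),
              rep("co_culture", 3),
              rep("engagement_inflammatory", 4),
              rep("engagement_non_inflammatory", 4)),
    weight = c(0.10, 0.10, 0.10, 0.10, 0.15, 0.15, 0.20, rep(0.0125, 8)),
    min_points = c(0, 0, -5, -5, -5, -5, -5, rep(-1, 8)),
    max_points = c(5, 5, 5, 5, 5, 5, 5, rep(1, 8)),
    stringsAsFactors = FALSE
  )
  structure(scheme, class = c("scoring_scheme", "data.frame"))
}

validate_scheme <- function(scheme) {
  stopifnot(is.data.frame(scheme),
            all(c("component", "block", "weight", "min_points", "max_points")
                %in% names(scheme)))
  if (anyDuplicated(scheme$component)) stop("duplicate scheme components")
  if (any(scheme$weight < 0)) stop("negative weights are not allowed")
  if (any(scheme$min_points > scheme$max_points)) {
    stop("min_points exceeds max_points for some component")
  }
  invisible(scheme)
}

#' Weighted composite score for one compound
#'
#' Multiplies each component's integer points by its weight and accumulates
#' the contributions in scheme order; subtotals are running (cumulative)
#' sums, so the subtotal printed after a block includes every component from
#' the top of the column. Components missing from the evidence (not assayed)
#' contribute 0 points, with a warning.
#'
#' @param evidence named numeric vector (or single-row data.frame) of
#'   integer points per scheme component.
#' @param scheme a `scoring_scheme`; default [default_scheme()].
#' @param compound compound name carried into the scorecard.
#' @return A `scorecard`: list with `compound`, `table` (component, block,
#'   points, weight, contribution, cumulative), `subtotals` (cumulative
#'   subtotal at the end of each block) and `total`.
#' @examples
#' pts <- c(concordance_acute = 0, concordance_chronic = 3, bbb = 5,
#'          water_solubility = 5, tnfa = 2, nitrite = 1, viability = 0,
#'          engagement_Nfe2l2_inflammatory = 1,
#'          engagement_Nfe2l2_non_inflammatory = 1)
#' weighted_score(pts, compound = "desmethylclomipramine")$total  # 1.775
#' @export
weighted_score <- function(evidence, scheme = default_scheme(),
                           compound = "compound") {
  validate_scheme(scheme)
  if (is.data.frame(evidence)) {
    stopifnot(nrow(evidence) == 1L)
    evidence <- unlist(evidence[1L, , drop = TRUE])
  }
  if (is.null(names(evidence)) || any(!nzchar(names(evidence)))) {
    stop("evidence must be a named vector of points")
  }
  unknown <- setdiff(names(evidence), scheme$component)
  if (length(unknown) > 0L) {
    stop("evidence names absent from the scheme: ",
         paste(unknown, collapse = ", "))
  }
  pts <- evidence[match(scheme$component, names(evidence))]
  missing <- is.na(pts)
  if (any(missing)) {
    warning("no evidence for component(s) ",
            paste(scheme$component[missing], collapse = ", "),
            "; scoring them 0")
    pts[missing] <- 0
  }
  out_of_range <- pts < scheme$min_points | pts > scheme$max_points
  if (any(out_of_range)) {
    stop("points outside the allowed range for: ",
         paste(sprintf("%s (%g not in [%g, %g])",
                       scheme$component[out_of_range], pts[out_of_range],
                       scheme$min_points[out_of_range],
                       scheme$max_points[out_of_range]), collapse = "; "))
  }
  contribution <- unname(pts) * scheme$weight
  tab <- data.frame(component = scheme$component, block = scheme$block,
                    points = unname(pts), weight = scheme$weight,
                    contribution = contribution,
                    cumulative = cumsum(contribution),
                    stringsAsFactors = FALSE)
  block_end <- !duplicated(tab$block, fromLast = TRUE)
  subtotals <- stats::setNames(tab$cumulative[block_end], tab$block[block_end])
  structure(list(compound = compound, table = tab, subtotals = subtotals,
                 total = sum(contribution)),
            class = "scorecard")
}

#' Achievable bounds of a scoring scheme
#'
#' The minimum and maximum weighted total: every component at its worst or
#' best allowed points. In the default scheme the concordance components
#' cannot go negative (their floor is 0), the pharmacokinetic and assay
#' components bottom out at -5 and each engagement slot at -1, giving the
#' range (-3.6, 4.6).
#'
#' @param scheme a `scoring_scheme`.
#' @return numeric vector `c(min_total, max_total)`.
#' @export
score_bounds <- function(scheme = default_scheme()) {
  validate_scheme(scheme)
  c(min_total = sum(scheme$min_points * scheme$weight),
    max_total = sum(scheme$max_points * scheme$weight))
}

#' Rank compounds by composite score
#'
#' Orders scorecards by descending total, breaking ties by the cumulative
#' subtotal through the co-culture block and then alphabetically; the
#' top-ranked compound is flagged "go" for in vivo advancement.
#'
#' @param cards list of `scorecard` objects from [weighted_score()].
#' @return data.frame `rank`, `compound`, `total`, `coculture_subtotal`,
#'   `decision`.
#' @export
rank_compounds <- function(cards) {
  if (length(cards) < 1L) stop("need at least one scorecard")
  stopifnot(all(vapply(cards, inherits, logical(1), "scorecard")))
  totals <- vapply(cards, `[[`, numeric(1), "total")
  cocult <- vapply(cards, function(cd) {
    st <- cd$subtotals
    if ("co_culture" %in% names(st)) st[["co_culture"]] else cd$total
  }, numeric(1))
  compounds <- vapply(cards, `[[`, character(1), "compound")
  # round the sort keys so accumulated floating-point error cannot break a
  # genuine tie between weighted sums
  ord <- order(-round(totals, 9), -round(cocult, 9), compounds)
  data.frame(rank = seq_along(ord),
             compound = compounds[ord],
             total = totals[ord],
             coculture_subtotal = cocult[ord],
             decision = c("go", rep("no-go", length(ord) - 1L)),
             stringsAsFactors = FALSE)
}

#' @export
print.scorecard <- function(x, ...) {
  cat(sprintf("Scorecard: %s (total %.4g)\n", x$compound, x$total))
  print.data.frame(x$table, digits = 4)
  cat("Cumulative subtotals:\n")
  print(round(x$subtotals, 4))
  invisible(x)
}
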