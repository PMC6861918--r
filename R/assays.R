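#' Percent of untreated control
#'
#' Ratio of treated to control group means on the original assay scale,
#' expressed as a percentage. 100 means no effect; below 100 means
#' inhibition.
#'
#' @param treated numeric vector of treated-well values (>= 0).
#' @param control numeric vector of control-well values (>= 0, mean > 0).
#' @return percent of control (numeric scalar).
#' @export
percent_of_control <- function(treated, control) {
  if (length(treated) == 0L || length(control) == 0L) {
    stop("treated and control must be non-empty")
  }
  if (any(treated < 0) || any(control < 0)) stop("assay values must be >= 0")
  m <- mean(control)
  if (m <= 0) stop("control mean is zero; percent of control undefined")
  mean(treated) / m * 100
}

# Exact null distribution of the (doubled) rank sum of group 1 by dynamic
# programming over midranks. Doubling makes midranks (multiples of 0.5)
# integers. Returns counts[s+1] = number of size-n1 subsets with doubled
# rank sum s.
mw_ranksum_counts <- function(r2, n1) {
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  counts <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  counts[1L, 1L] <- 1
  for (ri in r2) {
    for (k in seq.int(n1, 1L)) {
      src <- counts[k, seq_len(smax + 1L - ri)]
      if (any(src > 0)) {
        counts[k + 1L, (ri + 1L):(smax + 1L)] <-
          counts[k + 1L, (ri + 1L):(smax + 1L)] + src
      }
    }
  }
  counts[n1 + 1L, ]
}

#' Two-sided Mann-Whitney U test against a control group
#'
#' For small samples (`n1 + n2 <=` `exact_limit`, default 16) the p-value is
#' exact: the full null distribution of the rank sum is computed by dynamic
#' programming over the (tie-midranked) combined ranking, equivalent to
#' enumerating all `choose(n1+n2, n1)` group assignments. For larger samples
#' the normal approximation with tie correction and continuity correction is
#' used. The two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#' Completely tied data (zero rank variance) give p = 1.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param exact_limit switch to the normal approximation above this combined
#'   sample size.
#' @return two-sided p-value (numeric scalar).
#' @examples
#' mann_whitney_vs_control(c(1, 2, 3), c(10, 11, 12))  # exact: 0.1
#' @export
mann_whitney_vs_control <- function(a, b, exact_limit = 16L) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (any(!is.finite(c(a, b)))) stop("values must be finite")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  if (stats::var(r) == 0) return(1)  # all values tied across both groups
  w <- sum(r[seq_len(n1)])
  if (n <= exact_limit) {
    counts <- mw_ranksum_counts(as.integer(round(2 * r)), n1)
    total <- sum(counts)
    w2 <- as.integer(round(2 * w))
    pl <- sum(counts[seq_len(w2 + 1L)]) / total
    pu <- sum(counts[(w2 + 1L):length(counts)]) / total
    return(min(1, 2 * min(pl, pu)))
  }
  # normal approximation, tie-corrected variance, continuity correction
  u <- w - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Dose dependence between two concentration groups
#'
#' Compares wells at a lower and a higher concentration of the same compound
#' and analyte with the Mann-Whitney U test. The higher concentration is
#' called more effective when its mean effect is stronger (lower values for
#' inhibition readouts such as TNFa or nitrite; higher values for viability)
#' and the comparison reaches p < 0.05.
#'
#' @param lower,higher numeric well values at the lower / higher
#'   concentration (each >= 2 wells).
#' @param lower_conc,higher_conc the concentration labels (must differ).
#' @param inhibition `TRUE` for readouts where a stronger effect means lower
#'   values (default), `FALSE` for viability.
#' @return list with elements `p` and `more_effective`.
#' @export
dose_dependence <- function(lower, higher, lower_conc, higher_conc,
                            inhibition = TRUE) {
  if (identical(lower_conc, higher_conc)) {
    stop("concentration labels are equal; nothing to compare")
  }
  p <- mann_whitney_vs_control(lower, higher)
  stronger <- if (inhibition) mean(higher) < mean(lower)
              else mean(higher) > mean(lower)
  list(p = p, more_effective = isTRUE(stronger) && p < 0.05)
}

#' Banded assay points from percent of control
#'
#' Converts a percent-of-control readout and its significance flag into the
#' -5..5 banded points of the scoring scheme. Inhibition readouts (`TNFa`,
#' `nitrite`): a non-significant result scores 0; a significant increase
#' above 100% scores -5; significant reductions score 1 through 5 as the
#' percent falls to <=90 / <=70 / <=50 / <=30 / <=10, with 90-100% the
#' no-credit zone. Viability (`viability`): non-significant 0; a significant
#' drop below 100% scores -5; significant increases score 1 through 5 as the
#' percent exceeds 115 / 150 / 200 / 250 / 300, with 100-115% the no-credit
#' zone. Band edges are inclusive on the favourable side.
#'
#' @param analyte one of "TNFa", "nitrite", "viability".
#' @param percent percent of control (>= 0).
#' @param significant logical significance gate (two-sided Mann-Whitney
#'   p < 0.05 vs control).
#' @return integer points in -5..5.
#' @export
assay_points <- function(analyte, percent, significant) {
  if (length(analyte) != 1L || !analyte %in% c("TNFa", "nitrite", "viability")) {
    stop("unknown analyte: ", paste(analyte, collapse = ","))
  }
  if (percent < 0) stop("percent must be >= 0")
  if (!isTRUE(significant)) return(0L)
  if (analyte %in% c("TNFa", "nitrite")) {
    if (percent > 100) return(-5L)
    if (percent <= 10) return(5L)
    if (percent <= 30) return(4L)
    if (percent <= 50) return(3L)
    if (percent <= 70) return(2L)
    if (percent <= 90) return(1L)
    return(0L)
  }
  # viability
  if (percent < 100) return(-5L)
  if (percent > 300) return(5L)
  if (percent > 250) return(4L)
  if (percent > 200) return(3L)
  if (percent > 150) return(2L)
  if (percent > 115) return(1L)
  0L
}

#' Analyse a co-culture plate table
#'
#' For every (treatment, concentration, analyte) cell, pools wells across
#' experiments, computes percent of control against the untreated control
#' wells of the same analyte, tests significance with the Mann-Whitney U
#' test, and then assigns one banded point value per (treatment, analyte):
#' the band of the strongest significant concentration (minimum percent for
#' inhibition readouts, maximum for viability), or 0 when no concentration
#' reaches significance.
#'
#' @param plate data.frame with columns `experiment_id`, `well_id`,
#'   `treatment`, `concentration_uM`, `analyte`, `value`.
#' @param control_treatment label of the untreated control wells.
#' @param alpha significance threshold for the Mann-Whitney gate.
#' @return list with `results` (per treatment x concentration x analyte:
#'   `percent`, `p`, `significant`, `n_wells`) and `points` (per treatment x
#'   analyte: `percent` at the strongest significant concentration and
#'   `points`).
#' @export
analyze_plate <- function(plate, control_treatment = "control", alpha = 0.05) {
  stopifnot(is.data.frame(plate),
            all(c("treatment", "concentration_uM", "analyte", "value")
                %in% names(plate)))
  if (any(plate$value < 0)) stop("assay values must be >= 0")
  results <- NULL
  for (an in unique(plate$analyte)) {
    sub <- plate[plate$analyte == an, , drop = FALSE]
    ctrl <- sub$value[sub$treatment == control_treatment]
    if (length(ctrl) == 0L) {
      stop("no '", control_treatment, "' wells for analyte ", an)
    }
    trt <- sub[sub$treatment != control_treatment, , drop = FALSE]
    cells <- unique(trt[, c("treatment", "concentration_uM")])
    for (i in seq_len(nrow(cells))) {
      vals <- trt$value[trt$treatment == cells$treatment[i] &
                        trt$concentration_uM == cells$concentration_uM[i]]
      p <- mann_whitney_vs_control(vals, ctrl)
      results <- rbind(results, data.frame(
        treatment = cells$treatment[i],
        concentration_uM = cells$concentration_uM[i],
        analyte = an,
        percent = percent_of_control(vals, ctrl),
        p = p,
        significant = p < alpha,
        n_wells = length(vals),
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(results) <- NULL
  points <- NULL
  combos <- unique(results[, c("treatment", "analyte")])
  for (i in seq_len(nrow(combos))) {
    rows <- results[results$treatment == combos$treatment[i] &
                    results$analyte == combos$analyte[i], , drop = FALSE]
    sig <- rows[rows$significant, , drop = FALSE]
    if (nrow(sig) == 0L) {
      best_pct <- NA_real_; pts <- 0L
    } else {
      best_pct <- if (combos$analyte[i] == "viability") max(sig$percent)
                  else min(sig$percent)
      pts <- assay_points(combos$analyte[i], best_pct, TRUE)
    }
    points <- rbind(points, data.frame(
      treatment = combos$treatment[i], analyte = combos$analyte[i],
      percent = best_pct, points = pts, stringsAsFactors = FALSE
    ))
  }
  rownames(points) <- NULL
  list(results = results, points = points)
}
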