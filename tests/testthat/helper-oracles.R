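# Brute-force Mann-Whitney oracle: enumerate all C(n, n1) assignments of the
# combined ranks to group 1 and count rank sums at least as extreme as the
# observed one. Independent of the package's dynamic-programming route.
mw_oracle_p <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  ws <- apply(utils::combn(n, n1), 2L, function(idx) sum(r[idx]))
  if (stats::var(r) == 0) return(1)
  pl <- mean(ws <= w + 1e-9)
  pu <- mean(ws >= w - 1e-9)
  min(1, 2 * min(pl, pu))
}

# component-point profiles of the published scorecard columns that are
# internally consistent
desmethylclomipramine_points <- c(
  concordance_acute = 0, concordance_chronic = 3, bbb = 5,
  water_solubility = 5, tnfa = 2, nitrite = 1, viability = 0,
  engagement_Nfe2l2_inflammatory = 1, engagement_Gclm_inflammatory = 0,
  engagement_Hmox1_inflammatory = 0, engagement_Nqo1_inflammatory = 0,
  engagement_Nfe2l2_non_inflammatory = 1, engagement_Gclm_non_inflammatory = 0,
  engagement_Hmox1_non_inflammatory = 0, engagement_Nqo1_non_inflammatory = 0)

trimipramine_points <- c(
  concordance_acute = 0, concordance_chronic = 0, bbb = 5,
  water_solubility = 5, tnfa = 2, nitrite = 1, viability = 0)

sirolimus_points <- c(
  concordance_acute = 0, concordance_chronic = 0, bbb = 5,
  water_solubility = 5, tnfa = 2, nitrite = 2, viability = 1)

# cheap single-combination CV configuration used where the grid search is
# not the property under test
cheap_cv <- function(seed, n_repeats = 1L) {
  cv_config(strategy = "none",
            grid = data.frame(max_depth = 2L, eta = 0.1, nrounds = 30L),
            n_repeats = n_repeats, seed = seed)
}
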