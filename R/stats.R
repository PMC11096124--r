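#' Ordered development phase ladder
#'
#' Five states: preclinical, phase I, II, III, launched. A pair's highest
#' phase reached determines success at each transition: `N` at a transition
#' counts pairs at or beyond the "from" phase, `X` counts pairs at or beyond
#' the "to" phase, so launched pairs count as successes at every upstream
#' transition and active pairs stalled at phase k count as non-successes at k.
#'
#' @export
phase_levels <- c("preclinical", "I", "II", "III", "launched")

phase_rank <- function(phase) {
  r <- match(phase, phase_levels)
  if (anyNA(r)) stop("unknown phase: ",
                     paste(unique(phase[is.na(r)]), collapse = ", "))
  r
}

#' Collapse drug programmes to target-indication pairs
#'
#' The unit of analysis is the T-I pair: multiple drugs sharing a target and
#' indication collapse to one row carrying the maximum phase reached; the
#' pair is active if any of its drugs is active.
#'
#' @param programs data.frame with `gene`, `indication_term`,
#'   `highest_phase`, `status`, optionally `year_added`.
#' @return one row per (gene, indication_term).
#' @export
collapse_to_pairs <- function(programs) {
  key <- interaction(programs$gene, programs$indication_term, drop = TRUE)
  idx <- split(seq_len(nrow(programs)), key)
  rows <- lapply(idx, function(i) {
    p <- programs[i, , drop = FALSE]
    data.frame(gene = p$gene[1], indication_term = p$indication_term[1],
               highest_phase = phase_levels[max(phase_rank(p$highest_phase))],
               status = if (any(p$status == "active")) "active" else "historical",
               n_drugs = nrow(p))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$gene, out$indication_term), , drop = FALSE]
}

#' Contingency stratum for one phase transition
#'
#' @param pairs data.frame with `highest_phase` and logical `supported`.
#' @param from_phase,to_phase phase names with `from_phase` strictly before
#'   `to_phase` on the ladder.
#' @param label optional stratum label.
#' @return data.frame row of class `contingency_stratum`: `label`, `X_G`,
#'   `N_G`, `X_notG`, `N_notG`.
#' @export
contingency_by_phase <- function(pairs, from_phase, to_phase, label = NULL) {
  f <- phase_rank(from_phase); t <- phase_rank(to_phase)
  if (f >= t) stop("invalid transition: from_phase must precede to_phase")
  r <- phase_rank(pairs$highest_phase)
  at_risk <- r >= f
  succ <- r >= t
  s <- data.frame(
    label = label %||% paste0(from_phase, "->", to_phase),
    X_G = sum(succ & pairs$supported),
    N_G = sum(at_risk & pairs$supported),
    X_notG = sum(succ & !pairs$supported),
    N_notG = sum(at_risk & !pairs$supported))
  class(s) <- c("contingency_stratum", class(s))
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

z_for <- function(alpha) stats::qnorm(1 - alpha / 2)

#' Katz confidence interval for a risk ratio
#'
#' `exp(log(rr) +/- z * sqrt(1/x1 - 1/n1 + 1/x0 - 1/n0))`.
#'
#' @param x1,n1 successes/at-risk with support; `x0,n0` without.
#' @param alpha two-sided level (default 0.05 for 95% CIs).
#' @return c(lower, upper); `NA`s if either success count is 0.
#' @export
katz_ci <- function(x1, n1, x0, n0, alpha = 0.05) {
  if (x1 == 0 || x0 == 0) return(c(NA_real_, NA_real_))
  rr <- (x1 / n1) / (x0 / n0)
  se <- sqrt(1 / x1 - 1 / n1 + 1 / x0 - 1 / n0)
  exp(log(rr) + c(-1, 1) * z_for(alpha) * se)
}

#' Relative success for one contingency stratum
#'
#' RS = (X_G/N_G) / (X_notG/N_notG), the risk ratio of the probability of
#' success with genetic support over the probability without, with a Katz
#' confidence interval. A zero success count in either arm yields a
#' degenerate result (RS 0 or undefined, no CI); empty arms are errors.
#'
#' @param stratum a row from [contingency_by_phase()] (or any data.frame/list
#'   with `X_G`, `N_G`, `X_notG`, `N_notG`).
#' @param alpha two-sided level (default 0.05).
#' @return list with `rs`, `ci_low`, `ci_high`, `p_g`, `p_s`, `degenerate`.
#' @export
relative_success <- function(stratum, alpha = 0.05) {
  x1 <- stratum$X_G; n1 <- stratum$N_G
  x0 <- stratum$X_notG; n0 <- stratum$N_notG
  if (any(c(x1, n1, x0, n0) < 0) || x1 > n1 || x0 > n0)
    stop("invalid contingency stratum")
  if (n1 == 0 || n0 == 0) stop("empty arm: N_G and N_notG must be positive")
  p_g <- n1 / (n1 + n0)
  p_s <- (x1 + x0) / (n1 + n0)
  if (x1 == 0 || x0 == 0) {
    return(list(rs = if (x0 == 0) NA_real_ else 0, ci_low = NA_real_,
                ci_high = NA_real_, p_g = p_g, p_s = p_s, degenerate = TRUE))
  }
  ci <- katz_ci(x1, n1, x0, n0, alpha)
  list(rs = (x1 / n1) / (x0 / n0), ci_low = ci[1], ci_high = ci[2],
       p_g = p_g, p_s = p_s, degenerate = FALSE)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x successes, `0 <= x <= n`.
#' @param n trials, `n > 0`.
#' @param alpha two-sided level (default 0.05).
#' @return c(lower, upper), both in `[0, 1]`.
#' @export
wilson_ci <- function(x, n, alpha = 0.05) {
  if (n <= 0) stop("empty sample: n must be positive")
  if (x < 0 || x > n) stop("x must be in [0, n]")
  z <- z_for(alpha)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  pmax(0, pmin(1, c(centre - half, centre + half) / denom))
}

#' Overall phase I-to-launch success and relative success
#'
#' Overall P(S) is the product of the per-phase success probabilities
#' (I->II, II->III, III->launch) with a Wald CI on the log scale (variance of
#' the log product is the sum of (1-p_k)/(n_k p_k)). Overall RS is computed
#' from a single stratum whose N counts pairs entering phase I and whose X
#' counts pairs succeeding phase III (launched), with its Katz CI.
#'
#' @param pairs data.frame with `highest_phase` and logical `supported`.
#' @param alpha two-sided level.
#' @return list with `p_s` (overall, pooled), `p_s_ci`, per-arm overall
#'   probabilities, `rs` result (as [relative_success()]), and the per-phase
#'   strata used.
#' @export
overall_success <- function(pairs, alpha = 0.05) {
  trans <- list(c("I", "II"), c("II", "III"), c("III", "launched"))
  strata <- do.call(rbind, lapply(trans, function(tr)
    contingency_by_phase(pairs, tr[1], tr[2])))
  x <- strata$X_G + strata$X_notG
  n <- strata$N_G + strata$N_notG
  p <- x / n
  degenerate <- any(p == 0) || any(n == 0)
  ps <- prod(p)
  ci <- if (degenerate) c(NA_real_, NA_real_) else {
    se_log <- sqrt(sum((1 - p) / (n * p)))
    exp(log(ps) + c(-1, 1) * z_for(alpha) * se_log)
  }
  overall_stratum <- contingency_by_phase(pairs, "I", "launched",
                                          label = "I->launched")
  list(p_s = ps, p_s_ci = pmin(1, ci), per_phase = strata,
       degenerate = degenerate,
       rs = relative_success(overall_stratum, alpha),
       overall_stratum = overall_stratum)
}

#' Cochran-Mantel-Haenszel test across 2x2 strata
#'
#' Tests common association of support with success across strata (e.g.
#' therapy areas): `(sum_k (a_k - E_k))^2 / sum_k V_k` with hypergeometric
#' mean and variance per stratum, no continuity correction, referred to
#' chi-squared on 1 df. Identical to [stats::mantelhaen.test()] with
#' `correct = FALSE` (which requires >= 2 strata; this implementation also
#' covers the single-stratum case, where the statistic equals (n-1)/n times
#' the uncorrected Pearson chi-squared).
#'
#' @param strata data.frame with columns `X_G`, `N_G`, `X_notG`, `N_notG`
#'   (one row per stratum).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
cmh_test <- function(strata) {
  if (!nrow(strata)) stop("undefined test: no strata")
  a <- strata$X_G
  n1 <- strata$N_G; n2 <- strata$N_notG
  m1 <- strata$X_G + strata$X_notG
  tt <- n1 + n2
  m2 <- tt - m1
  use <- tt > 1
  if (!any(use) || sum(m1) == 0 || sum(m2) == 0)
    stop("undefined test: all-zero margins")
  e <- n1 * m1 / tt
  v <- n1 * n2 * m1 * m2 / (tt^2 * (tt - 1))
  stat <- sum(a[use] - e[use])^2 / sum(v[use])
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       df = 1)
}

#' Logistic trend of launch probability on a binned covariate
#'
#' Single-covariate logistic regression with a two-sided Wald p-value.
#' Complete separation is flagged (no p-value reported).
#'
#' @param outcome logical/0-1 launch flags.
#' @param covariate numeric binned covariate.
#' @return list with `slope`, `p_value`, `separation`.
#' @export
trend_test <- function(outcome, covariate) {
  ok <- !is.na(outcome) & !is.na(covariate)
  outcome <- as.numeric(outcome[ok]); covariate <- covariate[ok]
  if (length(unique(covariate)) < 2)
    stop("need >= 2 distinct covariate values")
  fit <- suppressWarnings(
    stats::glm(outcome ~ covariate, family = stats::binomial()))
  co <- summary(fit)$coefficients
  sep <- !fit$converged || any(abs(co[, "Estimate"]) > 15) ||
    all(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  if (sep)
    return(list(slope = unname(co["covariate", "Estimate"]),
                p_value = NA_real_, separation = TRUE))
  list(slope = unname(co["covariate", "Estimate"]),
       p_value = unname(co["covariate", "Pr(>|z|)"]), separation = FALSE)
}

#' Weighted Pearson correlation
#'
#' Weighted product-moment correlation with weights normalized to mean 1 and
#' a t-test p-value on `length(x)` observations (so equal weights reduce
#' exactly to the unweighted Pearson test).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param w positive weights (default equal).
#' @return list with `rho`, `p_value`, `n`.
#' @export
weighted_corr <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x))
  if (length(x) < 3) stop("need >= 3 observations")
  if (any(w <= 0)) stop("weights must be positive")
  cw <- stats::cov.wt(cbind(x, y), wt = w / sum(w), cor = TRUE,
                      method = "unbiased")
  rho <- cw$cor[1, 2]
  if (is.na(rho))
    stop("undefined correlation: zero variance in x or y")
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0, n = n))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tval), df = n - 2), n = n)
}

#' Ordinal model of pipeline progression for drug-indication pairs
#'
#' Proportional-odds logit of the phase reached by each D-I pair on the
#' pair's support flag and the drug's own highest phase reached for any
#' indication ([MASS::polr()] with `Hess = TRUE`). Reports the odds ratio
#' `exp(coef)` for support with a two-sided normal p-value.
#'
#' @param di data.frame with `phase_reached`, `drug_highest_phase` (phase
#'   names) and logical `supported`.
#' @return list with `odds_ratio`, `p_value`, `coef`, `fit`.
#' @export
ordinal_advancement <- function(di) {
  y <- factor(di$phase_reached, levels = phase_levels, ordered = TRUE)
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("undefined model: single outcome level")
  dat <- data.frame(y = y, supported = as.numeric(di$supported),
                    drug_phase = phase_rank(di$drug_highest_phase))
  fit <- MASS::polr(y ~ supported + drug_phase, data = dat, Hess = TRUE)
  ct <- summary(fit)$coefficients
  tval <- ct["supported", "t value"]
  list(odds_ratio = exp(unname(ct["supported", "Value"])),
       p_value = 2 * stats::pnorm(-abs(tval)),
       coef = unname(ct["supported", "Value"]), fit = fit)
}

#' Therapy-area assignment for indication terms
#'
#' Maps each term to the top-level areas it occupies in the ontology tree.
#' All matching areas are retained, except that terms mapping to oncology
#' lose their mappings to all other areas, and "other" is used only for
#' terms mapping to no area at all.
#'
#' @param terms character vector of term IDs.
#' @param tree_positions data.frame with columns `term`, `area`.
#' @param oncology_label the dominating area label (default "oncology").
#' @return named list: for each input term, its character vector of areas.
#' @export
therapy_areas <- function(terms, tree_positions,
                          oncology_label = "oncology") {
  stopifnot(all(c("term", "area") %in% names(tree_positions)))
  lapply(stats::setNames(terms, terms), function(t) {
    areas <- unique(tree_positions$area[tree_positions$term == t])
    if (!length(areas)) return("other")
    if (oncology_label %in% areas) return(oncology_label)
    areas
  })
}

#' Proportion as printed (percent, one rounding convention)
#'
#' Reports x/n as a percentage rounded to the given number of significant
#' digits when below 1% and to `digits` decimal places otherwise — the
#' convention used for all ratio summaries in this package.
#'
#' @param x numerator, `n` denominator.
#' @param digits decimals for percentages >= 1 (default 1).
#' @param n denominator.
#' @return numeric percentage.
#' @export
proportion_pct <- function(x, n, digits = 1) {
  p <- 100 * x / n
  if (p < 1) signif(p, 2) else round(p, digits)
}
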