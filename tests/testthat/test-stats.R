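pairs_df <- function(phases, supported = rep(FALSE, length(phases))) {
  data.frame(gene = paste0("G", seq_along(phases)), indication_term = "I",
             highest_phase = phases, supported = supported)
}

test_that("contingency counting follows the at-or-beyond convention", {
  p <- pairs_df(c("I", "II", "II", "launched"))
  st <- contingency_by_phase(p, "I", "II")
  expect_equal(st$N_notG, 4)
  expect_equal(st$X_notG, 3)
  rs <- relative_success(within(st, {X_G <- 0; N_G <- 1}))
  expect_equal(rs$p_s, 3 / 5)
  # all launched: P(S) = 1 at every transition
  alll <- pairs_df(rep("launched", 6))
  for (tr in list(c("preclinical", "I"), c("I", "II"), c("III", "launched"))) {
    st <- contingency_by_phase(alll, tr[1], tr[2])
    expect_equal((st$X_G + st$X_notG) / (st$N_G + st$N_notG), 1)
  }
  expect_error(contingency_by_phase(alll, "II", "II"), "invalid transition")
  expect_error(contingency_by_phase(alll, "III", "I"), "invalid transition")
})

test_that("relative success and Katz CI match frozen hand evaluations", {
  st <- list(X_G = 10, N_G = 100, X_notG = 5, N_notG = 100)
  rs <- relative_success(st)
  expect_equal(rs$rs, 2.0)
  # hand evaluation: exp(ln 2 +/- 1.96 * sqrt(1/10 - 1/100 + 1/5 - 1/100))
  expect_equal(rs$ci_low, 0.708951, tolerance = 1e-3)
  expect_equal(rs$ci_high, 5.642136, tolerance = 1e-3)
  expect_equal(rs$p_g, 0.5)
  expect_equal(rs$p_s, 0.075)
  # degenerate arms
  deg <- relative_success(list(X_G = 5, N_G = 10, X_notG = 0, N_notG = 10))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$ci_low))
  expect_error(relative_success(list(X_G = 0, N_G = 0, X_notG = 1,
                                     N_notG = 10)), "empty arm")
})

test_that("Wilson interval matches the textbook evaluation and boundaries", {
  expect_equal(wilson_ci(5, 10), c(0.236593, 0.763407), tolerance = 1e-3)
  expect_equal(wilson_ci(0, 10)[1], 0)
  expect_equal(wilson_ci(10, 10)[2], 1)
  expect_error(wilson_ci(1, 0), "empty sample")
})

test_that("overall success is the product of per-phase probabilities", {
  # 8 pairs at phase I, 4 reach II, 2 reach III, 1 launches: P(S) each 0.5
  phases <- c(rep("I", 4), rep("II", 2), "III", "launched")
  p <- pairs_df(phases, supported = rep(c(TRUE, FALSE), 4))
  ov <- overall_success(p)
  expect_equal(ov$p_s, 0.125)
  expect_true(ov$p_s_ci[1] <= 0.125 && 0.125 <= ov$p_s_ci[2])
  # supported and unsupported identical: overall RS = 1
  ph <- c(rep("I", 2), rep("II", 2), rep("III", 2), rep("launched", 2))
  p2 <- pairs_df(ph, supported = rep(c(TRUE, FALSE), 4))
  expect_equal(overall_success(p2)$rs$rs, 1)
  # overall stratum: N = entered phase I, X = launched
  expect_equal(ov$overall_stratum$N_G + ov$overall_stratum$N_notG, 8)
  expect_equal(ov$overall_stratum$X_G + ov$overall_stratum$X_notG, 1)
})

test_that("single-stratum CMH equals (n-1)/n times Pearson chi-squared", {
  st <- data.frame(X_G = 30, N_G = 100, X_notG = 20, N_notG = 120)
  got <- cmh_test(st)
  tab <- matrix(c(30, 70, 20, 100), 2, 2)
  n <- sum(tab)
  pearson <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  expect_equal(got$statistic, unname(pearson) * (n - 1) / n,
               tolerance = 1e-6)
  # exact null across strata: statistic ~ 0, p ~ 1
  null_st <- data.frame(X_G = c(10, 20), N_G = c(50, 100),
                        X_notG = c(20, 10), N_notG = c(100, 50))
  got0 <- cmh_test(null_st)
  expect_lt(got0$statistic, 1e-10)
  expect_gt(got0$p_value, 0.999)
})

test_that("CMH detects a common odds ratio across constructed strata", {
  set.seed(21)
  mk <- function() {
    n <- 200
    x_g <- rbinom(1, n, 0.45)   # OR 3 vs baseline ~0.214
    x_n <- rbinom(1, n, 0.214)
    data.frame(X_G = x_g, N_G = n, X_notG = x_n, N_notG = n)
  }
  strata <- do.call(rbind, replicate(3, mk(), simplify = FALSE))
  got <- cmh_test(strata)
  expect_lt(got$p_value, 0.05)
  # independent cross-check against the standard library implementation
  arr <- array(0, dim = c(2, 2, 3))
  for (k in 1:3) arr[, , k] <- c(strata$X_G[k], strata$N_G[k] - strata$X_G[k],
                                 strata$X_notG[k],
                                 strata$N_notG[k] - strata$X_notG[k])
  ref <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("logistic trend recovers a simulated effect and flags separation", {
  set.seed(31)
  n <- 10000
  x <- sample(0:4, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-2 + 0.3 * x))
  tt <- trend_test(y, x)
  expect_false(tt$separation)
  expect_equal(tt$slope, 0.3, tolerance = 0.1)
  expect_lt(tt$p_value, 1e-6)
  # covariate identical to outcome: complete separation
  sep <- trend_test(c(rep(0, 20), rep(1, 20)), c(rep(0, 20), rep(1, 20)))
  expect_true(sep$separation)
  expect_true(is.na(sep$p_value))
  expect_error(trend_test(c(0, 1), c(2, 2)), "distinct covariate")
})

test_that("weighted correlation reduces to Pearson and handles dominance", {
  set.seed(5)
  x <- rnorm(20); y <- 2 * x + rnorm(20, sd = 0.5)
  wc <- weighted_corr(x, y, rep(1, 20))
  ct <- cor.test(x, y)
  expect_equal(wc$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(wc$p_value, ct$p.value, tolerance = 1e-10)
  expect_equal(weighted_corr(x, 2 * x)$rho, 1)
  # one dominant weight drags rho toward that point's local relation:
  # direct formula cross-check
  x4 <- c(0, 1, 2, 3); y4 <- c(0, -1, -2, 9); w4 <- c(1, 1, 1, 100)
  wc4 <- weighted_corr(x4, y4, w4)
  wn <- w4 / sum(w4)
  mx <- sum(wn * x4); my <- sum(wn * y4)
  rho_direct <- sum(wn * (x4 - mx) * (y4 - my)) /
    sqrt(sum(wn * (x4 - mx)^2) * sum(wn * (y4 - my)^2))
  expect_equal(wc4$rho, rho_direct, tolerance = 1e-12)
  expect_gt(wc4$rho, 0)
  expect_error(weighted_corr(rep(1, 5), rnorm(5)), "undefined correlation")
})

test_that("ordinal advancement model recovers null and injected support odds", {
  set.seed(41)
  n <- 4000
  drug_phase <- sample(c("II", "III", "launched"), n, replace = TRUE)
  supported <- runif(n) < 0.3
  # null: phase reached independent of support given drug phase
  reach_null <- vapply(seq_len(n), function(i) {
    top <- prank(drug_phase[i])
    phase_levels[sample(seq_len(top), 1)]
  }, character(1))
  m0 <- ordinal_advancement(data.frame(phase_reached = reach_null,
                                       drug_highest_phase = drug_phase,
                                       supported = supported))
  expect_gt(m0$odds_ratio, 0.85)
  expect_lt(m0$odds_ratio, 1.2)
  # injected proportional-odds effect for support
  beta <- log(1.8)
  reach <- vapply(seq_len(n), function(i) {
    eta <- 0.5 * prank(drug_phase[i]) + beta * supported[i]
    cuts <- c(1.5, 2.5, 3.5)
    phase_levels[1 + sum(plogis(eta - cuts) > runif(1))]
  }, character(1))
  m1 <- ordinal_advancement(data.frame(phase_reached = reach,
                                       drug_highest_phase = drug_phase,
                                       supported = supported))
  se <- abs(m1$coef / qnorm(1 - m1$p_value / 2))
  expect_lt(abs(m1$coef - beta), 3 * se + 0.05)
  expect_gt(m1$odds_ratio, 1.3)
  expect_error(
    ordinal_advancement(data.frame(phase_reached = rep("launched", 5),
                                   drug_highest_phase = "launched",
                                   supported = c(TRUE, FALSE, TRUE, FALSE,
                                                 TRUE))),
    "single outcome level")
})

test_that("therapy areas keep multiples except under oncology dominance", {
  tp <- data.frame(term = c("T1", "T1", "T2", "T2"),
                   area = c("oncology", "immune", "cardiovascular",
                            "metabolic"))
  a <- therapy_areas(c("T1", "T2", "T9"), tp)
  expect_identical(a[["T1"]], "oncology")
  expect_setequal(a[["T2"]], c("cardiovascular", "metabolic"))
  expect_identical(a[["T9"]], "other")
})

test_that("estimates are invariant to input row order", {
  b <- small_bundle(seed = 3)
  pairs <- collapse_to_pairs(b$programs)
  truth <- b$truth$realized
  key <- paste(pairs$gene, pairs$indication_term)
  pairs$supported <- truth$supported[match(key, paste(truth$gene,
                                                      truth$indication_term))]
  st1 <- contingency_by_phase(pairs, "I", "II")
  shuf <- pairs[sample(nrow(pairs)), ]
  st2 <- contingency_by_phase(shuf, "I", "II")
  expect_equal(st1[, -1], st2[, -1])
})
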