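test_that("closed-form natural effects equal the two-point summation oracle", {
  set.seed(501)
  for (r in 1:100) {
    p <- random_mediation_params()
    got <- rilmed:::natural_effects_point(p$beta, p$theta, a = 1, astar = 0,
                                          c_cond = p$c_cond)
    want <- oracle_natural_effects(p$beta, p$theta, a = 1, astar = 0,
                                   c_cond = p$c_cond)
    expect_equal(got, want, tolerance = 1e-10)
    expect_lt(abs(got[["logTR_te"]] - got[["logTR_nde"]] - got[["logTR_nie"]]),
              1e-12)
  }
})

test_that("closed forms agree with Monte-Carlo counterfactual simulation", {
  set.seed(502)
  for (r in 1:10) {
    p <- random_mediation_params()
    got <- rilmed:::natural_effects_point(p$beta, p$theta, c_cond = p$c_cond)
    mc <- mc_natural_effects(p$beta, p$theta, c_cond = p$c_cond, n = 2e5)
    expect_lt(abs(got[["logTR_nde"]] - mc$nde[["est"]]), 3 * mc$nde[["se"]])
    expect_lt(abs(got[["logTR_nie"]] - mc$nie[["est"]]), 3 * mc$nie[["se"]])
  }
})

test_that("a silent mediator or a blocked exposure-mediator path forces NIE = 1", {
  beta <- c("(Intercept)" = -0.4, modality = -1, x1 = 0.5)
  theta <- c("(Intercept)" = 3.6, modality = 0.2, g4ril = 0, x1 = -0.2)
  eff <- rilmed:::natural_effects_point(beta, theta, c_cond = c(x1 = 0.3))
  expect_equal(eff[["logTR_nie"]], 0)
  expect_equal(eff[["logTR_nde"]], 0.2)

  beta2 <- beta; beta2[["modality"]] <- 0
  theta2 <- theta; theta2[["g4ril"]] <- -0.5
  eff2 <- rilmed:::natural_effects_point(beta2, theta2, c_cond = c(x1 = 0.3))
  expect_equal(eff2[["logTR_nie"]], 0)
})

test_that("hazard-scale conversion is the negated, shape-scaled time ratio", {
  expect_equal(exp(to_hazard_scale(0)), 1)
  expect_equal(exp(to_hazard_scale(log(2))), 0.5)
  expect_equal(to_hazard_scale(0.1, shape = 2), -0.2)
})

test_that("proportion mediated reproduces its algebraic special cases", {
  expect_equal(proportion_mediated(log(0.8), 0)$pm, 0)
  expect_equal(proportion_mediated(0, log(0.9))$pm, 1)
  # printed-rounded inputs: direct HR 0.79, indirect HR 0.95
  pm <- proportion_mediated(log(0.79), log(0.95))
  expect_equal(round(pm$pm, 3), 0.158)
  expect_true(pm$valid)
  # harmful total effect is flagged, not clamped
  bad <- proportion_mediated(log(1.4), log(0.95))
  expect_false(bad$valid)
  expect_match(bad$reason, "HR >= 1")
  und <- proportion_mediated(log(2), -log(2))
  expect_false(und$valid)
})

test_that("the NIE-to-median conversion matches its arithmetic", {
  expect_equal(nie_to_median_diff(1, reference_median = 40.9)$estimate, 0)
  expect_equal(nie_to_median_diff(0.5, reference_hazard = log(2) / 50)$estimate, 50)
  d <- nie_to_median_diff(0.95, reference_median = 40.9, ci_nie = c(0.91, 0.99))
  expect_equal(round(d$estimate, 2), 2.15)
  expect_lt(d$conf.low, d$estimate)
  expect_gt(d$conf.high, d$estimate)
  expect_error(nie_to_median_diff(-1, reference_median = 40), "positive")
})

test_that("a mediator with zero outcome coefficient and covariance gives a degenerate NIE CI", {
  beta <- c("(Intercept)" = -0.5, modality = -1)
  theta <- c("(Intercept)" = 3.5, modality = 0.25, g4ril = 0)
  mfit <- rilmed:::new_ril_fit("logistic", beta, diag(0.01, 2), -10, 100, 40, NULL)
  vt <- diag(c(0.01, 0.01, 0)); dimnames(vt) <- list(names(theta), names(theta))
  ofit <- rilmed:::new_ril_fit("exp_aft", theta, vt, -50, 100, 60, NULL)
  ci <- effect_cis(mfit, ofit)
  nie <- ci[ci$effect == "nie", ]
  expect_equal(nie$hr, 1)
  expect_equal(nie$conf.low, 1)
  expect_equal(nie$conf.high, 1)
})

test_that("mediate decomposes exactly and recovers a calibrated generator", {
  co <- simulate_cohort(default_paper_params(n = 5000), seed = 61)
  ps <- fit_ps_model(co)
  pairs <- optimal_match(ps, co)
  m <- matched_cohort(co, pairs)
  med <- mediate(m, ps = ps$scores[match(m$id, co$id)])
  g <- glance(med)
  expect_lt(abs(log(g$hr_te) - log(g$hr_nde) - log(g$hr_nie)), 1e-12)
  expect_lt(g$hr_nie, 1)
  expect_lt(g$hr_nde, 1)
  # total effect close to the generator's target direct x indirect product
  te_row <- med$effects[med$effects$effect == "te", ]
  expect_lt(abs(log(te_row$hr) - log(0.75)), 3 * te_row$std.error)
  # interaction flag must match the fitted design
  expect_error(natural_effects(med$mediator_fit, med$outcome_fit,
                               interaction = TRUE), "inconsistent")
})

test_that("interaction-term mediation still matches the oracle and decomposes", {
  set.seed(62)
  d <- simulate_simple_world(3000,
                             beta = c("(Intercept)" = -0.6, modality = -1, x = 0.5),
                             theta = c("(Intercept)" = 3.7, modality = 0.2,
                                       g4ril = -0.35, x = -0.2))
  med <- mediate(d, covariates = "x", interaction = TRUE, c_cond = c(x = 0))
  eff <- med$effects
  expect_lt(abs(log(eff$hr[3]) - log(eff$hr[1]) - log(eff$hr[2])), 1e-12)
  want <- oracle_natural_effects(coef(med$mediator_fit), coef(med$outcome_fit),
                                 c_cond = c(x = 0))
  expect_equal(eff$log_tr, unname(want), tolerance = 1e-10)
})

test_that("the NIE interval covers 1 under a null exposure-mediator path", {
  set.seed(503)
  reps <- 200
  beta <- c("(Intercept)" = -0.3, modality = 0, x = 0.6)
  theta <- c("(Intercept)" = 3.8, modality = 0.2, g4ril = -0.4, x = -0.25)
  covered <- vapply(seq_len(reps), function(r) {
    d <- simulate_simple_world(1000, beta, theta)
    med <- mediate(d, covariates = "x", c_cond = c(x = 0))
    nie <- med$effects[med$effects$effect == "nie", ]
    nie$conf.low <= 1 && 1 <= nie$conf.high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("delta and bootstrap intervals agree on a moderate cohort", {
  set.seed(504)
  beta <- c("(Intercept)" = -0.5, modality = -1.1, x = 0.6)
  theta <- c("(Intercept)" = 3.8, modality = 0.25, g4ril = -0.4, x = -0.25)
  d <- simulate_simple_world(2000, beta, theta)
  delta <- mediate(d, covariates = "x", c_cond = c(x = 0))
  boot <- mediate(d, covariates = "x", c_cond = c(x = 0),
                  ci_method = "bootstrap", boot_reps = 1000, seed = 77)
  for (e in c("nde", "nie", "te")) {
    dl <- delta$effects[delta$effects$effect == e, ]
    bt <- boot$effects[boot$effects$effect == e, ]
    expect_equal(dl$hr, bt$hr)   # same point estimate
    expect_lt(abs(log(bt$conf.low) - log(dl$conf.low)),
              0.15 * abs(log(dl$conf.low)) + 0.02)
    expect_lt(abs(log(bt$conf.high) - log(dl$conf.high)),
              0.15 * abs(log(dl$conf.high)) + 0.02)
  }
})

test_that("effects are invariant to the time unit", {
  set.seed(505)
  beta <- c("(Intercept)" = -0.5, modality = -1, x = 0.5)
  theta <- c("(Intercept)" = 3.6, modality = 0.2, g4ril = -0.35, x = -0.2)
  d <- simulate_simple_world(1500, beta, theta)
  m1 <- mediate(d, covariates = "x", c_cond = c(x = 0))
  d_days <- dplyr::mutate(d, os_months = os_months * 30.44)
  m2 <- mediate(d_days, covariates = "x", c_cond = c(x = 0))
  expect_equal(m1$effects$hr, m2$effects$hr, tolerance = 1e-8)
  expect_equal(m1$pm, m2$pm, tolerance = 1e-8)
})

test_that("stratified mediation handles constant, balanced, and empty strata", {
  set.seed(506)
  beta <- c("(Intercept)" = -0.4, modality = -1, x = 0.5)
  theta <- c("(Intercept)" = 3.7, modality = 0.2, g4ril = -0.35, x = -0.2)
  d <- simulate_simple_world(1200, beta, theta)

  d$all_one <- 1L
  s1 <- subgroup_mediation(d, "all_one", covariates = "x", c_cond = c(x = 0))
  m <- mediate(d, covariates = "x", c_cond = c(x = 0))
  expect_equal(s1$hr_nie, glance(m)$hr_nie)

  # identical mechanisms in two strata: estimates within joint sampling error
  d2 <- simulate_simple_world(8000, beta, theta)
  d2$stratum <- rep(0:1, each = 4000)
  s2 <- subgroup_mediation(d2, "stratum", covariates = "x", c_cond = c(x = 0))
  se <- vapply(s2$result, function(r) {
    r$effects$std.error[r$effects$effect == "nie"]
  }, numeric(1))
  expect_lt(abs(log(s2$hr_nie[1]) - log(s2$hr_nie[2])), 3 * sqrt(sum(se^2)))
  expect_false(any(s2$underpowered))

  d$dead_stratum <- ifelse(seq_len(nrow(d)) <= 20, 0L, 1L)
  d$event[d$dead_stratum == 0] <- 0L
  expect_warning(s3 <- subgroup_mediation(d, "dead_stratum", covariates = "x",
                                          c_cond = c(x = 0)), "no events")
  expect_equal(nrow(s3), 1)
})
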