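# numerically safe log(1 + exp(x))
log1pexp <- function(x) {
  ifelse(x > 35, x, ifelse(x < -35, exp(x), log1p(exp(x))))
}

#' Natural direct and indirect effects on the log time-ratio scale
#'
#' Closed forms for a binary mediator fitted by logistic regression and a
#' survival outcome fitted by an exponential accelerated failure time model.
#' With mediator linear predictor `L_x = beta0 + beta1 x + beta2'c` and
#' mediator-on-outcome term `k_x = theta2 + theta3 x`, the counterfactual
#' expectation `E[T(x, M(x'))|c]` is proportional to
#' `exp(theta1 x) * E[exp(k_x M)]` with `M ~ Bernoulli(expit(L_x'))`, and the
#' two-point Bernoulli expectation gives
#'
#' * `logTR_NIE = log1pexp(L_a + k_a) + log1pexp(L_a*) -
#'    log1pexp(L_a* + k_a) - log1pexp(L_a)`
#' * `logTR_NDE = theta1 (a - a*) + log1pexp(L_a* + k_a) -
#'    log1pexp(L_a* + k_a*)`
#'
#' and `logTR_TE = logTR_NDE + logTR_NIE` exactly. Outcome-model covariates
#' cancel from all three ratios.
#'
#' @param mediator_fit `ril_fit` from [fit_logistic()]: mediator on exposure
#'   plus adjustment covariates.
#' @param outcome_fit `ril_fit` from [fit_exp_aft()]: survival on exposure,
#'   mediator, optionally their interaction, plus adjustment covariates.
#' @param a,astar exposed and reference exposure levels (default 1 vs 0).
#' @param c_cond named numeric vector of conditioning values for the
#'   mediator-model covariates (default: all zero; [mediate()] passes sample
#'   means).
#' @param exposure,mediator coefficient names of the exposure and mediator
#'   terms.
#' @param interaction does the outcome model carry an exposure-mediator
#'   interaction term? Checked against the fit.
#' @return named numeric vector `c(logTR_nde, logTR_nie, logTR_te)`.
#' @export
natural_effects <- function(mediator_fit, outcome_fit, a = 1, astar = 0,
                            c_cond = NULL, exposure = "modality",
                            mediator = "g4ril", interaction = FALSE) {
  if (a == astar) abort("a and astar must differ")
  beta <- coef(mediator_fit)
  theta <- coef(outcome_fit)
  if (!mediator %in% names(theta)) {
    abort(paste0("outcome model has no mediator term '", mediator, "'"))
  }
  int_name <- paste0(exposure, ":", mediator)
  if (!int_name %in% names(theta)) int_name <- paste0(mediator, ":", exposure)
  has_int <- int_name %in% names(theta)
  if (interaction != has_int) {
    abort("interaction flag is inconsistent with the outcome-model design")
  }
  natural_effects_point(beta, theta, a = a, astar = astar, c_cond = c_cond,
                        exposure = exposure, mediator = mediator)
}

# pure-coefficient version (also the delta-method kernel)
natural_effects_point <- function(beta, theta, a = 1, astar = 0, c_cond = NULL,
                                  exposure = "modality", mediator = "g4ril") {
  covs <- setdiff(names(beta), c("(Intercept)", exposure))
  cvals <- setNames(rep(0, length(covs)), covs)
  if (length(c_cond)) {
    unknown <- setdiff(names(c_cond), covs)
    if (length(unknown)) {
      abort(paste0("c_cond names not in the mediator model: ",
                   paste(unknown, collapse = ", ")))
    }
    cvals[names(c_cond)] <- c_cond
  }
  if (any(!is.finite(cvals))) abort("c_cond must be finite")
  bc <- if (length(covs)) sum(beta[covs] * cvals) else 0
  L <- function(x) beta[["(Intercept)"]] + beta[[exposure]] * x + bc
  int_name <- intersect(c(paste0(exposure, ":", mediator),
                          paste0(mediator, ":", exposure)), names(theta))
  th3 <- if (length(int_name)) theta[[int_name[1]]] else 0
  k <- function(x) theta[[mediator]] + th3 * x

  log_tr_nie <- log1pexp(L(a) + k(a)) + log1pexp(L(astar)) -
    log1pexp(L(astar) + k(a)) - log1pexp(L(a))
  log_tr_nde <- theta[[exposure]] * (a - astar) +
    log1pexp(L(astar) + k(a)) - log1pexp(L(astar) + k(astar))
  c(logTR_nde = unname(log_tr_nde), logTR_nie = unname(log_tr_nie),
    logTR_te = unname(log_tr_nde + log_tr_nie))
}

#' Convert a log time-ratio to a log hazard ratio
#'
#' Under a Weibull AFT model with shape `gamma`, `log HR = -gamma * log TR`;
#' the package default fixes the shape at 1 (exponential model).
#'
#' @param logTR log time-ratio(s).
#' @param shape Weibull shape parameter.
#' @return log hazard ratio(s).
#' @export
to_hazard_scale <- function(logTR, shape = 1) -shape * logTR

#' Proportion of the total effect mediated
#'
#' On the hazard-ratio scale,
#' `PM = exp(NDE) * (exp(NIE) - 1) / (exp(NDE) * exp(NIE) - 1)`, the
#' excess-relative-hazard share of the mediated path. The value is returned
#' unclamped with a validity flag: the formula is interpretable as a
#' proportion only when the total-effect HR is below 1 and both effects point
#' the same way.
#'
#' @param loghr_nde,loghr_nie natural direct and indirect effects as log
#'   hazard ratios.
#' @return list with `pm`, `valid`, `reason`.
#' @export
proportion_mediated <- function(loghr_nde, loghr_nie) {
  te <- loghr_nde + loghr_nie
  if (te == 0) {
    return(list(pm = NA_real_, valid = FALSE, reason = "total-effect HR is exactly 1"))
  }
  pm <- exp(loghr_nde) * (exp(loghr_nie) - 1) / (exp(te) - 1)
  valid <- TRUE; reason <- ""
  if (exp(te) >= 1) { valid <- FALSE; reason <- "total-effect HR >= 1" }
  if (pm < 0 || pm > 1) {
    valid <- FALSE
    reason <- paste0(reason, if (nzchar(reason)) "; ", "PM outside [0, 1]")
  }
  list(pm = pm, valid = valid, reason = reason)
}

#' Median-survival difference attributable to the mediated path
#'
#' Scales a reference-arm exponential hazard by the indirect-effect hazard
#' ratio and differences the implied medians:
#' `delta = ln2/(lambda * hr_nie) - ln2/lambda = (ln2/lambda) (1/hr_nie - 1)`.
#' Interval endpoints substitute the NIE interval endpoints.
#'
#' @param hr_nie indirect-effect hazard ratio (> 0).
#' @param reference_hazard reference-arm hazard rate per month (> 0); give
#'   either this or `reference_median`.
#' @param reference_median reference-arm median survival in months.
#' @param ci_nie optional length-2 NIE hazard-ratio interval.
#' @return one-row tibble: `estimate`, `conf.low`, `conf.high` (months).
#' @export
nie_to_median_diff <- function(hr_nie, reference_hazard = NULL,
                               reference_median = NULL, ci_nie = NULL) {
  if (is.null(reference_hazard)) {
    if (is.null(reference_median)) abort("supply reference_hazard or reference_median")
    if (reference_median <= 0) abort("reference_median must be positive")
    reference_hazard <- log(2) / reference_median
  }
  if (reference_hazard <= 0 || hr_nie <= 0) abort("hazard inputs must be positive")
  delta <- function(hr) (log(2) / reference_hazard) * (1 / hr - 1)
  lo <- hi <- NA_real_
  if (!is.null(ci_nie)) {
    ends <- sort(delta(ci_nie))
    lo <- ends[1]; hi <- ends[2]
  }
  tibble::tibble(estimate = delta(hr_nie), conf.low = lo, conf.high = hi)
}

# delta-method covariance of (logTR_nde, logTR_nie, logTR_te) over the
# stacked (beta, theta) with block-diagonal joint covariance
effect_delta_vcov <- function(mediator_fit, outcome_fit, a, astar, c_cond,
                              exposure, mediator) {
  beta <- coef(mediator_fit); theta <- coef(outcome_fit)
  nb <- length(beta)
  par <- c(beta, theta)
  eff <- function(p) {
    natural_effects_point(p[seq_len(nb)], p[-seq_len(nb)], a = a, astar = astar,
                          c_cond = c_cond, exposure = exposure, mediator = mediator)
  }
  G <- matrix(0, 3, length(par))
  for (j in seq_along(par)) {
    h <- 1e-6 * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm_ <- par; pm_[j] <- pm_[j] - h
    G[, j] <- (eff(pp) - eff(pm_)) / (2 * h)
  }
  Sigma <- matrix(0, length(par), length(par))
  Sigma[seq_len(nb), seq_len(nb)] <- vcov(mediator_fit)
  Sigma[-seq_len(nb), -seq_len(nb)] <- vcov(outcome_fit)
  if (any(!is.finite(Sigma))) abort("singular or invalid joint covariance")
  V <- G %*% Sigma %*% t(G)
  dimnames(V) <- list(c("nde", "nie", "te"), c("nde", "nie", "te"))
  V
}

#' Delta-method confidence intervals for the natural effects
#'
#' Propagates the block-diagonal joint covariance of the mediator and outcome
#' fits through the closed-form effects by central-difference gradients
#' (step `1e-6 * max(1, |param|)`).
#'
#' @inheritParams natural_effects
#' @param conf.level confidence level.
#' @return tibble with one row per effect (`nde`, `nie`, `te`): `log_tr`,
#'   `log_hr`, `hr`, `std.error` (log scale), `conf.low`, `conf.high`
#'   (hazard-ratio scale), `p.value`.
#' @export
effect_cis <- function(mediator_fit, outcome_fit, a = 1, astar = 0,
                       c_cond = NULL, exposure = "modality", mediator = "g4ril",
                       conf.level = 0.95) {
  est <- natural_effects_point(coef(mediator_fit), coef(outcome_fit),
                               a = a, astar = astar, c_cond = c_cond,
                               exposure = exposure, mediator = mediator)
  V <- effect_delta_vcov(mediator_fit, outcome_fit, a, astar, c_cond,
                         exposure, mediator)
  se <- unname(sqrt(pmax(diag(V), 0)))
  z <- qnorm(1 - (1 - conf.level) / 2)
  log_hr <- to_hazard_scale(est)
  tibble::tibble(
    effect = c("nde", "nie", "te"),
    log_tr = unname(est), log_hr = unname(log_hr), hr = exp(unname(log_hr)),
    std.error = unname(se),
    conf.low = exp(unname(log_hr) - z * se),
    conf.high = exp(unname(log_hr) + z * se),
    p.value = 2 * pnorm(-abs(unname(log_hr)) / ifelse(se > 0, se, Inf))
  )
}

#' Regression-based causal mediation for a censored survival outcome
#'
#' Fits the mediator logistic model (mediator ~ exposure + adjustment) and
#' the exponential AFT outcome model (time ~ exposure + mediator
#' [+ interaction] + adjustment), evaluates the closed-form natural effects
#' at the conditioning values, and reports hazard-ratio-scale effects with
#' delta-method (default) or bootstrap confidence intervals, the proportion
#' mediated, and the indirect effect converted to a median-survival
#' difference against the reference arm.
#'
#' @param data validated cohort (typically the matched cohort).
#' @param ps optional per-patient propensity scores, aligned to `data`; added
#'   as the adjustment covariate `ps` (the design of the source analysis).
#'   Set `logit_ps = TRUE` to adjust on the logit scale instead.
#' @param covariates further adjustment covariate names shared by both
#'   models.
#' @param a,astar exposed and reference levels (1 = protons, 0 = photons).
#' @param interaction include the exposure-mediator product in the outcome
#'   model.
#' @param c_cond conditioning values for the adjustment covariates; default
#'   is their sample means.
#' @param ci_method `"delta"` or `"bootstrap"` (percentile, resampling whole
#'   matched pairs when a `pair_id` column is present, otherwise rows).
#' @param boot_reps,seed bootstrap replicates and master seed.
#' @param exposure,mediator,time,event column names.
#' @param logit_ps adjust for `qlogis(ps)` instead of `ps`.
#' @return a `mediation_result`; see [tidy.mediation_result()] and
#'   [glance.mediation_result()].
#' @export
mediate <- function(data, ps = NULL, covariates = NULL, a = 1, astar = 0,
                    interaction = FALSE, c_cond = NULL,
                    ci_method = c("delta", "bootstrap"), boot_reps = 500,
                    seed = 1L, exposure = "modality", mediator = "g4ril",
                    time = "os_months", event = "event", logit_ps = FALSE) {
  ci_method <- match.arg(ci_method)
  data <- tibble::as_tibble(data)
  if (!is.null(ps)) {
    if (length(ps) != nrow(data)) abort("ps scores not aligned to cohort rows")
    data$ps <- if (logit_ps) logit(pmin(pmax(ps, 1e-12), 1 - 1e-12)) else ps
    covariates <- union(covariates, "ps")
  }
  adj <- covariates %||% character(0)
  if (is.null(c_cond) && length(adj)) {
    num <- adj[vapply(data[adj], is.numeric, logical(1))]
    c_cond <- vapply(data[num], mean, numeric(1))
  }

  med_rhs <- paste(c(exposure, adj), collapse = " + ")
  out_terms <- c(exposure, mediator,
                 if (interaction) paste0(exposure, ":", mediator), adj)
  med_f <- as.formula(paste0(mediator, " ~ ", med_rhs))
  out_f <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                             paste(out_terms, collapse = " + ")))

  point_fits <- function(d) {
    list(mediator = fit_logistic(d, med_f), outcome = fit_exp_aft(d, out_f))
  }
  fits <- point_fits(data)
  effects <- effect_cis(fits$mediator, fits$outcome, a = a, astar = astar,
                        c_cond = c_cond, exposure = exposure, mediator = mediator)

  # reference-arm exponential hazard for the median conversion:
  # intercept-only fit, so lambda = events / total follow-up time
  ref <- data[data[[exposure]] == astar, ]
  ref_fit <- fit_exp_aft(ref, as.formula(paste0("survival::Surv(", time, ", ",
                                                event, ") ~ 1")))
  ref_hazard <- exp(-coef(ref_fit)[["(Intercept)"]])

  boot <- NULL
  if (ci_method == "bootstrap") {
    eff_stat <- function(d) {
      f <- point_fits(d)
      est <- natural_effects_point(coef(f$mediator), coef(f$outcome), a = a,
                                   astar = astar, c_cond = c_cond,
                                   exposure = exposure, mediator = mediator)
      to_hazard_scale(est)
    }
    draws <- with_substream(seed, "mediation_bootstrap", {
      purrr::map(seq_len(boot_reps), function(r) {
        d <- if ("pair_id" %in% names(data)) {
          ids <- sample(unique(data$pair_id), replace = TRUE)
          dplyr::bind_rows(lapply(ids, function(pid) data[data$pair_id == pid, ]))
        } else {
          data[sample(nrow(data), replace = TRUE), ]
        }
        tryCatch(eff_stat(d), error = function(e) rep(NA_real_, 3))
      })
    })
    B <- do.call(rbind, draws)
    ok <- stats::complete.cases(B)
    if (mean(ok) < 0.8) warn("more than 20% of bootstrap refits failed")
    qs <- apply(B[ok, , drop = FALSE], 2, quantile, probs = c(0.025, 0.975))
    effects$conf.low <- exp(qs[1, ])
    effects$conf.high <- exp(qs[2, ])
    boot <- B[ok, , drop = FALSE]
  }

  nde <- effects$log_hr[effects$effect == "nde"]
  nie <- effects$log_hr[effects$effect == "nie"]
  pm <- proportion_mediated(nde, nie)
  nie_row <- effects[effects$effect == "nie", ]
  med_diff <- nie_to_median_diff(nie_row$hr, reference_hazard = ref_hazard,
                                 ci_nie = c(nie_row$conf.low, nie_row$conf.high))

  structure(list(
    effects = effects, pm = pm$pm, pm_valid = pm$valid, pm_reason = pm$reason,
    median_diff = med_diff, reference_hazard = unname(ref_hazard),
    reference_median = unname(log(2) / ref_hazard),
    mediator_fit = fits$mediator, outcome_fit = fits$outcome,
    config = list(a = a, astar = astar, interaction = interaction,
                  c_cond = c_cond, ci_method = ci_method,
                  boot_reps = if (ci_method == "bootstrap") boot_reps else NULL,
                  seed = seed, exposure = exposure, mediator = mediator),
    bootstrap = boot,
    n = fits$outcome$n, n_events = fits$outcome$n_events
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n = %d, events = %d (%s CIs)\n",
              x$n, x$n_events, x$config$ci_method))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-3s HR %.3f (95%% CI %.3f-%.3f; P = %.4f)\n",
                toupper(e$effect[i]), e$hr[i], e$conf.low[i], e$conf.high[i],
                e$p.value[i]))
  }
  cat(sprintf("  proportion mediated %.3f%s\n", x$pm,
              if (!x$pm_valid) paste0(" [flagged: ", x$pm_reason, "]") else ""))
  cat(sprintf("  mediated median-survival gain %.2f months (95%% CI %.2f-%.2f)\n",
              x$median_diff$estimate, x$median_diff$conf.low,
              x$median_diff$conf.high))
  invisible(x)
}

#' Tidy / summarise a mediation result
#'
#' @param x a `mediation_result`.
#' @param ... unused.
#' @return `tidy()`: one row per effect (nde, nie, te) with log time-ratio,
#'   log hazard ratio, hazard ratio, CI and p-value. `glance()`: a one-row
#'   overview (effects, PM with validity flag, mediated median gain, sizes).
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) x$effects

#' @rdname tidy.mediation_result
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  e <- x$effects
  hr <- setNames(e$hr, e$effect)
  tibble::tibble(hr_te = hr[["te"]], hr_nde = hr[["nde"]], hr_nie = hr[["nie"]],
                 pm = x$pm, pm_valid = x$pm_valid,
                 median_diff = x$median_diff$estimate,
                 reference_median = x$reference_median,
                 n = x$n, n_events = x$n_events,
                 ci_method = x$config$ci_method)
}

#' Forest-style plot of the mediation effects
#'
#' @param object a `mediation_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  e <- dplyr::mutate(object$effects,
                     effect = factor(toupper(.data$effect),
                                     levels = c("TE", "NDE", "NIE")))
  ggplot2::ggplot(e, ggplot2::aes(x = .data$hr, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (log scale)", y = NULL,
                  title = "Total, direct and mediated effects on survival") +
    ggplot2::theme_minimal()
}

#' Stratified mediation analysis
#'
#' Runs [mediate()] independently within each level of a stratifying column
#' (e.g. surgical resection), skipping strata with no events and flagging
#' strata with fewer events than `min_events`.
#'
#' @inheritParams mediate
#' @param strata stratifying column name.
#' @param min_events events floor below which a stratum is flagged
#'   underpowered.
#' @param ... further arguments to [mediate()].
#' @return a tibble with one row per analysed stratum: `stratum`, `n`,
#'   `n_events`, `underpowered`, the glance columns, and a `result`
#'   list-column of `mediation_result`s.
#' @export
subgroup_mediation <- function(data, strata, ps = NULL, min_events = 10, ...) {
  if (!strata %in% names(data)) abort(paste0("strata column not found: ", strata))
  lev <- sort(unique(data[[strata]]))
  rows <- purrr::map(lev, function(lv) {
    idx <- data[[strata]] == lv
    d <- data[idx, ]
    if (sum(d$event) == 0) {
      warn(paste0("stratum ", strata, " = ", lv, " has no events; skipped"))
      return(NULL)
    }
    res <- mediate(d, ps = if (is.null(ps)) NULL else ps[idx], ...)
    dplyr::bind_cols(tibble::tibble(stratum = as.character(lv),
                                    underpowered = res$n_events < min_events),
                     glance(res)) |>
      dplyr::mutate(result = list(res))
  })
  dplyr::bind_rows(rows)
}
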