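#' Fitted-model container shared by all estimators
#'
#' Every estimator in the package returns a `ril_fit`: named coefficients on
#' the model's natural scale (log-odds, log-time, or log-hazard), the
#' observed-information covariance, the log-likelihood, and the sample /
#' event counts. [generics::tidy()] and [generics::glance()] methods give
#' broom-style output.
#'
#' @name ril_fit
NULL

new_ril_fit <- function(model_kind, coefficients, vcov, loglik, n, n_events, fit,
                        extra = list()) {
  stopifnot(model_kind %in% c("logistic", "exp_aft", "weibull_aft", "cox"))
  if (n_events > n) abort("n_events exceeds n")
  v <- (vcov + t(vcov)) / 2
  if (any(eigen(v, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    abort("covariance matrix is not positive semi-definite")
  }
  structure(c(list(model_kind = model_kind, coefficients = coefficients,
                   vcov = v, loglik = loglik, n = as.integer(n),
                   n_events = as.integer(n_events), fit = fit), extra),
            class = "ril_fit")
}

#' @export
print.ril_fit <- function(x, ...) {
  cat(sprintf("<ril_fit: %s>  n = %d, events = %d, logLik = %.3f\n",
              x$model_kind, x$n, x$n_events, x$loglik))
  print(tidy(x))
  invisible(x)
}

#' @export
coef.ril_fit <- function(object, ...) object$coefficients

#' @export
vcov.ril_fit <- function(object, ...) object$vcov

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model
#'
#' @param x a `ril_fit`.
#' @param exponentiate report `exp(estimate)` (odds/hazard/time ratios) and
#'   exponentiated Wald limits.
#' @param conf.level confidence level for the Wald interval.
#' @param ... unused.
#' @return a tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @method tidy ril_fit
#' @export
tidy.ril_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    conf.low = unname(est - z * se), conf.high = unname(est + z * se)
  )
  if (exponentiate) {
    out <- dplyr::mutate(out, estimate = exp(.data$estimate),
                         conf.low = exp(.data$conf.low),
                         conf.high = exp(.data$conf.high))
  }
  out
}

#' @param x a `ril_fit`.
#' @param ... unused.
#' @rdname tidy.ril_fit
#' @method glance ril_fit
#' @export
glance.ril_fit <- function(x, ...) {
  tibble::tibble(model_kind = x$model_kind, logLik = x$loglik,
                 n = x$n, n_events = x$n_events,
                 df = length(x$coefficients))
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; aliased column(s): ",
                 paste(bad, collapse = ", ")))
  }
}

#' Logistic regression returning a `ril_fit`
#'
#' Maximum likelihood via iteratively reweighted least squares. Errors on
#' rank-deficient designs and on (quasi-)separation, which the paper-style
#' odds-ratio tables cannot tolerate silently.
#'
#' @param data a data frame.
#' @param formula model formula with a binary (0/1 or two-level factor)
#'   response.
#' @return a `ril_fit` with `model_kind = "logistic"`; coefficients are
#'   log-odds ratios.
#' @export
fit_logistic <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1))) abort("response must be binary")
  if (length(unique(y)) < 2) abort("response is constant; model is degenerate")
  X <- model.matrix(formula, mf)
  check_full_rank(X)
  fit <- suppressWarnings(glm(formula, data = data, family = binomial(),
                              control = stats::glm.control(epsilon = 1e-12,
                                                           maxit = 100)))
  mu <- fitted(fit)
  if (any(abs(coef(fit)) > 15) || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    abort("separation detected: a fitted probability is numerically 0 or 1")
  }
  if (!fit$converged) abort("logistic fit did not converge")
  new_ril_fit("logistic", coef(fit), vcov(fit), as.numeric(logLik(fit)),
              n = length(y), n_events = sum(y), fit = fit,
              extra = list(formula = formula))
}

# censored exponential-AFT log-likelihood and score, used for the
# gradient-at-optimum invariant and as an independent check on survreg
exp_aft_loglik <- function(theta, times, events, X) {
  mu <- as.vector(X %*% theta)
  sum(events * (-mu) - times * exp(-mu))
}
exp_aft_score <- function(theta, times, events, X) {
  mu <- as.vector(X %*% theta)
  as.vector(t(X) %*% (times * exp(-mu) - events))
}

logistic_score <- function(b, y, X) {
  as.vector(t(X) %*% (y - expit(as.vector(X %*% b))))
}

#' Exponential (or free-shape Weibull) accelerated failure time model
#'
#' Coefficients are on the log-time scale: a positive coefficient lengthens
#' survival. With the shape fixed at 1 (the default, an exponential model)
#' the log hazard ratio of a term equals minus its coefficient.
#'
#' @param data a data frame.
#' @param formula a formula with a [survival::Surv()] response, e.g.
#'   `Surv(os_months, event) ~ modality + g4ril`.
#' @param free_shape fit a free Weibull shape instead of fixing it at 1
#'   (sensitivity analysis only).
#' @return a `ril_fit` (`model_kind` `"exp_aft"` or `"weibull_aft"`);
#'   coefficient covariance excludes the scale parameter when the shape is
#'   fixed.
#' @export
fit_exp_aft <- function(data, formula, free_shape = FALSE) {
  dist <- if (free_shape) "weibull" else "exponential"
  fit <- survival::survreg(formula, data = data, dist = dist,
                           control = survival::survreg.control(maxiter = 100,
                                                               rel.tolerance = 1e-10))
  y <- stats::model.response(stats::model.frame(formula, data))
  events <- y[, "status"]
  if (sum(events) == 0) abort("no events: exponential AFT likelihood is unbounded")
  times <- y[, "time"]
  if (any(times <= 0)) abort("survival times must be strictly positive")
  k <- length(coef(fit))
  X <- model.matrix(formula, data)
  check_full_rank(X)
  if (!free_shape) {
    g <- exp_aft_score(coef(fit), times, events, X)
    if (sqrt(sum(g^2)) > 1e-4 * max(1, sum(events))) {
      abort(sprintf("exponential AFT fit did not converge (score norm %.3g)",
                    sqrt(sum(g^2))))
    }
  }
  new_ril_fit(if (free_shape) "weibull_aft" else "exp_aft",
              coef(fit), vcov(fit)[seq_len(k), seq_len(k), drop = FALSE],
              as.numeric(logLik(fit)),
              n = length(times), n_events = sum(events), fit = fit,
              extra = list(formula = formula,
                           shape = if (free_shape) 1 / fit$scale else 1))
}

#' Cox proportional hazards model
#'
#' Partial-likelihood Newton-Raphson via [survival::coxph()], Efron tie
#' handling by default.
#'
#' @inheritParams fit_exp_aft
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return a `ril_fit` with `model_kind = "cox"`; coefficients are log hazard
#'   ratios.
#' @export
fit_cox <- function(data, formula, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  y <- stats::model.response(stats::model.frame(formula, data))
  if (sum(y[, "status"]) < 1) abort("at least one event is required")
  fit <- survival::coxph(formula, data = data, ties = ties,
                         control = survival::coxph.control(eps = 1e-10, iter.max = 100))
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15)) {
    abort("monotone partial likelihood: a coefficient diverged (no events in a level?)")
  }
  new_ril_fit("cox", coef(fit), vcov(fit), fit$loglik[2],
              n = fit$n, n_events = fit$nevent, fit = fit,
              extra = list(formula = formula, ties = ties))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood variance; confidence limits on the
#' log-log scale, so the median interval is Brookmeyer-Crowley.
#'
#' @param data a data frame.
#' @param time,event,group column names (character); `group = NULL` for a
#'   single pooled curve.
#' @param conf.level confidence level.
#' @return a `km_curve` object; [tidy()] gives the step function,
#'   [glance()] the per-group median with CI.
#' @export
km_estimate <- function(data, time = "os_months", event = "event", group = NULL,
                        conf.level = 0.95) {
  rhs <- if (is.null(group)) "1" else group
  f <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", rhs))
  fit <- survival::survfit(f, data = data, conf.type = "log-log",
                           conf.int = conf.level)
  structure(list(fit = fit, group = group, time = time, event = event),
            class = "km_curve")
}

km_strata <- function(x) {
  fit <- x$fit
  if (is.null(fit$strata)) {
    rep("all", length(fit$time))
  } else {
    sub("^[^=]*=", "", rep(names(fit$strata), fit$strata))
  }
}

#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) {
  fit <- x$fit
  tibble::tibble(group = km_strata(x), time = fit$time,
                 n.risk = fit$n.risk, n.event = fit$n.event,
                 estimate = fit$surv, std.error = fit$std.err,
                 conf.low = fit$lower, conf.high = fit$upper)
}

#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  s <- summary(x$fit)$table
  if (is.null(dim(s))) s <- matrix(s, nrow = 1, dimnames = list("all", names(s)))
  tibble::tibble(group = sub("^[^=]*=", "", rownames(s)),
                 n = s[, "records"], events = s[, "events"],
                 median = s[, "median"],
                 median_low = s[, grep("LCL", colnames(s))],
                 median_high = s[, grep("UCL", colnames(s))])
}

#' Survival probability at fixed times with Greenwood-based CI
#'
#' @param x a `km_curve`.
#' @param times numeric vector of times (months).
#' @return tibble of `group`, `time`, `estimate`, `conf.low`, `conf.high`.
#' @export
km_rate_at <- function(x, times) {
  s <- summary(x$fit, times = times, extend = TRUE)
  grp <- if (is.null(s$strata)) "all" else sub("^[^=]*=", "", as.character(s$strata))
  tibble::tibble(group = grp, time = s$time, estimate = s$surv,
                 conf.low = s$lower, conf.high = s$upper)
}

#' Log-rank test
#'
#' Observed-minus-expected chi-squared with hypergeometric variance.
#'
#' @inheritParams km_estimate
#' @param group grouping column (>= 2 non-empty levels).
#' @return one-row tibble: `statistic`, `df`, `p.value`.
#' @export
logrank_test <- function(data, time = "os_months", event = "event",
                         group = "modality") {
  g <- factor(data[[group]])
  if (nlevels(droplevels(g)) < 2) abort("log-rank needs at least 2 non-empty groups")
  f <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", group))
  sd_ <- survival::survdiff(f, data = data)
  df <- length(sd_$n) - 1
  tibble::tibble(statistic = sd_$chisq, df = df,
                 p.value = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Regression table in the published layout
#'
#' Formats a `ril_fit` as the familiar `OR (95% CI; P)` / `HR (95% CI; P)`
#' table. For AFT fits the ratio column is the hazard ratio `exp(-coef)`
#' (shape 1).
#'
#' @param fit a `ril_fit`.
#' @return a tibble: `term`, `ratio`, `conf.low`, `conf.high`, `p.value`,
#'   `label`.
#' @export
fit_table <- function(fit) {
  td <- tidy(fit)
  flip <- fit$model_kind %in% c("exp_aft", "weibull_aft")
  shape <- if (flip) (fit$shape %||% 1) else 1
  est <- if (flip) exp(-shape * td$estimate) else exp(td$estimate)
  lo <- if (flip) exp(-shape * td$conf.high) else exp(td$conf.low)
  hi <- if (flip) exp(-shape * td$conf.low) else exp(td$conf.high)
  tibble::tibble(term = td$term, ratio = est, conf.low = lo, conf.high = hi,
                 p.value = td$p.value,
                 label = sprintf("%.2f (%.2f-%.2f; P = %.3f)", est, lo, hi, td$p.value))
}
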