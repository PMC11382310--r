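default_candidates <- function() {
  c("age", "sex", "baseline_alc", "ptv", "ecog", "location", "stage",
    "chemo_cycles", "barretts", "histology", "surgery")
}

#' Univariate confounder screen
#'
#' For each candidate covariate, fits a single-covariate logistic regression
#' of the exposure and a single-covariate Cox regression of overall survival,
#' and flags covariates associated with either endpoint at level `alpha`.
#' Multi-level factors are summarised by their smallest per-level Wald p.
#'
#' @param data validated cohort tibble.
#' @param candidates covariate names to screen.
#' @param alpha significance level for flagging (default 0.05).
#' @param exposure,time,event column names.
#' @return a tibble: `covariate`, `log_or`, `p_exposure`, `log_hr`, `p_os`,
#'   `flagged`, `note`.
#' @export
univariate_screen <- function(data, candidates = default_candidates(),
                              alpha = 0.05, exposure = "modality",
                              time = "os_months", event = "event") {
  missing_c <- setdiff(candidates, names(data))
  if (length(missing_c) > 0) {
    abort(paste0("unknown candidate covariate(s): ", paste(missing_c, collapse = ", ")))
  }
  one <- function(v) {
    x <- data[[v]]
    if (length(unique(x)) < 2) {
      warn(paste0("covariate '", v, "' is constant; excluded from screen"))
      return(tibble::tibble(covariate = v, log_or = NA_real_, p_exposure = NA_real_,
                            log_hr = NA_real_, p_os = NA_real_, flagged = FALSE,
                            note = "constant"))
    }
    note <- ""
    lg <- tryCatch(
      tidy(fit_logistic(data, as.formula(paste0(exposure, " ~ ", v)))),
      error = function(e) {
        if (grepl("separation", conditionMessage(e))) {
          warn(paste0("covariate '", v, "' separates the exposure arms"))
          note <<- "separation"
          tibble::tibble(term = v, estimate = Inf, p.value = 0)
        } else {
          note <<- conditionMessage(e)
          NULL
        }
      })
    cx <- tryCatch(
      tidy(fit_cox(data, as.formula(paste0("survival::Surv(", time, ", ", event,
                                           ") ~ ", v)))),
      error = function(e) NULL)
    pick <- function(td) {
      if (is.null(td)) return(c(NA_real_, NA_real_))
      td <- td[td$term != "(Intercept)", ]
      i <- which.min(td$p.value)
      c(td$estimate[i], td$p.value[i])
    }
    le <- pick(lg); ce <- pick(cx)
    flagged <- isTRUE(le[2] < alpha) || isTRUE(ce[2] < alpha)
    tibble::tibble(covariate = v, log_or = le[1], p_exposure = le[2],
                   log_hr = ce[1], p_os = ce[2], flagged = flagged, note = note)
  }
  purrr::map_dfr(candidates, one)
}

term_wald_p <- function(fit) {
  # term-level Wald chi-square, pooling the coefficient block of each term
  asg <- attr(model.matrix(fit), "assign")
  labs <- attr(terms(fit), "term.labels")
  b <- coef(fit); V <- vcov(fit)
  vapply(seq_along(labs), function(k) {
    idx <- which(asg == k)
    bi <- b[idx]
    Vi <- V[idx, idx, drop = FALSE]
    w <- tryCatch(as.numeric(t(bi) %*% solve(Vi, bi)), error = function(e) NA_real_)
    pchisq(w, df = length(idx), lower.tail = FALSE)
  }, numeric(1)) |> setNames(labs)
}

#' Propensity model with backward elimination and forced covariates
#'
#' Starts from the full multivariable logistic model of the exposure on all
#' candidates, then repeatedly removes the non-forced term with the largest
#' term-level Wald p while that p exceeds `p_remove` (or, with
#' `criterion = "aic"`, while removal lowers the AIC), refitting after each
#' removal. Forced covariates are never removed.
#'
#' @param data validated cohort tibble.
#' @param candidates candidate covariate names (must include `forced`).
#' @param forced covariates always kept (default age and surgical status).
#' @param criterion `"wald"` (remove while max p > `p_remove`) or `"aic"`.
#' @param p_remove removal threshold for the Wald criterion.
#' @param exposure exposure column.
#' @return a `ps_model`: the final `glm`, `selected` term names, `forced`,
#'   and per-patient `scores` = estimated P(exposure = 1 | C) in (0, 1).
#' @export
fit_ps_model <- function(data, candidates = default_candidates(),
                         forced = c("age", "surgery"), criterion = c("wald", "aic"),
                         p_remove = 0.05, exposure = "modality") {
  criterion <- match.arg(criterion)
  if (!all(forced %in% candidates)) abort("candidates must contain all forced covariates")
  current <- candidates
  refit <- function(terms) {
    f <- as.formula(paste0(exposure, " ~ ", paste(terms, collapse = " + ")))
    fit <- suppressWarnings(glm(f, data = data, family = binomial()))
    if (!fit$converged) {
      abort(paste0("propensity model did not converge with covariates: ",
                   paste(terms, collapse = ", ")))
    }
    fit
  }
  fit <- refit(current)
  repeat {
    removable <- setdiff(current, forced)
    if (length(removable) == 0) break
    if (criterion == "wald") {
      p <- term_wald_p(fit)[removable]
      worst <- names(which.max(p))
      if (!length(worst) || max(p, na.rm = TRUE) <= p_remove) break
    } else {
      aic0 <- stats::AIC(fit)
      aics <- vapply(removable, function(v) {
        stats::AIC(refit(setdiff(current, v)))
      }, numeric(1))
      worst <- names(which.min(aics))
      if (min(aics) >= aic0) break
    }
    current <- setdiff(current, worst)
    fit <- refit(current)
  }
  scores <- as.numeric(fitted(fit))
  scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  structure(list(fit = fit, selected = current, forced = forced,
                 exposure = exposure, criterion = criterion,
                 scores = scores, id = data$id),
            class = "ps_model")
}

#' @export
print.ps_model <- function(x, ...) {
  cat(sprintf("<ps_model> %s ~ %s  (forced: %s; %s criterion)\n",
              x$exposure, paste(x$selected, collapse = " + "),
              paste(x$forced, collapse = ", "), x$criterion))
  invisible(x)
}

#' @method tidy ps_model
#' @export
tidy.ps_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @method glance ps_model
#' @export
glance.ps_model <- function(x, ...) {
  tibble::tibble(n = length(x$scores), n_terms = length(x$selected),
                 aic = stats::AIC(x$fit), criterion = x$criterion)
}

# greedy nearest-neighbour matching (benchmark for the optimality property)
greedy_match <- function(d_treated, d_control) {
  used <- rep(FALSE, length(d_control))
  total <- 0
  pick <- integer(length(d_treated))
  for (i in seq_along(d_treated)) {
    dd <- abs(d_control - d_treated[i])
    dd[used] <- Inf
    j <- which.min(dd)
    used[j] <- TRUE
    pick[i] <- j
    total <- total + dd[j]
  }
  list(pick = pick, total = total)
}

# exact min-total-distance 1:1 matching of all treated to distinct controls.
# On a line with absolute distance an optimal matching is non-crossing, so
# both arms can be taken in sorted order and solved by dynamic programming:
# f(i, j) = cost of matching the first i treated within the first j controls,
# f(i, j) = min(f(i, j-1), f(i-1, j-1) + |t_i - c_j|), with the inner
# recursion vectorised as a cumulative minimum.
optimal_match_1d <- function(d_treated, d_control) {
  nt <- length(d_treated); nc <- length(d_control)
  stopifnot(nt <= nc)
  f_prev <- rep(0, nc + 1)              # f(i-1, j), j = 0..nc
  choice <- matrix(FALSE, nt, nc)       # TRUE: treated i matched to control j
  for (i in seq_len(nt)) {
    js <- i:nc
    v <- f_prev[js] + abs(d_treated[i] - d_control[js])  # take control j
    cm <- cummin(v)
    choice[i, js] <- v <= c(Inf, cm[-length(cm)])        # take beats skipping
    f_prev <- c(rep(Inf, i), cm)
  }
  pick <- integer(nt)
  j <- nc
  for (i in nt:1) {
    while (!choice[i, j]) j <- j - 1
    pick[i] <- j
    j <- j - 1
  }
  list(pick = pick, total = f_prev[nc + 1])
}

#' Optimal 1:1 propensity matching
#'
#' Pairs every member of the smaller arm with a distinct member of the larger
#' arm so that the total absolute pairwise distance is globally minimal (the
#' bipartite assignment optimum — no other complete pairing has a smaller
#' total). Distances are on the logit of the propensity score by default.
#' Ties are broken by lowest patient id.
#'
#' @param ps_model a [fit_ps_model()] result (or a numeric score vector).
#' @param data the cohort the model was fit on (ids must align).
#' @param distance_scale `"logit"` (default) or `"probability"`.
#' @param caliper optional maximal pair distance; wider pairs are dropped
#'   after the optimal solution is found.
#' @param exposure exposure column.
#' @return a `matched_pairs` tibble (`treated_id`, `control_id`, `distance`)
#'   with attributes `total_distance` and `distance_scale`.
#' @export
optimal_match <- function(ps_model, data, distance_scale = c("logit", "probability"),
                          caliper = NULL, exposure = "modality") {
  distance_scale <- match.arg(distance_scale)
  scores <- if (inherits(ps_model, "ps_model")) ps_model$scores else as.numeric(ps_model)
  if (length(scores) != nrow(data)) abort("scores and cohort rows are not aligned")
  d <- if (distance_scale == "logit") logit(scores) else scores
  trt <- data[[exposure]] == 1
  if (sum(trt) == 0 || sum(!trt) == 0) abort("both arms must be non-empty")

  side <- function(keep) {
    o <- order(d[keep], data$id[keep])
    list(d = d[keep][o], id = data$id[keep][o])
  }
  t_side <- side(trt); c_side <- side(!trt)
  swapped <- length(t_side$d) > length(c_side$d)
  small <- if (swapped) c_side else t_side
  large <- if (swapped) t_side else c_side
  sol <- optimal_match_1d(small$d, large$d)

  pairs <- tibble::tibble(
    treated_id = if (swapped) large$id[sol$pick] else small$id,
    control_id = if (swapped) small$id else large$id[sol$pick],
    distance = abs(small$d - large$d[sol$pick])
  )
  if (!is.null(caliper)) pairs <- pairs[pairs$distance <= caliper, ]
  pairs <- dplyr::arrange(pairs, .data$treated_id)
  attr(pairs, "total_distance") <- sum(pairs$distance)
  attr(pairs, "distance_scale") <- distance_scale
  class(pairs) <- c("matched_pairs", class(pairs))
  pairs
}

#' Restrict a cohort to its matched pairs
#'
#' @param data the full cohort.
#' @param pairs a [optimal_match()] result.
#' @return the matched subset with a `pair_id` column, row order treated
#'   pair-by-pair.
#' @export
matched_cohort <- function(data, pairs) {
  idx_t <- match(pairs$treated_id, data$id)
  idx_c <- match(pairs$control_id, data$id)
  if (anyNA(idx_t) || anyNA(idx_c)) abort("pair ids not found in cohort")
  out <- data[as.vector(rbind(idx_t, idx_c)), ]
  out$pair_id <- rep(seq_len(nrow(pairs)), each = 2)
  attr(out, "provenance") <- "matched"
  out
}

smd_one <- function(x, g, sd_ref = NULL) {
  if (is.numeric(x)) {
    s <- sd_ref %||% sqrt((var(x[g]) + var(x[!g])) / 2)
    if (s == 0) return(0)
    (mean(x[g]) - mean(x[!g])) / s
  } else {
    p1 <- mean(x[g] == levels(factor(x))[length(levels(factor(x)))])
    p0 <- mean(x[!g] == levels(factor(x))[length(levels(factor(x)))])
    s <- sd_ref %||% sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
    if (s == 0) return(0)
    (p1 - p0) / s
  }
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (pooled-SD denominator from the
#' pre-matching sample, the usual convention so before/after are on one
#' scale) plus the same Welch-t / chi-squared p-values as
#' [summarize_cohort()].
#'
#' @param data the full cohort.
#' @param pairs a [optimal_match()] result.
#' @param covariates covariate columns to assess.
#' @param exposure exposure column.
#' @return tibble: `covariate`, `smd_before`, `smd_after`, `p_before`,
#'   `p_after`.
#' @export
match_diagnostics <- function(data, pairs, covariates = default_candidates(),
                              exposure = "modality") {
  matched <- matched_cohort(data, pairs)
  if (nrow(matched) == 0) abort("matched cohort is empty")
  g_all <- data[[exposure]] == 1
  g_m <- matched[[exposure]] == 1
  pval <- function(x, g) {
    if (is.numeric(x)) {
      tryCatch(stats::t.test(x[g], x[!g])$p.value, error = function(e) NA_real_)
    } else {
      tab <- table(x, g)
      tryCatch(suppressWarnings(
        stats::chisq.test(tab, correct = nrow(tab) == 2 && ncol(tab) == 2)$p.value),
        error = function(e) NA_real_)
    }
  }
  purrr::map_dfr(covariates, function(v) {
    x_all <- data[[v]]; x_m <- matched[[v]]
    sd_ref <- if (is.numeric(x_all)) {
      sqrt((var(x_all[g_all]) + var(x_all[!g_all])) / 2)
    } else {
      lev <- levels(factor(x_all))[nlevels(factor(x_all))]
      p1 <- mean(x_all[g_all] == lev); p0 <- mean(x_all[!g_all] == lev)
      sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
    }
    tibble::tibble(covariate = v,
                   smd_before = smd_one(x_all, g_all, sd_ref),
                   smd_after = smd_one(x_m, g_m, sd_ref),
                   p_before = pval(x_all, g_all),
                   p_after = pval(x_m, g_m))
  })
}
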