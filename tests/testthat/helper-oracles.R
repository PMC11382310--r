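# Independent oracles used across the suite.

# Counterfactual expectations by direct two-point summation over the Bernoulli
# mediator: E[T(x, M(x')) | c] = exp(th0 + th1 x + th4'c) *
#   [(1 - p_{x'}) + p_{x'} exp(th2 + th3 x)],  p_x = expit(b0 + b1 x + b2'c).
# Effects are ratios of these expectations; they do not use the package's
# closed forms.
oracle_natural_effects <- function(beta, theta, a = 1, astar = 0, c_cond = NULL,
                                   exposure = "modality", mediator = "g4ril") {
  covs <- setdiff(names(beta), c("(Intercept)", exposure))
  cvals <- setNames(rep(0, length(covs)), covs)
  if (length(c_cond)) cvals[names(c_cond)] <- c_cond
  p_m <- function(x) {
    plogis(beta[["(Intercept)"]] + beta[[exposure]] * x +
             if (length(covs)) sum(beta[covs] * cvals) else 0)
  }
  int_nm <- intersect(c(paste0(exposure, ":", mediator),
                        paste0(mediator, ":", exposure)), names(theta))
  th3 <- if (length(int_nm)) theta[[int_nm[1]]] else 0
  ET <- function(x, xprime) {
    p <- p_m(xprime)
    exp(theta[[exposure]] * x) *
      ((1 - p) + p * exp(theta[[mediator]] + th3 * x))
  }
  nde <- log(ET(a, astar) / ET(astar, astar))
  nie <- log(ET(a, a) / ET(a, astar))
  c(logTR_nde = unname(nde), logTR_nie = unname(nie),
    logTR_te = unname(nde + nie))
}

# Monte-Carlo counterfactual simulation of the same expectations. Returns
# point estimates and delta-method MC standard errors of each log effect.
mc_natural_effects <- function(beta, theta, a = 1, astar = 0, c_cond = NULL,
                               n = 1e6, exposure = "modality",
                               mediator = "g4ril") {
  covs <- setdiff(names(beta), c("(Intercept)", exposure))
  cvals <- setNames(rep(0, length(covs)), covs)
  if (length(c_cond)) cvals[names(c_cond)] <- c_cond
  int_nm <- intersect(c(paste0(exposure, ":", mediator),
                        paste0(mediator, ":", exposure)), names(theta))
  th3 <- if (length(int_nm)) theta[[int_nm[1]]] else 0
  draw_T <- function(x, xprime) {
    p <- plogis(beta[["(Intercept)"]] + beta[[exposure]] * xprime +
                  if (length(covs)) sum(beta[covs] * cvals) else 0)
    m <- rbinom(n, 1, p)
    mu <- theta[[exposure]] * x + theta[[mediator]] * m + th3 * x * m
    exp(mu) * rexp(n)
  }
  stat <- function(num, den) {
    # log of ratio of means with MC variance by the delta method
    est <- log(mean(num) / mean(den))
    se <- sqrt(var(num) / (n * mean(num)^2) + var(den) / (n * mean(den)^2))
    c(est = est, se = se)
  }
  t_aa <- draw_T(a, a); t_aastar <- draw_T(a, astar); t_ss <- draw_T(astar, astar)
  list(nde = stat(t_aastar, t_ss), nie = stat(t_aa, t_aastar))
}

# random mediation parameter draws over moderate, well-conditioned ranges
random_mediation_params <- function() {
  beta <- c("(Intercept)" = runif(1, -1.5, 1.5), modality = runif(1, -2, 2),
            x1 = runif(1, -1, 1), x2 = runif(1, -1, 1))
  theta <- c("(Intercept)" = runif(1, 2, 5), modality = runif(1, -0.6, 0.6),
             g4ril = runif(1, -0.8, 0.8), "modality:g4ril" = runif(1, -0.5, 0.5),
             x1 = runif(1, -0.5, 0.5), x2 = runif(1, -0.5, 0.5))
  c_cond <- c(x1 = runif(1, -1, 1), x2 = runif(1, -1, 1))
  list(beta = beta, theta = theta, c_cond = c_cond)
}

# all permutations of 1:n as a matrix (memoised; n! rows)
perm_matrix <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- if (n == 1) matrix(1L) else {
      sub <- perm_matrix(n - 1)
      do.call(rbind, lapply(seq_len(n), function(k) {
        cbind(k, ifelse(sub >= k, sub + 1L, sub))
      }))
    }
    cache[[key]] <<- p
    p
  }
})

# exhaustive minimum total |distance| over all complete 1:1 pairings
# (all permutations when arms are equal, all picks x permutations otherwise)
brute_force_match_total <- function(d_treated, d_control) {
  if (length(d_treated) > length(d_control)) {
    tmp <- d_treated; d_treated <- d_control; d_control <- tmp
  }
  if (length(d_treated) == length(d_control)) {
    P <- perm_matrix(length(d_treated))
    totals <- rowSums(abs(matrix(d_control[P], nrow(P)) -
                            matrix(d_treated, nrow(P), ncol(P), byrow = TRUE)))
    return(min(totals))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  picks <- utils::combn(length(d_control), length(d_treated), simplify = FALSE)
  for (sel in picks) {
    for (p in perms(sel)) {
      best <- min(best, sum(abs(d_treated - d_control[p])))
    }
  }
  best
}

# expand a 2x2 exposure-by-outcome table into patient rows
table2x2_to_df <- function(n_ctrl_no, n_ctrl_yes, n_trt_no, n_trt_yes) {
  tibble::tibble(
    exposure = rep(c(0, 0, 1, 1), c(n_ctrl_no, n_ctrl_yes, n_trt_no, n_trt_yes)),
    outcome = rep(c(0, 1, 0, 1), c(n_ctrl_no, n_ctrl_yes, n_trt_no, n_trt_yes))
  )
}

# a small single-covariate world whose structure matches the mediation
# analysis model exactly (used for coverage and null-calibration checks)
simulate_simple_world <- function(n, beta, theta, censor = c(20, 200)) {
  x <- rnorm(n)
  a <- rbinom(n, 1, plogis(0.3 * x))
  m <- rbinom(n, 1, plogis(beta[["(Intercept)"]] + beta[["modality"]] * a +
                             beta[["x"]] * x))
  mu <- theta[["(Intercept)"]] + theta[["modality"]] * a + theta[["g4ril"]] * m +
    theta[["x"]] * x
  tstar <- exp(mu) * rexp(n)
  u <- runif(n, censor[1], censor[2])
  tibble::tibble(x = x, modality = a, g4ril = m,
                 os_months = pmin(tstar, u), event = as.integer(tstar <= u))
}
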