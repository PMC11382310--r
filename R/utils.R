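#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats as.formula coef glm logLik median model.matrix na.omit
#'   pchisq plogis pnorm predict qlogis qnorm quantile rbinom rexp rnorm runif fitted
#'   sd setNames terms uniroot var vcov binomial
#' @importFrom utils head modifyList
NULL

expit <- function(x) plogis(x)
logit <- function(p) qlogis(p)

#' Derive a reproducible sub-seed from a master seed and a stage name
#'
#' All stochastic stages consume a named substream derived from one master
#' integer seed, so that reordering pipeline stages does not change the draws
#' any single stage sees.
#'
#' @param seed master integer seed.
#' @param name character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}
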