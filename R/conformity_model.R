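#' Boyd-Richerson conformist-transmission transform
#'
#' Maps a social-information proportion `x` (fraction of demonstrator
#' activity at the black feeder) to the centred social-information term
#' \deqn{f(x) = x + c\,x(1-x)(2x-1) - 0.5.}
#' The cubic vanishes at `x` = 0, 1/2, 1, so `f(0) = -0.5`, `f(0.5) = 0`
#' and `f(1) = 0.5` for every `shape`. Positive `shape` bends the response
#' into the sigmoid characteristic of conformity (disproportionate copying
#' of the majority); negative `shape` gives an anti-conformist response;
#' `shape = 0` reduces to the linear term `x - 0.5`. The transform is odd
#' about `x = 0.5`: `f(1 - x) = -f(x)`.
#'
#' The transform is deliberately not clipped to \[-0.5, 0.5\]: for
#' |shape| > 1 it exits that interval, and the model places no constraint
#' on the shape parameter.
#'
#' @param x numeric vector of proportions in \[0, 1\].
#' @param shape conformity shape parameter (the model's `c`).
#' @return Numeric vector, same length as `x` (recycled against `shape`).
#' @export
conformity_transform <- function(x, shape) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("proportion outside [0, 1]")
  }
  x - 0.5 + shape * x * (1 - x) * (2 * x - 1)
}

#' Model parameters for the conformist choice model
#'
#' The model's unknowns: on the logit scale, `beta1` is the baseline
#' preference for the black feeder, `beta2` the effect of the side of the
#' cage the black feeder was on, and `beta3` the coefficient of the
#' social-information term; `shape` is the conformity shape parameter
#' (written `c` in summaries), and `measure` the predictor the indicator
#' selects (`"birds"`, `"visits"` or `"pecks"`).
#'
#' @param beta1,beta2,beta3,shape finite reals.
#' @param measure one of `"birds"`, `"visits"`, `"pecks"`.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(beta1 = 0, beta2 = 0, beta3 = 0, shape = 0,
                             measure = c("birds", "visits", "pecks")) {
  measure <- match.arg(measure)
  vals <- c(beta1, beta2, beta3, shape)
  if (!all(is.finite(vals))) stop("parameters must be finite")
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 shape = shape, measure = measure),
            class = "model_parameters")
}

#' Prior specification
#'
#' Independent normal priors on `beta1..3` and `shape`, parameterized by
#' precision (stored as given; the implied standard deviation is
#' `1/sqrt(precision)`, i.e. sqrt(10) at the default precision 0.1), and a
#' categorical prior over the three predictor indicators.
#'
#' @param mean prior mean (default 0).
#' @param precision prior precision (> 0, default 0.1).
#' @param indicator_probs probabilities over (birds, visits, pecks);
#'   must sum to 1 (default uniform).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mean = 0, precision = 0.1,
                       indicator_probs = c(1, 1, 1) / 3) {
  stopifnot(precision > 0, length(indicator_probs) == 3,
            all(indicator_probs >= 0),
            abs(sum(indicator_probs) - 1) < 1e-8)
  structure(list(mean = mean, precision = precision,
                 sd = 1 / sqrt(precision),
                 indicator_probs = indicator_probs),
            class = "prior_spec")
}

#' Probability that the observer's first peck is at the black feeder
#'
#' Computes `plogis(beta1 + beta2 * black_side + beta3 * f(X))` per trial,
#' where `X` is the proportion for the measure selected by
#' `params$measure` and `f` is [conformity_transform()].
#'
#' @param params [model_parameters()].
#' @param trials trial table; every trial must have nonzero total for the
#'   selected measure.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
choice_probability <- function(params, trials) {
  x <- trial_proportion(trials, params$measure)
  eta <- params$beta1 + params$beta2 * trials$black_side +
    params$beta3 * conformity_transform(x, params$shape)
  plogis(eta)
}

# Stable log(1 + exp(eta)); tolerates |eta| up to ~700.
log1pexp <- function(eta) {
  ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
}

#' Bernoulli log-likelihood of a trial table
#'
#' Sum over trials of `y log p + (1 - y) log(1 - p)` with `p` from
#' [choice_probability()], computed on the logit scale so it stays finite
#' for extreme linear predictors.
#'
#' @inheritParams choice_probability
#' @return A single finite number.
#' @export
log_likelihood <- function(params, trials) {
  if (nrow(trials) == 0) stop("empty trial table")
  x <- trial_proportion(trials, params$measure)
  eta <- params$beta1 + params$beta2 * trials$black_side +
    params$beta3 * conformity_transform(x, params$shape)
  y <- trials$observer_first_peck_black
  sum(y * eta - log1pexp(eta))
}

#' Log prior density
#'
#' Sum of normal log-densities for `beta1..3` and `shape` (mean
#' `prior$mean`, sd `1/sqrt(prior$precision)`), plus the log indicator
#' probability of `params$measure`.
#'
#' @param params [model_parameters()].
#' @param prior [prior_spec()].
#' @return A single number.
#' @export
log_prior <- function(params, prior = prior_spec()) {
  stopifnot(inherits(prior, "prior_spec"))
  k <- match(params$measure, MEASURES)
  sum(dnorm(c(params$beta1, params$beta2, params$beta3, params$shape),
            mean = prior$mean, sd = prior$sd, log = TRUE)) +
    log(prior$indicator_probs[k])
}

#' Unnormalized log posterior
#'
#' `log_likelihood(params, trials) + log_prior(params, prior)`; the
#' quantity targeted by the sampler and by grid-quadrature cross-checks.
#'
#' @inheritParams log_likelihood
#' @param prior [prior_spec()].
#' @return A single number.
#' @export
log_posterior_unnorm <- function(params, trials, prior = prior_spec()) {
  log_likelihood(params, trials) + log_prior(params, prior)
}
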