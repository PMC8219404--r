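#' MCMC configuration
#'
#' @param n_chains number of chains (>= 2 so convergence diagnostics are
#'   defined; default 3).
#' @param n_iter iterations per chain including burn-in (default 50000).
#' @param n_burn burn-in iterations discarded per chain (default 10000).
#' @param thin retain every `thin`-th post-burn-in draw (default 1).
#' @param scales initial random-walk proposal standard deviations, one per
#'   continuous parameter (recycled; default 0.5).
#' @param adapt tune proposal scales during burn-in toward acceptance in
#'   \[0.2, 0.5\]; scales are frozen after burn-in (default `TRUE`).
#' @param seed integer master seed; chain `i` runs under
#'   `set.seed(seed + i - 1)`.
#' @param target_min_ess minimum effective sample size (summed across
#'   chains) required of every sampled continuous parameter before a run
#'   is summarized (default 3000). If unmet, the run length is doubled
#'   and the chains re-run (same seeds) until met or `max_extend` times
#'   the original length is reached.
#' @param rhat_upper_max maximum allowed upper confidence bound of the
#'   Gelman-Rubin diagnostic (default 1.01).
#' @param max_extend cap on run-length extension, as a multiple of
#'   `n_iter` (default 10).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 50000, n_burn = 10000,
                        thin = 1, scales = 0.5, adapt = TRUE, seed = 1,
                        target_min_ess = 3000, rhat_upper_max = 1.01,
                        max_extend = 10) {
  stopifnot(n_chains >= 1, n_iter > n_burn, n_burn >= 0, thin >= 1,
            all(scales > 0), max_extend >= 1)
  seed <- as.integer(seed)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
                 thin = thin, scales = scales, adapt = adapt, seed = seed,
                 target_min_ess = target_min_ess,
                 rhat_upper_max = rhat_upper_max, max_extend = max_extend),
            class = "mcmc_config")
}

# Assemble the n x 3 matrix of social-information proportions.
# Unused NA entries (zero activity on a measure not in play) are filled
# with 0.5 so the C++ kernel never touches NaN; callers must ensure the
# measures actually in play have no NA rows.
social_matrix <- function(trials) {
  X <- cbind(birds = trial_proportion(trials, "birds", strict = FALSE),
             visits = trial_proportion(trials, "visits", strict = FALSE),
             pecks = trial_proportion(trials, "pecks", strict = FALSE))
  X
}

#' Draw posterior samples by Metropolis-within-Gibbs
#'
#' Runs `config$n_chains` chains of the conformist choice model. Each
#' iteration makes random-walk Metropolis updates of the continuous
#' parameters (beta1, beta2, beta3, shape `c`), then — unless the
#' indicator is fixed — draws the predictor indicator `m` from its
#' closed-form full conditional, `P(m = k)` proportional to the indicator
#' prior times the likelihood under predictor `k`. With an empty trial
#' table the sampler targets the prior (useful for prior-recovery
#' checks).
#'
#' In the pair model (`pair` given) there is no indicator: the linear
#' predictor has two social-information terms, each with its own
#' coefficient and its own shape parameter, both under the same normal
#' prior.
#'
#' Trials with zero total on a measure in play are excluded with a
#' message when the indicator is fixed; with a free indicator (or a pair
#' model) all measures are in play and such trials raise an error.
#'
#' Runs are exactly reproducible: identical inputs and seed give
#' bit-identical chains.
#'
#' @param trials trial table (may have zero rows).
#' @param prior [prior_spec()].
#' @param config [mcmc_config()].
#' @param fixed_measure optional `"birds"`, `"visits"` or `"pecks"`: pin
#'   the indicator to that predictor.
#' @param pin optional named list pinning continuous parameters at fixed
#'   values (names among `beta1`, `beta2`, `beta3`, `c`), e.g.
#'   `list(beta2 = 0, c = 0)`; pinned parameters are not updated.
#' @param pair optional character vector of two distinct measures
#'   selecting the two-term pair model (no indicator).
#' @return An object of class `freqdep_chains`: a list with `draws` (one
#'   matrix per chain, columns named as in the draws CSV), `acceptance`,
#'   `scales`, `model`, `fixed_measure`, `pair`, `pinned`, `config` (with
#'   the realized `n_iter` after any extension), and `n_trials`.
#' @export
sample_posterior <- function(trials, prior = prior_spec(),
                             config = mcmc_config(), fixed_measure = NULL,
                             pin = NULL, pair = NULL) {
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "mcmc_config"))
  if (nrow(trials) > 0) validate_trials(trials)

  model <- if (is.null(pair)) "indicator" else "pair"
  if (model == "pair") {
    pair <- match.arg(pair, MEASURES, several.ok = TRUE)
    if (length(pair) != 2 || pair[1] == pair[2]) {
      stop("`pair` must name two distinct measures")
    }
    if (!is.null(fixed_measure)) stop("`fixed_measure` does not apply to the pair model")
  }
  fixed_m <- 0L
  if (!is.null(fixed_measure)) {
    fixed_m <- measure_index(fixed_measure)
  }

  if (nrow(trials) == 0) {
    message("empty trial table: sampling from the prior")
    y <- numeric(0); side <- numeric(0)
    X <- matrix(numeric(0), nrow = 0, ncol = 3)
  } else {
    X <- social_matrix(trials)
    in_play <- if (model == "pair") pair else if (fixed_m > 0) MEASURES[fixed_m] else MEASURES
    usable <- rep(TRUE, nrow(trials))
    for (msr in in_play) usable <- usable & !is.na(X[, msr])
    if (!all(usable)) {
      if (fixed_m > 0 && model == "indicator") {
        message("excluding ", sum(!usable), " trial(s) with zero ",
                MEASURES[fixed_m], " activity: ",
                paste(trials$trial_id[!usable], collapse = ", "))
        trials <- trials[usable, , drop = FALSE]
        if (nrow(trials) == 0) stop("no analysable trials remain")
        X <- social_matrix(trials)
      } else {
        stop("trial(s) unanalysable under a measure in play: ",
             paste(trials$trial_id[!usable], collapse = ", "))
      }
    }
    X[is.na(X)] <- 0.5
    y <- as.numeric(trials$observer_first_peck_black)
    side <- as.numeric(trials$black_side)
    if (length(unique(y)) == 1) {
      message("all observer outcomes identical (", y[1], "); fitting anyway")
    }
  }

  if (model == "indicator") {
    par_names <- c("beta1", "beta2", "beta3", "c")
    term_cols <- 2L  # unused in indicator mode
  } else {
    par_names <- c("beta1", "beta2",
                   paste0("beta3_", pair[1]), paste0("c_", pair[1]),
                   paste0("beta3_", pair[2]), paste0("c_", pair[2]))
    term_cols <- match(pair, MEASURES) - 1L
  }
  P <- length(par_names)

  update <- rep(TRUE, P)
  pin_vals <- rep(NA_real_, P)
  if (!is.null(pin)) {
    if (is.null(names(pin)) || !all(names(pin) %in% par_names)) {
      stop("`pin` names must be among: ", paste(par_names, collapse = ", "))
    }
    idx <- match(names(pin), par_names)
    update[idx] <- FALSE
    pin_vals[idx] <- as.numeric(unlist(pin))
  }

  scales <- rep(config$scales, length.out = P)
  run_all <- function(n_iter, n_burn) {
    lapply(seq_len(config$n_chains), function(ch) {
      set.seed(config$seed + ch - 1L)
      init <- rnorm(P, mean = prior$mean, sd = 1)
      init[!update] <- pin_vals[!update]
      run_chain_cpp(y, side, X, term_cols, model == "indicator", fixed_m,
                    log(prior$indicator_probs), prior$mean, prior$precision,
                    as.integer(n_iter), as.integer(n_burn),
                    as.integer(config$thin), init, scales, update,
                    config$adapt)
    })
  }

  n_iter <- config$n_iter
  repeat {
    raw <- run_all(n_iter, config$n_burn)
    draws <- lapply(raw, function(r) {
      d <- r$draws
      colnames(d) <- c(par_names, "m")
      d
    })
    sampled <- par_names[update]
    min_ess <- min(vapply(sampled, function(p) {
      ess_sum(lapply(draws, function(d) d[, p]))
    }, numeric(1)))
    if (is.na(config$target_min_ess) || min_ess >= config$target_min_ess ||
        2 * n_iter > config$max_extend * config$n_iter) {
      break
    }
    n_iter <- 2 * n_iter
  }

  realized <- config
  realized$n_iter <- n_iter
  structure(list(
    draws = draws,
    acceptance = lapply(raw, function(r) {
      a <- r$acceptance
      names(a) <- par_names
      a
    }),
    scales = lapply(raw, function(r) {
      s <- r$scales
      names(s) <- par_names
      s
    }),
    model = model, fixed_measure = fixed_measure, pair = pair,
    pinned = if (is.null(pin)) character(0) else names(pin),
    par_names = par_names, sampled = par_names[update],
    config = realized, n_trials = length(y)
  ), class = "freqdep_chains")
}

#' Construct a chains object from raw draw matrices
#'
#' Wraps pre-computed per-chain draw matrices in the container the
#' diagnostic and summary functions expect. Intended for testing the
#' convergence machinery on synthetic chains.
#'
#' @param draws list of numeric matrices (one per chain, equal
#'   dimensions, identical column names). A column named `m` is treated
#'   as the indicator; all other columns as continuous parameters.
#' @param config [mcmc_config()] supplying the gating thresholds.
#' @return A `freqdep_chains` object.
#' @export
chains_from_draws <- function(draws, config = mcmc_config()) {
  stopifnot(is.list(draws), length(draws) >= 1,
            !is.null(colnames(draws[[1]])))
  cn <- colnames(draws[[1]])
  par_names <- setdiff(cn, "m")
  if (!("m" %in% cn)) {
    draws <- lapply(draws, function(d) cbind(d, m = NA_real_))
  }
  structure(list(draws = draws, acceptance = NULL, scales = NULL,
                 model = "indicator", fixed_measure = NULL, pair = NULL,
                 pinned = character(0), par_names = par_names,
                 sampled = par_names, config = config,
                 n_trials = NA_integer_),
            class = "freqdep_chains")
}

#' @export
print.freqdep_chains <- function(x, ...) {
  kept <- nrow(x$draws[[1]])
  cat("freqdep_chains:", length(x$draws), "chain(s) x", kept,
      "retained draws;", x$model, "model")
  if (!is.null(x$fixed_measure)) cat(" (fixed measure:", x$fixed_measure, ")")
  if (!is.null(x$pair)) cat(" (pair:", paste(x$pair, collapse = "+"), ")")
  cat("\nparameters:", paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

# Pooled draws across chains as one matrix.
pooled_draws <- function(chains) {
  do.call(rbind, chains$draws)
}
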