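# Analysis front-ends: fixed-indicator fits of each predictor, the joint
# indicator-selection fit, two-predictor pair fits, collinearity
# reporting, frequency-response curves, and the parameter-recovery
# harness.

fit_common <- function(trials, prior, config, override, ...) {
  if (nrow(trials) == 0) stop("cannot fit an empty trial table")
  validate_trials(trials)
  chains <- sample_posterior(trials, prior = prior, config = config, ...)
  out <- summarize_chains(chains, override = override)
  out$chains <- chains
  out
}

#' Fit the model with the predictor indicator fixed
#'
#' Tests the effect of one predictor (`birds`, `visits` or `pecks`) on
#' its own by pinning the indicator to it. Trials with zero activity on
#' that measure are excluded with a message.
#'
#' @param trials trial table.
#' @param measure the predictor to fix.
#' @param prior [prior_spec()].
#' @param config [mcmc_config()].
#' @param override summarize even if convergence gating fails.
#' @return A `posterior_summary` with the chains attached as `$chains`.
#' @export
fit_fixed <- function(trials, measure = c("birds", "visits", "pecks"),
                      prior = prior_spec(), config = mcmc_config(),
                      override = FALSE) {
  measure <- match.arg(measure)
  fit_common(trials, prior, config, override, fixed_measure = measure)
}

#' Fit the joint indicator-selection model
#'
#' The categorical indicator chooses among the three predictors each
#' iteration; its posterior weights measure the predictors' relative
#' predictive power. All trials must be analysable under all three
#' measures.
#'
#' @inheritParams fit_fixed
#' @return A `posterior_summary` (with indicator `weights`) and chains.
#' @export
fit_joint <- function(trials, prior = prior_spec(), config = mcmc_config(),
                      override = FALSE) {
  fit_common(trials, prior, config, override)
}

#' Fit a two-predictor pair model
#'
#' Includes two social-information terms at once (e.g. birds and pecks),
#' each with its own coefficient and its own shape parameter, both under
#' the standard prior; there is no indicator.
#'
#' @inheritParams fit_fixed
#' @param pair character vector of two distinct measures.
#' @return A `posterior_summary` and chains.
#' @export
fit_pair <- function(trials, pair = c("birds", "pecks"),
                     prior = prior_spec(), config = mcmc_config(),
                     override = FALSE) {
  fit_common(trials, prior, config, override, pair = pair)
}

#' Pairwise correlations among the three social predictors
#'
#' Pearson correlations of the birds, visits and pecks proportions across
#' trials; the standard check for the multicollinearity that motivates
#' indicator-based selection over a single joint regression. Trials with
#' an undefined proportion are dropped pairwise; a constant column yields
#' `NA` entries with a warning.
#'
#' @param trials trial table with at least 3 analysable trials.
#' @return A 3x3 symmetric correlation matrix.
#' @export
collinearity_report <- function(trials) {
  validate_trials(trials)
  props <- social_matrix(trials)
  if (sum(stats::complete.cases(props)) < 3) {
    stop("need at least 3 trials analysable under all measures")
  }
  const <- apply(props, 2, function(x) var(x, na.rm = TRUE) == 0)
  if (any(const)) {
    warning("constant predictor column(s): ",
            paste(names(const)[const], collapse = ", "),
            "; correlations undefined (NA)")
  }
  suppressWarnings(cor(props, use = "pairwise.complete.obs"))
}

#' Posterior frequency-response curve
#'
#' For each grid value of the social-information proportion X, computes
#' the per-draw choice probability and returns the pooled median and 95%
#' central credible interval. The side-of-cage covariate is marginalized
#' by averaging the curve over both side values. For free-indicator
#' chains, draws are restricted to iterations where the indicator equals
#' the requested measure (the conditional posterior given that
#' predictor).
#'
#' @param chains a `freqdep_chains` object from an indicator-model run.
#' @param measure measure whose draws to use (required for
#'   free-indicator chains; for fixed-indicator chains defaults to the
#'   fixed measure).
#' @param grid X values in \[0, 1\] (default 101 equally spaced points).
#' @param max_draws cap on the number of draws used, taken as an evenly
#'   spaced (deterministic) subsample (default 4000).
#' @return data.frame of class `response_curve`: `x`, `median`, `lower`,
#'   `upper`.
#' @export
response_curve <- function(chains, measure = NULL,
                           grid = seq(0, 1, length.out = 101),
                           max_draws = 4000) {
  stopifnot(inherits(chains, "freqdep_chains"))
  if (chains$model != "indicator") {
    stop("response curves are defined for indicator-model chains")
  }
  if (any(grid < 0 | grid > 1)) stop("grid must lie in [0, 1]")
  pooled <- pooled_draws(chains)
  if (is.null(measure)) {
    if (is.null(chains$fixed_measure)) {
      stop("`measure` is required for free-indicator chains")
    }
    measure <- chains$fixed_measure
  }
  k <- measure_index(measure)
  if (is.null(chains$fixed_measure) && !all(is.na(pooled[, "m"]))) {
    pooled <- pooled[pooled[, "m"] == k, , drop = FALSE]
    if (nrow(pooled) < 100) {
      stop("fewer than 100 draws have m = ", measure,
           "; indicator weight too small for a stable curve")
    }
  }
  if (nrow(pooled) > max_draws) {
    idx <- round(seq(1, nrow(pooled), length.out = max_draws))
    pooled <- pooled[idx, , drop = FALSE]
  }
  f <- outer(pooled[, "c"], grid,
             function(cc, x) x - 0.5 + cc * x * (1 - x) * (2 * x - 1))
  eta0 <- pooled[, "beta1"] + pooled[, "beta3"] * f
  p <- (plogis(eta0) + plogis(eta0 + pooled[, "beta2"])) / 2
  qs <- apply(p, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  structure(data.frame(x = grid, median = qs[2, ], lower = qs[1, ],
                       upper = qs[3, ]),
            class = c("response_curve", "data.frame"))
}

#' Parameter-recovery experiment
#'
#' The validation loop for the whole inference chain: simulate a dataset
#' from a known truth, fit it, and score the fit against the truth,
#' repeated over seeded replicates. Per continuous parameter it reports
#' the mean bias of the posterior median, the fraction of replicates
#' whose 95% CCI covers the true value, and the fraction recovering the
#' true sign; for joint fits, the fraction of replicates in which the
#' true predictor gets the largest indicator weight. Convergence
#' failures are recorded per replicate, not fatal.
#'
#' @param truth a [simulation_truth()].
#' @param n_replicates number of replicates (>= 2).
#' @param config [mcmc_config()] used for each fit (its `seed` is
#'   overridden per replicate).
#' @param mode `"fixed"` (fit with the indicator pinned to the true
#'   measure) or `"joint"` (free indicator).
#' @param master_seed master seed; replicate `i` uses
#'   `master_seed + 7 * i` for both simulation and fitting.
#' @return An object of class `recovery_report`: list with `table`
#'   (parameter, true, bias, coverage, sign_rate), `selection_rate`,
#'   `n_replicates`, `n_converged`, `master_seed`, `mode`.
#' @export
recovery_experiment <- function(truth, n_replicates, config = mcmc_config(),
                                mode = c("fixed", "joint"),
                                master_seed = config$seed) {
  stopifnot(inherits(truth, "simulation_truth"), n_replicates >= 2)
  mode <- match.arg(mode)
  master_seed <- as.integer(master_seed)
  true_vals <- c(beta1 = truth$params$beta1, beta2 = truth$params$beta2,
                 beta3 = truth$params$beta3, c = truth$params$shape)
  k_true <- match(truth$params$measure, MEASURES)

  med <- cov_hit <- sign_hit <- matrix(NA_real_, n_replicates, 4,
                                       dimnames = list(NULL, names(true_vals)))
  selected <- rep(NA, n_replicates)
  converged <- rep(NA, n_replicates)

  for (i in seq_len(n_replicates)) {
    seed_i <- master_seed + 7L * i
    sim <- simulate_dataset(truth$design, truth$activity, truth$params,
                            seed = seed_i)
    cfg <- config
    cfg$seed <- seed_i
    fit <- if (mode == "fixed") {
      fit_fixed(sim$trials, truth$params$measure, config = cfg,
                override = TRUE)
    } else {
      fit_joint(sim$trials, config = cfg, override = TRUE)
    }
    converged[i] <- fit$convergence$pass
    tab <- fit$table
    for (p in names(true_vals)) {
      row <- tab[tab$parameter == p, ]
      med[i, p] <- row$median
      cov_hit[i, p] <- row$lower <= true_vals[p] && true_vals[p] <= row$upper
      sign_hit[i, p] <- if (true_vals[p] == 0) NA else
        sign(row$median) == sign(true_vals[p])
    }
    if (mode == "joint" && !is.null(fit$weights)) {
      selected[i] <- which.max(fit$weights) == k_true
    }
  }

  table <- data.frame(
    parameter = names(true_vals),
    true = unname(true_vals),
    bias = colMeans(med) - true_vals,
    coverage = colMeans(cov_hit),
    sign_rate = colMeans(sign_hit)  # NA where the true value is 0
  )
  rownames(table) <- NULL
  structure(list(table = table,
                 selection_rate = if (all(is.na(selected))) NA_real_ else
                   mean(selected, na.rm = TRUE),
                 n_replicates = n_replicates,
                 n_converged = sum(converged),
                 master_seed = master_seed, mode = mode),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("parameter recovery (", x$mode, " fits, ", x$n_replicates,
      " replicates, ", x$n_converged, " converged)\n", sep = "")
  tab <- x$table
  tab$bias <- round(tab$bias, 3)
  print(tab, row.names = FALSE)
  if (!is.na(x$selection_rate)) {
    cat("true-predictor selection rate:", round(x$selection_rate, 3), "\n")
  }
  invisible(x)
}
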