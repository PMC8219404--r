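# Posterior summaries in the reporting convention of the analysis:
# pooled-chain median and 95% central credible interval per parameter,
# posterior weight per indicator category.

#' Summarize posterior chains
#'
#' Pools draws across chains and reports, per continuous parameter, the
#' median and the 95% central credible interval (2.5% and 97.5% quantiles
#' with linear interpolation between order statistics), and for the
#' indicator the posterior weight of each predictor (fraction of pooled
#' draws). Summaries are refused when the run fails its convergence
#' gates — minimum effective sample size and Gelman-Rubin upper bound —
#' unless `override = TRUE`; the refusal carries the
#' [convergence_report()].
#'
#' @param chains a `freqdep_chains` object.
#' @param override summarize even if convergence gating fails.
#' @param label optional model label stored in the summary.
#' @return An object of class `posterior_summary`: list with `table`
#'   (parameter, median, lower, upper), `weights` (3-vector or `NULL`),
#'   `convergence`, `label`, `n_trials`.
#' @export
summarize_chains <- function(chains, override = FALSE, label = NULL) {
  stopifnot(inherits(chains, "freqdep_chains"))
  report <- convergence_report(chains)
  if (!report$pass && !override) {
    stop(structure(class = c("freqdep_convergence_error", "error",
                             "condition"),
                   list(message = paste0(
                     "refusing to summarize: convergence gates not met ",
                     "(min ESS ", round(min(report$table$ess)),
                     " vs target ", report$target_min_ess,
                     "; max R-hat upper ",
                     format(max(report$table$rhat_upper), digits = 4),
                     " vs limit ", report$rhat_upper_max,
                     "). Pass override = TRUE to summarize anyway."),
                     call = sys.call(-1), report = report)))
  }
  pooled <- pooled_draws(chains)
  pars <- chains$par_names
  tab <- do.call(rbind, lapply(pars, function(p) {
    x <- pooled[, p]
    q <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    data.frame(parameter = p, median = q[2], lower = q[1], upper = q[3])
  }))
  rownames(tab) <- NULL
  weights <- NULL
  if (chains$model == "indicator" && !all(is.na(pooled[, "m"]))) {
    weights <- vapply(1:3, function(k) mean(pooled[, "m"] == k), numeric(1))
    names(weights) <- MEASURES
  }
  if (is.null(label)) {
    label <- if (chains$model == "pair") {
      paste0("pair:", paste(chains$pair, collapse = "+"))
    } else if (!is.null(chains$fixed_measure)) {
      paste0("fixed:", chains$fixed_measure)
    } else "joint"
  }
  structure(list(table = tab, weights = weights, convergence = report,
                 label = label, n_trials = chains$n_trials),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, digits = 2, ...) {
  cat("posterior summary [", x$label, "], ",
      if (is.na(x$n_trials)) "?" else x$n_trials, " trials\n", sep = "")
  tab <- x$table
  tab$median <- round(tab$median, digits)
  tab$lower <- round(tab$lower, digits)
  tab$upper <- round(tab$upper, digits)
  tab$`95% CCI` <- sprintf("[%.*f, %.*f]", digits, tab$lower, digits,
                           tab$upper)
  print(tab[, c("parameter", "median", "95% CCI")], row.names = FALSE)
  if (!is.null(x$weights)) {
    cat("indicator weights:",
        paste(sprintf("%s %.2f", names(x$weights), x$weights),
              collapse = ", "), "\n")
  }
  cat("convergence:", if (x$convergence$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Write chains to a columnar draws CSV
#'
#' Columns: `chain`, `iteration`, then one column per parameter (the
#' shape parameter is written as `c`; the indicator as `m`, empty for
#' pair models). Full precision is preserved (15 significant digits), so
#' a round trip through [read_draws()] reproduces the draws.
#'
#' @param chains a `freqdep_chains` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(chains, path) {
  stopifnot(inherits(chains, "freqdep_chains"))
  tabs <- lapply(seq_along(chains$draws), function(ch) {
    d <- chains$draws[[ch]]
    data.frame(chain = ch, iteration = seq_len(nrow(d)), d,
               check.names = FALSE)
  })
  out <- do.call(rbind, tabs)
  num <- setdiff(names(out), c("chain", "iteration", "m"))
  for (col in num) out[[col]] <- formatC(out[[col]], digits = 15,
                                         format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a draws CSV back into a chains object
#'
#' @param path file written by [write_draws()].
#' @param config [mcmc_config()] supplying gating thresholds for
#'   downstream summaries.
#' @return A `freqdep_chains` object.
#' @export
read_draws <- function(path, config = mcmc_config()) {
  tab <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("chain", "iteration") %in% names(tab)))
  pars <- setdiff(names(tab), c("chain", "iteration"))
  draws <- lapply(sort(unique(tab$chain)), function(ch) {
    d <- as.matrix(tab[tab$chain == ch, pars, drop = FALSE])
    rownames(d) <- NULL
    d
  })
  ch <- chains_from_draws(draws, config = config)
  m_all <- unlist(lapply(ch$draws, function(d) d[, "m"]))
  if (all(is.na(m_all))) {
    ch$model <- "pair"
  } else if (length(unique(m_all)) == 1) {
    ch$fixed_measure <- MEASURES[m_all[1]]
  }
  ch
}

#' Write a posterior summary as JSON
#'
#' Serializes the summary table, indicator weights and convergence report
#' with full numeric precision.
#'
#' @param summary a `posterior_summary` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "posterior_summary"))
  out <- list(label = summary$label, n_trials = summary$n_trials,
              parameters = summary$table,
              weights = as.list(summary$weights),
              convergence = list(pass = summary$convergence$pass,
                                 table = summary$convergence$table))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
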