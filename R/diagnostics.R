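# Convergence diagnostics: Gelman-Rubin potential scale reduction factor
# and autocorrelation-based effective sample size.

# Extract one parameter's per-chain draws as a list of numeric vectors.
chain_vectors <- function(chains, parameter) {
  if (inherits(chains, "freqdep_chains")) {
    if (!(parameter %in% colnames(chains$draws[[1]]))) {
      stop("unknown parameter: ", parameter)
    }
    lapply(chains$draws, function(d) as.numeric(d[, parameter]))
  } else if (is.list(chains)) {
    lapply(chains, as.numeric)
  } else {
    stop("`chains` must be a freqdep_chains object or a list of vectors")
  }
}

# Core PSRF on a list of equal-length chains: classic between/within
# variance construction with the F-distribution upper confidence bound.
psrf_core <- function(xs, conf = 0.95) {
  m <- length(xs)
  n <- length(xs[[1]])
  s2 <- vapply(xs, var, numeric(1))
  xbar <- vapply(xs, mean, numeric(1))
  W <- mean(s2)
  B <- n * var(xbar)
  if (W <= 0) {
    # all chains constant: identical chains converge trivially
    return(c(point = 1, upper = 1))
  }
  muhat <- mean(xbar)
  var_w <- var(s2) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (cov(s2, xbar^2) - 2 * muhat * cov(s2, xbar))
  V <- (n - 1) / n * W + (1 + 1 / m) * B / n
  var_V <- ((n - 1)^2 * var_w + (1 + 1 / m)^2 * var_b +
              2 * (n - 1) * (1 + 1 / m) * cov_wb) / n^2
  df_adj <- if (var_V <= 0) 1 else {
    df_V <- 2 * V^2 / var_V
    (df_V + 3) / (df_V + 1)
  }
  R2_fixed <- (n - 1) / n
  R2_random <- (1 + 1 / m) * (1 / n) * (B / W)
  point <- sqrt(df_adj * (R2_fixed + R2_random))
  df_w <- if (var_w <= 0) Inf else 2 * W^2 / var_w
  upper <- sqrt(df_adj * (R2_fixed +
                            qf((1 + conf) / 2, m - 1, df_w) * R2_random))
  c(point = point, upper = upper)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor with its upper confidence bound, from
#' the classic between/within-chain variance construction. By default each
#' chain is split in half (split-R-hat), so within-chain drift also
#' inflates the statistic; the run is judged converged when the upper
#' bound does not exceed the configured threshold (1.01 by default).
#'
#' @param chains a `freqdep_chains` object or a list of equal-length
#'   numeric vectors (one per chain; at least two chains required).
#' @param parameter parameter name when `chains` is a `freqdep_chains`
#'   object.
#' @param split halve each chain before computing (default `TRUE`).
#' @param conf confidence level of the upper bound (default 0.95).
#' @return Named numeric vector `c(point, upper)`.
#' @export
gelman_rubin <- function(chains, parameter = NULL, split = TRUE,
                         conf = 0.95) {
  xs <- chain_vectors(chains, parameter)
  if (length(xs) < 2) stop("Gelman-Rubin diagnostic needs at least 2 chains")
  n <- unique(lengths(xs))
  if (length(n) != 1) stop("chains must have equal retained lengths")
  if (split) {
    half <- floor(n / 2)
    xs <- c(lapply(xs, function(x) x[seq_len(half)]),
            lapply(xs, function(x) x[seq.int(n - half + 1, n)]))
  }
  psrf_core(xs, conf = conf)
}

# ESS of a single chain: integrated autocorrelation time estimated with
# Geyer's initial positive sequence over paired autocorrelations.
ess_one <- function(x, lag_max = NULL) {
  n <- length(x)
  if (n < 4 || !is.finite(var(x)) || var(x) <= 0) {
    warning("constant or too-short chain: ESS reported as 0")
    return(0)
  }
  if (is.null(lag_max)) lag_max <- min(n - 1, 1000)
  rho <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)
  # pair consecutive autocorrelations (rho_0 + rho_1, rho_2 + rho_3, ...)
  n_pairs <- floor(length(rho) / 2)
  gamma <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  pos <- which(gamma <= 0)
  keep <- if (length(pos) == 0) n_pairs else pos[1] - 1
  tau <- -1 + 2 * sum(gamma[seq_len(keep)])
  tau <- max(tau, 1e-12)
  n / tau
}

# Sum of per-chain ESS values; xs is a list of numeric vectors.
ess_sum <- function(xs) {
  sum(vapply(xs, ess_one, numeric(1)))
}

#' Effective sample size
#'
#' Autocorrelation-adjusted count of independent-equivalent draws: per
#' chain, the chain length divided by the integrated autocorrelation time
#' (estimated with the initial-positive-sequence rule on paired
#' autocorrelations), summed across chains. A constant chain yields 0
#' with a warning.
#'
#' @inheritParams gelman_rubin
#' @return A single non-negative number.
#' @export
effective_sample_size <- function(chains, parameter = NULL) {
  ess_sum(chain_vectors(chains, parameter))
}

#' Convergence report for a sampled run
#'
#' Per continuous sampled parameter: split-R-hat point estimate and upper
#' confidence bound, and effective sample size summed across chains. The
#' run passes when every ESS reaches `config$target_min_ess` and every
#' R-hat upper bound is at most `config$rhat_upper_max`. For free-
#' indicator runs the per-chain indicator weights and their largest
#' between-chain discrepancy are reported as a stability check (not
#' gated).
#'
#' @param chains a `freqdep_chains` object.
#' @return An object of class `convergence_report`: list with `table`
#'   (data.frame: parameter, rhat, rhat_upper, ess), `pass`,
#'   `target_min_ess`, `rhat_upper_max`, and optionally `chain_weights`
#'   and `max_weight_gap`.
#' @export
convergence_report <- function(chains) {
  stopifnot(inherits(chains, "freqdep_chains"))
  pars <- chains$sampled
  tab <- do.call(rbind, lapply(pars, function(p) {
    gr <- if (length(chains$draws) >= 2) gelman_rubin(chains, p) else
      c(point = NA_real_, upper = NA_real_)
    data.frame(parameter = p, rhat = gr[["point"]],
               rhat_upper = gr[["upper"]],
               ess = effective_sample_size(chains, p))
  }))
  rownames(tab) <- NULL
  cfg <- chains$config
  pass <- all(tab$ess >= cfg$target_min_ess) &&
    all(is.na(tab$rhat_upper) | tab$rhat_upper <= cfg$rhat_upper_max)
  rep <- list(table = tab, pass = pass,
              target_min_ess = cfg$target_min_ess,
              rhat_upper_max = cfg$rhat_upper_max)
  if (chains$model == "indicator" && is.null(chains$fixed_measure) &&
      !all(is.na(chains$draws[[1]][, "m"]))) {
    w <- t(vapply(chains$draws, function(d) {
      vapply(1:3, function(k) mean(d[, "m"] == k), numeric(1))
    }, numeric(3)))
    colnames(w) <- MEASURES
    rep$chain_weights <- w
    rep$max_weight_gap <- max(apply(w, 2, function(col) diff(range(col))))
  }
  structure(rep, class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence report (target ESS >=", x$target_min_ess,
      ", R-hat upper <=", x$rhat_upper_max, "):",
      if (x$pass) "PASS" else "FAIL", "\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$max_weight_gap)) {
    cat("max between-chain indicator-weight gap:",
        format(x$max_weight_gap, digits = 3), "\n")
  }
  invisible(x)
}
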