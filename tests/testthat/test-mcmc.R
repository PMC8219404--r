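test_that("identical inputs and seed give bit-identical chains", {
  tab <- toy5()
  cfg <- small_config()
  a <- sample_posterior(tab, config = cfg, fixed_measure = "pecks")
  b <- sample_posterior(tab, config = cfg, fixed_measure = "pecks")
  expect_identical(a$draws, b$draws)
  c <- sample_posterior(tab, config = small_config(seed = 100),
                        fixed_measure = "pecks")
  expect_false(identical(a$draws, c$draws))
})

test_that("sampler reproduces a standard normal stub target", {
  # no data + unit-precision prior + all other parameters pinned gives a
  # 1-d standard normal target for the symmetric random-walk kernel
  cfg <- mcmc_config(n_chains = 3, n_iter = 10000, n_burn = 2000,
                     seed = 4, target_min_ess = 0)
  ch <- suppressMessages(sample_posterior(
    empty_trials(), prior = prior_spec(precision = 1), config = cfg,
    fixed_measure = "pecks", pin = list(beta2 = 0, beta3 = 0, c = 0)))
  x <- do.call(rbind, ch$draws)[, "beta1"]
  expect_equal(mean(x), 0, tolerance = 0.06)
  expect_equal(sd(x), 1, tolerance = 0.05)
  expect_lt(abs(mean(x < 1.96) - 0.975), 0.01)
})

test_that("burn-in adaptation pulls acceptance rates into the target band", {
  set.seed(5)
  tab <- make_trials(rbinom(40, 1, 0.5))
  cfg <- mcmc_config(n_chains = 2, n_iter = 8000, n_burn = 4000,
                     scales = 40, seed = 12, target_min_ess = 0)
  ch <- sample_posterior(tab, config = cfg, fixed_measure = "pecks")
  rates <- unlist(ch$acceptance)
  expect_true(all(rates > 0.1 & rates < 0.6))
})

test_that("predictors with identical data get equal indicator weights", {
  # visits and pecks columns numerically identical; birds differs
  set.seed(6)
  tab <- make_trials(rbinom(30, 1, 0.5),
                     visits_black = c(2, 8), visits_white = c(8, 2),
                     pecks_black = c(2, 8), pecks_white = c(8, 2),
                     birds_black = 3, birds_white = 3)
  cfg <- mcmc_config(n_chains = 2, n_iter = 12000, n_burn = 2000,
                     seed = 21, target_min_ess = 0)
  ch <- sample_posterior(tab, config = cfg)
  m <- do.call(rbind, ch$draws)[, "m"]
  w <- vapply(1:3, function(k) mean(m == k), numeric(1))
  expect_equal(w[2], w[3], tolerance = 0.05)
  expect_equal(sum(w), 1)
})

test_that("Gelman-Rubin diagnostic separates converged from divergent chains", {
  set.seed(8)
  x <- rnorm(2000)
  dup <- gelman_rubin(list(x, x))
  expect_equal(unname(dup["point"]), 1, tolerance = 1e-3)

  indep <- gelman_rubin(list(rnorm(5000), rnorm(5000), rnorm(5000)))
  expect_lt(indep[["point"]], 1.01)
  expect_gte(indep[["point"]], 1 - 1e-3)

  offset <- gelman_rubin(list(rnorm(2000), rnorm(2000) + 10))
  expect_gt(offset[["point"]], 1.5)
  expect_gte(offset[["upper"]], offset[["point"]])

  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")
})

test_that("Gelman-Rubin matches the reference implementation on shared input", {
  skip_if_not_installed("coda")
  set.seed(9)
  xs <- list(rnorm(1500, 0, 1), rnorm(1500, 0.05, 1.1), rnorm(1500, -0.02, 0.9))
  ours <- gelman_rubin(xs, split = FALSE)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(xs, coda::mcmc)),
                           autoburnin = FALSE, transform = FALSE)
  expect_equal(unname(ours["point"]), as.numeric(ref$psrf[1, 1]),
               tolerance = 1e-8)
  expect_equal(unname(ours["upper"]), as.numeric(ref$psrf[1, 2]),
               tolerance = 1e-8)
})

test_that("effective sample size tracks the closed-form autocorrelation answer", {
  set.seed(10)
  white <- rnorm(20000)
  expect_equal(effective_sample_size(list(white)), 20000,
               tolerance = 0.1)
  ar <- ar1_chain(40000, 0.5, seed = 11)
  # AR(1): ESS = n (1 - rho) / (1 + rho)
  expect_equal(effective_sample_size(list(ar)), 40000 * 0.5 / 1.5,
               tolerance = 0.15)
  expect_warning(ess0 <- effective_sample_size(list(rep(2, 500))),
                 "constant")
  expect_equal(ess0, 0)
})

test_that("ESS sums across chains", {
  set.seed(13)
  a <- rnorm(5000); b <- rnorm(5000)
  expect_equal(effective_sample_size(list(a, b)),
               effective_sample_size(list(a)) +
                 effective_sample_size(list(b)))
})

test_that("summaries use pooled medians and linear-interpolation quantiles", {
  d <- cbind(beta1 = as.numeric(1:5), m = rep(3, 5))
  ch <- chains_from_draws(list(d), config = mcmc_config(target_min_ess = 0))
  s <- suppressWarnings(summarize_chains(ch, override = TRUE))
  row <- s$table[s$table$parameter == "beta1", ]
  expect_equal(row$median, 3)
  expect_equal(row$lower, 1.1)
  expect_equal(row$upper, 4.9)
  expect_equal(unname(s$weights), c(0, 0, 1))
})

test_that("summaries are refused when convergence gates fail", {
  set.seed(14)
  d <- lapply(1:3, function(i) cbind(beta1 = rnorm(200), m = rep(1, 200)))
  ch <- chains_from_draws(d, config = mcmc_config())  # target ESS 3000
  expect_error(summarize_chains(ch), "refusing to summarize")
  expect_s3_class(tryCatch(summarize_chains(ch), error = identity),
                  "freqdep_convergence_error")
  s <- summarize_chains(ch, override = TRUE)
  expect_s3_class(s, "posterior_summary")
  expect_false(s$convergence$pass)
})

test_that("run length auto-extends until the ESS target is met", {
  cfg <- mcmc_config(n_chains = 2, n_iter = 1000, n_burn = 600, scales = 6,
                     seed = 31, target_min_ess = 1500, max_extend = 30)
  ch <- suppressMessages(sample_posterior(empty_trials(), config = cfg,
                                          fixed_measure = "pecks"))
  expect_gt(ch$config$n_iter, 1000)
  min_ess <- min(vapply(c("beta1", "beta2", "beta3", "c"), function(p) {
    effective_sample_size(ch, p)
  }, numeric(1)))
  expect_gte(min_ess, 1500)
})

test_that("draws survive a CSV round trip and drive identical summaries", {
  tab <- toy5()
  ch <- sample_posterior(tab, config = small_config(), fixed_measure = "pecks")
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(ch, path)
  back <- read_draws(path, config = small_config())
  expect_equal(back$draws[[1]][, "beta1"],
               unname(ch$draws[[1]][, "beta1"]))
  expect_identical(back$fixed_measure, "pecks")
  s1 <- summarize_chains(ch, override = TRUE)
  s2 <- summarize_chains(back, override = TRUE)
  expect_equal(s1$table$median, s2$table$median)
})
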