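test_that("design cells are counterbalanced to within one trial", {
  # 4 ratios x 2 colour assignments x 2 sides = 16 cells
  d16 <- generate_design(design_spec(n_trials = 16), seed = 1)
  cells <- table(d16$ratio_label, d16$black_group, d16$black_side)
  expect_true(all(cells == 1))

  d66 <- generate_design(design_spec(n_trials = 66), seed = 1)
  cells66 <- table(d66$ratio_label, d66$black_group, d66$black_side)
  expect_true(all(cells66 %in% c(4, 5)))  # 66 = 16 * 4 + 2
  expect_equal(sum(cells66), 66)
  expect_true(all(table(d66$sex) == 33))
})

test_that("design generation is deterministic under a seed", {
  a <- generate_design(design_spec(n_trials = 33), seed = 7)
  b <- generate_design(design_spec(n_trials = 33), seed = 7)
  expect_identical(a, b)
  c <- generate_design(design_spec(n_trials = 33), seed = 8)
  expect_false(identical(a, c))
})

test_that("birds proportions only take the values the ratio set implies", {
  sim <- simulate_dataset(design_spec(n_trials = 200), activity_spec(),
                          model_parameters(), seed = 3)
  props <- trial_proportion(sim$trials, "birds")
  expect_true(all(sapply(props, function(p) {
    any(abs(p - c(1/3, 2/3, 1/2, 1/6, 5/6)) < 1e-12)
  })))
})

test_that("perfect fidelity with zero count noise makes all three proportions identical", {
  skel <- generate_design(design_spec(n_trials = 40), seed = 4)
  act <- generate_activity(skel, activity_spec(fidelity = 1,
                                               count_noise = "none"),
                           seed = 5)
  birds <- act$birds_black / (act$birds_black + act$birds_white)
  visits <- act$visits_black / (act$visits_black + act$visits_white)
  pecks <- act$pecks_black / (act$pecks_black + act$pecks_white)
  expect_equal(visits, birds)
  expect_equal(pecks, birds)
})

test_that("balanced groups with perfect fidelity give proportions near one half", {
  skel <- generate_design(design_spec(n_trials = 400,
                                      ratios = list(c(3, 3))), seed = 6)
  act <- generate_activity(skel, activity_spec(fidelity = 1), seed = 7)
  pv <- act$visits_black / (act$visits_black + act$visits_white)
  # binomial-style sampling error around the 0.5 expectation
  expect_equal(mean(pv), 0.5, tolerance = 0.02)
  expect_lt(sd(pv), 0.15)
})

test_that("the decorrelate switch separates the correlated and decorrelated regimes", {
  n <- 6000
  sim_on <- simulate_dataset(design_spec(n_trials = n),
                             activity_spec(decorrelate = TRUE),
                             model_parameters(), seed = 8)
  sim_off <- simulate_dataset(design_spec(n_trials = n), activity_spec(),
                              model_parameters(), seed = 8)
  r_on <- cor(trial_proportion(sim_on$trials, "birds"),
              trial_proportion(sim_on$trials, "pecks"))
  r_off <- cor(trial_proportion(sim_off$trials, "birds"),
               trial_proportion(sim_off$trials, "pecks"))
  expect_lt(r_on, 0.5)
  expect_gt(r_off, 0.9)
})

test_that("observer choices follow the model-implied probabilities", {
  # beta3 = 10, c = 0 with X = 1 trials only: P(black) = plogis(5)
  tab <- make_trials(rep(0, 4000), pecks_black = 12, pecks_white = 0)
  y <- generate_observer_choice(tab, model_parameters(beta3 = 10,
                                                      measure = "pecks"),
                                seed = 9)
  expect_equal(mean(y), plogis(5), tolerance = 0.02)
  y0 <- generate_observer_choice(tab, model_parameters(measure = "pecks"),
                                 seed = 10)
  expect_equal(mean(y0), 0.5, tolerance = 0.02)
  expect_identical(y, generate_observer_choice(
    tab, model_parameters(beta3 = 10, measure = "pecks"), seed = 9))
})

test_that("empirical outcome frequency matches the generating mean probability", {
  params <- pecks_truth_params()
  sim <- simulate_dataset(design_spec(n_trials = 10000), activity_spec(),
                          params, seed = 11)
  p <- choice_probability(params, sim$trials)
  expect_equal(mean(sim$trials$observer_first_peck_black), mean(p),
               tolerance = 0.02)
})

test_that("simulated datasets are valid, deterministic, and carry their truth", {
  sim <- simulate_dataset(design_spec(n_trials = 66), activity_spec(),
                          pecks_truth_params(), seed = 12)
  expect_equal(nrow(sim$trials), 66)
  expect_silent(validate_trials(sim$trials))
  expect_true(all(sim$trials$visits_black + sim$trials$visits_white >= 1))
  expect_true(all(sim$trials$pecks_black + sim$trials$pecks_white >= 1))
  expect_identical(sim$truth$params, pecks_truth_params())
  expect_identical(sim$truth$seed, 12L)

  again <- simulate_dataset(design_spec(n_trials = 66), activity_spec(),
                            pecks_truth_params(), seed = 12)
  expect_identical(sim$trials, again$trials)
  other <- simulate_dataset(design_spec(n_trials = 66), activity_spec(),
                            pecks_truth_params(), seed = 13)
  expect_false(identical(sim$trials$observer_first_peck_black,
                         other$trials$observer_first_peck_black))
})

test_that("truth and config objects survive a YAML round trip", {
  truth <- simulation_truth(pecks_truth_params(),
                            design_spec(n_trials = 30),
                            activity_spec(decorrelate = TRUE), seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$params$beta3, 4.35)
  expect_equal(back$params$shape, -3.79)
  expect_equal(back$design$n_trials, 30)
  expect_true(back$activity$decorrelate)

  cfg <- mcmc_config(n_iter = 12340, n_burn = 1000, seed = 77)
  cpath <- withr::local_tempfile(fileext = ".yaml")
  write_mcmc_config(cfg, cpath)
  cback <- read_mcmc_config(cpath)
  expect_equal(cback$n_iter, 12340)
  expect_equal(cback$seed, 77L)
})
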