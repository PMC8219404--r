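# Demonstrator-observer trial simulator. Emulates the experiment's design:
# majority:minority demonstrator group-size ratios {1:2, 2:4, 3:3, 1:5},
# counterbalanced feeder colour and cage side, single-sex trials, and
# per-group visit/peck activity whose derived proportions can be kept
# strongly correlated with the birds proportion or decorrelated on demand.

#' Design specification for simulated trials
#'
#' @param n_trials number of observer trials (default 66, the size of an
#'   analysable same-sex dataset under this design).
#' @param ratios list of unordered positive-integer group-size pairs
#'   (minority, majority); default `1:2, 2:4, 3:3, 1:5`.
#' @param sexes sex labels cycled over trials (single-sex trials).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_trials = 66,
                        ratios = list(c(1, 2), c(2, 4), c(3, 3), c(1, 5)),
                        sexes = c("f", "m")) {
  stopifnot(n_trials >= 1, length(ratios) >= 1,
            all(vapply(ratios, function(r) {
              length(r) == 2 && all(r == round(r)) && all(r >= 1)
            }, logical(1))))
  ratios <- lapply(ratios, sort)
  structure(list(n_trials = n_trials, ratios = ratios, sexes = sexes),
            class = "design_spec")
}

#' Activity specification for simulated demonstrators
#'
#' Controls the volume and colour-fidelity of demonstrator activity.
#' Group visit totals are drawn from a count distribution with mean
#' (group size) x `mean_visits`; peck totals given visits have mean
#' (visits) x `mean_pecks_per_visit`. Each visit or peck is then
#' attributed to the group's own feeder colour with probability
#' `fidelity`, otherwise to the other colour, so the visit/peck
#' proportions are noisy correlates of the birds proportion.
#'
#' With `decorrelate = TRUE`, each group's visit rate and peck rate are
#' multiplied by independent lognormal factors (sd of log = `rate_sd`)
#' and volumes are based on the average rather than the actual group
#' size, so the visit and peck proportions decouple from the birds
#' proportion (the regime in which the three predictors can be told
#' apart).
#'
#' @param mean_visits mean visits per demonstrator bird (default 8).
#' @param mean_pecks_per_visit mean pecks per visit (default 6).
#' @param fidelity probability an event goes to the group's own colour;
#'   in (0.5, 1\] (default 0.95).
#' @param count_noise `"poisson"` (default), `"negbin"` (over-dispersed),
#'   or `"none"` (deterministic volumes: exact expected counts).
#' @param dispersion over-dispersion of the negative binomial
#'   (variance = mu (1 + dispersion x mu); default 0.2; ignored unless
#'   `count_noise = "negbin"`).
#' @param decorrelate decouple visit/peck proportions from the birds
#'   proportion (default `FALSE`).
#' @param rate_sd sd of the log rate multipliers used when
#'   `decorrelate = TRUE` (default 1.5).
#' @return An object of class `activity_spec`.
#' @export
activity_spec <- function(mean_visits = 8, mean_pecks_per_visit = 6,
                          fidelity = 0.95,
                          count_noise = c("poisson", "negbin", "none"),
                          dispersion = 0.2, decorrelate = FALSE,
                          rate_sd = 1.5) {
  count_noise <- match.arg(count_noise)
  stopifnot(mean_visits > 0, mean_pecks_per_visit > 0,
            fidelity > 0.5, fidelity <= 1, dispersion >= 0, rate_sd >= 0)
  structure(list(mean_visits = mean_visits,
                 mean_pecks_per_visit = mean_pecks_per_visit,
                 fidelity = fidelity, count_noise = count_noise,
                 dispersion = dispersion, decorrelate = decorrelate,
                 rate_sd = rate_sd),
            class = "activity_spec")
}

#' Generate a counterbalanced trial design
#'
#' Assigns each trial a group-size ratio, which group (majority or
#' minority) feeds at the black feeder, and the side of the observer cage
#' the black feeder is on, such that the counts of the
#' ratio x colour x side cells differ by at most one; sexes are balanced
#' across trials. Trial order and the allocation of any remainder cells
#' are randomized under `seed`.
#'
#' @param design a [design_spec()].
#' @param seed integer seed.
#' @return data.frame of trial skeletons: `trial_id`, `ratio_label`,
#'   `black_group`, `black_side`, `sex`, `birds_black`, `birds_white`.
#' @export
generate_design <- function(design, seed = 1) {
  stopifnot(inherits(design, "design_spec"))
  set.seed(as.integer(seed))
  n <- design$n_trials
  cells <- expand.grid(ratio = seq_along(design$ratios),
                       black_group = c("majority", "minority"),
                       black_side = c(0L, 1L),
                       stringsAsFactors = FALSE)
  k <- nrow(cells)
  counts <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) {
    extra <- sample.int(k, rem)
    counts[extra] <- counts[extra] + 1
  }
  rows <- cells[rep(seq_len(k), counts), , drop = FALSE]
  rows <- rows[sample.int(n), , drop = FALSE]
  rownames(rows) <- NULL
  pair <- do.call(rbind, design$ratios[rows$ratio])
  minority <- pair[, 1]
  majority <- pair[, 2]
  black <- ifelse(rows$black_group == "majority", majority, minority)
  white <- ifelse(rows$black_group == "majority", minority, majority)
  data.frame(
    trial_id = sprintf("T%03d", seq_len(n)),
    ratio_label = paste0(minority, ":", majority),
    black_group = rows$black_group,
    black_side = rows$black_side,
    sex = sample(rep(design$sexes, length.out = n)),
    birds_black = as.integer(black),
    birds_white = as.integer(white),
    stringsAsFactors = FALSE
  )
}

# Draw count totals with the configured noise family; mu is a vector of
# means, one per group.
draw_counts <- function(mu, activity) {
  switch(activity$count_noise,
         poisson = rpois(length(mu), mu),
         negbin = if (activity$dispersion == 0) rpois(length(mu), mu) else
           rnbinom(length(mu), mu = mu, size = 1 / activity$dispersion),
         none = round(mu))
}

#' Generate demonstrator activity counts for trial skeletons
#'
#' Adds visit and peck counts per feeder colour to the skeletons from
#' [generate_design()]. Any trial whose visit or peck total is zero is
#' redrawn, so every generated trial is analysable under all three
#' measures.
#'
#' @param skeletons data.frame from [generate_design()].
#' @param activity an [activity_spec()].
#' @param seed integer seed.
#' @return The skeletons with `visits_black`, `visits_white`,
#'   `pecks_black`, `pecks_white` columns added.
#' @export
generate_activity <- function(skeletons, activity = activity_spec(),
                              seed = 1) {
  stopifnot(inherits(activity, "activity_spec"))
  set.seed(as.integer(seed))
  n <- nrow(skeletons)
  q <- activity$fidelity

  draw_trial <- function(nb, nw) {
    sizes <- c(nb, nw)
    base <- if (activity$decorrelate) rep(mean(sizes), 2) else sizes
    mult_v <- if (activity$decorrelate && activity$rate_sd > 0) {
      exp(rnorm(2, 0, activity$rate_sd))
    } else c(1, 1)
    mult_p <- if (activity$decorrelate && activity$rate_sd > 0) {
      exp(rnorm(2, 0, activity$rate_sd))
    } else c(1, 1)
    visits_group <- draw_counts(base * activity$mean_visits * mult_v,
                                activity)
    pecks_group <- draw_counts(visits_group * activity$mean_pecks_per_visit *
                                 mult_p, activity)
    # attribute each event to the group's own colour with probability q;
    # group 1 is the black-trained group
    if (q == 1 || activity$count_noise == "none") {
      vb_own <- round(q * visits_group[1]); vw_def <- round((1 - q) * visits_group[2])
      pb_own <- round(q * pecks_group[1]); pw_def <- round((1 - q) * pecks_group[2])
      vb <- vb_own + vw_def
      vw <- sum(visits_group) - vb
      pb <- pb_own + pw_def
      pw <- sum(pecks_group) - pb
    } else {
      vb <- rbinom(1, visits_group[1], q) + rbinom(1, visits_group[2], 1 - q)
      vw <- sum(visits_group) - vb
      pb <- rbinom(1, pecks_group[1], q) + rbinom(1, pecks_group[2], 1 - q)
      pw <- sum(pecks_group) - pb
    }
    c(vb, vw, pb, pw)
  }

  out <- matrix(0L, nrow = n, ncol = 4)
  for (i in seq_len(n)) {
    repeat {
      cnt <- draw_trial(skeletons$birds_black[i], skeletons$birds_white[i])
      if (cnt[1] + cnt[2] >= 1 && cnt[3] + cnt[4] >= 1) break
    }
    out[i, ] <- as.integer(cnt)
  }
  skeletons$visits_black <- out[, 1]
  skeletons$visits_white <- out[, 2]
  skeletons$pecks_black <- out[, 3]
  skeletons$pecks_white <- out[, 4]
  skeletons
}

#' Generate observer first-peck outcomes
#'
#' Draws each trial's binary outcome from a Bernoulli with probability
#' [choice_probability()] under the generating parameters.
#'
#' @param trials trial table rows with demonstrator counts and
#'   `black_side` (outcome column not required).
#' @param params generating [model_parameters()].
#' @param seed integer seed.
#' @return Integer vector of outcomes (1 = first peck at black feeder).
#' @export
generate_observer_choice <- function(trials, params, seed = 1) {
  set.seed(as.integer(seed))
  p <- choice_probability(params, trials)
  rbinom(nrow(trials), 1, p)
}

#' Simulation truth record
#'
#' Bundles the generating parameters, design and activity specification
#' with the master seed; given the seed this fully determines the
#' simulated dataset, so recovery experiments can score fits against it.
#'
#' @param params generating [model_parameters()].
#' @param design a [design_spec()].
#' @param activity an [activity_spec()].
#' @param seed integer master seed (recorded; stages use `seed`,
#'   `seed + 1`, `seed + 2`).
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(params, design = design_spec(),
                             activity = activity_spec(), seed = 1) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(design, "design_spec"),
            inherits(activity, "activity_spec"))
  structure(list(params = params, design = design, activity = activity,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Simulate a complete demonstrator-observer dataset
#'
#' Composes [generate_design()] (seed), [generate_activity()]
#' (seed + 1) and [generate_observer_choice()] (seed + 2) into a
#' validated trial table with its [simulation_truth()].
#'
#' @param design a [design_spec()].
#' @param activity an [activity_spec()].
#' @param params generating [model_parameters()].
#' @param seed integer master seed.
#' @return List with `trials` (validated trial table) and `truth`.
#' @export
simulate_dataset <- function(design = design_spec(),
                             activity = activity_spec(),
                             params = model_parameters(), seed = 1) {
  seed <- as.integer(seed)
  skel <- generate_design(design, seed = seed)
  skel <- generate_activity(skel, activity, seed = seed + 1L)
  skel$observer_first_peck_black <- generate_observer_choice(
    skel, params, seed = seed + 2L)
  trials <- skel[, trial_columns()]
  validate_trials(trials)
  list(trials = trials,
       truth = simulation_truth(params, design, activity, seed))
}
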