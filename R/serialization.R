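# YAML serialization of configuration and simulation-truth objects, used
# by the command-line interface and by recovery workflows.

#' Read an MCMC configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [mcmc_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return An `mcmc_config` object.
#' @export
read_mcmc_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(mcmc_config))
  extra <- setdiff(names(vals), allowed)
  if (length(extra) > 0) {
    stop("unknown mcmc_config key(s) in ", path, ": ",
         paste(extra, collapse = ", "))
  }
  do.call(mcmc_config, vals)
}

#' Write an MCMC configuration to YAML
#'
#' @param config an [mcmc_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mcmc_config <- function(config, path) {
  stopifnot(inherits(config, "mcmc_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a simulation truth from YAML
#'
#' Expected top-level keys: `params` (beta1, beta2, beta3, shape/c,
#' measure), optional `design` ([design_spec()] fields; `ratios` as a
#' list of 2-vectors), optional `activity` ([activity_spec()] fields),
#' optional `seed`.
#'
#' @param path YAML file.
#' @return A `simulation_truth` object.
#' @export
read_truth <- function(path) {
  vals <- yaml::read_yaml(path)
  stopifnot(!is.null(vals$params))
  pv <- vals$params
  if (!is.null(pv$c) && is.null(pv$shape)) {
    pv$shape <- pv$c
    pv$c <- NULL
  }
  params <- do.call(model_parameters, pv)
  design <- if (is.null(vals$design)) design_spec() else {
    dv <- vals$design
    if (!is.null(dv$ratios)) dv$ratios <- lapply(dv$ratios, unlist)
    do.call(design_spec, dv)
  }
  activity <- if (is.null(vals$activity)) activity_spec() else
    do.call(activity_spec, vals$activity)
  simulation_truth(params, design, activity,
                   seed = if (is.null(vals$seed)) 1L else vals$seed)
}

#' Write a simulation truth to YAML
#'
#' @param truth a [simulation_truth()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  out <- list(
    params = unclass(truth$params),
    design = unclass(truth$design),
    activity = unclass(truth$activity),
    seed = truth$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
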