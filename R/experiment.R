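#' Configure a synthetic split-root experiment
#'
#' Defines the layout of a simulated split-root experiment: the treatment
#' (`resource_partitioned`: the two compartments receive distinct growth
#' calibrations; `resource_mixed`: both compartments share one calibration),
#' the replicate count, the growth duration, the root-tracing schedule and
#' the seed. Defaults mirror the emulated study: 9 partitioned / 4 mixed
#' replicates and tracing three times per week.
#'
#' @param treatment `"resource_partitioned"` or `"resource_mixed"`.
#' @param calibrations Named list of two [calibration()] objects, one per
#'   compartment (names become the compartment labels). For the mixed
#'   treatment the two entries must hold identical parameter values.
#' @param n_replicates Number of replicate clones.
#' @param duration Days from planting to harvest.
#' @param trace_days Days on which roots are traced; default three times
#'   weekly (days 2, 4, 7 of each week) up to `duration`.
#' @param seed Integer seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(treatment = c("resource_partitioned",
                                            "resource_mixed"),
                              calibrations,
                              n_replicates = if (treatment == "resource_mixed") 4L else 9L,
                              duration = 18,
                              trace_days = NULL,
                              seed = 1L) {
  treatment <- match.arg(treatment)
  stopifnot(is.list(calibrations), length(calibrations) == 2L)
  if (is.null(names(calibrations)) || any(names(calibrations) == ""))
    stop("'calibrations' must be a named list (names = compartment labels)")
  for (cl in calibrations) stopifnot(inherits(cl, "rsa_calibration"))
  same <- identical(strip_calib(calibrations[[1]]), strip_calib(calibrations[[2]]))
  if (treatment == "resource_mixed" && !same)
    stop("resource_mixed requires identical calibrations for both compartments")
  if (treatment == "resource_partitioned" && same)
    stop("resource_partitioned requires two distinct calibrations")
  if (n_replicates < 0) stop("n_replicates must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  if (is.null(trace_days)) {
    weeks <- seq(0, ceiling(duration / 7) - 1L) * 7
    trace_days <- as.numeric(outer(c(2, 4, 7), weeks, `+`))
    trace_days <- sort(trace_days[trace_days <= duration])
  }
  stopifnot(all(diff(trace_days) > 0), all(trace_days <= duration))
  structure(list(treatment = treatment, calibrations = calibrations,
                 n_replicates = as.integer(n_replicates),
                 duration = duration, trace_days = trace_days,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# parameter values only (ignore compartment labels) for identity comparison
strip_calib <- function(cl) {
  lapply(unclass(cl), function(p) p[setdiff(names(p), "compartment")])
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Split-root experiment: %s, %d replicates, %g days, seed %d\n",
              x$treatment, x$n_replicates, x$duration, x$seed))
  cat(sprintf("  compartments: %s\n", paste(names(x$calibrations), collapse = " | ")))
  cat(sprintf("  tracing on days: %s\n", paste(x$trace_days, collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic split-root experiment
#'
#' Simulates `n_replicates` independent clones. Each clone grows one root
#' system per compartment under that compartment's calibration; cumulative
#' total root length is recorded at every tracing day and converted to a
#' *traced* length by a Beta(2, 8)-distributed visibility fraction (mean 0.2,
#' constant within a replicate's compartment) emulating that only roots
#' pressed against the observation window can be traced. Per-order biomass
#' receives a lognormal multiplicative perturbation (CV 10%) per replicate
#' and compartment, so specific root length varies across clones. The same
#' config and seed reproduce the result exactly.
#'
#' @param config An [experiment_config()].
#' @param seed Overrides `config$seed` when given.
#' @param keep_systems Keep full geometries of all simulated systems.
#' @return Object of class `rsa_experiment`: list with `traits` (pooled
#'   [trait_table()] over all replicates/compartments), `traces` (data frame
#'   `replicate`, `compartment`, `day`, `traced_length_cm`), `systems`
#'   (nested list or NULL) and `config`.
#' @export
generate_experiment <- function(config, seed = NULL, keep_systems = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- as.integer(seed %||% config$seed)
  set.seed(seed)
  n <- config$n_replicates
  comps <- names(config$calibrations)
  traits <- list(); traces <- list()
  systems <- if (keep_systems) vector("list", n) else NULL
  if (n > 0) {
    subseeds <- matrix(sample.int(.Machine$integer.max, n * 2L), nrow = n)
    for (i in seq_len(n)) {
      reps <- list()
      for (k in seq_along(comps)) {
        comp <- comps[[k]]
        calib <- config$calibrations[[k]]
        set.seed(subseeds[i, k])
        visibility <- stats::rbeta(1L, 2, 8)
        biomass_mult <- stats::rlnorm(1L, meanlog = -0.1^2 / 2, sdlog = 0.1)
        xside <- if (k == 1L) 1 else -1
        sys <- new_root_system(calib, origin = c(xside * 1, 0, 0))
        sys$compartment <- comp
        total <- numeric(length(config$trace_days))
        prev <- 0
        for (j in seq_along(config$trace_days)) {
          sys <- grow(sys, calib, dt = config$trace_days[j] - prev)
          prev <- config$trace_days[j]
          total[j] <- sum(vapply(sys$axes, `[[`, numeric(1), "length"))
        }
        if (prev < config$duration)
          sys <- grow(sys, calib, dt = config$duration - prev)
        tt <- trait_table(sys, replicate = i)
        tt$compartment <- comp
        tt$biomass_g <- tt$biomass_g * biomass_mult
        traits[[length(traits) + 1L]] <- tt
        traces[[length(traces) + 1L]] <- data.frame(
          replicate = i, compartment = comp, day = config$trace_days,
          traced_length_cm = total * visibility)
        if (keep_systems) reps[[comp]] <- sys
      }
      if (keep_systems) systems[[i]] <- reps
    }
  }
  structure(list(
    traits = if (length(traits)) do.call(rbind, traits) else
      trait_table_empty(),
    traces = if (length(traces)) do.call(rbind, traces) else
      data.frame(replicate = integer(), compartment = character(),
                 day = numeric(), traced_length_cm = numeric()),
    systems = systems, config = config, seed = seed
  ), class = "rsa_experiment")
}

trait_table_empty <- function() {
  data.frame(replicate = integer(), compartment = character(),
             branching_number = integer(), length_cm = numeric(),
             surface_area_cm2 = numeric(), tips = integer(),
             axes = integer(), biomass_g = numeric(),
             mean_angle_deg = numeric())
}

#' @export
print.rsa_experiment <- function(x, ...) {
  cat(sprintf("Synthetic split-root experiment: %s, %d replicates (seed %d)\n",
              x$config$treatment, x$config$n_replicates, x$seed))
  cat(sprintf("  %d trait rows, %d trace records\n",
              nrow(x$traits), nrow(x$traces)))
  invisible(x)
}

#' Packaged resource-partitioned experiment configuration
#'
#' The default synthetic emulation of the split-root study: 9 replicates of
#' the resource-partitioned treatment with the packaged nutrient and water
#' calibrations, or 4 replicates of the resource-mixed treatment with the
#' mixed calibration on both sides.
#'
#' @param treatment `"resource_partitioned"` or `"resource_mixed"`.
#' @param seed Integer seed.
#' @param ... Passed to [experiment_config()] (e.g. `n_replicates`).
#' @return An [experiment_config()].
#' @export
packaged_experiment <- function(treatment = c("resource_partitioned",
                                              "resource_mixed"),
                                seed = 1L, ...) {
  treatment <- match.arg(treatment)
  cal <- packaged_calibrations()
  calibs <- if (treatment == "resource_partitioned")
    list(nutrient = cal$nutrient, water = cal$water)
  else list(mixed_A = cal$mixed, mixed_B = cal$mixed)
  experiment_config(treatment, calibs, seed = seed, ...)
}
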