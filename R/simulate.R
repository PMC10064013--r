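#' Simulate one root system
#'
#' Convenience wrapper: creates a system from `calib` and grows it for
#' `duration` days. If `dt` is `NULL` the growth is performed in a single
#' continuous-time pass (branch emergence times are exact, so this is the
#' fastest route); give `dt` to step the clock, e.g. to record intermediate
#' states.
#'
#' @inheritParams new_root_system
#' @param duration Days of growth.
#' @param dt Optional step size, days.
#' @param ... Passed on to [grow()] (`resolution`, `gamma`).
#' @return A `root_system` at day `duration`.
#' @export
simulate_root_system <- function(calib, duration, dt = NULL, seed = NULL,
                                 origin = c(1, 0, 0), box = c(20, 27, 107),
                                 barrier_gap = 4, ...) {
  sys <- new_root_system(calib, origin = origin, box = box,
                         barrier_gap = barrier_gap, seed = seed)
  if (is.null(dt)) return(grow(sys, dt = duration, ...))
  while (sys$clock < duration - 1e-9) {
    sys <- grow(sys, dt = min(dt, duration - sys$clock), ...)
  }
  sys
}

#' Simulate a seeded ensemble of root systems
#'
#' Runs `n_replicates` independent simulations of one calibration and returns
#' the per-branching-number mean and dispersion of total root length, the
#' per-replicate totals, and (optionally) the systems themselves. The same
#' seed always reproduces the same ensemble.
#'
#' @inheritParams simulate_root_system
#' @param n_replicates Number of independent systems (>= 1; 0 gives an empty
#'   ensemble).
#' @param seed Integer seed for the whole ensemble.
#' @param keep_systems Keep the full geometries (memory-heavy for large
#'   ensembles)? Per-replicate totals are always kept.
#' @return A list of class `rsa_ensemble` with elements `summary` (data frame:
#'   branching_number, mean_length_cm, sd_length_cm, mean_axes), `totals`
#'   (per-replicate data frame as [root_totals()] plus a `replicate` column)
#'   and `systems` (list or NULL).
#' @export
simulate_ensemble <- function(calib, duration, n_replicates, seed,
                              keep_systems = FALSE, ...) {
  stopifnot(n_replicates >= 0)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, max(n_replicates, 1L))
  totals <- vector("list", n_replicates)
  systems <- if (keep_systems) vector("list", n_replicates) else NULL
  for (i in seq_len(n_replicates)) {
    sys <- simulate_root_system(calib, duration, seed = subseeds[i], ...)
    tt <- root_totals(sys)
    tt$replicate <- i
    totals[[i]] <- tt
    if (keep_systems) systems[[i]] <- sys
  }
  totals <- do.call(rbind, totals)
  summary <- NULL
  if (n_replicates > 0) {
    orders <- sort(unique(totals$branching_number))
    summary <- do.call(rbind, lapply(orders, function(b) {
      l <- totals$length_cm[totals$branching_number == b]
      a <- totals$axes[totals$branching_number == b]
      data.frame(branching_number = b,
                 mean_length_cm = mean(l),
                 sd_length_cm = if (length(l) > 1) stats::sd(l) else 0,
                 mean_axes = mean(a))
    }))
  }
  structure(list(summary = summary, totals = totals, systems = systems,
                 calibration = calib, duration = duration,
                 n_replicates = n_replicates, seed = seed),
            class = "rsa_ensemble")
}

#' @export
print.rsa_ensemble <- function(x, ...) {
  cat(sprintf("Root system ensemble: %d replicates of '%s', %g days\n",
              x$n_replicates, attr(x$calibration, "name"), x$duration))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
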