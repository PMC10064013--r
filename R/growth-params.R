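#' Growth parameter set for one root branching number
#'
#' A `growth_params` object holds the stochastic growth parameters governing
#' roots of a single branching number (developmental order; 0 = primary root
#' emerging from the rhizome) growing in one split-root compartment. Roots of
#' branching number `b` elongate at a constant rate `r` (cm day^-1) until they
#' reach their maximum length `lmax` (cm), and carry lateral branch sites of
#' branching number `b + 1` spaced every `ln` cm of arc length, outside an
#' unbranched zone of `la` cm at the root base and `lb` cm behind the tip.
#' `r`, `lmax` and `ln` are realized per axis as draws from normal
#' distributions with the stated means and standard deviations, censored below
#' at 1% of the mean; the axial insertion angle of a branch is drawn from
#' `Normal(theta_mean, theta_sd)` (degrees from the parent heading) and its
#' radial (circumferential) angle uniformly on \[0, 360).
#'
#' @param branching_number Integer >= 0; developmental order the set governs.
#' @param compartment Label of the split-root compartment (e.g. `"nutrient"`,
#'   `"water"`, `"mixed"`).
#' @param r_mean,r_sd Elongation rate mean and sd, cm day^-1.
#' @param lmax_mean,lmax_sd Maximum root length mean and sd, cm.
#' @param la Unbranched (basal) zone at the root base, cm.
#' @param lb Unbranched (apical) zone behind the root tip, cm.
#' @param ln_mean,ln_sd Inter-branch interval mean and sd, cm.
#' @param theta_mean,theta_sd Axial insertion angle mean and sd, degrees;
#'   for branching number 0 the angle is measured from the vertical.
#' @param maxB Initial number of primary roots; only meaningful (and required)
#'   for branching number 0, must be `NA` otherwise.
#' @param radius Root radius, cm (used for surface area, `2*pi*radius*length`).
#' @param linear_density Dry mass per unit length, g cm^-1.
#' @param tropism_sigma Heading perturbation per 0.1-cm growth step, degrees.
#' @param max_order Highest branching number allowed to emerge in the system
#'   this set belongs to.
#'
#' @return An object of class `growth_params` (a validated named list).
#' @examples
#' gp <- growth_params(0, "water", r_mean = 1, r_sd = 0, lmax_mean = 10,
#'                     lmax_sd = 0, la = 1, lb = 1, ln_mean = 2, ln_sd = 0,
#'                     theta_mean = 10, theta_sd = 0, maxB = 1, max_order = 1)
#' gp$lmax_mean
#' @export
growth_params <- function(branching_number, compartment,
                          r_mean, r_sd,
                          lmax_mean, lmax_sd,
                          la, lb,
                          ln_mean, ln_sd,
                          theta_mean, theta_sd,
                          maxB = NA_integer_,
                          radius = 0.02,
                          linear_density = 1e-4,
                          tropism_sigma = 10,
                          max_order = branching_number) {
  p <- list(
    branching_number = as.integer(branching_number),
    compartment = as.character(compartment),
    r_mean = as.numeric(r_mean), r_sd = as.numeric(r_sd),
    lmax_mean = as.numeric(lmax_mean), lmax_sd = as.numeric(lmax_sd),
    la = as.numeric(la), lb = as.numeric(lb),
    ln_mean = as.numeric(ln_mean), ln_sd = as.numeric(ln_sd),
    theta_mean = as.numeric(theta_mean), theta_sd = as.numeric(theta_sd),
    maxB = if (is.na(maxB)) NA_integer_ else as.integer(maxB),
    radius = as.numeric(radius),
    linear_density = as.numeric(linear_density),
    tropism_sigma = as.numeric(tropism_sigma),
    max_order = as.integer(max_order)
  )
  class(p) <- "growth_params"
  validate_growth_params(p)
  p
}

#' Validate a growth parameter set
#'
#' Checks the internal consistency rules of a [growth_params()] object and
#' stops with an error naming the offending field otherwise.
#'
#' @param p A `growth_params` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_growth_params <- function(p) {
  stopifnot(inherits(p, "growth_params"))
  bad <- function(field, why) {
    stop(sprintf("invalid growth_params: field '%s' %s", field, why),
         call. = FALSE)
  }
  nonneg <- c("r_mean", "r_sd", "lmax_mean", "lmax_sd", "la", "lb",
              "ln_mean", "ln_sd", "theta_sd", "radius", "linear_density",
              "tropism_sigma")
  for (f in nonneg) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      bad(f, "must be a single non-negative number")
  }
  if (p$branching_number < 0L) bad("branching_number", "must be >= 0")
  if (p$la + p$lb > p$lmax_mean + 1e-9)
    bad("la", sprintf("la + lb (%.3g) must not exceed lmax_mean (%.3g)",
                      p$la + p$lb, p$lmax_mean))
  if (p$max_order > p$branching_number && p$ln_mean <= 0)
    bad("ln_mean", "must be > 0 when laterals can emerge (max_order > branching_number)")
  if (p$theta_mean < 0 || p$theta_mean >= 180)
    bad("theta_mean", "must lie in [0, 180)")
  if (p$branching_number == 0L) {
    if (is.na(p$maxB) || p$maxB < 1L)
      bad("maxB", "must be >= 1 for branching number 0")
  } else if (!is.na(p$maxB)) {
    bad("maxB", "is only meaningful for branching number 0")
  }
  if (p$max_order < p$branching_number)
    bad("max_order", "must be >= branching_number")
  invisible(p)
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth parameters: branching number %d, compartment '%s'\n",
              x$branching_number, x$compartment))
  cat(sprintf("  r     = %.3g +/- %.3g cm/day\n", x$r_mean, x$r_sd))
  cat(sprintf("  lmax  = %.3g +/- %.3g cm   (la %.3g, lb %.3g)\n",
              x$lmax_mean, x$lmax_sd, x$la, x$lb))
  cat(sprintf("  ln    = %.3g +/- %.3g cm\n", x$ln_mean, x$ln_sd))
  cat(sprintf("  theta = %.3g +/- %.3g deg\n", x$theta_mean, x$theta_sd))
  if (!is.na(x$maxB)) cat(sprintf("  maxB  = %d primary roots\n", x$maxB))
  invisible(x)
}

#' Bundle per-order growth parameter sets into a compartment calibration
#'
#' A calibration is the complete parameterization of root growth in one
#' compartment: one [growth_params()] set per branching number from 0 up to
#' the calibration's `max_order`.
#'
#' @param ... `growth_params` objects, one per branching number 0, 1, 2, ...
#' @param name Calibration label; defaults to the compartment of the first set.
#' @return An object of class `rsa_calibration`: a list of `growth_params`
#'   indexed by `as.character(branching_number)`.
#' @export
calibration <- function(..., name = NULL) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "growth_params")) {
    sets <- sets[[1]]
  }
  if (!length(sets)) stop("calibration needs at least one growth_params set")
  for (s in sets) validate_growth_params(s)
  ord <- vapply(sets, `[[`, integer(1), "branching_number")
  if (!identical(sort(ord), seq_along(ord) - 1L))
    stop("calibration must contain branching numbers 0..k exactly once each")
  sets <- sets[order(ord)]
  names(sets) <- as.character(sort(ord))
  mo <- unique(vapply(sets, `[[`, integer(1), "max_order"))
  if (length(mo) != 1L)
    stop("all growth_params in a calibration must agree on max_order")
  if (mo != length(sets) - 1L)
    stop(sprintf("calibration holds orders 0..%d but max_order is %d",
                 length(sets) - 1L, mo))
  structure(sets, class = "rsa_calibration",
            name = name %||% sets[[1]]$compartment)
}

#' @export
print.rsa_calibration <- function(x, ...) {
  cat(sprintf("Root growth calibration '%s': branching numbers 0..%d, %d primaries\n",
              attr(x, "name"), length(x) - 1L, x[["0"]]$maxB))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Realize per-axis stochastic growth parameters
#'
#' Draws the per-axis elongation rate, maximum length and branching interval
#' from normal distributions with the means and standard deviations of `p`,
#' censored below at `floor_frac` of each mean (so sd = 0 returns the mean
#' exactly and no draw can be non-positive).
#'
#' @param p A [growth_params()] object.
#' @param floor_frac Lower censoring point as a fraction of each mean.
#' @return Named list with elements `r`, `lmax`, `ln` (cm day^-1, cm, cm).
#' @examples
#' set.seed(1)
#' gp <- growth_params(0, "water", 1, 0.1, 30, 5, 1, 1, 0.2, 0.05,
#'                     45, 9, maxB = 1, max_order = 1)
#' sample_axis_params(gp)
#' @export
sample_axis_params <- function(p, floor_frac = 0.01) {
  validate_growth_params(p)
  draw <- function(m, s) {
    if (s == 0) return(m)
    max(stats::rnorm(1L, m, s), floor_frac * m)
  }
  list(r = draw(p$r_mean, p$r_sd),
       lmax = draw(p$lmax_mean, p$lmax_sd),
       ln = draw(p$ln_mean, p$ln_sd))
}

#' Sample insertion angles for a new root
#'
#' The axial insertion angle (degrees between the new root and its parent's
#' local heading; for primaries, from the vertical) is drawn from
#' `Normal(theta_mean, theta_sd)` and clamped to \[0, 180); the radial angle
#' around the parent axis is uniform on \[0, 360).
#'
#' @param p A [growth_params()] object for the *new* root's branching number.
#' @return Named list with `axial` and `radial`, degrees.
#' @export
sample_angles <- function(p) {
  validate_growth_params(p)
  axial <- if (p$theta_sd == 0) p$theta_mean else
    stats::rnorm(1L, p$theta_mean, p$theta_sd)
  axial <- min(max(axial, 0), 180 - 1e-9)
  list(axial = axial, radial = stats::runif(1L, 0, 360))
}
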