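#' Create an empty root system in a split-root box
#'
#' Initializes a root system at day 0 inside a growth box that is split into
#' two compartments by a vertical barrier. Coordinates are right-handed with
#' z pointing downward (depth, cm) and the origin of depth at the substrate
#' surface; the box spans `[-box[1]/2, box[1]/2]` in x, `[-box[2]/2, box[2]/2]`
#' in y and `[0, box[3]]` in z. The barrier is the plane x = 0 for depths
#' z >= `barrier_gap`; the gap above it is where the rhizome sits so that
#' primaries can enter either compartment. `maxB` primary roots (branching
#' number 0) are created at the planting position with insertion angles drawn
#' from the order-0 parameter set, measured from the vertical.
#'
#' @param calib An [calibration()] object for the compartment being simulated.
#' @param origin Planting position, cm; default 1 cm into the x > 0 side.
#' @param box Box dimensions (x, y, z), cm.
#' @param barrier_gap Depth at which the barrier starts, cm.
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @return An object of class `root_system`.
#' @export
new_root_system <- function(calib, origin = c(1, 0, 0),
                            box = c(20, 27, 107), barrier_gap = 4,
                            seed = NULL) {
  stopifnot(inherits(calib, "rsa_calibration"), length(origin) == 3L,
            length(box) == 3L)
  if (!is.null(seed)) set.seed(seed)
  p0 <- calib[["0"]]
  sys <- structure(list(
    axes = list(),
    box = as.numeric(box),
    barrier_gap = as.numeric(barrier_gap),
    origin = as.numeric(origin),
    compartment = attr(calib, "name"),
    calibration = calib,
    clock = 0,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = "root_system")
  for (b in seq_len(p0$maxB)) {
    ang <- sample_angles(p0)
    rp <- sample_axis_params(p0)
    h <- heading_from_vertical(ang$axial, ang$radial)
    sys$axes[[b]] <- list(
      id = b, bn = 0L, parent_id = NA_integer_,
      insertion_arclength = 0, axial_angle = ang$axial,
      radial_angle = ang$radial, birth_time = 0,
      r = rp$r, lmax = rp$lmax, ln = rp$ln,
      radius = p0$radius, length = 0,
      points = matrix(sys$origin, nrow = 1L),
      heading = h, sites_spawned = 0L
    )
  }
  sys
}

# unit heading at `axial` degrees from straight down (+z), azimuth `radial` deg
heading_from_vertical <- function(axial, radial) {
  a <- axial * pi / 180
  ph <- radial * pi / 180
  c(sin(a) * cos(ph), sin(a) * sin(ph), cos(a))
}

#' @export
print.root_system <- function(x, ...) {
  bn <- vapply(x$axes, `[[`, integer(1), "bn")
  len <- vapply(x$axes, `[[`, numeric(1), "length")
  cat(sprintf("Root system ('%s' compartment), day %.1f: %d axes, %.1f cm total\n",
              x$compartment, x$clock, length(x$axes), sum(len)))
  if (length(bn)) {
    tab <- vapply(sort(unique(bn)), function(b)
      c(axes = sum(bn == b), length = sum(len[bn == b])), numeric(2))
    colnames(tab) <- paste0("bn", sort(unique(bn)))
    print(round(tab, 2))
  }
  invisible(x)
}

#' Per-branching-number totals of a root system
#'
#' @param system A `root_system`.
#' @return Data frame with one row per branching number present: axis count
#'   (= tip count: every axis carries exactly one tip), total length (cm),
#'   total surface area (cm^2, from per-order radii), total biomass (g, from
#'   per-order linear densities) and mean axial insertion angle (degrees).
#' @export
root_totals <- function(system) {
  stopifnot(inherits(system, "root_system"))
  calib <- system$calibration
  bn <- vapply(system$axes, `[[`, integer(1), "bn")
  len <- vapply(system$axes, `[[`, numeric(1), "length")
  ang <- vapply(system$axes, `[[`, numeric(1), "axial_angle")
  rad <- vapply(system$axes, `[[`, numeric(1), "radius")
  if (!length(bn)) bn_max <- -1L else bn_max <- max(bn)
  if (!is.null(calib)) bn_max <- max(bn_max, calib[["0"]]$max_order)
  if (bn_max < 0L) return(trait_table_empty()[, -(1:2)])
  out <- lapply(0:bn_max, function(b) {
    i <- bn == b
    dens <- if (!is.null(calib)) calib[[as.character(b)]]$linear_density
            else NA_real_
    data.frame(
      branching_number = b,
      axes = sum(i),
      tips = sum(i),
      length_cm = sum(len[i]),
      surface_area_cm2 = 2 * pi * sum(rad[i] * len[i]),
      biomass_g = dens * sum(len[i]),
      mean_angle_deg = if (any(i)) mean(ang[i]) else NA_real_
    )
  })
  do.call(rbind, out)
}

# arc-length positions of polyline vertices of one axis
axis_arclengths <- function(ax) {
  pts <- ax$points
  if (nrow(pts) < 2L) return(0)
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# point and local tangent at arc length s along an axis polyline
axis_point_at <- function(ax, s) {
  cs <- axis_arclengths(ax)
  n <- length(cs)
  if (n == 1L || s <= 0) {
    return(list(point = ax$points[1L, ], tangent = ax$heading))
  }
  s <- min(s, cs[n])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(i, n - 1L)
  p0 <- ax$points[i, ]; p1 <- ax$points[i + 1L, ]
  seg <- p1 - p0
  segl <- sqrt(sum(seg^2))
  tangent <- if (segl > 0) seg / segl else ax$heading
  list(point = p0 + tangent * (s - cs[i]), tangent = tangent)
}
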