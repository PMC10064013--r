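#' Grow a root system forward in time
#'
#' Advances the system clock by `dt` days. Every living axis elongates at its
#' realized rate `r` until it reaches its realized maximum length `lmax`;
#' geometry is laid down in `resolution`-cm segments whose heading is the
#' previous heading pulled toward the vertical by the gravitropic fraction
#' `gamma` and perturbed by a `Normal(0, tropism_sigma)` angle in a uniformly
#' random azimuth. Segments are reflected at the box walls and at the
#' split-root barrier (the plane x = 0 below the barrier gap). Lateral
#' branches of order b+1 appear on an axis of order b at arc-length sites
#' `la + i*ln` (i = 0, 1, ...) as soon as the axis first exceeds length
#' `site + lb`, with the exact emergence time back-computed from the parent's
#' elongation rate, so branch counts do not depend on the time step.
#'
#' Because branch emergence times are continuous, growing by one large `dt`
#' or by many small ones yields identical lengths and branch counts whenever
#' the parameter standard deviations are zero; with stochastic parameters,
#' reproducibility is per seed and call schedule.
#'
#' @param system A [new_root_system()] object.
#' @param params An [calibration()]; defaults to the one stored in `system`.
#' @param dt Time step, days (>= 0; `dt = 0` returns the system unchanged).
#' @param resolution Geometry segment length, cm.
#' @param gamma Gravitropic pull per segment, in \[0, 1\].
#' @return The grown `root_system`.
#' @examples
#' calib <- calibration(growth_params(0, "w", 1, 0, 10, 0, 1, 1, 2, 0,
#'                                    0, 0, maxB = 1, tropism_sigma = 0,
#'                                    max_order = 0))
#' sys <- new_root_system(calib, seed = 1)
#' sys <- grow(sys, dt = 5)
#' sys$axes[[1]]$length   # 5 cm
#' @export
grow <- function(system, params = NULL, dt, resolution = 0.1, gamma = 0.15) {
  stopifnot(inherits(system, "root_system"), dt >= 0)
  params <- params %||% system$calibration
  stopifnot(inherits(params, "rsa_calibration"))
  if (dt == 0) return(system)
  t1 <- system$clock + dt
  max_order <- params[["0"]]$max_order
  axes <- system$axes
  n <- length(axes)
  repeat {
    changed <- FALSE
    ## elongation pass
    for (i in seq_len(n)) {
      ax <- axes[[i]]
      if (ax$birth_time >= t1) next
      target <- min(ax$r * (t1 - ax$birth_time), ax$lmax)
      if (target > ax$length + 1e-12) {
        p <- params[[as.character(ax$bn)]]
        axes[[i]] <- extend_axis(ax, target, system$box, system$barrier_gap,
                                 resolution, gamma, p$tropism_sigma)
        changed <- TRUE
      }
    }
    ## branching pass
    i <- 1L
    while (i <= n) {
      ax <- axes[[i]]
      if (ax$bn < max_order) {
        pp <- params[[as.character(ax$bn)]]       # parent's zones
        cp <- params[[as.character(ax$bn + 1L)]]  # child's parameter set
        repeat {
          site <- pp$la + ax$sites_spawned * ax$ln
          if (site + pp$lb > ax$length + 1e-9) break
          birth <- ax$birth_time + (site + pp$lb) / ax$r
          loc <- axis_point_at(ax, site)
          ang <- sample_angles(cp)
          rp <- sample_axis_params(cp)
          n <- n + 1L
          axes[[n]] <- list(
            id = n, bn = ax$bn + 1L, parent_id = ax$id,
            insertion_arclength = site, axial_angle = ang$axial,
            radial_angle = ang$radial, birth_time = birth,
            r = rp$r, lmax = rp$lmax, ln = rp$ln,
            radius = cp$radius, length = 0,
            points = matrix(loc$point, nrow = 1L),
            heading = rotate_about(loc$tangent, ang$axial, ang$radial),
            sites_spawned = 0L
          )
          ax$sites_spawned <- ax$sites_spawned + 1L
          axes[[i]] <- ax
          changed <- TRUE
        }
      }
      i <- i + 1L
    }
    if (!changed) break
  }
  system$axes <- axes
  system$clock <- t1
  system
}

# rotate unit vector `t` by `axial` degrees away from itself, azimuth `radial`
rotate_about <- function(t, axial, radial) {
  a <- axial * pi / 180
  ph <- radial * pi / 180
  ref <- if (abs(t[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(t[2L] * ref[3L] - t[3L] * ref[2L],
         t[3L] * ref[1L] - t[1L] * ref[3L],
         t[1L] * ref[2L] - t[2L] * ref[1L])
  u <- u / sqrt(sum(u^2))
  v <- c(t[2L] * u[3L] - t[3L] * u[2L],
         t[3L] * u[1L] - t[1L] * u[3L],
         t[1L] * u[2L] - t[2L] * u[1L])
  cos(a) * t + sin(a) * (cos(ph) * u + sin(ph) * v)
}

# elongate one axis to `target` cm, laying down segments with tropism and
# reflecting at walls and barrier; returns the updated axis
extend_axis <- function(ax, target, box, barrier_gap, resolution, gamma,
                        sigma) {
  add <- target - ax$length
  nseg <- ceiling(add / resolution - 1e-9)
  if (nseg <= 0L) return(ax)
  perturb <- if (sigma > 0) stats::rnorm(nseg, 0, sigma * pi / 180)
             else numeric(nseg)
  azim <- stats::runif(nseg, 0, 2 * pi)
  xlim <- box[1L] / 2; ylim <- box[2L] / 2; zlim <- box[3L]
  h <- ax$heading
  p <- ax$points[nrow(ax$points), ]
  newpts <- matrix(0, nrow = nseg, ncol = 3L)
  len <- ax$length
  for (j in seq_len(nseg)) {
    s <- min(resolution, target - len)
    # gravitropic pull toward +z (down), then heading noise
    h <- (1 - gamma) * h
    h[3L] <- h[3L] + gamma
    h <- h / sqrt(sum(h^2))
    a <- perturb[j]
    if (a != 0) {
      ref <- if (abs(h[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- c(h[2L] * ref[3L] - h[3L] * ref[2L],
             h[3L] * ref[1L] - h[1L] * ref[3L],
             h[1L] * ref[2L] - h[2L] * ref[1L])
      u <- u / sqrt(sum(u^2))
      v <- c(h[2L] * u[3L] - h[3L] * u[2L],
             h[3L] * u[1L] - h[1L] * u[3L],
             h[1L] * u[2L] - h[2L] * u[1L])
      ph <- azim[j]
      h <- cos(a) * h + sin(a) * (cos(ph) * u + sin(ph) * v)
    }
    # reflect at walls and at the barrier until the step stays inside
    inside <- FALSE
    for (k in 1:4) {
      q <- p + s * h
      ok <- TRUE
      if (q[1L] < -xlim || q[1L] > xlim) { h[1L] <- -h[1L]; ok <- FALSE }
      if (q[2L] < -ylim || q[2L] > ylim) { h[2L] <- -h[2L]; ok <- FALSE }
      if (q[3L] < 0 || q[3L] > zlim)     { h[3L] <- -h[3L]; ok <- FALSE }
      # barrier: no crossing of x = 0 below the gap
      if (ok && sign(q[1L]) != sign(p[1L]) && q[1L] != 0 &&
          max(p[3L], q[3L]) >= barrier_gap) {
        h[1L] <- -h[1L]; ok <- FALSE
      }
      if (ok) { inside <- TRUE; break }
    }
    if (!inside) {
      # corner case: step toward the interior of the current compartment
      # (a convex region), which is always admissible from an inside point
      ctr <- c(sign(p[1L]) * xlim / 2, 0, min(max(p[3L], 1), zlim - 1))
      d <- ctr - p
      h <- d / sqrt(sum(d^2))
    }
    p <- p + s * h
    newpts[j, ] <- p
    len <- len + s
  }
  ax$points <- rbind(ax$points, newpts)
  ax$heading <- h
  ax$length <- len
  ax
}
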