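# Shared fixtures: small calibrations built in code, plus an independent
# closed-form/enumeration oracle for the deterministic growth limit.

# deterministic (all sds 0, no tropism) calibration over orders 0..k
det_calib <- function(specs, maxB = 1) {
  k <- length(specs) - 1L
  sets <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    growth_params(i - 1L, "det",
                  r_mean = s$r, r_sd = 0,
                  lmax_mean = s$lmax, lmax_sd = 0,
                  la = s$la, lb = s$lb,
                  ln_mean = s$ln, ln_sd = 0,
                  theta_mean = s$theta %||% 0, theta_sd = 0,
                  maxB = if (i == 1L) maxB else NA,
                  tropism_sigma = 0, max_order = k)
  })
  calibration(sets, name = "det")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# independent enumeration oracle: per-order axis counts and total lengths at
# time t for a deterministic calibration (recursion over branch sites; never
# touches the growth engine)
oracle_totals <- function(calib, t) {
  k <- calib[["0"]]$max_order
  counts <- numeric(k + 1)
  lengths <- numeric(k + 1)
  recurse <- function(order, birth) {
    if (birth > t + 1e-9) return()
    p <- calib[[as.character(order)]]
    counts[order + 1] <<- counts[order + 1] + 1
    len <- min(p$r_mean * (t - birth), p$lmax_mean)
    lengths[order + 1] <<- lengths[order + 1] + max(len, 0)
    if (order < k) {
      i <- 0
      repeat {
        site <- p$la + i * p$ln_mean
        if (site + p$lb > p$lmax_mean + 1e-9) break
        recurse(order + 1, birth + (site + p$lb) / p$r_mean)
        i <- i + 1
      }
    }
  }
  for (b in seq_len(calib[["0"]]$maxB)) recurse(0L, 0)
  data.frame(branching_number = 0:k, axes = counts, length_cm = lengths)
}

# small stochastic two-order calibration for geometry/property tests
small_stochastic_calib <- function() {
  calibration(
    growth_params(0, "s", r_mean = 1, r_sd = 0.1, lmax_mean = 8, lmax_sd = 1,
                  la = 0.5, lb = 0.5, ln_mean = 0.5, ln_sd = 0.05,
                  theta_mean = 20, theta_sd = 8, maxB = 3,
                  tropism_sigma = 10, max_order = 1),
    growth_params(1, "s", r_mean = 0.4, r_sd = 0.05, lmax_mean = 1.5,
                  lmax_sd = 0.4, la = 0.3, lb = 0.3, ln_mean = 0.5,
                  ln_sd = 0.05, theta_mean = 50, theta_sd = 10,
                  tropism_sigma = 15, max_order = 1),
    name = "small")
}
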