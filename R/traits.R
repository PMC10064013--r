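#' Build a per-order trait table
#'
#' Converts simulated architectures into the tabular form produced by
#' root-scan software: one row per (replicate, compartment, branching number)
#' with total length, surface area, tip and axis counts, biomass and mean
#' axial insertion angle. All trait operations
#' ([branching_intensity()], [branching_density()], [branching_ratio()],
#' [allocation_proportions()], [srl()], [mass_fraction()]) consume this table.
#'
#' @param x A `root_system`, an `rsa_ensemble`, or a data frame already in
#'   trait-table form (returned unchanged after validation).
#' @param replicate Replicate id used when `x` is a single system.
#' @return Data frame with columns `replicate`, `compartment`,
#'   `branching_number`, `length_cm`, `surface_area_cm2`, `tips`, `axes`,
#'   `biomass_g`, `mean_angle_deg`.
#' @export
trait_table <- function(x, replicate = 1L) {
  if (inherits(x, "root_system")) {
    tt <- root_totals(x)
    tt$replicate <- replicate
    tt$compartment <- x$compartment
    return(tt[, trait_table_cols()])
  }
  if (inherits(x, "rsa_ensemble")) {
    tt <- x$totals
    tt$compartment <- attr(x$calibration, "name")
    return(tt[, trait_table_cols()])
  }
  if (is.data.frame(x)) {
    miss <- setdiff(trait_table_cols(), names(x))
    if (length(miss))
      stop("trait table is missing columns: ", paste(miss, collapse = ", "))
    num <- c("length_cm", "surface_area_cm2", "tips", "axes", "biomass_g")
    for (f in num) if (any(x[[f]] < 0, na.rm = TRUE))
      stop("trait table column '", f, "' contains negative values")
    return(x[, trait_table_cols()])
  }
  stop("cannot build a trait table from class ", paste(class(x), collapse = "/"))
}

trait_table_cols <- function() {
  c("replicate", "compartment", "branching_number", "length_cm",
    "surface_area_cm2", "tips", "axes", "biomass_g", "mean_angle_deg")
}

sum_at <- function(table, bn, col) {
  sum(table[[col]][table$branching_number == bn], na.rm = TRUE)
}

undefined_value <- function(what) {
  warning(what, call. = FALSE)
  NA_real_
}

#' Branching intensity (BI)
#'
#' Tips of branching number `bn` per cm of root length of the *same*
#' branching number.
#'
#' @param table A [trait_table()] (or subset of its rows; rows are pooled).
#' @param bn Branching number.
#' @return Tips cm^-1; `NA` with a warning if the order has zero length.
#' @export
branching_intensity <- function(table, bn) {
  table <- trait_table(table)
  len <- sum_at(table, bn, "length_cm")
  if (len <= 0)
    return(undefined_value(sprintf(
      "branching_intensity undefined: zero root length at branching number %d", bn)))
  sum_at(table, bn, "tips") / len
}

#' Branching density (BD)
#'
#' Tips of branching number `bn` per cm of root length of the *preceding*
#' branching number. Not applicable at `bn = 0` (no preceding order): returns
#' `NA`.
#'
#' @inheritParams branching_intensity
#' @return Tips cm^-1; `NA` for `bn = 0`; `NA` with a warning if the
#'   preceding order has zero length.
#' @export
branching_density <- function(table, bn) {
  if (bn == 0) return(NA_real_)
  table <- trait_table(table)
  len <- sum_at(table, bn - 1, "length_cm")
  if (len <= 0)
    return(undefined_value(sprintf(
      "branching_density undefined: zero root length at branching number %d", bn - 1)))
  sum_at(table, bn, "tips") / len
}

#' Branching ratio (BR)
#'
#' Tips of branching number `bn` per individual root of the *preceding*
#' branching number. Not applicable at `bn = 0`: returns `NA`.
#'
#' @inheritParams branching_intensity
#' @return Tips root^-1; `NA` for `bn = 0`; `NA` with a warning if the
#'   preceding order has zero roots.
#' @export
branching_ratio <- function(table, bn) {
  if (bn == 0) return(NA_real_)
  table <- trait_table(table)
  ax <- sum_at(table, bn - 1, "axes")
  if (ax <= 0)
    return(undefined_value(sprintf(
      "branching_ratio undefined: zero roots at branching number %d", bn - 1)))
  sum_at(table, bn, "tips") / ax
}

#' Allocation proportion between two split-root compartments
#'
#' Fraction of a metric (root length, surface area or tip count) at one
#' branching number that sits in compartment A: `A / (A + B)`. The proportions
#' of A and B necessarily sum to 1.
#'
#' @param tableA,tableB Trait-table rows for the two compartments.
#' @param bn Branching number.
#' @param metric One of `"length"`, `"surface_area"`, `"tips"`.
#' @return Proportion in \[0, 1\]; `NA` with a warning when both sides are 0.
#' @export
allocation_proportions <- function(tableA, tableB, bn,
                                   metric = c("length", "surface_area", "tips")) {
  metric <- match.arg(metric)
  col <- switch(metric, length = "length_cm",
                surface_area = "surface_area_cm2", tips = "tips")
  a <- sum_at(trait_table(tableA), bn, col)
  b <- sum_at(trait_table(tableB), bn, col)
  if (a + b <= 0)
    return(undefined_value(sprintf(
      "allocation undefined: %s is zero in both compartments at branching number %d",
      metric, bn)))
  a / (a + b)
}

#' Specific root length (SRL)
#'
#' Total root length divided by total root biomass over a compartment,
#' cm g^-1.
#'
#' @param table A [trait_table()].
#' @param compartment Optional compartment label to subset on; default uses
#'   all rows.
#' @return SRL in cm g^-1; `NA` with a warning on zero biomass.
#' @export
srl <- function(table, compartment = NULL) {
  table <- trait_table(table)
  if (!is.null(compartment)) table <- table[table$compartment == compartment, ]
  mass <- sum(table$biomass_g, na.rm = TRUE)
  if (mass <= 0)
    return(undefined_value("srl undefined: zero root biomass"))
  sum(table$length_cm, na.rm = TRUE) / mass
}

#' Root biomass mass fraction of a compartment
#'
#' Root biomass in one compartment divided by the clone's total root biomass;
#' fractions over all compartments sum to 1.
#'
#' @param table A [trait_table()] holding all compartments of one clone (or
#'   a pooled set of replicates).
#' @param compartment Compartment label.
#' @return Fraction in \[0, 1\]; `NA` with a warning on zero total biomass.
#' @export
mass_fraction <- function(table, compartment) {
  table <- trait_table(table)
  total <- sum(table$biomass_g, na.rm = TRUE)
  if (total <= 0)
    return(undefined_value("mass_fraction undefined: zero total root biomass"))
  sum(table$biomass_g[table$compartment == compartment], na.rm = TRUE) / total
}

#' Per-order trait summary (BI, BD, BR, BA)
#'
#' Computes branching intensity, density, ratio and mean branch angle for
#' every (replicate, compartment, branching number) combination of a trait
#' table.
#'
#' @param table A [trait_table()].
#' @return Data frame with columns `replicate`, `compartment`,
#'   `branching_number`, `BI`, `BD`, `BR`, `BA_deg`.
#' @export
trait_summary <- function(table) {
  table <- trait_table(table)
  keys <- unique(table[, c("replicate", "compartment")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- table[table$replicate == keys$replicate[i] &
                   table$compartment == keys$compartment[i], ]
    for (b in sort(unique(sub$branching_number))) {
      out[[length(out) + 1L]] <- data.frame(
        replicate = keys$replicate[i],
        compartment = keys$compartment[i],
        branching_number = b,
        BI = suppressWarnings(branching_intensity(sub, b)),
        BD = suppressWarnings(branching_density(sub, b)),
        BR = suppressWarnings(branching_ratio(sub, b)),
        BA_deg = sub$mean_angle_deg[sub$branching_number == b][1L]
      )
    }
  }
  do.call(rbind, out)
}
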