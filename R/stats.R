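#' Exact binomial test of split-root allocation
#'
#' Two-sided exact binomial test of whether a metric is allocated evenly
#' (p0 = 0.5) between the two compartments, with the metric expressed in
#' discrete units (e.g. root length in 1-mm units, tips as counts).
#'
#' @param successes Units observed in compartment A.
#' @param total Units observed in A and B together (> 0).
#' @param p0 Null allocation proportion.
#' @return List of class `comparison_result`: `estimate` (proportion in A),
#'   `statistic` (successes), `p_value`, `n` (total units).
#' @examples
#' proportion_test(5, 10)$p_value    # 1
#' proportion_test(0, 8)$p_value     # 2 * 0.5^8
#' @export
proportion_test <- function(successes, total, p0 = 0.5) {
  if (total <= 0) stop("total must be > 0")
  if (successes < 0 || successes > total)
    stop("successes must lie in [0, total]")
  bt <- stats::binom.test(successes, total, p = p0)
  structure(list(estimate = successes / total,
                 statistic = successes,
                 p_value = bt$p.value,
                 n = total),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Allocation test: %d/%d units (%.3f), exact binomial p = %.4g\n",
              x$statistic, x$n, x$estimate, x$p_value))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within-group F test on `k` groups with `(k - 1, N - k)`
#' degrees of freedom. If every value in every group is identical the F
#' statistic is defined as 0 with p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty, at
#'   least one with >= 2 values).
#' @return List with `F`, `df` (length 2), `p_value`, `group_means`, `n`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(3, 4, 5)))$F   # 6 on (1, 4) df
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs at least one value")
  if (all(sizes < 2L)) stop("at least one group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  df <- c(length(groups) - 1L, length(y) - length(groups))
  if (all(y == y[1L])) {
    return(list(F = 0, df = df, p_value = 1,
                group_means = vapply(groups, mean, numeric(1)),
                n = sizes))
  }
  a <- stats::anova(stats::lm(y ~ g))
  list(F = a$`F value`[1L], df = df, p_value = a$`Pr(>F)`[1L],
       group_means = vapply(groups, mean, numeric(1)), n = sizes)
}

#' Compare compartment allocation for every metric and branching number
#'
#' Runs [proportion_test()] on the allocation of root length (1-mm units),
#' surface area (1-mm^2 units) and tip counts between the two compartments
#' of a trait table, separately per branching number, pooled over replicates.
#'
#' @param table A [trait_table()] holding exactly two compartments.
#' @param compartment_A The compartment whose allocation is reported;
#'   defaults to the first label present.
#' @return Data frame with columns `branching_number`, `metric`, `estimate`,
#'   `statistic`, `p_value`, `n_A`, `n_B`.
#' @export
compare_allocation <- function(table, compartment_A = NULL) {
  table <- trait_table(table)
  comps <- unique(table$compartment)
  if (length(comps) != 2L)
    stop("compare_allocation needs a trait table with exactly two compartments")
  compartment_A <- compartment_A %||% comps[[1L]]
  compartment_B <- setdiff(comps, compartment_A)
  units <- list(length = function(d) round(sum(d$length_cm) * 10),
                surface_area = function(d) round(sum(d$surface_area_cm2) * 100),
                tips = function(d) sum(d$tips))
  out <- list()
  for (b in sort(unique(table$branching_number))) {
    for (m in names(units)) {
      a <- units[[m]](table[table$branching_number == b &
                              table$compartment == compartment_A, ])
      bb <- units[[m]](table[table$branching_number == b &
                               table$compartment == compartment_B, ])
      if (a + bb == 0) next
      pt <- proportion_test(a, a + bb)
      out[[length(out) + 1L]] <- data.frame(
        branching_number = b, metric = m, estimate = pt$estimate,
        statistic = pt$statistic, p_value = pt$p_value, n_A = a, n_B = bb)
    }
  }
  do.call(rbind, out)
}
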