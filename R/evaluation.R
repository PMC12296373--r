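# Growth-vector aggregation and correlation-based validation.
#
# Growth vectors are tidy tibbles (sample_id, unit_id, value) where a
# unit is a taxon or a merged group. Two aggregation strategies move
# between levels: the "post" strategy averages simulated growth upward
# with abundance weights; the reference builder does the same for
# experimentally derived replication rates after averaging duplicated
# entries.

#' Abundance-weighted growth aggregation (post strategy)
#'
#' Per sample, the growth of a group is the abundance-weighted mean of
#' its members' growth rates:
#' `mu_group = sum(w_i mu_i) / sum(w_i)`, `w_i` = member relative
#' abundance in that sample.
#'
#' @param growth Growth vector: tibble `sample_id`, `unit_id`, `value`
#'   with units at the member (taxon) level.
#' @param abundances Abundance table supplying the weights.
#' @param scheme A `grouping_scheme` mapping taxa to groups.
#' @return Growth vector at the group level.
#' @export
posthoc_weighted_growth <- function(growth, abundances, scheme) {
  growth <- as_growth_vector_(growth)
  abundances <- as_abundance_table_(abundances)
  joined <- growth |>
    dplyr::inner_join(abundances, by = c(sample_id = "sample_id", unit_id = "taxon_id")) |>
    dplyr::inner_join(tibble::as_tibble(scheme), by = c(unit_id = "taxon_id"))
  assert_(nrow(joined) == nrow(growth),
          "every growth entry needs an abundance weight and a group assignment")
  zero <- joined |>
    dplyr::group_by(.data$sample_id, .data$group_id) |>
    dplyr::summarise(w = sum(.data$abundance), .groups = "drop") |>
    dplyr::filter(.data$w <= 0)
  assert_(nrow(zero) == 0,
          paste0("zero total weight in group(s): ",
                 paste(unique(zero$group_id), collapse = ", ")))
  joined |>
    dplyr::group_by(.data$sample_id, unit_id = .data$group_id) |>
    dplyr::summarise(value = sum(.data$value * .data$abundance) / sum(.data$abundance),
                     .groups = "drop")
}

#' Build the reference rates for a higher level
#'
#' Duplicate entries for the same (sample, unit) are first averaged with
#' an unweighted mean (repeated measurements of one taxon); the
#' higher-level reference is then the abundance-weighted mean of the
#' member rates, mirroring [posthoc_weighted_growth()].
#'
#' @param replication Growth vector of replication rates at member level.
#' @param scheme A `grouping_scheme`.
#' @param abundances Abundance table supplying the weights.
#' @return Growth vector of group-level reference rates.
#' @export
reference_replication_rates <- function(replication, scheme, abundances) {
  replication <- as_growth_vector_(replication) |>
    dplyr::group_by(.data$sample_id, .data$unit_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  posthoc_weighted_growth(replication, abundances, scheme)
}

#' Pearson product-moment correlation
#'
#' Thin, strict wrapper: refuses short or zero-variance input rather than
#' returning NA silently.
#'
#' @param x,y Equal-length numeric vectors, `length >= 3`, both with
#'   nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  assert_(is.numeric(x) && is.numeric(y) && length(x) == length(y),
          "x and y must be numeric vectors of equal length")
  assert_(length(x) >= 3, "need at least 3 paired observations")
  assert_(all(is.finite(x)) && all(is.finite(y)), "inputs must be finite")
  assert_(stats::sd(x) > 0 && stats::sd(y) > 0,
          "zero variance: correlation undefined")
  stats::cor(x, y, method = "pearson")
}

#' Correlate two growth vectors
#'
#' Pairs entries on (sample, unit) and either pools all pairs into one
#' Pearson correlation (default, matching correlation-across-samples
#' reporting) or computes one correlation per sample.
#'
#' @param predicted,reference Growth vectors.
#' @param by_sample If TRUE, one row per sample.
#' @return A tibble with `pearson_r` and `n` (plus `sample_id` when
#'   `by_sample`).
#' @export
growth_correlation <- function(predicted, reference, by_sample = FALSE) {
  predicted <- as_growth_vector_(predicted)
  reference <- as_growth_vector_(reference)
  joined <- dplyr::inner_join(predicted, reference,
                              by = c("sample_id", "unit_id"),
                              suffix = c("_pred", "_ref"))
  assert_(nrow(joined) >= 3, "fewer than 3 overlapping (sample, unit) pairs")
  if (by_sample) {
    joined |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(pearson_r = pearson(.data$value_pred, .data$value_ref),
                       n = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(pearson_r = pearson(joined$value_pred, joined$value_ref),
                   n = nrow(joined))
  }
}

#' Williams' test for two dependent correlations sharing one variable
#'
#' Compares `r12` and `r13` (correlations of predictors 2 and 3 with a
#' shared reference 1) given their intercorrelation `r23`, using the 1959
#' t statistic
#' \deqn{t = (r_{12}-r_{13})\sqrt{\frac{(n-1)(1+r_{23})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{23})^3}}}
#' with \eqn{|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 + 2 r_{12} r_{13}
#' r_{23}} and \eqn{\bar r = (r_{12}+r_{13})/2}, referred to a Student t
#' with `n - 3` degrees of freedom (two-sided).
#'
#' @param r12,r13 Correlations of each predictor with the reference.
#' @param r23 Correlation between the two predictors.
#' @param n Number of paired observations (> 3).
#' @return Object of class `correlation_comparison` with fields `r12`,
#'   `r13`, `r23`, `n`, `t_statistic`, `p_value`.
#' @examples
#' williams_test(0.5, 0.2, 0.3, 50)
#' @export
williams_test <- function(r12, r13, r23, n) {
  assert_(all(abs(c(r12, r13, r23)) <= 1), "correlations must lie in [-1, 1]")
  assert_(is.numeric(n) && length(n) == 1 && n > 3, "n must exceed 3")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  t <- (r12 - r13) * sqrt(((n - 1) * (1 + r23)) / denom)
  p <- 2 * stats::pt(-abs(t), df = n - 3)
  structure(list(r12 = r12, r13 = r13, r23 = r23, n = as.integer(n),
                 t_statistic = t, p_value = p),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat("Williams' test for dependent correlations\n",
      "  r12 = ", format(x$r12), ", r13 = ", format(x$r13),
      ", r23 = ", format(x$r23), ", n = ", x$n, "\n",
      "  t = ", format(x$t_statistic), ", df = ", x$n - 3,
      ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Compare two predictors against a shared reference
#'
#' Convenience wrapper computing the three correlations from growth
#' vectors and running [williams_test()].
#'
#' @param pred1,pred2 Growth vectors of the two predictors.
#' @param reference Growth vector of the shared reference.
#' @return A `correlation_comparison`.
#' @export
compare_predictions <- function(pred1, pred2, reference) {
  p1 <- as_growth_vector_(pred1)
  p2 <- as_growth_vector_(pred2)
  ref <- as_growth_vector_(reference)
  j <- ref |>
    dplyr::inner_join(p1, by = c("sample_id", "unit_id"), suffix = c("", "_1")) |>
    dplyr::inner_join(p2, by = c("sample_id", "unit_id"), suffix = c("_ref", "_2"))
  assert_(nrow(j) > 3, "need more than 3 complete (sample, unit) triples")
  williams_test(pearson(j$value_ref, j$value_1),
                pearson(j$value_ref, j$value_2),
                pearson(j$value_1, j$value_2),
                nrow(j))
}
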