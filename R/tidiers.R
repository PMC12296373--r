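# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fba Tidy fluxes of a `flux_result` into a tibble.
#' @param x A `flux_result`.
#' @param ... Unused.
#' @export
tidy.flux_result <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble::tibble(reaction_id = character(0), flux = numeric(0)))
  }
  tibble::tibble(reaction_id = names(x$fluxes), flux = as.numeric(x$fluxes))
}

#' @describeIn fba One-row summary of a `flux_result`.
#' @export
glance.flux_result <- function(x, ...) {
  tibble::tibble(objective_value = x$objective_value, status = x$status)
}

#' @describeIn community_growth Per-member growth rates as a tibble.
#' @param x A `growth_result`.
#' @param ... Unused.
#' @export
tidy.growth_result <- function(x, ...) {
  if (is.null(x$member_growth)) {
    return(tibble::tibble(taxon_id = character(0), abundance = numeric(0),
                          growth_rate = numeric(0)))
  }
  x$member_growth
}

#' @describeIn community_growth One-row community-level summary.
#' @export
glance.growth_result <- function(x, ...) {
  tibble::tibble(community_growth = x$community_growth,
                 n_members = if (is.null(x$member_growth)) 0L else nrow(x$member_growth),
                 status = x$status, method = x$method)
}

#' @describeIn williams_test Tidy the comparison into one row.
#' @param x A `correlation_comparison`.
#' @param ... Unused.
#' @export
tidy.correlation_comparison <- function(x, ...) {
  tibble::tibble(r12 = x$r12, r13 = x$r13, r23 = x$r23, n = x$n,
                 statistic = x$t_statistic, p.value = x$p_value,
                 df = x$n - 3L, method = "Williams' t (dependent correlations)")
}

#' @describeIn sensitivity_analysis Per-noise-level correlations.
#' @param x A `sensitivity_report`.
#' @param ... Unused.
#' @export
tidy.sensitivity_report <- function(x, ...) x$results

#' @describeIn sensitivity_analysis One-row summary with the baseline.
#' @export
glance.sensitivity_report <- function(x, ...) {
  tibble::tibble(baseline_r = x$baseline,
                 n_levels = nrow(x$results),
                 min_r = min(x$results$pearson_r),
                 max_r = max(x$results$pearson_r))
}
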