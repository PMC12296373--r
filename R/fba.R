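#' Media: maximal uptake rates for exchange reactions
#'
#' A medium maps exchange reaction ids to non-negative maximal uptake
#' rates (mmol/gDW/h). When a medium is applied, each listed exchange gets
#' its lower bound set to `-uptake`; exchanges not listed are closed to
#' uptake (lower bound raised to 0), so the medium fully defines the
#' environment. Passing `medium = NULL` to the solvers leaves the model's
#' own bounds untouched (a permissive default, since published cohort
#' simulations rarely state their diet).
#'
#' @param x Named numeric vector (exchange id -> uptake) or a data frame
#'   with columns `exchange_id`, `max_uptake`.
#' @return Named numeric vector of class `medium`.
#' @export
medium <- function(x) {
  if (is.data.frame(x)) {
    assert_(all(c("exchange_id", "max_uptake") %in% names(x)),
            "medium data frame needs columns exchange_id, max_uptake")
    v <- stats::setNames(as.numeric(x$max_uptake), x$exchange_id)
  } else {
    assert_(is.numeric(x) && !is.null(names(x)), "medium must be a named numeric vector")
    v <- x
  }
  assert_(all(is.finite(v)) && all(v >= 0), "medium uptake bounds must be finite and >= 0")
  structure(v, class = "medium")
}

#' Read / write a medium as two-column CSV
#'
#' @param path CSV file with header `exchange_id,max_uptake`.
#' @return [read_medium()] returns a `medium`; [write_medium()] its input,
#'   invisibly.
#' @export
read_medium <- function(path) {
  medium(readr::read_csv(path, show_col_types = FALSE))
}

#' @param med A `medium`.
#' @rdname read_medium
#' @export
write_medium <- function(med, path) {
  readr::write_csv(tibble::tibble(exchange_id = names(med), max_uptake = as.numeric(med)), path)
  invisible(med)
}

# Apply a medium to per-reaction bounds. Unlisted exchanges are closed to
# uptake; listed ones get lb = -uptake. Internal reactions untouched.
apply_medium_ <- function(model, med) {
  b <- bounds_(model)
  if (is.null(med)) return(b)
  med <- medium(med)
  # media may cover a superset of a model's exchanges (shared cohort medium)
  ex <- exchange_ids_(model)
  for (id in ex) {
    up <- if (id %in% names(med)) med[[id]] else 0
    b$lb[[id]] <- -up
    b$ub[[id]] <- max(b$ub[[id]], 0)
  }
  b
}

flux_result_ <- function(status, objective = NA_real_, fluxes = NULL) {
  structure(list(objective_value = objective, fluxes = fluxes, status = status),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat("<flux_result> status:", x$status,
      if (x$status == "optimal") paste0(" objective: ", signif(x$objective_value, 6)), "\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises the biomass objective flux subject to steady-state mass
#' balance (`S v = 0`) and flux bounds, optionally under a [medium()].
#'
#' @param model A valid [gem()].
#' @param medium Optional medium; see [medium()] for the bound convention.
#' @return A `flux_result`: `objective_value`, named `fluxes` (only when
#'   `status == "optimal"`), and `status` in
#'   `{"optimal", "infeasible", "unbounded"}`.
#' @examples
#' m <- make_toy_gem(substrates = list(S = c(uptake = 10, yield = 0.5)))
#' fba(m)$objective_value  # 5 = uptake x yield
#' @export
fba <- function(model, medium = NULL) {
  validate_gem(model)
  b <- apply_medium_(model, medium)
  S <- stoich_matrix_(model)
  obj <- as.numeric(rxn_ids_(model) == model$objective_id)
  sol <- lp_solve_(obj, S, rep(0, nrow(S)), b$lb, b$ub, maximize = TRUE)
  if (sol$status != "optimal") return(flux_result_(sol$status))
  flux_result_("optimal", sol$objective,
               stats::setNames(sol$solution, rxn_ids_(model)))
}

#' Flux variability analysis
#'
#' For each requested reaction, the minimal and maximal flux attainable
#' while biomass stays at or above `fraction_of_optimum` times the FBA
#' optimum (implemented as a lower bound on the biomass flux).
#'
#' @inheritParams fba
#' @param reaction_ids Reactions to scan (default: all).
#' @param fraction_of_optimum Number in `[0, 1]`; 0 means capability only.
#' @return Tibble with columns `reaction_id`, `min`, `max`.
#' @export
fva <- function(model, medium = NULL, reaction_ids = NULL, fraction_of_optimum = 1) {
  validate_gem(model)
  assert_(is.numeric(fraction_of_optimum) && fraction_of_optimum >= 0 && fraction_of_optimum <= 1,
          "fraction_of_optimum must lie in [0, 1]")
  rxn_ids <- rxn_ids_(model)
  targets <- reaction_ids %||% rxn_ids
  missing <- setdiff(targets, rxn_ids)
  assert_(length(missing) == 0, paste0("unknown reactions: ", paste(missing, collapse = ", ")))

  base <- fba(model, medium)
  if (base$status != "optimal") abort_(paste0("fva: base FBA is ", base$status))
  b <- apply_medium_(model, medium)
  bio <- match(model$objective_id, rxn_ids)
  b$lb[bio] <- max(b$lb[bio], fraction_of_optimum * base$objective_value)
  S <- stoich_matrix_(model)
  zero <- rep(0, nrow(S))

  res <- purrr::map(targets, function(id) {
    obj <- as.numeric(rxn_ids == id)
    lo <- lp_solve_(obj, S, zero, b$lb, b$ub, maximize = FALSE)
    hi <- lp_solve_(obj, S, zero, b$lb, b$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      abort_(paste0("fva: subproblem for '", id, "' returned ", lo$status, "/", hi$status))
    }
    tibble::tibble(reaction_id = id, min = lo$objective, max = hi$objective)
  })
  dplyr::bind_rows(res)
}

#' Find blocked exchange metabolites
#'
#' Extracellular metabolites whose exchange reaction cannot carry any flux
#' in the given medium (FVA range (0, 0) at `fraction_of_optimum = 0`, so
#' the test is capability, not growth-coupled flux).
#'
#' @inheritParams fba
#' @param tol Flux tolerance below which a range counts as zero.
#' @return Character vector of metabolite ids.
#' @export
find_blocked_exchanges <- function(model, medium = NULL, tol = 1e-6) {
  ex <- exchange_ids_(model)
  if (!length(ex)) return(character(0))
  rng <- fva(model, medium, reaction_ids = ex, fraction_of_optimum = 0)
  blocked <- rng$reaction_id[abs(rng$min) <= tol & abs(rng$max) <= tol]
  vapply(model$reactions[blocked], exchange_met_, "")
}
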