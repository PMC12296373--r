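# De novo metabolite-mediated interaction detection. A blocked metabolite
# here is one the focal organism can neither obtain from the medium nor
# produce internally, yet could consume if a partner supplied it; a
# partner able to secrete it creates a potential directed interaction.

#' Exchange capabilities of a model in a medium
#'
#' Classifies every exchanged (extracellular) metabolite of the model by
#' per-exchange flux variability at zero growth requirement:
#' * `producible` -- maximal secretion flux exceeds `tol` in the medium;
#' * `consumable` -- the medium supplies it and maximal uptake magnitude
#'   exceeds `tol`;
#' * `blocked` -- neither of the above, but uptake becomes feasible when
#'   the exchange is opened (bound `open_bound`), i.e. the organism
#'   depends on a partner for it.
#'
#' `blocked` is disjoint from `producible` and `consumable` by
#' construction. Exchanged metabolites that cannot carry flux even when
#' opened (true dead ends) fall in none of the three sets.
#'
#' @param model A [gem()].
#' @param medium A [medium()]; `NULL` uses the model's own bounds, with
#'   "supplied" meaning a negative exchange lower bound.
#' @param open_bound Uptake bound used to probe consumability of
#'   unsupplied metabolites.
#' @param tol Flux tolerance.
#' @return An `exchange_capability`: `unit_id`, `producible`,
#'   `consumable`, `blocked` (character vectors of metabolite ids).
#' @export
exchange_capabilities <- function(model, medium = NULL, open_bound = 10, tol = 1e-6) {
  validate_gem(model)
  ex <- exchange_ids_(model)
  cap <- structure(list(unit_id = model$id, producible = character(0),
                        consumable = character(0), blocked = character(0)),
                   class = "exchange_capability")
  if (!length(ex)) return(cap)
  b <- apply_medium_(model, medium)

  feasible <- tryCatch({fba(model, medium)$status == "optimal"}, error = function(e) FALSE)
  if (!feasible) {
    rlang::warn(paste0("exchange_capabilities('", model$id,
                       "'): solo model infeasible; reporting all exchanged metabolites as blocked"))
    cap$blocked <- unname(vapply(model$reactions[ex], exchange_met_, ""))
    return(cap)
  }

  rng <- fva(model, medium, reaction_ids = ex, fraction_of_optimum = 0)
  S <- stoich_matrix_(model)
  zero <- rep(0, nrow(S))
  ids <- rxn_ids_(model)

  for (id in ex) {
    met <- exchange_met_(model$reactions[[id]])
    r <- rng[rng$reaction_id == id, ]
    supplied <- b$lb[[id]] < -tol
    if (r$max > tol) cap$producible <- c(cap$producible, met)
    if (supplied && r$min < -tol) {
      cap$consumable <- c(cap$consumable, met)
    } else if (!supplied && !(r$max > tol)) {
      # probe: can it be taken up when the exchange is opened?
      lb2 <- b$lb; lb2[[id]] <- -open_bound
      obj <- as.numeric(ids == id)
      lo <- lp_solve_(obj, S, zero, lb2, b$ub, maximize = FALSE)
      if (lo$status == "optimal" && lo$objective < -tol) {
        cap$blocked <- c(cap$blocked, met)
      }
    }
  }
  cap
}

#' @export
print.exchange_capability <- function(x, ...) {
  cat("<exchange_capability> ", x$unit_id,
      "\n  producible: ", paste(x$producible, collapse = ", "),
      "\n  consumable: ", paste(x$consumable, collapse = ", "),
      "\n  blocked:    ", paste(x$blocked, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Detect metabolite-mediated interactions from capabilities
#'
#' Directed edge `A -> B` whenever some metabolite is producible by A and
#' blocked for B (B consumes it only if a partner supplies it); the edge
#' weight counts such metabolites. Self-edges are never emitted and the
#' result does not depend on the input order.
#'
#' @param capabilities List of `exchange_capability` objects (>= 2).
#' @return An `interaction_graph` tibble: `source`, `target`, `weight`,
#'   `sign` (always `"positive"`: a provision), `metabolites`
#'   (list-column).
#' @export
detect_interactions <- function(capabilities) {
  assert_(length(capabilities) >= 2, "need capabilities for at least 2 units")
  ids <- vapply(capabilities, `[[`, "", "unit_id")
  assert_(!anyDuplicated(ids), "duplicate unit ids in capabilities")
  names(capabilities) <- ids
  edges <- list()
  for (a in sort(ids)) {
    for (b in sort(ids)) {
      if (a == b) next
      shared <- intersect(capabilities[[a]]$producible, capabilities[[b]]$blocked)
      if (length(shared)) {
        edges[[paste(a, b)]] <- tibble::tibble(
          source = a, target = b, weight = length(shared),
          sign = "positive", metabolites = list(sort(shared))
        )
      }
    }
  }
  out <- dplyr::bind_rows(edges)
  if (nrow(out) == 0) {
    out <- tibble::tibble(source = character(0), target = character(0),
                          weight = numeric(0), sign = character(0),
                          metabolites = list())
  }
  interaction_graph_(out, type = "metabolite")
}

#' Merge per-sample interaction graphs by label
#'
#' Pools graphs belonging to the same label (e.g. disease status) into
#' one consensus graph per label; the merged weight of an edge is the
#' fraction of that label's graphs containing it (occurrence weighting),
#' so weights lie in (0, 1].
#'
#' @param graphs List of `interaction_graph`s.
#' @param labels Character vector, one label per graph.
#' @return Named list label -> merged `interaction_graph`.
#' @export
merge_graphs <- function(graphs, labels) {
  assert_(length(graphs) == length(labels) && length(graphs) > 0 || length(graphs) == 0,
          "graphs and labels must have equal length")
  if (!length(graphs)) return(list())
  labels <- as.character(labels)
  out <- list()
  for (lab in unique(labels)) {
    gs <- graphs[labels == lab]
    counted <- dplyr::bind_rows(purrr::map(gs, ~ tibble::as_tibble(.x)[, c("source", "target")])) |>
      dplyr::count(.data$source, .data$target, name = "n_samples") |>
      dplyr::mutate(weight = .data$n_samples / length(gs),
                    sign = "positive")
    out[[lab]] <- interaction_graph_(counted[, c("source", "target", "weight", "sign", "n_samples")],
                                     type = "merged")
  }
  out
}

#' Write an interaction graph as edge-list TSV or GraphML
#'
#' @param graph An `interaction_graph`.
#' @param path Output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_interaction_graph <- function(graph, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  tab <- tibble::as_tibble(graph)
  if ("metabolites" %in% names(tab)) {
    tab$metabolites <- vapply(tab$metabolites, paste, "", collapse = ";")
  }
  if (format == "tsv") {
    readr::write_tsv(tab, path)
  } else {
    g <- igraph::graph_from_data_frame(tab, directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
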