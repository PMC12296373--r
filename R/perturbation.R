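# Robustness analyses: Gaussian noise on abundance inputs, and the
# taxon-knockout interaction screen.

#' Add Gaussian noise to an abundance table
#'
#' Noise with mean 0 and standard deviation `noise_sd` is added
#' independently to every relative abundance (the quantity the growth
#' pipelines consume), negative values are clipped to 0 and each sample
#' is renormalised. Set `scale` to perturb on another unit, e.g.
#' `scale = 100` for noise calibrated to percent-style tables.
#'
#' A replicate in which every abundance of some sample clips to zero is
#' redrawn; after 100 failed attempts for one replicate an error is
#' raised.
#'
#' @param table Abundance table (fractions summing to 1 per sample).
#' @param noise_sd Noise standard deviation, in units of `scale`.
#' @param n_reps Number of replicate tables.
#' @param seed Integer; replicate `k` uses a seed derived from
#'   `(seed, k)`, so partial reruns reproduce.
#' @param scale Abundance units per fraction (default 1: noise on the
#'   fraction scale).
#' @return List of `n_reps` abundance tables.
#' @export
perturb_abundances <- function(table, noise_sd, n_reps, seed, scale = 1) {
  table <- as_abundance_table_(table)
  assert_(noise_sd >= 0, "noise_sd must be >= 0")
  assert_(n_reps >= 1, "n_reps must be >= 1")
  purrr::map(seq_len(n_reps), function(k) {
    for (try in seq_len(100)) {
      noise <- with_seed_(derive_seed_(seed, k, try),
                          stats::rnorm(nrow(table), sd = noise_sd))
      out <- table |>
        dplyr::mutate(abundance = pmax(0, .data$abundance * scale + noise)) |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::mutate(abundance = .data$abundance / sum(.data$abundance)) |>
        dplyr::ungroup()
      if (!anyNA(out$abundance) && all(is.finite(out$abundance))) return(out)
    }
    abort_("perturb_abundances: a sample clipped to all-zero in 100 consecutive draws")
  })
}

#' Sensitivity of a growth pipeline to abundance noise
#'
#' For each noise level: perturb the abundance table `n_reps` times
#' ([perturb_abundances()]), run the pipeline on every replicate, average
#' the growth predictions per (sample, unit) across replicates, and
#' correlate the mean predictions with the reference. Defaults follow the
#' conventional protocol: noise standard deviations 0.1, 0.7 and 1.5 with
#' five replicates each.
#'
#' @param pipeline Function: abundance table -> growth vector.
#' @param table Abundance table.
#' @param reference Growth vector to correlate against.
#' @param noise_sds Noise levels on the `scale` units.
#' @param n_reps Replicates per noise level.
#' @param seed Master seed; level `i`, replicate `k` derives its seed
#'   from `(seed, i, k)`.
#' @param scale Abundance units per fraction for the noise (see
#'   [perturb_abundances()]); default 1, i.e. noise on the fraction
#'   scale the pipelines consume.
#' @return A `sensitivity_report`: `baseline` (noiseless correlation),
#'   `results` (tibble noise_sd, pearson_r, n, n_failed), `mean_growth`
#'   (per-level averaged predictions).
#' @export
sensitivity_analysis <- function(pipeline, table, reference,
                                 noise_sds = c(0.1, 0.7, 1.5), n_reps = 5, seed = 1,
                                 scale = 1) {
  table <- as_abundance_table_(table)
  reference <- as_growth_vector_(reference)
  assert_(is.function(pipeline), "pipeline must be a function(table) -> growth vector")

  base_pred <- as_growth_vector_(pipeline(table))
  baseline <- growth_correlation(base_pred, reference)$pearson_r

  mean_growth <- list()
  results <- purrr::imap(stats::setNames(noise_sds, noise_sds), function(sd_i, nm) {
    i <- match(sd_i, noise_sds)
    preds <- list()
    failed <- 0L
    for (k in seq_len(n_reps)) {
      rep_tab <- perturb_abundances(table, sd_i, n_reps = 1,
                                    seed = derive_seed_(seed, i, k), scale = scale)[[1]]
      pred <- tryCatch(as_growth_vector_(pipeline(rep_tab)), error = function(e) NULL)
      if (is.null(pred)) failed <- failed + 1L else preds[[length(preds) + 1L]] <- pred
    }
    assert_(length(preds) > 0, paste0("all replicates failed at noise_sd ", sd_i))
    mg <- dplyr::bind_rows(preds) |>
      dplyr::group_by(.data$sample_id, .data$unit_id) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    mean_growth[[nm]] <<- mg
    cr <- growth_correlation(mg, reference)
    tibble::tibble(noise_sd = sd_i, pearson_r = cr$pearson_r, n = cr$n, n_failed = failed)
  })

  structure(list(baseline = baseline,
                 results = dplyr::bind_rows(results),
                 mean_growth = mean_growth),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> baseline r:", signif(x$baseline, 4), "\n")
  print(x$results)
  invisible(x)
}

interaction_graph_ <- function(edges, type) {
  out <- tibble::as_tibble(edges)
  structure(out, class = c("interaction_graph", class(tibble::tibble())), type = type)
}

#' Community-wide taxon knockout screen
#'
#' Knocks out each member in turn ([knockout_taxon()]) and records the
#' growth-rate change of every remaining member,
#' `delta_i = mu_i(without j) - mu_i(with j)`. Following the standard
#' sign convention for knockout interaction networks: removal that
#' *increases* a member's growth reveals competition (positive edge);
#' removal that *lowers* it reveals cooperation (negative edge). Changes
#' within `tol` are omitted.
#'
#' @param cm A `community_model` with at least two members.
#' @param method,tradeoff_fraction,renormalize Passed to
#'   [knockout_taxon()].
#' @param tol Minimal growth change treated as an interaction.
#' @return An `interaction_graph` tibble: `source` (knocked-out member),
#'   `target`, `weight` (growth change), `sign`.
#' @export
knockout_screen <- function(cm, method = c("cooperative_tradeoff", "sum"),
                            tradeoff_fraction = 1.0, renormalize = TRUE, tol = 1e-6) {
  method <- match.arg(method)
  assert_(inherits(cm, "community_model") && nrow(cm$members) >= 2,
          "knockout screen needs a community with >= 2 members")
  base <- community_growth(cm, method, tradeoff_fraction)
  assert_(base$status == "optimal", "baseline community simulation failed")
  mu0 <- stats::setNames(base$member_growth$growth_rate, base$member_growth$taxon_id)

  edges <- purrr::map(cm$members$taxon_id, function(j) {
    res <- knockout_taxon(cm, j, method, tradeoff_fraction, renormalize)
    if (res$status != "optimal") return(NULL)
    mu1 <- stats::setNames(res$member_growth$growth_rate, res$member_growth$taxon_id)
    delta <- mu1 - mu0[names(mu1)]
    keep <- abs(delta) > tol
    if (!any(keep)) return(NULL)
    tibble::tibble(source = j, target = names(delta)[keep],
                   weight = unname(delta[keep]),
                   sign = unname(ifelse(delta[keep] > 0, "positive", "negative")))
  })
  out <- dplyr::bind_rows(edges)
  if (nrow(out) == 0) {
    out <- tibble::tibble(source = character(0), target = character(0),
                          weight = numeric(0), sign = character(0))
  }
  interaction_graph_(out, type = "knockout")
}
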