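# End-to-end flows: simulate every sample of a cohort, with or without
# phylogenetic pooling, and produce the tabular reports.

#' Simulate community growth for every sample of a cohort
#'
#' Builds one community model per sample from the taxa present in it and
#' runs the chosen growth simulation.
#'
#' @param models Named list taxon_id -> [gem()].
#' @param abundances Abundance table (`sample_id`, `taxon_id`,
#'   `abundance`).
#' @param medium Optional shared [medium()].
#' @param method,tradeoff_fraction See [community_growth()].
#' @param abundance_cutoff Passed to [build_community()].
#' @return Growth vector tibble (`sample_id`, `unit_id`, `value`) with an
#'   extra `community_growth` column.
#' @export
simulate_growth <- function(models, abundances, medium = NULL,
                            method = c("cooperative_tradeoff", "sum"),
                            tradeoff_fraction = 1.0, abundance_cutoff = 1e-4) {
  method <- match.arg(method)
  abundances <- as_abundance_table_(abundances)
  out <- abundances |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      ab <- stats::setNames(df$abundance, df$taxon_id)
      cm <- build_community(models[names(ab)[ab > 0]], ab[ab > 0],
                            medium = medium, abundance_cutoff = abundance_cutoff)
      res <- community_growth(cm, method, tradeoff_fraction)
      assert_(res$status == "optimal",
              paste0("simulation not optimal for sample ", key$sample_id,
                     " (", res$status, ")"))
      tibble::tibble(sample_id = key$sample_id,
                     unit_id = res$member_growth$taxon_id,
                     value = res$member_growth$growth_rate,
                     community_growth = res$community_growth)
    })
  dplyr::bind_rows(out)
}

#' Pooled-model ("pre") growth predictions
#'
#' Merges the models of each group ([build_phylogems()]), then simulates
#' the pooled communities; predictions come out at the group level.
#'
#' @inheritParams simulate_growth
#' @param table Abundance table at the taxon level.
#' @param scheme A `grouping_scheme`.
#' @return Group-level growth vector.
#' @export
pre_phylo_growth <- function(models, table, scheme, medium = NULL,
                             method = c("cooperative_tradeoff", "sum"),
                             tradeoff_fraction = 1.0, abundance_cutoff = 1e-4) {
  method <- match.arg(method)
  pg <- build_phylogems(models, table, scheme)
  simulate_growth(pg$models, pg$abundances, medium, method,
                  tradeoff_fraction, abundance_cutoff)
}

#' Post-hoc aggregated ("post") growth predictions
#'
#' Simulates the unpooled taxon-level communities, then aggregates the
#' member growth rates to the group level by abundance-weighted mean.
#'
#' @inheritParams pre_phylo_growth
#' @return Group-level growth vector.
#' @export
post_phylo_growth <- function(models, table, scheme, medium = NULL,
                              method = c("cooperative_tradeoff", "sum"),
                              tradeoff_fraction = 1.0, abundance_cutoff = 1e-4) {
  method <- match.arg(method)
  raw <- simulate_growth(models, table, medium, method, tradeoff_fraction, abundance_cutoff)
  posthoc_weighted_growth(raw[, c("sample_id", "unit_id", "value")], table, scheme)
}

read_config_ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    assert_(length(p) >= 2, paste0("bad config line: ", paste(p, collapse = "=")))
    out[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = "="))
  }
  out
}

#' Run the full pooled-versus-standard pipeline
#'
#' One call chains grouping, pooled ("pre") and aggregated ("post")
#' growth prediction, the random-grouping null, correlation against
#' replication rates, and the reaction-set redundancy report, writing
#' TSVs plus a log into `out_dir`. Inputs come from a config (flat
#' `key = value` text file or named list); with `input = synthetic`
#' (default) a seeded synthetic cohort ([make_cohort()]) is generated,
#' otherwise `abundance_tsv`, `taxonomy_tsv`, `replication_tsv`, model
#' files (`models_dir`, one SBML/JSON per taxon) and optionally
#' `medium_csv` are read.
#'
#' Config keys (defaults in parentheses): `input` (synthetic), `rank`
#' (family), `method` (cooperative_tradeoff), `tradeoff_fraction` (1.0),
#' `seed` (1), `n_samples` (20), `n_groups` (5), `members_per_group`
#' (3), `planted_correlation` (0.8), `run_sensitivity` (false),
#' `run_knockout` (false), `run_interactions` (false), `out_dir`
#' (required).
#'
#' @param config Path to a config file, or a named list.
#' @return Invisibly, a list with the growth vectors, correlation table
#'   and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config_(config)
  assert_(is.list(config), "config must be a file path or a named list")
  cfg <- function(key, default = NULL) config[[key]] %||% default
  out_dir <- cfg("out_dir")
  assert_(!is.null(out_dir), "config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg("seed", 1))
  method <- cfg("method", "cooperative_tradeoff")
  tf <- as.numeric(cfg("tradeoff_fraction", 1.0))
  rank <- cfg("rank", "family")

  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), " ", ..., "\n",
                            sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("phylocomm ", as.character(utils::packageVersion("phylocomm")),
       " | R ", as.character(getRversion()))
  logf("seed=", seed, " method=", method, " tradeoff_fraction=", tf, " rank=", rank)

  if (identical(cfg("input", "synthetic"), "synthetic")) {
    cohort <- make_cohort(
      n_samples = as.integer(cfg("n_samples", 20)),
      n_groups = as.integer(cfg("n_groups", 5)),
      members_per_group = as.integer(cfg("members_per_group", 3)),
      planted_correlation = as.numeric(cfg("planted_correlation", 0.8)),
      seed = seed
    )
    logf("generated synthetic cohort: ", length(cohort$models), " taxa, ",
         length(unique(cohort$abundances$sample_id)), " samples")
  } else {
    taxonomy <- readr::read_tsv(cfg("taxonomy_tsv"), show_col_types = FALSE)
    abund <- readr::read_tsv(cfg("abundance_tsv"), show_col_types = FALSE)
    repl <- readr::read_tsv(cfg("replication_tsv"), show_col_types = FALSE)
    mdir <- cfg("models_dir")
    files <- list.files(mdir, pattern = "\\.(xml|sbml|json)$", full.names = TRUE)
    models <- purrr::map(files, read_gem)
    names(models) <- vapply(models, `[[`, "", "id")
    med <- if (!is.null(cfg("medium_csv"))) read_medium(cfg("medium_csv")) else NULL
    cohort <- list(models = models, abundances = as_abundance_table_(abund),
                   taxonomy = taxonomy, replication = as_growth_vector_(repl),
                   medium = med)
    logf("loaded ", length(models), " models from ", mdir)
  }

  scheme <- group_by_rank(cohort$taxonomy, rank)
  rand <- random_grouping(cohort$taxonomy$taxon_id, scheme, seed = derive_seed_(seed, 99))
  reference <- reference_replication_rates(cohort$replication, scheme, cohort$abundances)

  pre <- pre_phylo_growth(cohort$models, cohort$abundances, scheme, cohort$medium,
                          method, tf)
  post <- post_phylo_growth(cohort$models, cohort$abundances, scheme, cohort$medium,
                            method, tf)
  pre_rand <- pre_phylo_growth(cohort$models, cohort$abundances, rand, cohort$medium,
                               method, tf)
  ref_rand <- reference_replication_rates(cohort$replication, rand, cohort$abundances)

  correlations <- dplyr::bind_rows(
    dplyr::mutate(growth_correlation(pre, reference), flow = "pre", .before = 1),
    dplyr::mutate(growth_correlation(post, reference), flow = "post", .before = 1),
    dplyr::mutate(growth_correlation(pre_rand, ref_rand), flow = "pre_random", .before = 1)
  )
  logf("correlations: ", paste(correlations$flow, round(correlations$pearson_r, 4),
                               sep = "=", collapse = ", "))

  # redundancy: mean pairwise member distance, pooled vs unpooled, per sample
  pg <- build_phylogems(cohort$models, cohort$abundances, scheme)
  jacc <- dplyr::bind_rows(
    dplyr::mutate(jaccard_report_(cohort$models, cohort$abundances), community = "standard"),
    dplyr::mutate(jaccard_report_(pg$models, pg$abundances), community = "pooled")
  )

  readr::write_tsv(pre, file.path(out_dir, "growth_pre.tsv"))
  readr::write_tsv(post, file.path(out_dir, "growth_post.tsv"))
  readr::write_tsv(correlations, file.path(out_dir, "correlations.tsv"))
  readr::write_tsv(jacc, file.path(out_dir, "jaccard.tsv"))

  if (isTRUE(as.logical(cfg("run_sensitivity", "false")))) {
    pipe_fun <- function(tab) pre_phylo_growth(cohort$models, tab, scheme,
                                               cohort$medium, method, tf)
    sens <- sensitivity_analysis(pipe_fun, cohort$abundances, reference, seed = seed)
    readr::write_tsv(tidy(sens), file.path(out_dir, "sensitivity.tsv"))
    logf("sensitivity: baseline r=", round(sens$baseline, 4))
  }
  if (isTRUE(as.logical(cfg("run_knockout", "false")))) {
    s1 <- cohort$abundances$sample_id[1]
    df <- cohort$abundances[cohort$abundances$sample_id == s1, ]
    cm <- build_community(cohort$models, stats::setNames(df$abundance, df$taxon_id),
                          medium = cohort$medium)
    ko <- knockout_screen(cm, method = method, tradeoff_fraction = tf)
    write_interaction_graph(ko, file.path(out_dir, "knockout_edges.tsv"))
    logf("knockout screen on sample ", s1, ": ", nrow(ko), " edges")
  }
  if (isTRUE(as.logical(cfg("run_interactions", "false")))) {
    caps <- purrr::map(cohort$models, exchange_capabilities, medium = cohort$medium)
    ig <- detect_interactions(unname(caps))
    write_interaction_graph(ig, file.path(out_dir, "interactions.tsv"))
    logf("metabolite interactions: ", nrow(ig), " edges")
  }

  logf("done")
  invisible(list(pre = pre, post = post, correlations = correlations,
                 jaccard = jacc, out_dir = out_dir))
}

# per-sample mean pairwise reaction-set distance of the community members
jaccard_report_ <- function(models, abundances, abundance_cutoff = 1e-4) {
  abundances <- as_abundance_table_(abundances)
  out <- abundances |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      ab <- stats::setNames(df$abundance, df$taxon_id)
      cm <- build_community(models[names(ab)[ab > 0]], ab[ab > 0],
                            abundance_cutoff = abundance_cutoff)
      d <- suppressWarnings(inter_level_distances(cm))
      if (nrow(d) == 0) return(NULL)
      tibble::tibble(sample_id = key$sample_id,
                     n_members = nrow(cm$members),
                     mean_jaccard = mean(d$jaccard_distance),
                     median_jaccard = stats::median(d$jaccard_distance))
    })
  dplyr::bind_rows(out)
}
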