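#' Grouping schemes: partitions of taxa into merge groups
#'
#' A grouping scheme is a tibble with columns `taxon_id` and `group_id`
#' that partitions a set of taxa (each taxon in exactly one group), plus a
#' `method` attribute recording how it was built. Schemes drive both the
#' model merging and the post-hoc growth aggregation.
#'
#' @param x Data frame with columns `taxon_id`, `group_id`.
#' @param method One of `"rank"`, `"distance"`, `"manual"`, `"random"`.
#' @return A `grouping_scheme` tibble.
#' @export
grouping_scheme <- function(x, method = c("manual", "rank", "distance", "random")) {
  method <- match.arg(method)
  assert_(is.data.frame(x) && all(c("taxon_id", "group_id") %in% names(x)),
          "grouping scheme needs columns taxon_id, group_id")
  out <- tibble::as_tibble(x)[, c("taxon_id", "group_id")]
  assert_(!anyDuplicated(out$taxon_id), "grouping scheme must assign each taxon exactly once")
  structure(out, class = c("grouping_scheme", class(tibble::tibble())),
            method = method)
}

#' List the groups of a grouping scheme
#'
#' @param scheme A `grouping_scheme`.
#' @return Named list group_id -> character vector of taxon ids.
#' @export
groups_in_scheme <- function(scheme) split(scheme$taxon_id, scheme$group_id)

groups_as_list_ <- groups_in_scheme

#' Group taxa by a taxonomic rank
#'
#' @param taxa Data frame with a `taxon_id` column and one column per
#'   lineage rank (e.g. `order`, `family`, `genus`).
#' @param rank Name of the rank column to pool on.
#' @return A `grouping_scheme` whose group ids are the taxon names at the
#'   requested rank.
#' @examples
#' tax <- tibble::tibble(taxon_id = c("a", "b", "c"),
#'                       family = c("f1", "f1", "f2"))
#' group_by_rank(tax, "family")
#' @export
group_by_rank <- function(taxa, rank) {
  assert_(is.data.frame(taxa) && "taxon_id" %in% names(taxa), "taxa needs a taxon_id column")
  assert_(rank %in% names(taxa), paste0("rank '", rank, "' not present in the lineage table"))
  vals <- taxa[[rank]]
  bad <- taxa$taxon_id[is.na(vals) | !nzchar(as.character(vals))]
  assert_(length(bad) == 0,
          paste0("lineage lacks rank '", rank, "' for: ", paste(bad, collapse = ", ")))
  grouping_scheme(tibble::tibble(taxon_id = taxa$taxon_id, group_id = as.character(vals)),
                  method = "rank")
}

#' Group taxa by a similarity threshold
#'
#' Joins every pair of taxa with similarity at or above `threshold` and
#' takes connected components (single linkage) as groups, the minimal
#' closure that turns "similar pairs are merged" into a partition.
#' Complete linkage (every in-group pair above threshold) is available as
#' an alternative.
#'
#' @param sim Symmetric similarity matrix with values in `[0, 1]`, unit
#'   diagonal, and taxon ids as dimnames (or a square data frame).
#' @param threshold Similarity at or above which models merge (default
#'   0.6).
#' @param linkage `"single"` (components) or `"complete"`.
#' @return A `grouping_scheme` with groups `dist_1`, `dist_2`, ...
#' @export
group_by_distance <- function(sim, threshold = 0.6, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (is.data.frame(sim)) sim <- as.matrix(sim)
  assert_(is.matrix(sim) && nrow(sim) == ncol(sim), "similarity matrix must be square")
  assert_(!is.null(rownames(sim)), "similarity matrix needs taxon ids as dimnames")
  assert_(max(abs(sim - t(sim))) < 1e-8, "similarity matrix must be symmetric")
  assert_(all(sim >= 0 & sim <= 1), "similarities must lie in [0, 1]")
  assert_(is.numeric(threshold) && length(threshold) == 1 && threshold >= 0 && threshold <= 1,
          "threshold must lie in [0, 1]")
  taxa <- rownames(sim)
  comp <- if (linkage == "single") {
    adj <- sim >= threshold
    diag(adj) <- TRUE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    igraph::components(g)$membership
  } else {
    if (length(taxa) == 1) stats::setNames(1L, taxa) else {
      hc <- stats::hclust(stats::as.dist(1 - sim), method = "complete")
      stats::cutree(hc, h = 1 - threshold)
    }
  }
  grouping_scheme(tibble::tibble(taxon_id = taxa,
                                 group_id = paste0("dist_", comp[taxa])),
                  method = "distance")
}

#' Group taxa by explicit merge sets
#'
#' Listed sets become groups (named after their members joined by `+`);
#' all other taxa stay singletons. Used e.g. to merge two taxa with known
#' metabolic cooperation.
#'
#' @param taxa Character vector of taxon ids, or a data frame with a
#'   `taxon_id` column.
#' @param merge_sets List of disjoint character vectors.
#' @return A `grouping_scheme`.
#' @export
group_manual <- function(taxa, merge_sets = list()) {
  ids <- if (is.data.frame(taxa)) taxa$taxon_id else taxa
  all_listed <- unlist(merge_sets)
  assert_(!anyDuplicated(all_listed), "merge sets must be disjoint")
  missing <- setdiff(all_listed, ids)
  assert_(length(missing) == 0,
          paste0("merge sets name unknown taxa: ", paste(missing, collapse = ", ")))
  group_id <- stats::setNames(ids, ids)
  for (set in merge_sets) {
    group_id[set] <- paste(sort(set), collapse = "+")
  }
  grouping_scheme(tibble::tibble(taxon_id = ids, group_id = unname(group_id[ids])),
                  method = "manual")
}

#' Random grouping null: shuffle membership, keep group sizes
#'
#' Draws a random partition with exactly the template's group-size
#' multiset by permuting the taxa uniformly, the null model against which
#' structured (taxonomy- or distance-based) groupings are compared.
#'
#' @param taxa Character vector or data frame with `taxon_id`.
#' @param template A `grouping_scheme` over the same taxa.
#' @param seed Integer; same seed, same grouping.
#' @return A `grouping_scheme` with groups `rand_1`, `rand_2`, ...
#' @export
random_grouping <- function(taxa, template, seed) {
  ids <- if (is.data.frame(taxa)) taxa$taxon_id else taxa
  assert_(setequal(ids, template$taxon_id), "template must partition the same taxa")
  sizes <- vapply(groups_as_list_(template), length, 0L)
  perm <- with_seed_(seed, sample(ids))
  grouping_scheme(
    tibble::tibble(taxon_id = perm,
                   group_id = paste0("rand_", rep(seq_along(sizes), times = unname(sizes)))),
    method = "random"
  )
}

#' Sum abundances of merged taxa
#'
#' Per sample, the abundance of a group is the sum of its members'
#' abundances, so per-sample totals are preserved exactly.
#'
#' @param table Abundance table: tibble with `sample_id`, `taxon_id`,
#'   `abundance`.
#' @param scheme A `grouping_scheme` covering every taxon in the table.
#' @return An abundance table keyed by group ids (in `taxon_id`).
#' @export
aggregate_abundances <- function(table, scheme) {
  table <- as_abundance_table_(table)
  unmapped <- setdiff(unique(table$taxon_id), scheme$taxon_id)
  assert_(length(unmapped) == 0,
          paste0("taxa missing from the grouping scheme: ", paste(unmapped, collapse = ", ")))
  table |>
    dplyr::inner_join(tibble::as_tibble(scheme), by = "taxon_id") |>
    dplyr::group_by(.data$sample_id, taxon_id = .data$group_id) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
}
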