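# Reaction-set redundancy metrics. A community of highly similar models
# is redundant: its members' reaction sets overlap strongly and pairwise
# Jaccard distances are low. Pooling related models should *raise* the
# mean pairwise distance inside a community (the surviving models are the
# dissimilar ones) -- the quantity these helpers report.

#' Jaccard distance between two sets
#'
#' `1 - |intersection| / |union|` over arbitrary atomic vectors treated
#' as sets.
#'
#' @param a,b Vectors (coerced to sets); at least one element each.
#' @return Distance in `[0, 1]`.
#' @examples
#' jaccard_distance(letters[1:4], letters[3:7])  # 1 - 2/7
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  assert_(length(a) > 0 && length(b) > 0, "Jaccard distance of empty sets is undefined")
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise reaction-set distances between community members
#'
#' Jaccard distances over the members' reaction-id sets (member suffixes
#' and biomass reactions excluded), one row per unordered pair.
#'
#' @param cm A `community_model` with at least two members.
#' @return Tibble `unit_a`, `unit_b`, `jaccard_distance`; empty (with a
#'   warning) for fewer than two members.
#' @export
inter_level_distances <- function(cm) {
  assert_(inherits(cm, "community_model"), "cm must be a community_model")
  empty <- tibble::tibble(unit_a = character(0), unit_b = character(0),
                          jaccard_distance = numeric(0))
  if (nrow(cm$members) < 2) {
    rlang::warn("inter_level_distances: fewer than 2 members, nothing to compare")
    return(empty)
  }
  sets <- purrr::map(cm$members$model, reaction_set)
  names(sets) <- cm$members$taxon_id
  pairs <- utils::combn(cm$members$taxon_id, 2)
  tibble::tibble(
    unit_a = pairs[1, ],
    unit_b = pairs[2, ],
    jaccard_distance = purrr::map2_dbl(pairs[1, ], pairs[2, ],
                                       ~ jaccard_distance(sets[[.x]], sets[[.y]]))
  )
}

#' Reaction-set distance from each member to its merged model
#'
#' For members that were merged into a pooled model, each member's
#' reaction set is a subset of the merged set, so the distance reduces to
#' `1 - |member| / |merged|` (biomass reactions excluded on both sides).
#'
#' @param merged The merged [gem()].
#' @param members List of the member [gem()]s that went into the merge.
#' @return Tibble `unit_id`, `jaccard_distance`.
#' @export
intra_level_distances <- function(merged, members) {
  validate_gem(merged)
  merged_set <- reaction_set(merged)
  out <- purrr::imap(members, function(mod, nm) {
    id <- if (is.character(nm) && nzchar(nm)) nm else mod$id
    tibble::tibble(unit_id = id,
                   jaccard_distance = jaccard_distance(reaction_set(mod), merged_set))
  })
  dplyr::bind_rows(unname(out))
}
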