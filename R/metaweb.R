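#' Predict the all-pairs probabilistic metanetwork
#'
#' Applies a fitted interaction model to every resource x consumer pair in
#' the region, irrespective of co-occurrence, giving the probabilistic
#' metanetwork of feasible interactions.
#'
#' @param model A `"link_model"`.
#' @param resource,consumer Imputed trait tibbles.
#' @return Tibble `(resource_id, consumer_id, probability)` with exactly
#'   `nrow(resource) * nrow(consumer)` rows.
#' @export
predict_metaweb <- function(model, resource, consumer) {
  predict(model, all_pairs(resource, consumer), resource, consumer)
}

#' Prune a probabilistic metanetwork to binary links
#'
#' Keeps an interaction when its predicted probability strictly exceeds the
#' threshold (`probability > tau`), the rule used to prune the case-study
#' metanetwork at 0.4.
#'
#' @param web Metaweb tibble with a `probability` column.
#' @param tau Threshold in `[0, 1]` (default 0.4); see [choose_threshold()]
#'   for data-driven alternatives.
#' @return `web` with an integer `link` column (attribute `"threshold"`
#'   records `tau`).
#' @export
prune_metaweb <- function(web, tau = 0.4) {
  if (!is.numeric(tau) || tau < 0 || tau > 1) {
    stop_config("`tau` must lie in [0, 1]")
  }
  web$link <- as.integer(web$probability > tau)
  attr(web, "threshold") <- tau
  web
}

#' Species-level rewiring capacity
#'
#' The rewiring capacity of a species is the size of its fundamental
#' functional interaction niche: the standardized functional richness
#' ([fric_standardized()]) of its predicted partners in the pruned
#' metanetwork, measured in the partner trophic level's trait space. A
#' species linked to partners spanning the whole partner trait space scores
#' 1; an isolated species scores 0.
#'
#' @param web Pruned metaweb (tibble with a `link` column).
#' @param level Focal trophic level: `"consumer"` scores each consumer by
#'   its resource partners, `"resource"` vice versa.
#' @param partner_space `"trait_space"` of the partner level, built on all
#'   partner-level species.
#' @param standardize `"global_hull"` (default) divides each raw hull
#'   volume by the hull volume of all partner-level species;
#'   `"max_capacity"` divides by the largest observed raw volume instead.
#' @return Tibble `(species_id, trophic_level, n_partners, fric_raw,
#'   fric_std, degenerate, isolated)` with one row per focal species;
#'   attribute `"standardize"` records the denominator convention.
#' @export
rewiring_capacity <- function(web, level = c("consumer", "resource"),
                              partner_space,
                              standardize = c("global_hull", "max_capacity")) {
  level <- match.arg(level)
  standardize <- match.arg(standardize)
  if (!"link" %in% names(web)) {
    stop_data("metaweb has no `link` column; prune it first")
  }
  focal_col <- if (level == "consumer") "consumer_id" else "resource_id"
  partner_col <- if (level == "consumer") "resource_id" else "consumer_id"
  focal_ids <- unique(web[[focal_col]])
  partner_sets <- split(web[[partner_col]][web$link == 1L],
                        web[[focal_col]][web$link == 1L])
  rows <- purrr::map_dfr(focal_ids, function(id) {
    partners <- partner_sets[[id]] %||% character(0)
    fr <- fric_standardized(partners, partner_space)
    tibble::tibble(
      species_id = id, trophic_level = level,
      n_partners = length(partners),
      fric_raw = attr(fr, "volume"),
      fric_std = as.numeric(fr),
      degenerate = attr(fr, "degenerate"),
      isolated = length(partners) == 0L
    )
  })
  if (standardize == "max_capacity") {
    mx <- max(rows$fric_raw)
    rows$fric_std <- if (mx > 0) pmin(1, rows$fric_raw / mx) else 0
  }
  attr(rows, "standardize") <- standardize
  rows
}
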