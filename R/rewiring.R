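#' Species present in one grid cell at one trophic level
#'
#' @param occurrences Occurrence tibble `(cell_id, lon_min, lat_min,
#'   species_id, trophic_level)`.
#' @param cell A `cell_id`.
#' @param level `"resource"` or `"consumer"`.
#' @return Character vector of species ids (possibly empty).
#' @export
local_community <- function(occurrences, cell,
                            level = c("resource", "consumer")) {
  level <- match.arg(level)
  known <- unique(c(occurrences$cell_id, attr(occurrences, "cells")$cell_id))
  if (!cell %in% known) stop_key(sprintf("unknown cell_id: %s", cell))
  occurrences$species_id[occurrences$cell_id == cell &
                           occurrences$trophic_level == level]
}

#' Rewiring potential of one trophic level in one grid cell
#'
#' The partner pool of a cell is the union, over the focal-level species
#' present there, of their partner sets in the pruned metanetwork; partners
#' are pooled from the metanetwork regardless of whether they occur locally
#' (set `local_partners = TRUE` to restrict the pool to locally present
#' partners as a sensitivity analysis). The rewiring potential is the
#' standardized functional richness of that pool in the partner trait
#' space. An empty focal community gives `NA` (no species is different from
#' species with no functional spread); a pool too small for a hull gives 0,
#' flagged degenerate.
#'
#' @inheritParams local_community
#' @param web Pruned metaweb (tibble with `link` column).
#' @param partner_space `"trait_space"` of the partner level.
#' @param level Focal trophic level.
#' @param local_partners Restrict the pool to partners present in the cell?
#'   (default `FALSE`).
#' @return Value in `[0, 1]` or `NA`, with attributes `degenerate` and
#'   `pool_size`.
#' @export
rewiring_potential <- function(occurrences, web, partner_space, cell,
                               level = c("resource", "consumer"),
                               local_partners = FALSE) {
  level <- match.arg(level)
  community <- local_community(occurrences, cell, level)
  if (length(community) == 0) {
    return(structure(NA_real_, degenerate = NA, pool_size = 0L))
  }
  pool <- .partner_pool(web, community, level)
  if (local_partners) {
    partner_level <- if (level == "resource") "consumer" else "resource"
    pool <- intersect(pool, local_community(occurrences, cell, partner_level))
  }
  fr <- fric_standardized(pool, partner_space)
  structure(as.numeric(fr), degenerate = attr(fr, "degenerate"),
            pool_size = length(pool))
}

.partner_pool <- function(web, community, level) {
  focal_col <- if (level == "consumer") "consumer_id" else "resource_id"
  partner_col <- if (level == "consumer") "resource_id" else "consumer_id"
  linked <- web$link == 1L & web[[focal_col]] %in% community
  unique(web[[partner_col]][linked])
}

#' Map rewiring potential and richness over the occurrence grid
#'
#' Computes, for every grid cell and both trophic levels, the local species
#' richness, the metanetwork partner pool size, the rewiring potential
#' ([rewiring_potential()]), and the 3 x 3 bivariate richness-by-potential
#' class ([bivariate_classes()], assigned per level). Cells where no species
#' of the focal level occurs get `NA` potential.
#'
#' @inheritParams rewiring_potential
#' @param resource_space,consumer_space `"trait_space"` objects for the two
#'   levels (the partner space of the other level's species).
#' @param cells Tibble `(cell_id, lon_min, lat_min)` of cells to map;
#'   defaults to the `cells` attribute of `occurrences`, else the occupied
#'   cells.
#' @return Tibble with one row per cell per level: `cell_id`, `lon`, `lat`
#'   (cell centroids), `trophic_level`, `richness`, `partner_pool_size`,
#'   `potential`, `degenerate`, `bivariate_class`. The `"summary"` attribute
#'   holds per-level `n_cells`, `n_na`, `frac_potential_gt_0.8`.
#' @export
potential_map <- function(occurrences, web, resource_space, consumer_space,
                          cells = NULL, local_partners = FALSE) {
  cells <- cells %||% attr(occurrences, "cells") %||%
    dplyr::distinct(occurrences, .data$cell_id, .data$lon_min, .data$lat_min)
  half <- (attr(occurrences, "cell_size") %||% 0.5) / 2
  if (!"link" %in% names(web)) {
    stop_data("metaweb has no `link` column; prune it first")
  }
  # per-species partner sets, then one cached hull per distinct pool:
  # many cells share the same pooled partner set
  partner_sets <- list(
    resource = split(web$consumer_id[web$link == 1L],
                     web$resource_id[web$link == 1L]),
    consumer = split(web$resource_id[web$link == 1L],
                     web$consumer_id[web$link == 1L])
  )
  spaces <- list(resource = consumer_space, consumer = resource_space)
  cache <- new.env(parent = emptyenv())
  pooled_fric <- function(pool, level) {
    key <- paste(level, paste(sort(pool), collapse = ","))
    if (is.null(cache[[key]])) {
      cache[[key]] <- fric_standardized(pool, spaces[[level]])
    }
    cache[[key]]
  }
  occ_split <- split(
    occurrences[c("species_id", "trophic_level")],
    factor(occurrences$cell_id, levels = cells$cell_id)
  )
  out <- purrr::map_dfr(c("resource", "consumer"), function(level) {
    purrr::map_dfr(seq_len(nrow(cells)), function(i) {
      g <- occ_split[[cells$cell_id[i]]]
      community <- g$species_id[g$trophic_level == level]
      if (length(community) == 0) {
        pot <- NA_real_
        pool_n <- 0L
        degen <- NA
      } else {
        pool <- unique(unlist(partner_sets[[level]][community],
                              use.names = FALSE))
        pool <- pool %||% character(0)
        fr <- pooled_fric(pool, level)
        pot <- as.numeric(fr)
        pool_n <- length(pool)
        degen <- attr(fr, "degenerate")
      }
      tibble::tibble(
        cell_id = cells$cell_id[i],
        lon = cells$lon_min[i] + half, lat = cells$lat_min[i] + half,
        trophic_level = level,
        richness = length(community),
        partner_pool_size = pool_n,
        potential = pot, degenerate = degen
      )
    })
  })
  out <- out |>
    dplyr::group_by(.data$trophic_level) |>
    dplyr::mutate(bivariate_class = bivariate_classes(.data$potential,
                                                      .data$richness)) |>
    dplyr::ungroup()
  attr(out, "summary") <- potential_summary(out)
  attr(out, "local_partners") <- local_partners
  out
}

#' Per-level summary of a rewiring map
#'
#' @param map Tibble from [potential_map()].
#' @return Tibble per trophic level: `n_cells`, `n_na`,
#'   `frac_potential_gt_0.8` (fraction of non-NA cells with potential
#'   above 0.8).
#' @export
potential_summary <- function(map) {
  map |>
    dplyr::group_by(.data$trophic_level) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_na = sum(is.na(.data$potential)),
      frac_potential_gt_0.8 =
        mean(.data$potential[!is.na(.data$potential)] > 0.8),
      .groups = "drop"
    )
}

#' Joint tercile classes for co-mapping potential and richness
#'
#' Bins each variable into terciles over its non-NA values (quantile
#' breaks; values tied with a break go to the lower bin) and combines them
#' as `class = 3 * (richness_bin - 1) + potential_bin`, the 3 x 3 bivariate
#' legend used for co-mapping. `NA` in either variable propagates.
#'
#' @param potential,richness Aligned numeric vectors.
#' @param n_bins Bins per variable (default 3).
#' @return Integer vector of classes `1..n_bins^2` (or `NA`).
#' @export
bivariate_classes <- function(potential, richness, n_bins = 3) {
  stopifnot(length(potential) == length(richness))
  bin <- function(x) {
    ok <- !is.na(x)
    if (!any(ok)) return(rep(NA_integer_, length(x)))
    breaks <- quantile(x[ok], probs = seq_len(n_bins - 1) / n_bins,
                       names = FALSE)
    b <- rep(NA_integer_, length(x))
    b[ok] <- 1L + rowSums(outer(x[ok], breaks, `>`))
    b
  }
  pb <- bin(potential)
  rb <- bin(richness)
  as.integer(n_bins * (rb - 1L) + pb)
}
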