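#' Assemble the model training set from site networks
#'
#' Pools site networks to pair-level binary labels: a resource-consumer pair
#' is a presence (label 1) if it was observed interacting in at least one
#' site, and an inferred absence (label 0) if the two species co-occurred in
#' at least one site but were never observed interacting anywhere. Pairs
#' that never co-occur carry no information and are excluded.
#'
#' @param networks A `"site_networks"` list (`occurrences`, `edges`), e.g.
#'   from [gen_site_networks()] or [read_networks()].
#' @return A tibble `(resource_id, consumer_id, label)` with one row per
#'   distinct co-occurring pair.
#' @export
#' @examples
#' nets <- list(
#'   occurrences = tibble::tibble(
#'     site_id = "s1", species_id = c("P1", "P2", "H1", "H2"),
#'     trophic_level = c("resource", "resource", "consumer", "consumer"),
#'     lon = 0, lat = 0
#'   ),
#'   edges = tibble::tibble(site_id = "s1", resource_id = "P1",
#'                          consumer_id = "H1")
#' )
#' assemble_training_pairs(nets) # 1 presence, 3 inferred absences
assemble_training_pairs <- function(networks) {
  .validate_networks(networks)
  occ <- networks$occurrences
  cooc <- occ |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_map(function(g, key) {
      tidyr::expand_grid(
        resource_id = g$species_id[g$trophic_level == "resource"],
        consumer_id = g$species_id[g$trophic_level == "consumer"]
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::distinct()
  observed <- dplyr::distinct(networks$edges, .data$resource_id,
                              .data$consumer_id)
  cooc |>
    dplyr::mutate(label = as.integer(
      paste(.data$resource_id, .data$consumer_id) %in%
        paste(observed$resource_id, observed$consumer_id)
    )) |>
    dplyr::arrange(.data$resource_id, .data$consumer_id)
}

#' Impute missing trait values by taxon group
#'
#' Fills missing numeric values with the taxon-group mean and missing
#' categorical values with the taxon-group mode (ties broken by the
#' lexicographically smallest level), falling back to the global mean/mode
#' when the group holds no observed value. Imputed cells are recorded in the
#' `"imputed"` attribute of the result.
#'
#' @param table Trait tibble with `species_id` and `taxon_group` columns.
#' @param schema Optional `"trait_schema"`; defaults to the table's schema
#'   attribute or an inferred one.
#' @return The completed trait tibble; attribute `"imputed"` is a tibble
#'   `(species_id, trait)` flagging every filled cell.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   species_id = c("a", "b", "c"), trophic_level = "resource",
#'   taxon_group = "g1", height = c(2, 4, NA)
#' )
#' impute_traits(tab)$height # 2 4 3
impute_traits <- function(table, schema = NULL) {
  if (is.null(schema)) schema <- attr(table, "schema") %||% infer_schema(table)
  flags <- list()
  for (cl in names(schema)) {
    x <- table[[cl]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) {
      stop_data(sprintf("trait `%s` has no observed values to impute from", cl))
    }
    fill_num <- function(v) mean(v, na.rm = TRUE)
    fill_mode <- function(v) {
      tab <- table(v[!is.na(v)])
      # ties: lexicographically smallest level (table() orders names)
      names(tab)[which.max(tab)]
    }
    fill <- if (schema[[cl]]$type == "numeric") fill_num else fill_mode
    global <- fill(x)
    grp_fill <- vapply(split(x, table$taxon_group), function(v) {
      if (all(is.na(v))) if (is.numeric(x)) NA_real_ else NA_character_
      else fill(v)
    }, if (schema[[cl]]$type == "numeric") numeric(1) else character(1))
    repl <- grp_fill[table$taxon_group[miss]]
    repl[is.na(repl)] <- global
    if (schema[[cl]]$type == "numeric") {
      table[[cl]][miss] <- as.numeric(repl)
    } else {
      table[[cl]][miss] <- as.character(repl)
    }
    flags[[cl]] <- tibble::tibble(species_id = table$species_id[miss],
                                  trait = cl)
  }
  attr(table, "schema") <- schema
  attr(table, "imputed") <- if (length(flags)) {
    dplyr::bind_rows(flags)
  } else {
    tibble::tibble(species_id = character(), trait = character())
  }
  table
}
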