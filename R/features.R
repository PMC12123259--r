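#' All-pairs index of two trait tables
#'
#' @param resource,consumer Trait tibbles.
#' @return Tibble `(resource_id, consumer_id)` with one row per pair
#'   (`nrow(resource) * nrow(consumer)` rows).
#' @export
all_pairs <- function(resource, consumer) {
  tidyr::expand_grid(resource_id = resource$species_id,
                     consumer_id = consumer$species_id)
}

#' Build the pair-level feature table for the interaction model
#'
#' One row per (resource, consumer) pair holding the resource's trait values
#' (prefixed `r_`), the consumer's (prefixed `c_`), and both taxon groups.
#' Categorical traits and taxon groups are encoded as integer codes with the
#' level-to-code mapping recorded in the `"encoding"` attribute; passing the
#' stored encoding back guarantees the identical scheme at prediction time,
#' and any level or column drift between fit and predict is a hard error.
#' Feature columns are sorted by name so the layout is deterministic.
#'
#' @param pairs Tibble with `resource_id`, `consumer_id` and optionally
#'   `label`.
#' @param resource,consumer Imputed trait tibbles.
#' @param encoding Encoding map from a previous call (named list of level
#'   vectors); `NULL` builds a fresh one from the data.
#' @return Tibble of id columns, optional `label`, and numeric feature
#'   columns; attribute `"encoding"` carries the categorical code map.
#' @export
build_features <- function(pairs, resource, consumer, encoding = NULL) {
  miss_r <- setdiff(pairs$resource_id, resource$species_id)
  miss_c <- setdiff(pairs$consumer_id, consumer$species_id)
  if (length(miss_r) || length(miss_c)) {
    stop_key(sprintf("unresolvable species id(s): %s",
                     paste(head(c(miss_r, miss_c), 5), collapse = ", ")))
  }
  prep <- function(tab, prefix) {
    keep <- setdiff(names(tab), c("trophic_level"))
    tab <- tab[keep]
    names(tab) <- ifelse(names(tab) == "species_id", "species_id",
                         paste0(prefix, names(tab)))
    tab
  }
  wide <- pairs |>
    dplyr::left_join(prep(resource, "r_"),
                     by = c(resource_id = "species_id")) |>
    dplyr::left_join(prep(consumer, "c_"),
                     by = c(consumer_id = "species_id"))
  id_cols <- intersect(c("resource_id", "consumer_id", "label"), names(wide))
  feat_cols <- sort(setdiff(names(wide), id_cols))
  cat_cols <- feat_cols[!vapply(wide[feat_cols], is.numeric, logical(1))]
  if (!is.null(encoding)) {
    drift <- union(setdiff(cat_cols, names(encoding)),
                   setdiff(names(encoding), cat_cols))
    if (length(drift)) {
      stop_schema(sprintf("feature schema drift in column(s): %s",
                          paste(drift, collapse = ", ")))
    }
  } else {
    encoding <- lapply(wide[cat_cols], function(v) sort(unique(v)))
  }
  for (cl in cat_cols) {
    codes <- match(wide[[cl]], encoding[[cl]])
    if (anyNA(codes)) {
      bad <- unique(wide[[cl]][is.na(codes)])
      stop_schema(sprintf("column `%s`: level(s) %s unseen at fit time",
                          cl, paste(head(bad, 5), collapse = ", ")))
    }
    wide[[cl]] <- as.integer(codes)
  }
  out <- wide[c(id_cols, feat_cols)]
  attr(out, "encoding") <- encoding
  attr(out, "feature_names") <- feat_cols
  out
}

.feature_matrix <- function(features) {
  cols <- attr(features, "feature_names")
  as.matrix(features[cols])
}
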