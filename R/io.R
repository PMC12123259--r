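#' Declare a trait-table schema
#'
#' A schema types every trait column of a trait table: numeric columns carry
#' an optional unit, categorical columns a finite level set. The identity
#' columns (`species_id`, `trophic_level`, `taxon_group`) are implicit.
#'
#' @param ... Named column specifications, each created with
#'   [trait_numeric()] or [trait_categorical()].
#' @return A named list with class `"trait_schema"`.
#' @export
#' @examples
#' sc <- trait_schema(
#'   corolla_length = trait_numeric("mm"),
#'   flower_colour = trait_categorical(c("red", "white"))
#' )
trait_schema <- function(...) {
  cols <- list(...)
  if (length(cols) == 0 || is.null(names(cols)) || any(names(cols) == "")) {
    stop_schema("every schema column must be named")
  }
  structure(cols, class = "trait_schema")
}

#' @rdname trait_schema
#' @param unit Unit string for a numeric trait (documentation only).
#' @export
trait_numeric <- function(unit = NA_character_) {
  list(type = "numeric", unit = unit)
}

#' @rdname trait_schema
#' @param levels Character vector of allowed levels.
#' @export
trait_categorical <- function(levels) {
  list(type = "categorical", levels = as.character(levels))
}

#' Infer a schema from a typed trait table
#'
#' Numeric columns become numeric traits; character columns become
#' categorical traits with levels equal to their sorted observed values.
#'
#' @param table A trait table (tibble).
#' @return A `"trait_schema"`.
#' @export
infer_schema <- function(table) {
  tcols <- setdiff(names(table), .id_cols)
  specs <- lapply(tcols, function(cl) {
    if (is.numeric(table[[cl]])) {
      trait_numeric()
    } else {
      trait_categorical(sort(unique(stats::na.omit(as.character(table[[cl]])))))
    }
  })
  structure(setNames(specs, tcols), class = "trait_schema")
}

.id_cols <- c("species_id", "trophic_level", "taxon_group")

.schema_path <- function(path) {
  paste0(sub("\\.csv$", "", path), "_schema.json")
}

#' Read and write trait tables
#'
#' Trait tables are UTF-8 CSV files with a mandatory header, columns
#' `species_id`, `trophic_level`, `taxon_group` plus one column per trait,
#' and `""` marking missing values. The column types live in a sidecar JSON
#' schema (written next to the CSV as `<name>_schema.json`). Reading is
#' strict: unknown columns, duplicated ids, non-numeric values in numeric
#' traits and out-of-level categorical values are rejected with an error
#' naming the offending row/column; nothing is silently coerced.
#'
#' @param path CSV file path.
#' @param schema A `"trait_schema"`; when `NULL`, [read_traits()] loads the
#'   sidecar JSON and [write_traits()] infers one from the table.
#' @param table Trait tibble to write.
#' @return `read_traits()` returns the trait tibble with the schema attached
#'   as attribute `"schema"`; `write_traits()` returns `path` invisibly.
#' @export
read_traits <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  if (is.null(schema)) {
    sp <- .schema_path(path)
    if (!file.exists(sp)) {
      stop_schema(sprintf("no schema given and no sidecar found at %s", sp))
    }
    schema <- .schema_from_json(sp)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = "", progress = FALSE)
  for (cl in .id_cols) {
    if (!cl %in% names(raw)) {
      stop_schema(sprintf("column `%s` missing from %s", cl, path))
    }
  }
  extra <- setdiff(names(raw), c(.id_cols, names(schema)))
  if (length(extra)) {
    stop_schema(sprintf("unknown column(s) not in schema: %s",
                        paste(extra, collapse = ", ")))
  }
  missing_tr <- setdiff(names(schema), names(raw))
  if (length(missing_tr)) {
    stop_schema(sprintf("schema trait(s) absent from file: %s",
                        paste(missing_tr, collapse = ", ")))
  }
  dup <- raw$species_id[duplicated(raw$species_id)]
  if (length(dup)) {
    stop_schema(sprintf("duplicated species_id: %s",
                        paste(unique(dup), collapse = ", ")))
  }
  for (cl in names(schema)) {
    spec <- schema[[cl]]
    if (spec$type == "numeric") {
      num <- suppressWarnings(as.numeric(raw[[cl]]))
      bad <- which(is.na(num) & !is.na(raw[[cl]]))
      if (length(bad)) {
        stop_schema(sprintf(
          "column `%s`: non-numeric value \"%s\" at row %d",
          cl, raw[[cl]][bad[1]], bad[1]
        ))
      }
      raw[[cl]] <- num
    } else {
      bad <- which(!is.na(raw[[cl]]) & !(raw[[cl]] %in% spec$levels))
      if (length(bad)) {
        stop_schema(sprintf(
          "column `%s`: value \"%s\" at row %d outside declared levels {%s}",
          cl, raw[[cl]][bad[1]], bad[1], paste(spec$levels, collapse = ", ")
        ))
      }
    }
  }
  out <- raw[c(.id_cols, names(schema))]
  attr(out, "schema") <- schema
  out
}

#' @rdname read_traits
#' @export
write_traits <- function(table, path, schema = NULL) {
  if (is.null(schema)) schema <- attr(table, "schema") %||% infer_schema(table)
  readr::write_csv(table[c(.id_cols, names(schema))], path, na = "")
  jsonlite::write_json(
    lapply(unclass(schema), function(s) s[!vapply(s, \(v) all(is.na(v)), TRUE)]),
    .schema_path(path), auto_unbox = TRUE
  )
  invisible(path)
}

.schema_from_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(js, function(s) {
    if (identical(s$type, "numeric")) {
      trait_numeric(s$unit %||% NA_character_)
    } else if (identical(s$type, "categorical")) {
      trait_categorical(s$levels)
    } else {
      stop_schema(sprintf("unknown trait type `%s` in schema", s$type))
    }
  })
  structure(specs, class = "trait_schema")
}

#' Read and write site networks
#'
#' Site networks are stored as a CSV pair: an occurrence file
#' `(site_id, species_id, trophic_level, lon, lat)` listing each site's
#' species, and an edge file `(site_id, resource_id, consumer_id)` of binary
#' observed interactions. Reading validates that every edge references
#' species recorded at its site.
#'
#' @param networks A `"site_networks"` list (`occurrences`, `edges`).
#' @param occ_path,edge_path CSV paths.
#' @return `read_networks()` returns a `"site_networks"` list;
#'   `write_networks()` returns the paths invisibly.
#' @export
write_networks <- function(networks, occ_path, edge_path) {
  readr::write_csv(networks$occurrences, occ_path, na = "")
  readr::write_csv(networks$edges, edge_path, na = "")
  invisible(c(occ_path, edge_path))
}

#' @rdname write_networks
#' @export
read_networks <- function(occ_path, edge_path) {
  occ <- readr::read_csv(occ_path, col_types = "cccdd", na = "",
                         progress = FALSE)
  edges <- readr::read_csv(edge_path, col_types = "ccc", na = "",
                           progress = FALSE)
  nets <- structure(list(occurrences = occ, edges = edges),
                    class = "site_networks")
  .validate_networks(nets)
  nets
}

.validate_networks <- function(networks) {
  occ <- networks$occurrences
  key <- paste(occ$site_id, occ$species_id)
  bad_r <- !(paste(networks$edges$site_id, networks$edges$resource_id) %in% key)
  bad_c <- !(paste(networks$edges$site_id, networks$edges$consumer_id) %in% key)
  if (any(bad_r | bad_c)) {
    i <- which(bad_r | bad_c)[1]
    stop_data(sprintf(
      "edge row %d references species %s absent from site %s",
      i,
      if (bad_r[i]) networks$edges$resource_id[i] else networks$edges$consumer_id[i],
      networks$edges$site_id[i]
    ))
  }
  invisible(networks)
}

#' Read and write species-by-cell occurrence tables
#'
#' Occurrence tables are CSVs `(cell_id, lon_min, lat_min, species_id,
#' trophic_level)`; `cell_id` encodes the lower-left corner of a half-open
#' `[lon, lon + size) x [lat, lat + size)` grid cell.
#'
#' @param occurrences Occurrence tibble.
#' @param path CSV path.
#' @return `read_occurrences()` returns the occurrence tibble;
#'   `write_occurrences()` returns `path` invisibly.
#' @export
write_occurrences <- function(occurrences, path) {
  readr::write_csv(occurrences, path, na = "")
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  readr::read_csv(path, col_types = "cddcc", na = "", progress = FALSE)
}

#' Write every artifact of a synthetic ecosystem to a directory
#'
#' Writes the standard CSV schemas: both trait tables (with sidecar JSON
#' schemas), the site-network occurrence/edge pair, the grid occurrence
#' table, and the ground-truth pair probabilities
#' `(resource_id, consumer_id, p_true)`.
#'
#' @param eco A `"synth_ecosystem"` from [simulate_ecosystem()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ecosystem <- function(eco, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_traits(eco$resource, file.path(dir, "resource_traits.csv"))
  write_traits(eco$consumer, file.path(dir, "consumer_traits.csv"))
  write_networks(eco$networks, file.path(dir, "site_occurrences.csv"),
                 file.path(dir, "site_edges.csv"))
  write_occurrences(eco$occurrences, file.path(dir, "grid_occurrences.csv"))
  readr::write_csv(eco$truth$pairs, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
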