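# Small factories shared across tests. Everything is generated in code.

tiny_config <- function(seed = 1, n_sites = 5, ...) {
  synth_config(seed = seed, n_resource = 15, n_consumer = 10,
               grid_nx = 6, grid_ny = 6, n_sites = n_sites, n_groups = 3, ...)
}

# one-site network with explicit species and edges
one_site_networks <- function(resources, consumers, edges,
                              site_id = "s1") {
  occ <- tibble::tibble(
    site_id = site_id,
    species_id = c(resources, consumers),
    trophic_level = rep(c("resource", "consumer"),
                        c(length(resources), length(consumers))),
    lon = 0, lat = 0
  )
  structure(
    list(occurrences = occ,
         edges = tibble::tibble(site_id = site_id,
                                resource_id = edges$resource_id %||% character(),
                                consumer_id = edges$consumer_id %||% character())),
    class = "site_networks"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trait table with n species on a given level, simple numeric traits
toy_traits <- function(n, level = "resource", prefix = "S", seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    species_id = sprintf("%s%02d", prefix, seq_len(n)),
    trophic_level = level,
    taxon_group = sample(c("g1", "g2"), n, replace = TRUE),
    size = runif(n, 1, 10),
    shape = runif(n, 0, 1),
    colour = sample(c("red", "white", "yellow"), n, replace = TRUE)
  ))
}

# Euclidean trait space directly from coordinates (bypasses Gower), for
# geometry tests with known positions
space_from_coords <- function(coords, ids = NULL) {
  ids <- ids %||% sprintf("x%02d", seq_len(nrow(coords)))
  rownames(coords) <- ids
  colnames(coords) <- paste0("axis_", seq_len(ncol(coords)))
  structure(list(ids = ids, coordinates = coords,
                 eigenvalues = rep(1, ncol(coords)), m = ncol(coords),
                 stress = 0, sqrt_correction = FALSE,
                 global_volume = hull_volume(coords)),
            class = "trait_space")
}

# shoelace polygon area of the 2-D convex hull (independent oracle)
shoelace_hull_area <- function(pts) {
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
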