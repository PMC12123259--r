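#' Generate trait tables for both trophic levels
#'
#' Draws mixed numeric/categorical trait tables for the resource (plant-like)
#' and consumer (hummingbird-like) level. Each level has one numeric matching
#' trait (`corolla_length` / `bill_length`, log-normal, mm), two auxiliary
#' numeric traits that have no effect on interaction feasibility, and one
#' categorical trait (`flower_colour` / `colour_preference`) entering the
#' kernel through the mismatch penalty. A `taxon_group` column is assigned by
#' k-means clustering of the scaled numeric traits, mimicking family/clade
#' structure that correlates with the traits.
#'
#' @param config A [synth_config()].
#' @return A list with tibbles `resource` and `consumer`, each with columns
#'   `species_id`, `trophic_level`, `taxon_group` and the trait columns.
#' @export
#' @examples
#' tr <- gen_traits(synth_config(seed = 1, n_resource = 12, n_consumer = 8))
#' tr$resource
gen_traits <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  colours <- c("orange", "purple", "red", "white")
  local_seed(.stage_seed(config, "traits"), {
    nr <- config$n_resource
    nc <- config$n_consumer
    resource <- tibble::tibble(
      species_id = sprintf("P%03d", seq_len(nr)),
      trophic_level = "resource",
      corolla_length = rlnorm(nr, config$corolla_meanlog, config$corolla_sdlog),
      plant_height = rlnorm(nr, log(2), 0.6),
      nectar_concentration = runif(nr, 10, 40),
      flower_colour = sample(colours, nr, replace = TRUE)
    )
    consumer <- tibble::tibble(
      species_id = sprintf("H%03d", seq_len(nc)),
      trophic_level = "consumer",
      bill_length = rlnorm(nc, config$bill_meanlog, config$bill_sdlog),
      body_mass = rlnorm(nc, log(5), 0.4),
      wing_index = runif(nc, 10, 40),
      colour_preference = sample(colours, nc, replace = TRUE)
    )
    resource$taxon_group <- .cluster_groups(
      resource[c("corolla_length", "plant_height", "nectar_concentration")],
      config$n_groups, "PF"
    )
    consumer$taxon_group <- .cluster_groups(
      consumer[c("bill_length", "body_mass", "wing_index")],
      config$n_groups, "HC"
    )
    cols <- c("species_id", "trophic_level", "taxon_group")
    list(
      resource = resource[c(cols, setdiff(names(resource), cols))],
      consumer = consumer[c(cols, setdiff(names(consumer), cols))]
    )
  })
}

.cluster_groups <- function(df, g, prefix) {
  x <- scale(as.matrix(df))
  if (g >= nrow(x)) return(sprintf("%s%d", prefix, seq_len(nrow(x))))
  km <- kmeans(x, centers = g, nstart = 5)
  sprintf("%s%d", prefix, km$cluster)
}

#' Trait-matching feasibility kernel
#'
#' The probability that a resource-consumer pair can interact, as a function
#' of the difference between the matching traits: a Gaussian in
#' `corolla - bill` with per-consumer tolerance `sigma`, scaled to `p_max` at
#' perfect match and multiplied by `1 - delta_cat` when the categorical
#' traits mismatch.
#'
#' @param corolla,bill Numeric matching trait values (same units).
#' @param sigma Consumer tolerance (> 0), same units as the traits.
#' @param mismatch Logical (or 0/1): categorical mismatch indicator.
#' @param p_max Plateau probability in `[0, 1]`.
#' @param delta_cat Categorical mismatch penalty in `[0, 1]`.
#' @return Probabilities in `[0, p_max]`, vectorised over the inputs.
#' @export
#' @examples
#' link_kernel(10, 12, sigma = 2, mismatch = FALSE) # 0.9 * exp(-0.5)
link_kernel <- function(corolla, bill, sigma, mismatch = FALSE,
                        p_max = 0.9, delta_cat = 0.5) {
  if (any(sigma <= 0)) stop_config("kernel tolerance `sigma` must be > 0")
  p_max * exp(-(corolla - bill)^2 / (2 * sigma^2)) *
    (1 - delta_cat * as.numeric(mismatch))
}

#' All-pairs true interaction probabilities
#'
#' Evaluates the feasibility kernel for every resource x consumer pair.
#'
#' @param resource,consumer Trait tibbles from [gen_traits()].
#' @param sigma Named numeric vector of per-consumer tolerances (names =
#'   consumer `species_id`).
#' @param config A [synth_config()] supplying `p_max` and `delta_cat`.
#' @return A tibble `(resource_id, consumer_id, p_true)` with one row per
#'   pair.
#' @export
true_link_prob <- function(resource, consumer, sigma, config) {
  if (any(sigma <= 0)) stop_config("kernel tolerance `sigma` must be > 0")
  pairs <- tidyr::expand_grid(resource_id = resource$species_id,
                              consumer_id = consumer$species_id)
  ri <- match(pairs$resource_id, resource$species_id)
  ci <- match(pairs$consumer_id, consumer$species_id)
  pairs$p_true <- link_kernel(
    corolla = resource$corolla_length[ri],
    bill = consumer$bill_length[ci],
    sigma = unname(sigma[pairs$consumer_id]),
    mismatch = resource$flower_colour[ri] != consumer$colour_preference[ci],
    p_max = config$p_max, delta_cat = config$delta_cat
  )
  pairs
}

#' Ground truth of the synthetic ecosystem
#'
#' Derives the per-consumer tolerances and evaluates the kernel for all
#' pairs. Tolerance is allometric: \eqn{\log \sigma_j} is
#' `sigma_log_mean + sigma_log_sd * z_j` with `z_j` the consumer's
#' standardized log body mass, so tolerance is marginally log-normal yet
#' carried by an observable trait. The true niche breadth of a species is
#' summarised as the number of partners with feasibility >= 0.5 and the
#' span of their matching trait.
#'
#' @inheritParams true_link_prob
#' @param config A [synth_config()].
#' @return A list with class `"synth_truth"`: `pairs` (tibble with `p_true`),
#'   `consumers` (tibble `species_id`, `optimum`, `sigma`, `breadth_n`,
#'   `breadth_span`), and `resources` (tibble `species_id`, `breadth_n`,
#'   `breadth_span`).
#' @export
ground_truth <- function(resource, consumer, config) {
  local_seed(.stage_seed(config, "truth"), {
    z <- as.numeric(scale(log(consumer$body_mass)))
    if (anyNA(z)) z <- rep(0, nrow(consumer)) # single consumer: sd undefined
    sigma <- setNames(
      exp(config$sigma_log_mean + config$sigma_log_sd * z),
      consumer$species_id
    )
    pairs <- true_link_prob(resource, consumer, sigma, config)
    feas <- dplyr::filter(pairs, .data$p_true >= 0.5)
    breadth <- function(ids, key, trait_tab, trait_col, match_col) {
      dplyr::left_join(
        tibble::tibble(species_id = ids),
        feas |>
          dplyr::left_join(trait_tab[c("species_id", trait_col)],
                           by = setNames("species_id", match_col)) |>
          dplyr::group_by(species_id = .data[[key]]) |>
          dplyr::summarise(
            breadth_n = dplyr::n(),
            breadth_span = diff(range(.data[[trait_col]])),
            .groups = "drop"
          ),
        by = "species_id"
      ) |>
        tidyr::replace_na(list(breadth_n = 0L, breadth_span = 0))
    }
    consumers <- tibble::tibble(
      species_id = consumer$species_id,
      optimum = consumer$bill_length,
      sigma = unname(sigma)
    ) |>
      dplyr::left_join(
        breadth(consumer$species_id, "consumer_id", resource,
                "corolla_length", "resource_id"),
        by = "species_id"
      )
    resources <- breadth(resource$species_id, "resource_id", consumer,
                         "bill_length", "consumer_id")
    structure(list(pairs = pairs, consumers = consumers,
                   resources = resources),
              class = "synth_truth")
  })
}

#' Grid cell index for a configuration
#'
#' @param config A [synth_config()].
#' @return Tibble `(cell_id, lon_min, lat_min)` covering the full grid;
#'   `cell_id` encodes the lower-left corner. Cells are half-open
#'   `[lon, lon + size) x [lat, lat + size)`.
#' @export
grid_cells <- function(config) {
  g <- tidyr::expand_grid(
    ix = seq_len(config$grid_nx) - 1L,
    iy = seq_len(config$grid_ny) - 1L
  )
  tibble::tibble(
    cell_id = sprintf("c%g_%g",
                      config$lon0 + g$ix * config$cell_size,
                      config$lat0 + g$iy * config$cell_size),
    lon_min = config$lon0 + g$ix * config$cell_size,
    lat_min = config$lat0 + g$iy * config$cell_size
  )
}

#' Generate species ranges on the occurrence grid
#'
#' Each species gets a circular range: a centroid uniform over the grid
#' extent and a radius uniform in `[radius_min, radius_max]` degrees. A
#' species is present in a cell when the cell centroid lies within the
#' radius; the cell containing the range centroid is always included, so
#' every species occupies at least one cell.
#'
#' @param config A [synth_config()].
#' @param traits List with `resource` and `consumer` trait tibbles (only the
#'   id and level columns are used).
#' @return An occurrence tibble `(cell_id, lon_min, lat_min, species_id,
#'   trophic_level)` with attributes `cells` (the full [grid_cells()] table)
#'   and `cell_size`.
#' @export
gen_ranges <- function(config, traits) {
  cells <- grid_cells(config)
  half <- config$cell_size / 2
  sp <- dplyr::bind_rows(
    traits$resource[c("species_id", "trophic_level")],
    traits$consumer[c("species_id", "trophic_level")]
  )
  lon_max <- config$lon0 + config$grid_nx * config$cell_size
  lat_max <- config$lat0 + config$grid_ny * config$cell_size
  occ <- local_seed(.stage_seed(config, "ranges"), {
    cx <- runif(nrow(sp), config$lon0, lon_max)
    cy <- runif(nrow(sp), config$lat0, lat_max)
    r <- runif(nrow(sp), config$radius_min, config$radius_max)
    purrr::pmap_dfr(
      list(sp$species_id, sp$trophic_level, cx, cy, r),
      function(id, lev, x, y, rad) {
        d2 <- (cells$lon_min + half - x)^2 + (cells$lat_min + half - y)^2
        inside <- d2 <= rad^2
        # guarantee presence in the centroid's own cell
        home <- which(cells$lon_min <= x & x < cells$lon_min + config$cell_size &
                        cells$lat_min <= y & y < cells$lat_min + config$cell_size)
        inside[home] <- TRUE
        dplyr::mutate(cells[inside, ], species_id = id, trophic_level = lev)
      }
    )
  })
  occ <- dplyr::arrange(occ, .data$cell_id, .data$trophic_level,
                        .data$species_id)
  attr(occ, "cells") <- cells
  attr(occ, "cell_size") <- config$cell_size
  occ
}

#' Sample imperfectly detected site networks
#'
#' Study sites are grid cells sampled without replacement among the cells
#' that hold at least one species of each trophic level. At each site, every
#' co-occurring resource-consumer pair is observed interacting with
#' probability `p_true * p_detect`, independently across sites; edges are
#' binary.
#'
#' @param occurrences Occurrence tibble from [gen_ranges()].
#' @param truth A `"synth_truth"` from [ground_truth()].
#' @param config A [synth_config()].
#' @return A list with class `"site_networks"`: `occurrences` (tibble
#'   `site_id`, `species_id`, `trophic_level`, `lon`, `lat`) and `edges`
#'   (tibble `site_id`, `resource_id`, `consumer_id`).
#' @export
gen_site_networks <- function(occurrences, truth, config) {
  half <- attr(occurrences, "cell_size") %||% config$cell_size
  half <- half / 2
  by_cell <- dplyr::count(occurrences, .data$cell_id, .data$trophic_level)
  eligible <- by_cell |>
    tidyr::pivot_wider(names_from = "trophic_level", values_from = "n",
                       values_fill = 0L) |>
    dplyr::filter(.data$resource > 0, .data$consumer > 0)
  if (nrow(eligible) == 0) {
    stop_data("no grid cell holds species at both trophic levels")
  }
  if (config$n_sites > nrow(eligible)) {
    stop_config(sprintf(
      "n_sites (%d) exceeds the %d cells occupied at both levels",
      config$n_sites, nrow(eligible)
    ))
  }
  p_lookup <- setNames(truth$pairs$p_true,
                       paste(truth$pairs$resource_id, truth$pairs$consumer_id))
  local_seed(.stage_seed(config, "networks"), {
    chosen <- sample(eligible$cell_id, config$n_sites)
    site_occ <- occurrences |>
      dplyr::filter(.data$cell_id %in% chosen) |>
      dplyr::transmute(
        site_id = paste0("site_", .data$cell_id),
        species_id = .data$species_id,
        trophic_level = .data$trophic_level,
        lon = .data$lon_min + half,
        lat = .data$lat_min + half
      )
    edges <- site_occ |>
      dplyr::group_by(.data$site_id) |>
      dplyr::group_map(function(g, key) {
        rs <- g$species_id[g$trophic_level == "resource"]
        cs <- g$species_id[g$trophic_level == "consumer"]
        pr <- tidyr::expand_grid(resource_id = rs, consumer_id = cs)
        p <- p_lookup[paste(pr$resource_id, pr$consumer_id)] * config$p_detect
        pr$site_id <- key$site_id
        pr[rbinom(nrow(pr), 1L, p) == 1L,
           c("site_id", "resource_id", "consumer_id")]
      }) |>
      dplyr::bind_rows()
    if (nrow(edges) == 0) {
      edges <- tibble::tibble(site_id = character(), resource_id = character(),
                              consumer_id = character())
    }
    structure(list(occurrences = site_occ, edges = edges),
              class = "site_networks")
  })
}

#' Simulate a full synthetic ecosystem
#'
#' Runs all generator stages in order: traits, latent kernel ground truth,
#' ranges on the grid, and imperfectly detected site networks.
#'
#' @param config A [synth_config()].
#' @return A list with class `"synth_ecosystem"`: `config`, `resource`,
#'   `consumer`, `truth`, `occurrences`, `networks`.
#' @export
#' @examples
#' eco <- simulate_ecosystem(synth_config(seed = 1, n_resource = 15,
#'                                        n_consumer = 10, n_sites = 5,
#'                                        grid_nx = 6, grid_ny = 6))
#' nrow(eco$truth$pairs)
simulate_ecosystem <- function(config) {
  traits <- gen_traits(config)
  truth <- ground_truth(traits$resource, traits$consumer, config)
  occurrences <- gen_ranges(config, traits)
  networks <- gen_site_networks(occurrences, truth, config)
  structure(
    list(config = config, resource = traits$resource,
         consumer = traits$consumer, truth = truth,
         occurrences = occurrences, networks = networks),
    class = "synth_ecosystem"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
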