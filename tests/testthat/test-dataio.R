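test_that("trait tables round-trip through CSV + sidecar schema", {
  tab <- toy_traits(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traits(tab, path)
  back <- read_traits(path)
  expect_equal(back, tab, ignore_attr = TRUE)
  expect_s3_class(attr(back, "schema"), "trait_schema")
})

test_that("trait reading is strict and names the offender", {
  tab <- toy_traits(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traits(tab, path)
  sc <- infer_schema(tab)

  # duplicated id
  dup <- tab
  dup$species_id[2] <- dup$species_id[1]
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dup, p2)
  expect_error(read_traits(p2, sc), "S01", class = "nichewire_schema_error")

  # categorical value outside the declared level set
  bad <- tab
  bad$colour[3] <- "chartreuse"
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, p3)
  err <- expect_error(read_traits(p3, sc), class = "nichewire_schema_error")
  expect_match(conditionMessage(err), "colour")
  expect_match(conditionMessage(err), "row 3")

  # non-numeric value in a numeric trait
  bad2 <- tab
  bad2$size <- as.character(bad2$size)
  bad2$size[1] <- "big"
  p4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad2, p4)
  err2 <- expect_error(read_traits(p4, sc), class = "nichewire_schema_error")
  expect_match(conditionMessage(err2), "size")

  # column not declared in the schema
  extra <- tab
  extra$mystery <- 1
  p5 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(extra, p5)
  expect_error(read_traits(p5, sc), "mystery",
               class = "nichewire_schema_error")
})

test_that("site networks and occurrence tables round-trip", {
  eco <- simulate_ecosystem(tiny_config(seed = 9))
  d <- withr::local_tempdir()
  write_networks(eco$networks, file.path(d, "occ.csv"),
                 file.path(d, "edge.csv"))
  back <- read_networks(file.path(d, "occ.csv"), file.path(d, "edge.csv"))
  expect_equal(back$occurrences, eco$networks$occurrences,
               ignore_attr = TRUE)
  expect_equal(back$edges, eco$networks$edges, ignore_attr = TRUE)

  write_occurrences(eco$occurrences, file.path(d, "grid.csv"))
  grid_back <- read_occurrences(file.path(d, "grid.csv"))
  expect_equal(grid_back, eco$occurrences, ignore_attr = TRUE)

  write_ecosystem(eco, file.path(d, "eco"))
  expect_true(all(file.exists(file.path(
    d, "eco",
    c("resource_traits.csv", "consumer_traits.csv", "site_occurrences.csv",
      "site_edges.csv", "grid_occurrences.csv", "ground_truth.csv")
  ))))
})

test_that("edges naming species missing from their site are rejected", {
  nets <- one_site_networks(c("P1", "P2"), c("H1"),
                            list(resource_id = "P9", consumer_id = "H1"))
  expect_error(assemble_training_pairs(nets), "P9",
               class = "nichewire_data_error")
})

test_that("training pairs enumerate presences and inferred absences", {
  # one site, 2 x 2 species, one observed edge -> 1 presence + 3 absences
  nets <- one_site_networks(c("P1", "P2"), c("H1", "H2"),
                            list(resource_id = "P1", consumer_id = "H1"))
  pairs <- assemble_training_pairs(nets)
  expect_equal(nrow(pairs), 4)
  expect_equal(sum(pairs$label), 1)
  expect_equal(pairs$label[pairs$resource_id == "P1" &
                             pairs$consumer_id == "H1"], 1L)
})

test_that("presence anywhere dominates absence elsewhere", {
  a <- one_site_networks("P1", "H1",
                         list(resource_id = "P1", consumer_id = "H1"), "sA")
  b <- one_site_networks("P1", "H1", list(), "sB")
  nets <- structure(
    list(occurrences = dplyr::bind_rows(a$occurrences, b$occurrences),
         edges = a$edges),
    class = "site_networks"
  )
  pairs <- assemble_training_pairs(nets)
  expect_equal(nrow(pairs), 1) # one row per distinct pair
  expect_equal(pairs$label, 1L)
})

test_that("pairs that never co-occur are excluded", {
  a <- one_site_networks("P1", "H1",
                         list(resource_id = "P1", consumer_id = "H1"), "sA")
  b <- one_site_networks("P2", "H2", list(), "sB")
  nets <- structure(
    list(occurrences = dplyr::bind_rows(a$occurrences, b$occurrences),
         edges = a$edges),
    class = "site_networks"
  )
  pairs <- assemble_training_pairs(nets)
  # P1-H2, P2-H1 never co-occur: only P1-H1 and P2-H2 remain
  expect_equal(nrow(pairs), 2)
  expect_setequal(paste(pairs$resource_id, pairs$consumer_id),
                  c("P1 H1", "P2 H2"))
})

test_that("imputation fills by group mean/mode with stated tie-breaks", {
  tab <- tibble::tibble(
    species_id = sprintf("s%d", 1:6),
    trophic_level = "resource",
    taxon_group = c("g1", "g1", "g1", "g2", "g2", "g2"),
    height = c(2, 4, NA, 10, 10, NA),
    colour = c("red", "red", "blue", NA, "blue", "red")
  )
  out <- impute_traits(tab)
  expect_equal(out$height[3], 3)   # group mean of {2, 4}
  expect_equal(out$height[6], 10)  # group mean of {10, 10}
  # g2 colours observed: {blue, red} -> tie -> lexicographically smallest
  expect_equal(out$colour[4], "blue")
  flags <- attr(out, "imputed")
  expect_setequal(paste(flags$species_id, flags$trait),
                  c("s3 height", "s6 height", "s4 colour"))

  # mode without tie
  tab2 <- tab
  tab2$colour <- c("red", "red", "blue", NA, "red", "red")
  expect_equal(impute_traits(tab2)$colour[4], "red")

  # complete table passes through unchanged
  full <- toy_traits(4)
  expect_equal(impute_traits(full)$size, full$size)
  expect_equal(nrow(attr(impute_traits(full), "imputed")), 0)

  # global fallback when the whole group is missing
  tab3 <- tab
  tab3$height <- c(2, 4, 3, NA, NA, NA)
  expect_equal(impute_traits(tab3)$height[4:6], rep(3, 3))

  # entirely missing trait is an error
  tab4 <- tab
  tab4$height <- NA_real_
  expect_error(impute_traits(tab4), "height",
               class = "nichewire_data_error")
})

test_that("co-occurring pair count bounds presences plus absences", {
  eco <- simulate_ecosystem(tiny_config(seed = 13))
  pairs <- assemble_training_pairs(eco$networks)
  cooc <- dplyr::distinct(pairs, resource_id, consumer_id)
  expect_equal(nrow(pairs), nrow(cooc)) # every co-occurring pair labelled once
  expect_lte(nrow(pairs), eco$config$n_resource * eco$config$n_consumer)
})
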