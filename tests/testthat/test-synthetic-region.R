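test_that("generated counts follow the configuration exactly", {
  cfg <- region_config(n_regions = 2, districts_per_region = c(2, 2),
                       municipalities_per_district = c(3, 3), seed = 7)
  ds <- generate_region(cfg)
  expect_length(ds$regions, 2)
  expect_equal(nrow(ds$districts), 4)
  expect_equal(nrow(ds$municipalities), 12)
  expect_equal(as.vector(table(ds$municipalities$district_id)),
               rep(3, 4))
  # every municipality in exactly one district, every district in one region
  expect_true(all(ds$municipalities$district_id %in% ds$districts$id))
  expect_true(all(ds$districts$region_id %in% ds$regions))
  expect_true(all(ds$facilities$municipality_id %in% ds$municipalities$id))
})

test_that("identical config and seed reproduce an identical dataset", {
  cfg <- small_region_config(seed = 11)
  ds1 <- generate_region(cfg)
  ds2 <- generate_region(cfg)
  expect_identical(ds1, ds2)
  expect_identical(serialize(ds1, NULL), serialize(ds2, NULL))
  ds3 <- generate_region(small_region_config(seed = 12))
  expect_false(identical(ds1$municipalities, ds3$municipalities))
})

test_that("a zero clinic rate produces no clinic facilities anywhere", {
  cfg <- region_config(n_regions = 2, districts_per_region = c(2, 2),
                       municipalities_per_district = c(3, 4),
                       facility_density = c(residential = 4, clinic = 0),
                       seed = 3)
  ds <- generate_region(cfg)
  expect_equal(sum(ds$facilities$service_class == "clinic"), 0)
  expect_gt(sum(ds$facilities$service_class == "residential"), 0)
})

test_that("invalid draw specs raise configuration errors naming the field", {
  expect_error(region_config(recipients_per_municipality =
                               draw_spec("nbinom", mu = 10)),
               "recipients_per_municipality")
  expect_error(region_config(road_edge_minutes =
                               draw_spec("unif", min = 5, max = 2)),
               "road_edge_minutes")
  expect_error(region_config(recipients_per_municipality =
                               draw_spec("zipf", s = 2)),
               "unknown distribution")
})

test_that("district road restrictions are connected and recipients conserve", {
  for (seed in c(2, 5, 9)) {
    ds <- generate_region(small_region_config(seed))
    # conservation: municipal recipients sum to the district X1 downstream
    base <- aggregate_district_base(ds)
    manual <- tapply(ds$municipalities$recipients_65plus,
                     ds$municipalities$district_id, sum)
    expect_identical(base$X1, as.integer(manual[base$district_id]))
    # intra-district connectivity
    for (d in ds$districts$id) {
      mun <- ds$municipalities$id[ds$municipalities$district_id == d]
      e <- ds$road_network$edges
      e <- e[e$from_node %in% mun & e$to_node %in% mun, ]
      g <- igraph::graph_from_data_frame(e[, 1:2], directed = FALSE,
                                         vertices = data.frame(name = mun))
      expect_true(igraph::is_connected(g))
    }
  }
})

test_that("timetable respects structural invariants", {
  ds <- generate_region(small_region_config(seed = 21))
  tt <- ds$timetable
  expect_true(all(tt$minutes >= 0))
  expect_true(all(tt$transfers >= 0))
  expect_true(all(tt$arrival == tt$departure + tt$minutes))
  expect_true(all(tt$origin %in% ds$municipalities$id))
  expect_true(all(tt$destination %in% ds$municipalities$id))
})

test_that("planting edits are recorded in the edit log", {
  ds <- generate_region(small_region_config(seed = 4))
  d <- ds$districts$id[1]
  out <- plant_gap_scenario(ds, d, "residential", "IT", "III")
  expect_gt(nrow(out$edit_log), 0)
  expect_true(any(out$edit_log$action == "inflate_edges"))
  expect_true(any(out$edit_log$action == "remove_facility") ||
                sum(ds$facilities$service_class == "residential" &
                      ds$facilities$municipality_id %in%
                      ds$municipalities$id[ds$municipalities$district_id == d]) == 0)
  # class I plants a provider into every municipality of the district
  out1 <- plant_gap_scenario(ds, d, "clinic", "PT", "I")
  mun <- ds$municipalities$id[ds$municipalities$district_id == d]
  expect_true(all(mun %in% facility_hosts(out1, "clinic")))
  expect_error(plant_gap_scenario(ds, "nope", "clinic", "PT", "I"),
               "unknown district")
})
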