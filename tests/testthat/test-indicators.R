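test_that("district base aggregation sums demand and capacity exactly", {
  ds <- tiny_dataset()
  base <- aggregate_district_base(ds)
  expect_equal(base$X1[base$district_id == "DA"], 150L + 50L)
  expect_equal(base$X2[base$district_id == "DA"], 40L)
  expect_equal(base$X3[base$district_id == "DA"], 0L)
  expect_equal(base$X3[base$district_id == "DB"], 10L)
  # region roll-up equals the sum of its districts
  ds2 <- generate_region(small_region_config(seed = 31))
  b2 <- aggregate_district_base(ds2)
  per_region <- tapply(b2$X1, ds2$districts$region_id[
    match(b2$district_id, ds2$districts$id)], sum)
  expect_equal(sum(per_region), sum(ds2$municipalities$recipients_65plus))
})

test_that("coverage reproduces the recipient-weighted share", {
  ds <- tiny_dataset()
  reach <- compute_reachability(ds)
  # DA residential IT: a1 (100) at 0 min, a2 (50) at 20 -> both within 30;
  # a3 (50) at 45 -> within 60 only. cov30 = 150/200*100 = 75
  expect_equal(coverage_percent("DA", "residential", "IT", 30, reach, ds), 75)
  expect_equal(coverage_percent("DA", "residential", "IT", 60, reach, ds), 100)
  expect_error(coverage_percent("??", "residential", "IT", 30, reach, ds),
               "unknown district")
  expect_error(coverage_percent("DA", "residential", "IT", 45, reach, ds),
               "band")
})

test_that("indicator table matches a brute-force per-municipality oracle", {
  set.seed(202)
  for (seed in c(13, 29)) {
    ds <- generate_region(small_region_config(seed))
    reach <- compute_reachability(ds)
    ind <- compute_indicators(ds, reach)
    groups <- data.frame(g = c("X4", "X5", "X6", "X7"),
                         cls = c("residential", "residential",
                                 "clinic", "clinic"),
                         md = c("IT", "PT", "IT", "PT"))
    d <- sample(ds$districts$id, 1)
    mun <- ds$municipalities[ds$municipalities$district_id == d, ]
    for (k in 1:4) {
      for (part in c(a = 30, b = 60)) {
        num <- 0; den <- 0
        for (i in seq_len(nrow(mun))) {           # one municipality at a time
          row <- reach[reach$municipality == mun$id[i] &
                         reach$service_class == groups$cls[k] &
                         reach$mode == groups$md[k], ]
          den <- den + mun$recipients_65plus[i]
          if (row[[paste0("within", part)]])
            num <- num + mun$recipients_65plus[i]
        }
        want <- if (den > 0) 100 * num / den else 0
        col <- paste0(groups$g[k], names(which(c(a = 30, b = 60) == part)))
        expect_equal(ind[[col]][ind$district_id == d], want)
      }
    }
  }
})

test_that("coverage nesting and reachability monotonicity hold", {
  ds <- generate_region(small_region_config(seed = 17))
  ind <- compute_indicators(ds)
  for (g in c("X4", "X5", "X6", "X7"))
    expect_true(all(ind[[paste0(g, "b")]] >= ind[[paste0(g, "a")]] - 1e-9))
  expect_true(all(ind[, -1] >= 0))
  covcols <- grep("^X[4-7]", names(ind), value = TRUE)
  expect_true(all(ind[covcols] <= 100 + 1e-9))
  # shortening a road edge never decreases any coverage value
  ds2 <- ds
  ds2$road_network$edges$minutes <- ds2$road_network$edges$minutes * 0.5
  ind2 <- compute_indicators(ds2)
  for (g in c("X4a", "X4b", "X6a", "X6b"))
    expect_true(all(ind2[[g]] >= ind[[g]] - 1e-9))
})

test_that("a district without recipients gets zero coverage and a warning", {
  ds <- tiny_dataset()
  ds$municipalities$recipients_65plus[ds$municipalities$district_id == "DB"] <- 0L
  expect_warning(ind <- compute_indicators(ds), "no recipients")
  expect_equal(ind$X4a[ind$district_id == "DB"], 0)
  expect_warning(
    coverage_percent("DB", "residential", "IT", 30,
                     compute_reachability(ds), ds),
    "no recipients")
})

test_that("coverage is invariant under splitting a municipality", {
  ds <- tiny_dataset()
  ind <- compute_indicators(ds)
  # split a2 (50 recipients) into two municipalities of 25 at the same spot
  ds2 <- ds
  ds2$municipalities$recipients_65plus[2] <- 25L
  extra <- ds2$municipalities[2, ]
  extra$id <- "a2b"; extra$network_node <- "a2b"
  ds2$municipalities <- rbind(ds2$municipalities, extra)
  ds2$road_network$nodes <- rbind(ds2$road_network$nodes,
                                  data.frame(id = "a2b", x = 10, y = 0))
  ds2$road_network$edges <- rbind(ds2$road_network$edges,
                                  data.frame(from_node = "a2b",
                                             to_node = "a1", minutes = 20))
  tt <- ds2$timetable[2, ]; tt$origin <- "a2b"
  ds2$timetable <- rbind(ds2$timetable, tt)
  ind2 <- compute_indicators(ds2)
  covcols <- grep("^X[4-7]", names(ind), value = TRUE)
  expect_equal(ind2[covcols], ind[covcols], tolerance = 1e-12)
})
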