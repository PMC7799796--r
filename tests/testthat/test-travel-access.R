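test_that("shortest travel times handle elementary cases", {
  net <- list(nodes = data.frame(id = c("A", "B", "C")),
              edges = data.frame(from_node = c("A", "B"),
                                 to_node = c("B", "C"),
                                 minutes = c(10, 5)))
  expect_equal(unname(shortest_travel_times(net, "A", "B")), 10)
  expect_equal(unname(shortest_travel_times(net, "A", "A")), 0)
  expect_equal(unname(shortest_travel_times(net, "A", c("B", "C"))), 10)
  # disconnected target
  net2 <- list(nodes = data.frame(id = c("A", "B", "Z")),
               edges = data.frame(from_node = "A", to_node = "B",
                                  minutes = 10))
  expect_equal(unname(shortest_travel_times(net2, "A", "Z")), Inf)
  expect_error(shortest_travel_times(net, "A", "Q"), "unknown node")
})

test_that("shortest paths agree with exhaustive path enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    net <- random_network(sample(3:8, 1))
    ids <- net$nodes$id
    targets <- sample(ids, sample(1:2, 1))
    got <- shortest_travel_times(net, ids, targets)
    for (o in ids)
      expect_equal(unname(got[o]),
                   oracle_min_to_nearest(net$edges, o, targets))
  }
})

test_that("adding an edge never increases any minimal travel time", {
  set.seed(55)
  for (rep in 1:20) {
    net <- random_network(6)
    targets <- sample(net$nodes$id, 2)
    before <- shortest_travel_times(net, net$nodes$id, targets)
    pair <- sample(net$nodes$id, 2)
    net$edges <- rbind(net$edges,
                       data.frame(from_node = pair[1], to_node = pair[2],
                                  minutes = round(stats::runif(1, 1, 30), 1)))
    after <- shortest_travel_times(net, net$nodes$id, targets)
    expect_true(all(after <= before + 1e-12))
  }
})

test_that("band membership is cumulative and treats Inf as nowhere", {
  m <- band_membership(c(29.9, 30, 45, 60, 61, Inf), c(30, 60))
  expect_equal(unname(m[, "within30"]), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(unname(m[, "within60"]), c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(!m[, "within30"] | m[, "within60"]))  # monotone
  expect_error(band_membership(10, c(60, 30)), "increasing")
})

test_that("connection filters apply the feasibility rules strictly", {
  cfg <- access_config()
  tt <- data.frame(
    origin = "a", destination = "b",
    departure = c(750, 750, 810, 770, 780, 600),
    arrival = c(840, 840, 840, 840, 840, 690),
    minutes = c(90, 89, 30, 70, 60, 90),
    transfers = c(0L, 6L, 0L, 5L, 0L, 0L),
    price = 20, distance_km = c(12, 12, 12, 12, 160, 12))
  out <- filter_connections(tt, cfg, arrival_times = 840L)
  # row 1: 90 min exactly (strictly shorter than 90 required) -> excluded
  # row 2: 6 transfers (max five) -> excluded
  # row 5: 160 km (below 150 required) -> excluded
  # row 6: wrong arrival time -> excluded
  expect_equal(out$minutes, c(30, 70))
  expect_equal(out$matched_arrival, c(840L, 840L))
  # tolerance admits near-miss arrivals
  cfg2 <- access_config(arrival_tolerance = 15)
  tt2 <- tt[6, ]; tt2$arrival <- 850; tt2$minutes <- 40
  expect_equal(nrow(filter_connections(tt2, cfg2, 840L)), 1)
  expect_equal(nrow(filter_connections(tt2, cfg, 840L)), 0)
})

test_that("best-connection selection minimizes the weighted score", {
  w <- access_config()$weighing_weights
  one <- data.frame(origin = "a", destination = "b", departure = 800L,
                    arrival = 840L, minutes = 40, transfers = 1L,
                    price = 25, distance_km = 20, matched_arrival = 840L)
  expect_equal(select_best_connection(one, w)$minutes, 40)
  # dominance on transfers, everything else equal
  two <- rbind(one, one); two$transfers <- c(2L, 0L)
  expect_equal(select_best_connection(two, w)$transfers, 0L)
  expect_error(select_best_connection(one[0, ], w), "no feasible")
  # five synthetic connections vs exhaustive scoring
  set.seed(77)
  for (rep in 1:30) {
    n <- 5
    feas <- data.frame(
      origin = "a", destination = "b",
      minutes = round(stats::runif(n, 20, 85)),
      transfers = sample(0:5, n, replace = TRUE),
      price = round(stats::runif(n, 10, 80), 1),
      matched_arrival = 840L)
    feas$arrival <- 840L
    feas$departure <- feas$arrival - as.integer(feas$minutes)
    best <- select_best_connection(feas, w)
    expect_equal(best$minutes,
                 feas$minutes[oracle_best_connection_index(feas, w)])
  }
})

test_that("reachability obeys the self-host rule and PT filter inclusion", {
  ds <- tiny_dataset()
  reach <- compute_reachability(ds)
  g <- function(m, cls, md)
    reach[reach$municipality == m & reach$service_class == cls &
            reach$mode == md, ]
  # a1 hosts the residential facility: 0 minutes both modes
  expect_equal(g("a1", "residential", "IT")$minutes, 0)
  expect_equal(g("a1", "residential", "PT")$minutes, 0)
  # a2 reaches it by road in 20, a3 in 45
  expect_equal(g("a2", "residential", "IT")$minutes, 20)
  expect_equal(g("a3", "residential", "IT")$minutes, 45)
  # clinic sits in b1: a1 by road 50 min (within60 only)
  expect_equal(g("a1", "clinic", "IT")$minutes, 50)
  expect_true(g("a1", "clinic", "IT")$within60)
  expect_false(g("a1", "clinic", "IT")$within30)
  # PT: a1 -> b1 arrives 14:00, but clinic requires 07:00/08:00 -> no match
  expect_equal(g("a1", "clinic", "PT")$minutes, Inf)
  expect_false(g("a1", "clinic", "PT")$within60)
  # a2 -> a1 (residential host) arrives 14:00 in 30 min
  expect_equal(g("a2", "residential", "PT")$minutes, 30)
  # a3 has no outbound connection: unreachable by PT
  expect_equal(g("a3", "residential", "PT")$minutes, Inf)
  # every municipality reachable by PT has a connection passing all filters
  cfg <- access_config()
  for (cls in service_classes()) {
    hosts <- facility_hosts(ds, cls)
    ok <- reach$service_class == cls & reach$mode == "PT" &
      is.finite(reach$minutes) & reach$minutes > 0
    for (m in reach$municipality[ok]) {
      feas <- filter_connections(ds$timetable, cfg, cfg$arrival_times[[cls]])
      expect_true(any(feas$origin == m & feas$destination %in% hosts))
    }
  }
})
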