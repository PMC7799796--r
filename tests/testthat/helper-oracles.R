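# Independent oracles and small fixture builders. Each oracle is a naive
# reimplementation kept deliberately separate from the package's code path.

# --- brute-force shortest path: enumerate every simple path ---------------
oracle_min_travel <- function(edges, origin, target) {
  if (origin == target) return(0)
  best <- Inf
  walk <- function(node, visited, cost) {
    if (cost >= best) return()
    if (node == target) { best <<- cost; return() }
    inc <- which(edges$from_node == node | edges$to_node == node)
    for (e in inc) {
      nxt <- if (edges$from_node[e] == node) edges$to_node[e]
             else edges$from_node[e]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), cost + edges$minutes[e])
    }
  }
  walk(origin, origin, 0)
  best
}

oracle_min_to_nearest <- function(edges, origin, targets) {
  min(vapply(targets, function(t) oracle_min_travel(edges, origin, t),
             numeric(1)))
}

random_network <- function(n_nodes, edge_prob = 0.45) {
  ids <- paste0("N", seq_len(n_nodes))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < edge_prob
  edges <- data.frame(from_node = pairs[1, keep], to_node = pairs[2, keep],
                      minutes = round(stats::runif(sum(keep), 1, 30), 1),
                      stringsAsFactors = FALSE)
  list(nodes = data.frame(id = ids, stringsAsFactors = FALSE),
       edges = edges)
}

# --- spreadsheet-style TOPSIS: explicit per-cell loops --------------------
oracle_topsis_closeness <- function(m, w) {
  n <- nrow(m); k <- ncol(m)
  r <- matrix(0, n, k)
  for (j in 1:k) {
    denom <- sqrt(sum(m[, j]^2))
    for (i in 1:n) r[i, j] <- if (denom > 0) m[i, j] / denom else 0
  }
  v <- matrix(0, n, k)
  for (j in 1:k) for (i in 1:n) v[i, j] <- w[j] * r[i, j]
  H <- numeric(k); D <- numeric(k)
  for (j in 1:k) { H[j] <- max(v[, j]); D[j] <- min(v[, j]) }
  cc <- numeric(n)
  for (i in 1:n) {
    dp <- sqrt(sum((v[i, ] - H)^2))
    dm <- sqrt(sum((v[i, ] - D)^2))
    cc[i] <- if (dp + dm == 0) 0.5 else dm / (dm + dp)
  }
  cc
}

# --- exhaustive weighted scoring of connections ---------------------------
oracle_best_connection_index <- function(feasible, weights) {
  a <- list(
    travel_minutes = feasible$minutes,
    arrival_slack = abs(feasible$arrival - feasible$matched_arrival),
    departure_lateness = feasible$matched_arrival - feasible$departure,
    transfers = feasible$transfers,
    price = feasible$price)
  score <- rep(0, nrow(feasible))
  for (nm in names(a)) {
    col <- a[[nm]]
    rng <- range(col)
    z <- if (rng[2] > rng[1]) (col - rng[1]) / (rng[2] - rng[1]) else
      rep(0, length(col))
    score <- score + weights[[nm]] * z
  }
  ord <- order(score, feasible$minutes, feasible$transfers, feasible$price)
  ord[1]
}

# --- hand-built two-district study area for indicator arithmetic ----------
# District DA: municipalities a1 (100 recipients, hosts a residential
# facility), a2 (50), a3 (50); DB: b1 (200, hosts a clinic facility).
# Roads: a1-a2 20 min, a2-a3 25 min, a1-b1 50 min.
tiny_dataset <- function() {
  ds <- list(
    regions = c("RA", "RB"),
    districts = data.frame(id = c("DA", "DB"), region_id = c("RA", "RB"),
                           name = c("A", "B"), stringsAsFactors = FALSE),
    municipalities = data.frame(
      id = c("a1", "a2", "a3", "b1"),
      district_id = c("DA", "DA", "DA", "DB"),
      x = c(0, 10, 20, 40), y = c(0, 0, 0, 0),
      recipients_65plus = c(100L, 50L, 50L, 200L),
      network_node = c("a1", "a2", "a3", "b1"),
      stringsAsFactors = FALSE),
    facilities = data.frame(
      id = c("F1", "F2"),
      service_class = c("residential", "clinic"),
      subtype = c("home_for_elderly", "day_care_centre"),
      municipality_id = c("a1", "b1"),
      capacity = c(40L, 10L), stringsAsFactors = FALSE),
    road_network = list(
      nodes = data.frame(id = c("a1", "a2", "a3", "b1"),
                         x = c(0, 10, 20, 40), y = c(0, 0, 0, 0),
                         stringsAsFactors = FALSE),
      edges = data.frame(from_node = c("a1", "a2", "a1"),
                         to_node = c("a2", "a3", "b1"),
                         minutes = c(20, 25, 50), stringsAsFactors = FALSE)),
    timetable = data.frame(
      origin = c("a1", "a2"), destination = c("b1", "a1"),
      departure = c(790L, 810L), arrival = c(840L, 840L),
      minutes = c(50, 30), transfers = c(1L, 0L),
      price = c(40, 20), distance_km = c(40, 10),
      stringsAsFactors = FALSE),
    edit_log = data.frame(action = character(), target = character(),
                          detail = character(), stringsAsFactors = FALSE),
    config = NULL)
  class(ds) <- "caregap_dataset"
  ds
}

small_region_config <- function(seed) {
  region_config(n_regions = 2,
                districts_per_region = c(2, 2),
                municipalities_per_district = c(3, 5),
                facility_density = c(residential = 3, clinic = 3),
                transit_coverage = 0.5,
                seed = seed)
}
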