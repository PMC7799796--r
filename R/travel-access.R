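#' Access computation settings
#'
#' Bundles the travel-time bands, the service-specific required arrival
#' times, the public-transport feasibility filters and the connection
#' weighing weights.
#'
#' Defaults follow the study design for commuting to care services:
#' cumulative 30- and 60-minute budgets; arrivals at 14:00 for residential
#' services and at 07:00 or 08:00 for day-care/day-services visits, on a
#' common workday (Tuesday); and public-transport connections admitted only
#' when the journey is shorter than 90 minutes, has at most five transfers
#' and covers a direct distance below 150 km.
#'
#' @param bands strictly increasing travel-time budgets in minutes.
#' @param arrival_times named list of required arrival times
#'   (minutes-of-day) per service class.
#' @param weekday label recorded with the run (no computation depends on it;
#'   the timetable is already the chosen day's).
#' @param pt_max_minutes journeys must be strictly shorter than this.
#' @param pt_max_transfers maximal number of changes (inclusive).
#' @param pt_max_distance_km direct distance must be strictly below this.
#' @param arrival_tolerance minutes of slack allowed around a required
#'   arrival time (0 = exact-minute matching).
#' @param weighing_weights nonnegative weights over the five connection
#'   attributes `travel_minutes`, `arrival_slack`, `departure_lateness`,
#'   `transfers`, `price` used by [select_best_connection()].
#' @param it_targets `"host_municipality"` (default; road travel is measured
#'   to the facility's hosting municipality node, symmetric with public
#'   transport) or `"facility_node"` (identical here since facilities sit on
#'   municipal nodes, kept as an explicit switch).
#' @return An object of class `caregap_access_config`.
#' @export
access_config <- function(bands = c(30, 60),
                          arrival_times = list(residential = 840L,
                                               clinic = c(420L, 480L)),
                          weekday = "Tuesday",
                          pt_max_minutes = 90,
                          pt_max_transfers = 5,
                          pt_max_distance_km = 150,
                          arrival_tolerance = 0,
                          weighing_weights = c(travel_minutes = 0.5,
                                               arrival_slack = 0.1,
                                               departure_lateness = 0.1,
                                               transfers = 0.2,
                                               price = 0.1),
                          it_targets = c("host_municipality",
                                         "facility_node")) {
  if (any(diff(bands) <= 0) || any(bands <= 0))
    stop("'bands' must be strictly increasing positive budgets",
         call. = FALSE)
  if (pt_max_minutes <= 0 || pt_max_transfers < 0 || pt_max_distance_km <= 0)
    stop("public-transport filters must be positive", call. = FALSE)
  if (any(weighing_weights < 0) || sum(weighing_weights) == 0)
    stop("'weighing_weights' must be nonnegative with a positive sum",
         call. = FALSE)
  cfg <- list(bands = bands, arrival_times = arrival_times,
              weekday = weekday, pt_max_minutes = pt_max_minutes,
              pt_max_transfers = pt_max_transfers,
              pt_max_distance_km = pt_max_distance_km,
              arrival_tolerance = arrival_tolerance,
              weighing_weights = weighing_weights,
              it_targets = match.arg(it_targets))
  class(cfg) <- "caregap_access_config"
  cfg
}

#' Minimal road travel time from each origin to the nearest target
#'
#' Single-source shortest paths over the undirected travel-time graph:
#' for every origin node the minimum, over all target nodes, of the
#' shortest-path travel time. The classical GIS "service area" question
#' ("which origins lie within b minutes of a facility?") is answered by
#' thresholding the result.
#'
#' @param network a road network: list with `nodes` (`id`) and `edges`
#'   (`from_node`, `to_node`, `minutes`) data frames.
#' @param origins,targets character vectors of node ids.
#' @return Named numeric vector, minutes per origin; `Inf` when no target
#'   is reachable. An origin that is itself a target gets 0.
#' @examples
#' net <- list(nodes = data.frame(id = c("A", "B")),
#'             edges = data.frame(from_node = "A", to_node = "B",
#'                                minutes = 10))
#' shortest_travel_times(net, "A", "B")
#' @export
shortest_travel_times <- function(network, origins, targets) {
  ids <- network$nodes$id
  unknown <- setdiff(c(origins, targets), ids)
  if (length(unknown))
    stop(sprintf("unknown node id(s): %s",
                 paste(unique(unknown), collapse = ", ")), call. = FALSE)
  if (length(targets) == 0)
    return(stats::setNames(rep(Inf, length(origins)), origins))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from_node", "to_node")],
    directed = FALSE,
    vertices = data.frame(name = ids))
  d <- igraph::distances(g, v = origins, to = unique(targets),
                         weights = network$edges$minutes)
  stats::setNames(apply(d, 1, min), origins)
}

#' Band membership of travel times
#'
#' Flags, for each travel time, whether it falls within each cumulative
#' budget: `flag_b` is true iff `minutes <= b`. Membership is monotone
#' across increasing bands, and infinite (unreachable) times belong to no
#' band.
#'
#' @param minutes numeric vector of minimal travel times (may be `Inf`).
#' @param bands strictly increasing budgets in minutes.
#' @return Logical matrix, one row per entry of `minutes`, columns named
#'   `within<band>`.
#' @examples
#' band_membership(c(29.9, 45, Inf), c(30, 60))
#' @export
band_membership <- function(minutes, bands = c(30, 60)) {
  if (any(diff(bands) <= 0))
    stop("'bands' must be strictly increasing", call. = FALSE)
  m <- outer(minutes, bands, "<=")
  dimnames(m) <- list(names(minutes), paste0("within", bands))
  m
}

#' Filter a timetable to feasible connections
#'
#' Retains exactly the connections satisfying every feasibility rule:
#' travel time strictly below `pt_max_minutes`, at most `pt_max_transfers`
#' changes, direct distance strictly below `pt_max_distance_km`, and
#' arrival at one of the required arrival times (exact minute match by
#' default; `arrival_tolerance` widens this symmetrically).
#'
#' @param timetable data frame with columns `origin`, `destination`,
#'   `departure`, `arrival` (minutes-of-day), `minutes`, `transfers`,
#'   `price`, `distance_km`.
#' @param cfg an [access_config()].
#' @param arrival_times required arrival times in minutes-of-day (e.g. the
#'   service class's entry of `cfg$arrival_times`).
#' @return The feasible subset, with an added `matched_arrival` column
#'   giving the required arrival time each connection matched.
#' @export
filter_connections <- function(timetable, cfg, arrival_times) {
  if (nrow(timetable) == 0) {
    timetable$matched_arrival <- integer(0)
    return(timetable)
  }
  ok <- timetable$minutes < cfg$pt_max_minutes &
    timetable$transfers <= cfg$pt_max_transfers &
    timetable$distance_km < cfg$pt_max_distance_km
  slack <- abs(outer(timetable$arrival, arrival_times, "-"))
  nearest <- apply(slack, 1, which.min)
  matched <- arrival_times[nearest]
  ok <- ok & abs(timetable$arrival - matched) <= cfg$arrival_tolerance
  out <- timetable[ok, , drop = FALSE]
  out$matched_arrival <- matched[ok]
  rownames(out) <- NULL
  out
}

#' Pick the most suitable connection by weighted scoring
#'
#' Among the feasible connections of one origin--destination pair, returns
#' the one minimizing a min--max-normalized weighted sum over five
#' attributes: travel time, arrival slack (distance of the arrival from the
#' required arrival time), departure lateness (how early one must set out,
#' `matched_arrival - departure`), number of transfers, and price. Ties are
#' broken deterministically: lowest travel time, then fewest transfers,
#' then lowest price, then input order.
#'
#' @param feasible data frame as returned by [filter_connections()]
#'   (requires the `matched_arrival` column); must be nonempty.
#' @param weights named weights over the five attributes; defaults from
#'   [access_config()].
#' @return The single selected row.
#' @export
select_best_connection <- function(feasible,
                                   weights = access_config()$weighing_weights) {
  if (nrow(feasible) == 0)
    stop("no feasible connection", call. = FALSE)
  attrs <- cbind(
    travel_minutes = feasible$minutes,
    arrival_slack = abs(feasible$arrival - feasible$matched_arrival),
    departure_lateness = feasible$matched_arrival - feasible$departure,
    transfers = feasible$transfers,
    price = feasible$price)
  norm <- apply(attrs, 2, function(col) {
    rng <- range(col)
    if (rng[1] == rng[2]) rep(0, length(col))
    else (col - rng[1]) / (rng[2] - rng[1])
  })
  norm <- matrix(norm, nrow = nrow(feasible),
                 dimnames = list(NULL, colnames(attrs)))
  score <- as.numeric(norm %*% weights[colnames(attrs)])
  ord <- order(score, feasible$minutes, feasible$transfers, feasible$price,
               seq_len(nrow(feasible)))
  feasible[ord[1], , drop = FALSE]
}

#' Multimodal reachability of the nearest facility per municipality
#'
#' For every municipality, service class and transport mode, computes the
#' minimal travel time to the nearest municipality hosting a facility of
#' that class, plus band membership flags.
#'
#' Individual transport (`IT`) uses shortest paths on the road network to
#' the hosting municipalities' nodes. Public transport (`PT`) uses the
#' timetable: connections are filtered by [filter_connections()] with the
#' class's required arrival times, the best connection per
#' origin--destination pair is chosen by [select_best_connection()], and
#' the minimum over destinations hosting the service is taken. A
#' municipality hosting a facility of the class reaches it in 0 minutes by
#' either mode. Municipalities with no feasible connection are unreachable
#' by PT (`Inf`, all flags false).
#'
#' @param dataset a `caregap_dataset`.
#' @param cfg an [access_config()].
#' @return Data frame with columns `municipality`, `service_class`, `mode`,
#'   `minutes` and one logical `within<band>` column per band.
#' @export
compute_reachability <- function(dataset, cfg = access_config()) {
  validate_dataset(dataset)
  mun <- dataset$municipalities
  out <- list()
  for (cls in service_classes()) {
    hosts <- facility_hosts(dataset, cls)
    host_nodes <- mun$network_node[mun$id %in% hosts]

    it_min <- if (length(host_nodes))
      shortest_travel_times(dataset$road_network, mun$network_node,
                            host_nodes)
    else rep(Inf, nrow(mun))
    it_min <- unname(it_min)

    pt_min <- .pt_minimal_minutes(dataset, cls, cfg)

    for (md in c("IT", "PT")) {
      minutes <- if (md == "IT") it_min else pt_min
      flags <- band_membership(minutes, cfg$bands)
      out[[length(out) + 1L]] <- data.frame(
        municipality = mun$id, service_class = cls, mode = md,
        minutes = minutes, flags, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Minimal PT minutes per municipality to the nearest host of `cls`.
.pt_minimal_minutes <- function(dataset, cls, cfg) {
  mun <- dataset$municipalities
  hosts <- facility_hosts(dataset, cls)
  minutes <- rep(Inf, nrow(mun))
  minutes[mun$id %in% hosts] <- 0

  tt <- dataset$timetable
  if (nrow(tt) == 0 || length(hosts) == 0) return(minutes)
  feas <- filter_connections(tt, cfg, cfg$arrival_times[[cls]])
  feas <- feas[feas$destination %in% hosts, , drop = FALSE]
  if (nrow(feas) == 0) return(minutes)
  pair <- interaction(feas$origin, feas$destination, drop = TRUE)
  best <- do.call(rbind, lapply(split(feas, pair), select_best_connection,
                                weights = cfg$weighing_weights))
  agg <- tapply(best$minutes, best$origin, min)
  idx <- match(names(agg), mun$id)
  minutes[idx] <- pmin(minutes[idx], as.numeric(agg))
  minutes
}
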