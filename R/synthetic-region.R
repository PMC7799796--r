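#' Configuration for the synthetic study-area generator
#'
#' Defines the size and statistical properties of a simulated study area:
#' a hierarchy of regions, districts and municipalities; per-municipality
#' counts of care-allowance recipients aged 65+; facilities of two service
#' classes with capacities; a road network with per-edge travel minutes; and
#' a public-transport connection table.
#'
#' The defaults emulate a Czech-like national study area: 13 regions holding
#' between 3 and 12 districts each, overdispersed recipient counts (a few
#' hundred per municipality), roughly ten residential facilities per district
#' but fewer than two day-care/day-services facilities per district (so some
#' districts hold none), residential capacities around 45--55 beds and clinic
#' capacities of 5--15 daily spots.
#'
#' @param n_regions number of regions.
#' @param districts_per_region integer range `c(min, max)` of districts drawn
#'   per region.
#' @param municipalities_per_district integer range `c(min, max)`.
#' @param recipients_per_municipality [draw_spec()] for counts of allowance
#'   recipients aged 65+ per municipality.
#' @param facility_density named numeric `c(residential = , clinic = )`:
#'   expected facilities per district by service class (Poisson rates; may
#'   be 0 so that districts without providers are producible).
#' @param capacity_spec named list of [draw_spec()]s per service class:
#'   beds (residential) or daily spots (clinic).
#' @param road_edge_minutes [draw_spec()] for road travel minutes per 10 km
#'   of edge length (edge minutes scale with Euclidean length).
#' @param transit_coverage fraction of ordered municipality pairs (within
#'   150 km of each other) that receive at least one transit connection.
#' @param seed integer seed; the same config and seed reproduce an identical
#'   dataset.
#' @return An object of class `caregap_region_config`.
#' @seealso [generate_region()]
#' @export
region_config <- function(n_regions = 13,
                          districts_per_region = c(3, 9),
                          municipalities_per_district = c(5, 12),
                          recipients_per_municipality =
                            draw_spec("nbinom", mu = 250, size = 1.2),
                          facility_density = c(residential = 10, clinic = 1.75),
                          capacity_spec = list(
                            residential = draw_spec("lnorm",
                                                    meanlog = log(45),
                                                    sdlog = 0.5),
                            clinic = draw_spec("unif", min = 5, max = 15)),
                          road_edge_minutes = draw_spec("unif",
                                                        min = 8, max = 14),
                          transit_coverage = 0.35,
                          seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              districts_per_region = as.integer(districts_per_region),
              municipalities_per_district =
                as.integer(municipalities_per_district),
              recipients_per_municipality = recipients_per_municipality,
              facility_density = facility_density,
              capacity_spec = capacity_spec,
              road_edge_minutes = road_edge_minutes,
              transit_coverage = transit_coverage,
              seed = as.integer(seed))
  class(cfg) <- "caregap_region_config"
  validate_region_config(cfg)
  cfg
}

validate_region_config <- function(cfg) {
  stopifnot(inherits(cfg, "caregap_region_config"))
  if (cfg$n_regions < 1)
    stop("'n_regions' must be >= 1", call. = FALSE)
  for (f in c("districts_per_region", "municipalities_per_district")) {
    rng <- cfg[[f]]
    if (length(rng) != 2 || any(rng < 1) || rng[1] > rng[2])
      stop(sprintf("'%s' must be an increasing range of counts >= 1", f),
           call. = FALSE)
  }
  validate_draw_spec(cfg$recipients_per_municipality,
                     "recipients_per_municipality")
  fd <- cfg$facility_density
  if (!all(c("residential", "clinic") %in% names(fd)) || any(fd < 0))
    stop("'facility_density' needs nonnegative 'residential' and 'clinic' rates",
         call. = FALSE)
  for (cls in c("residential", "clinic"))
    validate_draw_spec(cfg$capacity_spec[[cls]],
                       sprintf("capacity_spec$%s", cls))
  validate_draw_spec(cfg$road_edge_minutes, "road_edge_minutes")
  if (cfg$transit_coverage < 0 || cfg$transit_coverage > 1)
    stop("'transit_coverage' must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

.subtypes <- list(
  residential = c("home_for_elderly", "special_regime_home"),
  clinic      = c("day_care_centre", "day_services_centre")
)

#' Service classes and facility subtypes
#'
#' Two service classes are analysed: `residential` (homes for the elderly
#' and special-regime homes, long-term bed-based care) and `clinic`
#' (day-care centres and day-services centres, visit-only daytime care).
#'
#' @return `service_classes()` returns the two class labels;
#'   `facility_subtypes()` the subtype labels of one class.
#' @param service_class one of `"residential"`, `"clinic"`.
#' @export
service_classes <- function() c("residential", "clinic")

#' @rdname service_classes
#' @export
facility_subtypes <- function(service_class) {
  .subtypes[[match.arg(service_class, service_classes())]]
}

#' Generate a seeded synthetic study area
#'
#' Builds a full simulated study area from a [region_config()]: nested
#' regions, districts and municipalities with planar coordinates; allowance
#' recipient counts; facilities with capacities; a road network whose
#' restriction to any district is connected; and a transit timetable whose
#' connections have departure/arrival clock times, transfer counts, prices
#' and direct distances.
#'
#' Municipal placement is planar (abstract x/y in km). Intra-district roads
#' form a spanning tree plus random extra links; district and region hubs
#' are chained so the whole network is connected. Transit connections are
#' generated for a seeded random subset of ordered municipality pairs within
#' 150 km; most arrive exactly at 07:00, 08:00 or 14:00, and a minority
#' carry off-pattern arrival times, long durations or many transfers so that
#' the timetable filters have work to do on realistic input.
#'
#' @param config a [region_config()].
#' @return An object of class `caregap_dataset`: a list with elements
#'   `regions` (character), `districts`, `municipalities`, `facilities`
#'   (data frames), `road_network` (list of `nodes` and `edges` data frames),
#'   `timetable` (data frame), `edit_log` (data frame, empty until
#'   [plant_gap_scenario()] is used) and `config`.
#' @examples
#' ds <- generate_region(region_config(n_regions = 2,
#'                                     districts_per_region = c(2, 2),
#'                                     municipalities_per_district = c(3, 3),
#'                                     seed = 7))
#' nrow(ds$municipalities)
#' @export
generate_region <- function(config) {
  validate_region_config(config)
  with_seed(config$seed, .generate_region_impl(config))
}

.generate_region_impl <- function(cfg) {
  regions <- sprintf("R%02d", seq_len(cfg$n_regions))

  ## region centres on a grid, ~110 km spacing
  ncol_grid <- ceiling(sqrt(cfg$n_regions))
  rx <- ((seq_along(regions) - 1) %% ncol_grid) * 110
  ry <- ((seq_along(regions) - 1) %/% ncol_grid) * 110

  sample_range <- function(rng, n) {
    vals <- seq(rng[1], rng[2])
    if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = TRUE)
  }
  n_dist <- sample_range(cfg$districts_per_region, cfg$n_regions)
  districts <- data.frame(
    id = sprintf("D%03d", seq_len(sum(n_dist))),
    region_id = rep(regions, n_dist),
    stringsAsFactors = FALSE)
  districts$name <- paste0("District ", districts$id)
  dcx <- rep(rx, n_dist) + stats::runif(nrow(districts), -35, 35)
  dcy <- rep(ry, n_dist) + stats::runif(nrow(districts), -35, 35)

  n_mun <- sample_range(cfg$municipalities_per_district, nrow(districts))
  municipalities <- data.frame(
    id = sprintf("M%04d", seq_len(sum(n_mun))),
    district_id = rep(districts$id, n_mun),
    x = rep(dcx, n_mun) + stats::runif(sum(n_mun), -12, 12),
    y = rep(dcy, n_mun) + stats::runif(sum(n_mun), -12, 12),
    recipients_65plus =
      as.integer(round(draw_values(cfg$recipients_per_municipality,
                                   sum(n_mun)))),
    stringsAsFactors = FALSE)
  municipalities$recipients_65plus <-
    pmax(municipalities$recipients_65plus, 0L)
  municipalities$network_node <- municipalities$id

  facilities <- .generate_facilities(cfg, districts, municipalities)
  road <- .generate_road_network(cfg, districts, municipalities)
  timetable <- .generate_timetable(cfg, municipalities)

  ds <- list(regions = regions,
             districts = districts,
             municipalities = municipalities,
             facilities = facilities,
             road_network = road,
             timetable = timetable,
             edit_log = .empty_edit_log(),
             config = cfg)
  class(ds) <- "caregap_dataset"
  ds
}

.generate_facilities <- function(cfg, districts, municipalities) {
  rows <- list()
  for (cls in service_classes()) {
    n_fac <- stats::rpois(nrow(districts), cfg$facility_density[[cls]])
    for (d in seq_len(nrow(districts))) {
      if (n_fac[d] == 0) next
      mun <- municipalities$id[municipalities$district_id == districts$id[d]]
      host <- sample(mun, n_fac[d], replace = TRUE)
      sub <- sample(.subtypes[[cls]], n_fac[d], replace = TRUE,
                    prob = c(0.8, 0.2))
      cap <- pmax(1L, as.integer(round(
        draw_values(cfg$capacity_spec[[cls]], n_fac[d]))))
      rows[[length(rows) + 1L]] <- data.frame(
        service_class = cls, subtype = sub, municipality_id = host,
        capacity = cap, stringsAsFactors = FALSE)
    }
  }
  fac <- if (length(rows)) do.call(rbind, rows) else
    data.frame(service_class = character(), subtype = character(),
               municipality_id = character(), capacity = integer(),
               stringsAsFactors = FALSE)
  fac <- cbind(data.frame(id = sprintf("F%04d", seq_len(nrow(fac))),
                          stringsAsFactors = FALSE), fac)
  fac
}

.edge_minutes <- function(cfg, x1, y1, x2, y2) {
  km <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  pmax(1, round(km / 10 * draw_values(cfg$road_edge_minutes, length(km)), 1))
}

.generate_road_network <- function(cfg, districts, municipalities) {
  from <- character(0); to <- character(0)
  fx <- numeric(0); fy <- numeric(0); tx <- numeric(0); ty <- numeric(0)
  add_edge <- function(a, b) {
    ia <- match(a, municipalities$id); ib <- match(b, municipalities$id)
    from <<- c(from, a); to <<- c(to, b)
    fx <<- c(fx, municipalities$x[ia]); fy <<- c(fy, municipalities$y[ia])
    tx <<- c(tx, municipalities$x[ib]); ty <<- c(ty, municipalities$y[ib])
  }
  ## intra-district spanning tree + random extras
  for (d in districts$id) {
    idx <- which(municipalities$district_id == d)
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        prev <- idx[1:(k - 1)]
        dist <- (municipalities$x[prev] - municipalities$x[idx[k]])^2 +
                (municipalities$y[prev] - municipalities$y[idx[k]])^2
        add_edge(municipalities$id[idx[k]],
                 municipalities$id[prev[which.min(dist)]])
      }
      extra <- which(stats::runif(length(idx)) < 0.3)
      for (k in extra) {
        others <- setdiff(idx, idx[k])
        other <- others[sample.int(length(others), 1)]
        add_edge(municipalities$id[idx[k]], municipalities$id[other])
      }
    }
  }
  ## hub spanning trees: districts within a region, then regions
  hubs <- vapply(districts$id, function(d)
    municipalities$id[municipalities$district_id == d][1], character(1))
  for (r in unique(districts$region_id)) {
    h <- hubs[districts$region_id == r]
    if (length(h) > 1)
      for (k in 2:length(h)) {
        prev <- h[1:(k - 1)]
        i <- match(h[k], municipalities$id); j <- match(prev, municipalities$id)
        dist <- (municipalities$x[j] - municipalities$x[i])^2 +
                (municipalities$y[j] - municipalities$y[i])^2
        add_edge(h[k], prev[which.min(dist)])
      }
  }
  rhubs <- vapply(unique(districts$region_id), function(r)
    hubs[districts$region_id == r][1], character(1))
  if (length(rhubs) > 1)
    for (k in 2:length(rhubs)) {
      prev <- rhubs[1:(k - 1)]
      i <- match(rhubs[k], municipalities$id)
      j <- match(prev, municipalities$id)
      dist <- (municipalities$x[j] - municipalities$x[i])^2 +
              (municipalities$y[j] - municipalities$y[i])^2
      add_edge(rhubs[k], prev[which.min(dist)])
    }
  edges <- data.frame(from_node = from, to_node = to,
                      minutes = .edge_minutes(cfg, fx, fy, tx, ty),
                      stringsAsFactors = FALSE)
  ## drop accidental duplicates, keep the faster edge
  key <- paste(pmin(edges$from_node, edges$to_node),
               pmax(edges$from_node, edges$to_node))
  edges <- edges[order(key, edges$minutes), ]
  edges <- edges[!duplicated(paste(pmin(edges$from_node, edges$to_node),
                                   pmax(edges$from_node, edges$to_node))), ]
  rownames(edges) <- NULL
  list(nodes = data.frame(id = municipalities$id,
                          x = municipalities$x, y = municipalities$y,
                          stringsAsFactors = FALSE),
       edges = edges)
}

.arrival_pattern <- c(420L, 480L, 840L)  # 07:00, 08:00, 14:00

.empty_timetable <- function() {
  data.frame(origin = character(), destination = character(),
             departure = integer(), arrival = integer(),
             minutes = numeric(), transfers = integer(),
             price = numeric(), distance_km = numeric(),
             stringsAsFactors = FALSE)
}

.generate_timetable <- function(cfg, municipalities) {
  n <- nrow(municipalities)
  if (n < 2 || cfg$transit_coverage == 0) return(.empty_timetable())
  ## candidate ordered pairs within 150 km, sampled at the coverage rate
  dx <- outer(municipalities$x, municipalities$x, "-")
  dy <- outer(municipalities$y, municipalities$y, "-")
  km <- sqrt(dx^2 + dy^2)
  cand <- which(km < 150 & km > 0, arr.ind = TRUE)
  keep <- stats::runif(nrow(cand)) < cfg$transit_coverage
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(.empty_timetable())
  n_conn <- sample(1:2, nrow(cand), replace = TRUE)
  i <- rep(cand[, 1], n_conn); j <- rep(cand[, 2], n_conn)
  d_km <- km[cbind(i, j)]
  pace <- stats::runif(length(i), 1.2, 2.2)        # min per km incl. waits
  minutes <- round(pmax(5, d_km * pace + stats::rnorm(length(i), 0, 4)))
  transfers <- pmin(stats::rpois(length(i), 0.8), 6L)
  ## 80% of connections arrive on the 07:00/08:00/14:00 pattern
  on_pattern <- stats::runif(length(i)) < 0.8
  arrival <- ifelse(on_pattern,
                    sample(.arrival_pattern, length(i), replace = TRUE),
                    sample(300:1200, length(i), replace = TRUE))
  departure <- arrival - minutes
  ok <- departure >= 0 & minutes < 600
  data.frame(origin = municipalities$id[i][ok],
             destination = municipalities$id[j][ok],
             departure = as.integer(departure[ok]),
             arrival = as.integer(arrival[ok]),
             minutes = as.numeric(minutes[ok]),
             transfers = as.integer(transfers[ok]),
             price = round(2 + 1.5 * d_km[ok] * stats::runif(sum(ok), 0.8, 1.2),
                           1),
             distance_km = round(d_km[ok], 1),
             stringsAsFactors = FALSE)
}

.empty_edit_log <- function() {
  data.frame(action = character(), target = character(),
             detail = character(), stringsAsFactors = FALSE)
}

#' @export
print.caregap_dataset <- function(x, ...) {
  cat("Synthetic study area:",
      length(x$regions), "regions,",
      nrow(x$districts), "districts,",
      nrow(x$municipalities), "municipalities\n")
  cat("  facilities:",
      sum(x$facilities$service_class == "residential"), "residential /",
      sum(x$facilities$service_class == "clinic"), "clinic\n")
  cat("  road edges:", nrow(x$road_network$edges),
      " transit connections:", nrow(x$timetable), "\n")
  if (nrow(x$edit_log))
    cat("  planted edits:", nrow(x$edit_log), "\n")
  invisible(x)
}

validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "caregap_dataset"))
  if (anyDuplicated(ds$districts$id))
    stop("duplicate district ids", call. = FALSE)
  if (!all(ds$districts$region_id %in% ds$regions))
    stop("district references unknown region", call. = FALSE)
  if (!all(ds$municipalities$district_id %in% ds$districts$id))
    stop("municipality references unknown district", call. = FALSE)
  if (!all(ds$facilities$municipality_id %in% ds$municipalities$id))
    stop("facility references unknown municipality", call. = FALSE)
  for (k in seq_len(nrow(ds$facilities))) {
    cls <- ds$facilities$service_class[k]
    if (!ds$facilities$subtype[k] %in% .subtypes[[cls]])
      stop(sprintf("facility %s: subtype inconsistent with service class",
                   ds$facilities$id[k]), call. = FALSE)
  }
  if (any(ds$facilities$capacity <= 0))
    stop("facility capacities must be positive", call. = FALSE)
  if (any(ds$municipalities$recipients_65plus < 0))
    stop("recipient counts must be nonnegative", call. = FALSE)
  invisible(ds)
}

#' Municipalities hosting a facility of a service class
#' @param dataset a `caregap_dataset`.
#' @param service_class `"residential"` or `"clinic"`.
#' @return Character vector of municipality ids.
#' @export
facility_hosts <- function(dataset, service_class) {
  cls <- match.arg(service_class, service_classes())
  unique(dataset$facilities$municipality_id[
    dataset$facilities$service_class == cls])
}

#' Plant a known accessibility class into one district
#'
#' Edits facilities, road edges and/or transit connections of `dataset` so
#' that the district's later-computed coverage falls into the requested
#' accessibility class for the given service class and transport mode. Used
#' for recovery testing of the classifier: the planted class must be
#' returned by [classify_districts()] on the edited dataset.
#'
#' Construction by class:
#' \describe{
#'   \item{I (good)}{a facility of the class is placed in every municipality
#'     of the district, so each municipality reaches a provider in 0 minutes
#'     by either mode and a provider seat is present.}
#'   \item{II (lowered)}{all of the district's facilities of the class are
#'     removed and each municipality is given a direct 45-minute link (road
#'     edge or transit connection, per `mode`) to an external facility host:
#'     everything is reachable within 60 but nothing within 30, and no
#'     provider sits in the district.}
#'   \item{III (poor)}{all of the district's facilities of the class are
#'     removed and the district is cut off in the given mode (incident road
#'     edges inflated beyond any 60-minute budget, or outbound transit
#'     connections dropped).}
#' }
#'
#' Every edit is appended to `dataset$edit_log`.
#'
#' @param dataset a `caregap_dataset`.
#' @param district_id district to edit.
#' @param service_class `"residential"` or `"clinic"`.
#' @param mode `"IT"` (individual) or `"PT"` (public transport).
#' @param target_class `"I"`, `"II"` or `"III"`.
#' @return The edited dataset.
#' @export
plant_gap_scenario <- function(dataset, district_id, service_class, mode,
                               target_class) {
  validate_dataset(dataset)
  cls <- match.arg(service_class, service_classes())
  mode <- match.arg(mode, c("IT", "PT"))
  target_class <- match.arg(target_class, c("I", "II", "III"))
  if (!district_id %in% dataset$districts$id)
    stop(sprintf("unknown district '%s'", district_id), call. = FALSE)
  mun <- dataset$municipalities$id[
    dataset$municipalities$district_id == district_id]

  log <- dataset$edit_log
  note <- function(action, target, detail) {
    log <<- rbind(log, data.frame(action = action, target = target,
                                  detail = detail, stringsAsFactors = FALSE))
  }

  if (target_class == "I") {
    ## one facility of the class in every municipality of the district
    present <- dataset$facilities$municipality_id[
      dataset$facilities$service_class == cls]
    missing <- setdiff(mun, present)
    if (length(missing)) {
      new_id <- paste0("FP_", district_id, "_", substr(cls, 1, 3), "_",
                       seq_along(missing))
      add <- data.frame(id = new_id, service_class = cls,
                        subtype = .subtypes[[cls]][1],
                        municipality_id = missing,
                        capacity = 30L, stringsAsFactors = FALSE)
      dataset$facilities <- rbind(dataset$facilities, add)
      for (m in missing) note("add_facility", m, cls)
    }
  } else {
    ## II and III both require the district to hold no provider of the class
    drop <- dataset$facilities$service_class == cls &
      dataset$facilities$municipality_id %in% mun
    for (f in dataset$facilities$id[drop]) note("remove_facility", f, cls)
    dataset$facilities <- dataset$facilities[!drop, , drop = FALSE]

    if (target_class == "III") {
      if (mode == "IT") {
        hit <- dataset$road_network$edges$from_node %in% mun |
               dataset$road_network$edges$to_node %in% mun
        dataset$road_network$edges$minutes[hit] <- 10000
        note("inflate_edges", district_id, sprintf("%d road edges", sum(hit)))
      } else {
        hit <- dataset$timetable$origin %in% mun
        dataset$timetable <- dataset$timetable[!hit, , drop = FALSE]
        note("drop_connections", district_id,
             sprintf("%d outbound connections", sum(hit)))
      }
    } else {  # class II: reachable within 60 but not 30, no provider
      host <- setdiff(facility_hosts(dataset, cls), mun)
      if (length(host) == 0)
        stop(sprintf(
          "cannot plant class II in %s: no external %s facility host exists",
          district_id, cls), call. = FALSE)
      host <- host[1]
      if (mode == "IT") {
        add <- data.frame(from_node = mun, to_node = host, minutes = 45,
                          stringsAsFactors = FALSE)
        dataset$road_network$edges <- rbind(dataset$road_network$edges, add)
        note("add_edges", district_id,
             sprintf("direct 45-min links to %s", host))
        ## no faster road may reach a host: inflate other incident edges
        e <- dataset$road_network$edges
        hit <- (e$from_node %in% mun | e$to_node %in% mun) &
          !(e$to_node == host & e$from_node %in% mun) &
          !(e$from_node == host & e$to_node %in% mun)
        dataset$road_network$edges$minutes[hit] <- 10000
        note("inflate_edges", district_id, sprintf("%d road edges", sum(hit)))
      } else {
        hit <- dataset$timetable$origin %in% mun
        dataset$timetable <- dataset$timetable[!hit, , drop = FALSE]
        note("drop_connections", district_id,
             sprintf("%d outbound connections", sum(hit)))
        arr <- if (cls == "residential") 840L else 420L
        add <- data.frame(origin = mun, destination = host,
                          departure = arr - 45L, arrival = arr,
                          minutes = 45, transfers = 0L, price = 30,
                          distance_km = 40, stringsAsFactors = FALSE)
        dataset$timetable <- rbind(dataset$timetable, add)
        note("add_connections", district_id,
             sprintf("45-min connections to %s", host))
      }
    }
  }
  dataset$edit_log <- log
  rownames(dataset$facilities) <- NULL
  rownames(dataset$timetable) <- NULL
  validate_dataset(dataset)
}
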