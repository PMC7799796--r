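#' Write a synthetic dataset to CSV files
#'
#' Serializes a dataset into five CSV files under `dir`:
#' `districts.csv` (`id,region_id,name`), `municipalities.csv`
#' (`id,district_id,x,y,recipients_65plus,network_node`), `facilities.csv`
#' (`id,service_class,subtype,municipality_id,capacity`), `road_edges.csv`
#' (`from_node,to_node,minutes`) and `transit_connections.csv`
#' (`origin,destination,departure,arrival,minutes,transfers,price,distance_km`,
#' times as `HH:MM`). [load_dataset()] reads them back.
#'
#' @param dataset a `caregap_dataset`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  validate_dataset(dataset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tt <- dataset$timetable
  tt$departure <- minutes_to_hhmm(tt$departure)
  tt$arrival <- minutes_to_hhmm(tt$arrival)
  files <- c(
    districts = "districts.csv", municipalities = "municipalities.csv",
    facilities = "facilities.csv", road_edges = "road_edges.csv",
    transit_connections = "transit_connections.csv")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  utils::write.csv(dataset$districts, paths["districts"], row.names = FALSE)
  utils::write.csv(dataset$municipalities, paths["municipalities"],
                   row.names = FALSE)
  utils::write.csv(dataset$facilities, paths["facilities"],
                   row.names = FALSE)
  utils::write.csv(dataset$road_network$edges, paths["road_edges"],
                   row.names = FALSE)
  utils::write.csv(tt, paths["transit_connections"], row.names = FALSE)
  invisible(paths)
}

.load_csv <- function(path, required) {
  if (!file.exists(path))
    stop(sprintf("input file missing: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Load a dataset from CSV files
#'
#' Reads the five CSV files written by [write_dataset()] and rebuilds a
#' validated `caregap_dataset`. Referential problems (e.g. a facility
#' naming an unknown municipality) are reported with the offending file
#' and row.
#'
#' @param dir directory holding the CSV files.
#' @return A `caregap_dataset` (without a generator `config`).
#' @export
load_dataset <- function(dir) {
  districts <- .load_csv(file.path(dir, "districts.csv"),
                         c("id", "region_id", "name"))
  municipalities <- .load_csv(
    file.path(dir, "municipalities.csv"),
    c("id", "district_id", "x", "y", "recipients_65plus", "network_node"))
  facilities <- .load_csv(
    file.path(dir, "facilities.csv"),
    c("id", "service_class", "subtype", "municipality_id", "capacity"))
  edges <- .load_csv(file.path(dir, "road_edges.csv"),
                     c("from_node", "to_node", "minutes"))
  tt <- .load_csv(
    file.path(dir, "transit_connections.csv"),
    c("origin", "destination", "departure", "arrival", "minutes",
      "transfers", "price", "distance_km"))

  bad <- which(!municipalities$district_id %in% districts$id)
  if (length(bad))
    stop(sprintf("municipalities.csv row %d: unknown district '%s'",
                 bad[1], municipalities$district_id[bad[1]]), call. = FALSE)
  bad <- which(!facilities$municipality_id %in% municipalities$id)
  if (length(bad))
    stop(sprintf("facilities.csv row %d: unknown municipality '%s'",
                 bad[1], facilities$municipality_id[bad[1]]), call. = FALSE)
  bad <- which(!(edges$from_node %in% municipalities$network_node &
                   edges$to_node %in% municipalities$network_node))
  if (length(bad))
    stop(sprintf("road_edges.csv row %d: unknown node", bad[1]),
         call. = FALSE)
  if (nrow(tt)) {
    tt$departure <- hhmm_to_minutes(tt$departure)
    tt$arrival <- hhmm_to_minutes(tt$arrival)
  } else {
    tt$departure <- integer(0); tt$arrival <- integer(0)
  }

  ds <- list(regions = unique(districts$region_id),
             districts = districts,
             municipalities = municipalities,
             facilities = facilities,
             road_network = list(
               nodes = data.frame(id = municipalities$network_node,
                                  x = municipalities$x,
                                  y = municipalities$y,
                                  stringsAsFactors = FALSE),
               edges = edges),
             timetable = tt[, c("origin", "destination", "departure",
                                "arrival", "minutes", "transfers", "price",
                                "distance_km")],
             edit_log = .empty_edit_log(),
             config = NULL)
  class(ds) <- "caregap_dataset"
  validate_dataset(ds)
  ds
}

#' Export municipalities and facilities as GeoJSON points
#'
#' Optional spatial export: a `FeatureCollection` of point features for
#' every municipality (with recipient count) and facility (with service
#' class and capacity), in the dataset's planar coordinates. Requires the
#' `jsonlite` package.
#'
#' @param dataset a `caregap_dataset`.
#' @param path output `.geojson` path.
#' @return Invisibly, `path`.
#' @export
write_geojson <- function(dataset, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("GeoJSON export requires the 'jsonlite' package", call. = FALSE)
  feature <- function(x, y, props) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(x, y)),
         properties = props)
  }
  mun <- dataset$municipalities
  fac <- merge(dataset$facilities, mun[, c("id", "x", "y")],
               by.x = "municipality_id", by.y = "id")
  feats <- c(
    lapply(seq_len(nrow(mun)), function(i)
      feature(mun$x[i], mun$y[i],
              list(kind = "municipality", id = mun$id[i],
                   district_id = mun$district_id[i],
                   recipients_65plus = mun$recipients_65plus[i]))),
    lapply(seq_len(nrow(fac)), function(i)
      feature(fac$x[i], fac$y[i],
              list(kind = "facility", id = fac$id[i],
                   service_class = fac$service_class[i],
                   capacity = fac$capacity[i]))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(obj), f)
  unname(tools::md5sum(f))
}

#' Run the full three-phase accessibility analysis
#'
#' Executes the pipeline end to end -- reachability, coverage indicators,
#' gap classification, TOPSIS ranking, correlation analysis -- and writes
#' the seven result tables to `outdir`:
#' `reachability.csv`, `indicators.csv`, `gap_classes.csv`,
#' `scale_table.csv`, `topsis_scores.csv`, `topsis_summary.csv` and
#' `correlations.csv`. Coverage percentages are exported with one decimal
#' and closeness scores with three; unreachable travel times are written
#' as empty fields. Deterministic given the dataset seed and the bootstrap
#' seed.
#'
#' @param dataset a `caregap_dataset`, or `NULL` to generate one from
#'   `region`.
#' @param outdir output directory.
#' @param region a [region_config()] (used when `dataset` is `NULL`).
#' @param access an [access_config()].
#' @param rule a [scale_rule()].
#' @param weights TOPSIS group weights, as [default_group_weights()].
#' @param bootstrap a [bootstrap_config()].
#' @return A run report: list with `manifest` (named file paths), `seed`,
#'   `config_hash`, `warnings` (character) and `results` (the in-memory
#'   stage outputs).
#' @export
run_full_analysis <- function(dataset = NULL, outdir,
                              region = region_config(),
                              access = access_config(),
                              rule = scale_rule(),
                              weights = default_group_weights(),
                              bootstrap = bootstrap_config()) {
  warnings_seen <- character(0)
  collect <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = collect),
             error = function(e)
               stop(sprintf("stage '%s' failed: %s", name,
                            conditionMessage(e)), call. = FALSE))
  }

  if (is.null(dataset))
    dataset <- stage("generate", generate_region(region))
  reach <- stage("travel_access", compute_reachability(dataset, access))
  ind <- stage("indicators", compute_indicators(dataset, reach))
  classes <- stage("gap_classification",
                   classify_districts(dataset, reach, rule))
  digits_by_class <- c(residential = 1, clinic = 0)
  tables <- stage("gap_classification", {
    out <- list()
    for (cls in service_classes()) for (md in c("IT", "PT")) {
      sub <- classes[classes$service_class == cls & classes$mode == md, ]
      st <- aggregate_scale_table(sub$class, sub$region_id,
                                  digits = digits_by_class[[cls]])
      out[[paste(cls, md, sep = "_")]] <- st
    }
    out
  })
  scores <- stage("topsis_ranking",
                  suppressMessages(topsis_all_groups(ind, weights)))
  assoc_in <- association_table(ind, scores)
  assoc <- stage("association",
                 correlation_matrix(assoc_in, bootstrap,
                                    on_zero_variance = "na"))

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- .write_result_tables(reach, ind, classes, tables, scores,
                                   assoc, outdir)
  list(manifest = manifest,
       seed = c(dataset = dataset$config$seed %||% NA_integer_,
                bootstrap = bootstrap$seed),
       config_hash = .config_hash(list(region = dataset$config, access,
                                       rule, weights, bootstrap)),
       warnings = warnings_seen,
       results = list(dataset = dataset, reachability = reach,
                      indicators = ind, gap_classes = classes,
                      scale_tables = tables, scores = scores,
                      correlations = assoc))
}

.write_result_tables <- function(reach, ind, classes, tables, scores,
                                 assoc, outdir) {
  p <- function(f) file.path(outdir, f)

  r_out <- reach
  r_out$minutes <- ifelse(is.finite(r_out$minutes),
                          format(r_out$minutes, trim = TRUE), "")
  utils::write.csv(r_out, p("reachability.csv"), row.names = FALSE)

  i_out <- ind
  covcols <- grep("^X[4-7]", names(i_out), value = TRUE)
  i_out[covcols] <- lapply(i_out[covcols], round, 1)
  utils::write.csv(i_out, p("indicators.csv"), row.names = FALSE)

  utils::write.csv(
    classes[, c("district_id", "service_class", "mode", "class")],
    p("gap_classes.csv"), row.names = FALSE)

  st_rows <- do.call(rbind, lapply(names(tables), function(nm) {
    st <- tables[[nm]]
    counts <- st$counts
    counts$table <- nm
    total <- data.frame(region = "Total in %",
                        I = st$total_percent[["I"]],
                        II = st$total_percent[["II"]],
                        III = st$total_percent[["III"]],
                        table = nm, stringsAsFactors = FALSE)
    rbind(counts, total)
  }))
  utils::write.csv(st_rows[, c("table", "region", "I", "II", "III")],
                   p("scale_table.csv"), row.names = FALSE)

  s_out <- scores$scores
  cicols <- grep("ci$", names(s_out), value = TRUE)
  s_out[cicols] <- lapply(s_out[cicols], round, 3)
  utils::write.csv(s_out, p("topsis_scores.csv"), row.names = FALSE)
  utils::write.csv(scores$summary, p("topsis_summary.csv"),
                   row.names = FALSE)

  utils::write.csv(assoc$pairs, p("correlations.csv"), row.names = FALSE)

  files <- c("reachability.csv", "indicators.csv", "gap_classes.csv",
             "scale_table.csv", "topsis_scores.csv", "topsis_summary.csv",
             "correlations.csv")
  stats::setNames(file.path(outdir, files), sub("[.]csv$", "", files))
}
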