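#' District base indicators: demand and capacity
#'
#' Aggregates the three base indicators per district: `X1`, the number of
#' care-allowance recipients aged 65+ (the demand proxy, summed over the
#' district's municipalities); `X2`, total capacity in beds of residential
#' facilities located in the district; and `X3`, total daily-spot capacity
#' of day-care/day-services facilities.
#'
#' @param dataset a `caregap_dataset`.
#' @return Data frame with columns `district_id`, `X1`, `X2`, `X3`
#'   (exact integer sums).
#' @export
aggregate_district_base <- function(dataset) {
  validate_dataset(dataset)
  dist <- dataset$districts$id
  x1 <- tapply(dataset$municipalities$recipients_65plus,
               factor(dataset$municipalities$district_id, levels = dist),
               sum, default = 0L)
  fac <- merge(dataset$facilities,
               dataset$municipalities[, c("id", "district_id")],
               by.x = "municipality_id", by.y = "id")
  cap <- function(cls) {
    f <- fac[fac$service_class == cls, ]
    tapply(f$capacity, factor(f$district_id, levels = dist), sum,
           default = 0L)
  }
  data.frame(district_id = dist,
             X1 = as.integer(x1),
             X2 = as.integer(cap("residential")),
             X3 = as.integer(cap("clinic")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Recipient-weighted coverage of one district
#'
#' The share (in percent) of a district's allowance recipients living in
#' municipalities from which a facility of the service class is reachable
#' within the travel-time band by the given mode:
#' \deqn{100 \cdot \frac{\sum X1_{d,\,\mathrm{within\ band}}}{\sum X1_d}.}
#'
#' A district with zero recipients has no defined recipient-weighted
#' coverage; by the package's degenerate rule its coverage is 0 with a
#' warning (such districts are dropped from TOPSIS ranking downstream).
#'
#' @param district_id a district id.
#' @param service_class `"residential"` or `"clinic"`.
#' @param mode `"IT"` or `"PT"`.
#' @param band a band listed in the reachability table's `within<band>`
#'   columns (e.g. 30 or 60).
#' @param reachability output of [compute_reachability()].
#' @param dataset the `caregap_dataset` the reachability was computed from.
#' @return Coverage percentage in \[0, 100\].
#' @export
coverage_percent <- function(district_id, service_class, mode, band,
                             reachability, dataset) {
  if (!district_id %in% dataset$districts$id)
    stop(sprintf("unknown district '%s'", district_id), call. = FALSE)
  cls <- match.arg(service_class, service_classes())
  mode <- match.arg(mode, c("IT", "PT"))
  col <- paste0("within", band)
  if (!col %in% names(reachability))
    stop(sprintf("band %s not present in reachability table", band),
         call. = FALSE)
  mun <- dataset$municipalities[
    dataset$municipalities$district_id == district_id, ]
  r <- reachability[reachability$service_class == cls &
                      reachability$mode == mode &
                      reachability$municipality %in% mun$id, ]
  flags <- r[[col]][match(mun$id, r$municipality)]
  total <- sum(mun$recipients_65plus)
  if (total == 0) {
    warning(sprintf("district %s has no recipients; coverage set to 0",
                    district_id), call. = FALSE)
    return(0)
  }
  100 * sum(mun$recipients_65plus[flags]) / total
}

.coverage_groups <- data.frame(
  group = c("X4", "X5", "X6", "X7"),
  service_class = c("residential", "residential", "clinic", "clinic"),
  mode = c("IT", "PT", "IT", "PT"),
  stringsAsFactors = FALSE)

#' The full district indicator table X1--X7
#'
#' Combines [aggregate_district_base()] with the eight coverage indicators:
#' `X4` residential by individual transport, `X5` residential by public
#' transport, `X6` clinic by individual transport, `X7` clinic by public
#' transport, each decomposed into an `a` part (within the first band,
#' 30 minutes by default) and a `b` part (within the second band,
#' 60 minutes). Bands are cumulative, so the `b` value is never below the
#' `a` value.
#'
#' @param dataset a `caregap_dataset`.
#' @param reachability output of [compute_reachability()]; computed with
#'   default settings when omitted.
#' @param cfg the [access_config()] used when `reachability` is omitted.
#' @return Data frame with columns `district_id`, `X1`, `X2`, `X3` and
#'   `X4a`, `X4b`, ..., `X7b` (percentages, full precision).
#' @export
compute_indicators <- function(dataset, reachability = NULL,
                               cfg = access_config()) {
  if (is.null(reachability)) reachability <- compute_reachability(dataset, cfg)
  base <- aggregate_district_base(dataset)
  bands <- .reachability_bands(reachability)
  if (length(bands) < 2)
    stop("reachability table must carry two bands (a and b parts)",
         call. = FALSE)
  mun <- dataset$municipalities
  for (g in seq_len(nrow(.coverage_groups))) {
    grp <- .coverage_groups[g, ]
    r <- reachability[reachability$service_class == grp$service_class &
                        reachability$mode == grp$mode, ]
    rec <- mun$recipients_65plus[match(r$municipality, mun$id)]
    dfac <- factor(mun$district_id[match(r$municipality, mun$id)],
                   levels = base$district_id)
    for (part in 1:2) {
      col <- paste0("within", bands[part])
      num <- tapply(rec * r[[col]], dfac, sum, default = 0)
      val <- ifelse(base$X1 > 0, 100 * as.numeric(num) / base$X1, 0)
      base[[paste0(grp$group, c("a", "b")[part])]] <- val
    }
  }
  if (any(base$X1 == 0))
    warning(sprintf("district(s) with no recipients (coverage set to 0): %s",
                    paste(base$district_id[base$X1 == 0], collapse = ", ")),
            call. = FALSE)
  base
}

.reachability_bands <- function(reachability) {
  cols <- grep("^within", names(reachability), value = TRUE)
  sort(as.numeric(sub("^within", "", cols)))
}
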