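#' Three-tier accessibility scale rule
#'
#' The scale assigns each district, per service class and transport mode,
#' one of three accessibility classes:
#' \describe{
#'   \item{I -- good (no gap)}{at least one provider of the service holds a
#'     seat in the district and reachability within 30 minutes covers most
#'     of the district (80--100\%);}
#'   \item{II -- lowered (with a gap)}{the residual middle category:
#'     regardless of provider presence, 30-minute reachability covers only
#'     part of the district, the rest being reachable within or beyond
#'     60 minutes;}
#'   \item{III -- poor (significant gap)}{no provider holds a seat in the
#'     district and most of the district (60\% or more) lies beyond
#'     60 minutes.}
#' }
#'
#' The verbal scale leaves holes (e.g. a 30-minute share of 70--80\%
#' matches neither the good nor the lowered wording); the rule is made
#' total by half-open thresholds with II as the residual class, which keeps
#' the three categories exhaustive and mutually exclusive.
#'
#' @param good_min_cov30 minimal 30-minute coverage (\%) for class I.
#' @param lowered_min_cov30 lower edge (\%) of the lowered band, kept for
#'   documentation of the verbal scale; II is the residual class so the
#'   value does not enter the decision rule.
#' @param poor_max_cov60 maximal 60-minute coverage (\%) for class III
#'   (40 means at least 60\% of recipients are beyond 60 minutes).
#' @param basis `"recipients"` (coverage weighted by allowance recipients,
#'   the quantity the coverage indicators formalize) or `"area"`
#'   (municipality-count share as an areal proxy, for sensitivity runs).
#' @return An object of class `caregap_scale_rule`.
#' @export
scale_rule <- function(good_min_cov30 = 80, lowered_min_cov30 = 50,
                       poor_max_cov60 = 40,
                       basis = c("recipients", "area")) {
  if (!(0 <= lowered_min_cov30 && lowered_min_cov30 < good_min_cov30 &&
          good_min_cov30 <= 100))
    stop("need 0 <= lowered_min_cov30 < good_min_cov30 <= 100",
         call. = FALSE)
  rule <- list(good_min_cov30 = good_min_cov30,
               lowered_min_cov30 = lowered_min_cov30,
               poor_max_cov60 = poor_max_cov60,
               basis = match.arg(basis))
  class(rule) <- "caregap_scale_rule"
  rule
}

#' Classify one district-service-mode combination
#'
#' Vectorized decision rule of the three-tier scale: class I iff a provider
#' is present and 30-minute coverage reaches the good threshold; class III
#' iff no provider is present and 60-minute coverage is at or below the
#' poor threshold; class II otherwise. Checked in the order I, III, II, the
#' rule is exhaustive and returns exactly one class for every admissible
#' input.
#'
#' @param provider_present logical: at least one facility of the service
#'   class is located in the district.
#' @param cov30,cov60 coverage percentages within 30 and 60 minutes;
#'   `cov30 <= cov60` is required (bands are cumulative).
#' @param rule a [scale_rule()].
#' @return Character vector of classes `"I"`, `"II"`, `"III"`.
#' @examples
#' classify_gap(TRUE, 100, 100)   # I
#' classify_gap(FALSE, 60, 90)    # II
#' classify_gap(FALSE, 0, 0)      # III
#' @export
classify_gap <- function(provider_present, cov30, cov60,
                         rule = scale_rule()) {
  if (any(cov30 > cov60 + 1e-9))
    stop("cov30 exceeds cov60: bands must be cumulative", call. = FALSE)
  if (any(cov30 < 0 | cov60 > 100))
    stop("coverage values must lie in [0, 100]", call. = FALSE)
  ifelse(provider_present & cov30 >= rule$good_min_cov30, "I",
         ifelse(!provider_present & cov60 <= rule$poor_max_cov60, "III",
                "II"))
}

#' Classify every district for both services and modes
#'
#' Applies [classify_gap()] to each district, service class and transport
#' mode. Provider presence means at least one facility of the class is
#' physically located in the district, regardless of capacity. With
#' `rule$basis = "recipients"` the coverage values are the recipient-
#' weighted indicators; with `"area"` the municipality-count share within
#' each band is used instead.
#'
#' @param dataset a `caregap_dataset`.
#' @param reachability output of [compute_reachability()]; computed with
#'   `cfg` when omitted.
#' @param rule a [scale_rule()].
#' @param cfg an [access_config()].
#' @return Data frame with columns `district_id`, `region_id`,
#'   `service_class`, `mode`, `cov30`, `cov60`, `provider_present`,
#'   `class`.
#' @export
classify_districts <- function(dataset, reachability = NULL,
                               rule = scale_rule(), cfg = access_config()) {
  if (is.null(reachability)) reachability <- compute_reachability(dataset, cfg)
  bands <- .reachability_bands(reachability)
  mun <- dataset$municipalities
  out <- list()
  for (g in seq_len(nrow(.coverage_groups))) {
    grp <- .coverage_groups[g, ]
    r <- reachability[reachability$service_class == grp$service_class &
                        reachability$mode == grp$mode, ]
    dfac <- factor(mun$district_id[match(r$municipality, mun$id)],
                   levels = dataset$districts$id)
    covs <- lapply(bands[1:2], function(b) {
      col <- paste0("within", b)
      if (rule$basis == "recipients") {
        rec <- mun$recipients_65plus[match(r$municipality, mun$id)]
        num <- tapply(rec * r[[col]], dfac, sum, default = 0)
        den <- tapply(rec, dfac, sum, default = 0L)
      } else {
        num <- tapply(as.numeric(r[[col]]), dfac, sum, default = 0)
        den <- tapply(rep(1, nrow(r)), dfac, sum, default = 0L)
      }
      ifelse(den > 0, 100 * as.numeric(num) / as.numeric(den), 0)
    })
    hosts <- facility_hosts(dataset, grp$service_class)
    present <- dataset$districts$id %in%
      mun$district_id[mun$id %in% hosts]
    out[[g]] <- data.frame(
      district_id = dataset$districts$id,
      region_id = dataset$districts$region_id,
      service_class = grp$service_class, mode = grp$mode,
      cov30 = covs[[1]], cov60 = covs[[2]],
      provider_present = present,
      class = classify_gap(present, covs[[1]], covs[[2]], rule),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regional accessibility-scale table
#'
#' Aggregates district classes into the regional summary layout: one row
#' per region with counts of districts in classes I, II and III, plus a
#' "total in \%" row giving each class's share of all districts, rounded
#' to the requested number of digits (the study prints one decimal for the
#' residential service and whole percentages for the two clinic services).
#'
#' Input is either per-district classes with a parallel region vector, or a
#' ready-made region-by-class count table (worked-example reproduction).
#'
#' @param classes character vector of district classes (`"I"/"II"/"III"`),
#'   or a matrix/data frame of per-region counts with columns `I`, `II`,
#'   `III` (and optionally a `region` column / rownames).
#' @param regions region id per district (ignored when counts are given).
#' @param digits rounding digits for the total-percent row.
#' @return An object of class `caregap_scale_table`: list with `counts`
#'   (data frame `region`, `I`, `II`, `III`), `total_percent` (named
#'   numeric over the three classes), `n_districts` and `digits`.
#' @examples
#' aggregate_scale_table(c("I", "I", "II"), c("A", "A", "B"), digits = 1)
#' @export
aggregate_scale_table <- function(classes, regions = NULL, digits = 1) {
  lev <- c("I", "II", "III")
  if (is.matrix(classes) || is.data.frame(classes)) {
    counts <- as.data.frame(classes, stringsAsFactors = FALSE)
    if (!all(lev %in% names(counts)))
      stop("count input must have columns I, II, III", call. = FALSE)
    region <- counts$region %||% rownames(counts)
    counts <- data.frame(region = region,
                         I = as.integer(counts$I),
                         II = as.integer(counts$II),
                         III = as.integer(counts$III),
                         stringsAsFactors = FALSE)
  } else {
    bad <- is.na(classes) | !classes %in% lev
    if (any(bad))
      stop(sprintf("district(s) without a valid class at position(s): %s",
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    if (is.null(regions) || length(regions) != length(classes))
      stop("'regions' must pair each district with its region",
           call. = FALSE)
    tab <- table(factor(regions, levels = unique(regions)),
                 factor(classes, levels = lev))
    counts <- data.frame(region = rownames(tab),
                         I = as.integer(tab[, "I"]),
                         II = as.integer(tab[, "II"]),
                         III = as.integer(tab[, "III"]),
                         stringsAsFactors = FALSE)
  }
  total <- sum(counts$I, counts$II, counts$III)
  pct <- round(100 * c(I = sum(counts$I), II = sum(counts$II),
                       III = sum(counts$III)) / total, digits)
  structure(list(counts = counts, total_percent = pct,
                 n_districts = total, digits = digits),
            class = "caregap_scale_table")
}

#' @export
print.caregap_scale_table <- function(x, ...) {
  print(x$counts, row.names = FALSE)
  cat("Total in %:",
      paste(sprintf("%s=%s", names(x$total_percent),
                    format(x$total_percent)), collapse = "  "),
      sprintf("(n = %d districts)\n", x$n_districts))
  invisible(x)
}
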