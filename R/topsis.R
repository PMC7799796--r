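#' TOPSIS ranking of districts by spatial accessibility
#'
#' The Technique for Order of Preference by Similarity to Ideal Solution
#' ranks alternatives (districts) by their relative closeness to an ideal
#' alternative and distance from a base (anti-ideal) alternative. The five
#' classical steps are exposed individually ([topsis_normalize()],
#' [topsis_weight()], [topsis_ideal_base()], [topsis_distances()],
#' [topsis_closeness()]) and composed by [topsis()].
#'
#' All criteria here are benefit-type coverage percentages (higher is
#' better), so the ideal alternative takes each criterion's column maximum
#' of the weighted normalized matrix, and the base alternative the column
#' minimum.
#'
#' @param matrix numeric decision matrix, alternatives in rows (rownames =
#'   district ids), criteria in columns; at least 2 alternatives, no
#'   missing values.
#' @param weights nonnegative weight per criterion, at least one positive.
#' @return `topsis()` returns an object of class `caregap_topsis`: a list
#'   with the normalized matrix `r`, the weighted normalized matrix `v`,
#'   ideal `H` and base `D` alternatives, distances `d_plus` and `d_minus`,
#'   closeness `c` in \[0, 1\] and `rank` (descending closeness, ties
#'   broken by alternative id).
#' @examples
#' m <- rbind(A = c(100, 100), B = c(50, 100), C = c(0, 0))
#' topsis(m, c(0.6, 0.4))$c
#' @export
topsis <- function(matrix, weights) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("'matrix' must be a numeric matrix", call. = FALSE)
  if (nrow(matrix) < 2)
    stop("TOPSIS needs at least 2 alternatives", call. = FALSE)
  if (anyNA(matrix))
    stop("'matrix' must not contain missing values", call. = FALSE)
  if (length(weights) != ncol(matrix))
    stop("one weight per criterion is required", call. = FALSE)
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be nonnegative with at least one positive",
         call. = FALSE)
  r <- topsis_normalize(matrix)
  v <- topsis_weight(r, weights)
  hb <- topsis_ideal_base(v)
  d <- topsis_distances(v, hb$H, hb$D)
  cc <- topsis_closeness(d$d_plus, d$d_minus)
  ord <- order(-cc, rownames(matrix) %||% seq_len(nrow(matrix)))
  rank <- integer(nrow(matrix))
  rank[ord] <- seq_len(nrow(matrix))
  structure(list(r = r, v = v, H = hb$H, D = hb$D,
                 d_plus = d$d_plus, d_minus = d$d_minus,
                 c = cc, rank = rank),
            class = "caregap_topsis")
}

#' @rdname topsis
#' @export
topsis_normalize <- function(matrix) {
  norms <- sqrt(colSums(matrix^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sprintf("all-zero criterion column(s) %s normalized to 0",
                    paste(which(zero), collapse = ", ")), call. = FALSE)
    norms[zero] <- 1
  }
  sweep(matrix, 2, norms, "/")
}

#' @rdname topsis
#' @param r normalized matrix from [topsis_normalize()].
#' @export
topsis_weight <- function(r, weights) {
  if (any(weights == 0))
    warning("zero-weight criterion is non-discriminating", call. = FALSE)
  sweep(r, 2, weights, "*")
}

#' @rdname topsis
#' @param v weighted normalized matrix from [topsis_weight()].
#' @export
topsis_ideal_base <- function(v) {
  list(H = apply(v, 2, max), D = apply(v, 2, min))
}

#' @rdname topsis
#' @param H,D ideal and base alternatives from [topsis_ideal_base()].
#' @export
topsis_distances <- function(v, H, D) {
  list(d_plus = sqrt(rowSums(sweep(v, 2, H)^2)),
       d_minus = sqrt(rowSums(sweep(v, 2, D)^2)))
}

#' @rdname topsis
#' @param d_plus,d_minus Euclidean distances to the ideal and base
#'   alternatives.
#' @export
topsis_closeness <- function(d_plus, d_minus) {
  both_zero <- d_plus == 0 & d_minus == 0
  if (any(both_zero))
    warning("identical alternatives: closeness set to 0.5", call. = FALSE)
  ifelse(both_zero, 0.5, d_minus / (d_minus + d_plus))
}

#' Default criterion weights per indicator group
#'
#' Residential groups (X4, X5) weigh the within-30-minute part 0.60 and
#' the within-60-minute part 0.40; clinic groups (X6, X7) weigh them
#' 0.70 / 0.30, reflecting the stronger premium on short journeys for
#' daily visits.
#'
#' @return Named list of length-2 weight vectors for groups `X4`--`X7`.
#' @export
default_group_weights <- function() {
  list(X4 = c(a = 0.60, b = 0.40), X5 = c(a = 0.60, b = 0.40),
       X6 = c(a = 0.70, b = 0.30), X7 = c(a = 0.70, b = 0.30))
}

#' TOPSIS closeness for one coverage indicator group
#'
#' Runs the five TOPSIS steps on the two-criterion matrix of one group's
#' `a` (within 30 min) and `b` (within 60 min) coverage parts. Districts
#' with zero recipients carry no defined coverage and are dropped from the
#' group's ranking with a message.
#'
#' @param indicators output of [compute_indicators()].
#' @param group one of `"X4"`, `"X5"`, `"X6"`, `"X7"`.
#' @param weights length-2 weights for the (a, b) criteria.
#' @param drop_zero_recipient drop districts with `X1 == 0`?
#' @return A `caregap_topsis` object with an added `district_id` element.
#' @export
run_group_topsis <- function(indicators, group,
                             weights = default_group_weights()[[group]],
                             drop_zero_recipient = TRUE) {
  group <- match.arg(group, c("X4", "X5", "X6", "X7"))
  keep <- rep(TRUE, nrow(indicators))
  if (drop_zero_recipient && any(indicators$X1 == 0)) {
    keep <- indicators$X1 > 0
    message(sprintf("dropping %d zero-recipient district(s) from %s ranking",
                    sum(!keep), group))
  }
  ind <- indicators[keep, , drop = FALSE]
  if (nrow(ind) < 2)
    stop("fewer than 2 districts with valid coverage", call. = FALSE)
  m <- as.matrix(ind[, paste0(group, c("a", "b"))])
  rownames(m) <- ind$district_id
  res <- topsis(m, weights)
  res$district_id <- ind$district_id
  res
}

#' Group closeness scores and the mean-total score
#'
#' Runs [run_group_topsis()] for all four coverage groups and combines
#' them: each district's `MTci` is the arithmetic mean of its four group
#' closeness values. Descriptive statistics per score set use the sample
#' standard deviation (N-1), sample skewness and sample excess kurtosis
#' (the bias-corrected estimators reported by mainstream statistical
#' suites; `e1071` type 2).
#'
#' @param indicators output of [compute_indicators()].
#' @param weights named list of length-2 weight vectors per group.
#' @return An object of class `caregap_group_scores`: list with `scores`
#'   (data frame `district_id`, `X4ci`..`X7ci`, `MTci`, `rank_X4`..
#'   `rank_MT`) and `summary` (data frame of descriptive statistics per
#'   group).
#' @export
topsis_all_groups <- function(indicators,
                              weights = default_group_weights()) {
  groups <- c("X4", "X5", "X6", "X7")
  res <- lapply(groups, function(g)
    run_group_topsis(indicators, g, weights[[g]]))
  names(res) <- groups
  ids <- res[[1]]$district_id
  for (g in groups)
    if (!identical(res[[g]]$district_id, ids))
      stop(sprintf("group %s ranked a different district set", g),
           call. = FALSE)
  scores <- data.frame(district_id = ids, stringsAsFactors = FALSE)
  for (g in groups) {
    scores[[paste0(g, "ci")]] <- res[[g]]$c
    scores[[paste0("rank_", g)]] <- res[[g]]$rank
  }
  scores$MTci <- mean_total(scores[, paste0(groups, "ci")])
  ord <- order(-scores$MTci, scores$district_id)
  scores$rank_MT <- integer(nrow(scores))
  scores$rank_MT[ord] <- seq_len(nrow(scores))
  summ <- do.call(rbind, lapply(c(paste0(groups, "ci"), "MTci"), function(cn)
    data.frame(group = sub("ci$", "", cn), score_summary(scores[[cn]]),
               stringsAsFactors = FALSE)))
  structure(list(scores = scores, summary = summ, topsis = res),
            class = "caregap_group_scores")
}

#' @rdname topsis_all_groups
#' @param group_scores data frame (or matrix) of the four group closeness
#'   columns, one row per district; any missing group score is an error
#'   naming the district.
#' @export
mean_total <- function(group_scores) {
  m <- as.matrix(group_scores)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing group score: district row %d, group %s",
                 bad[1, 1], colnames(m)[bad[1, 2]] %||% bad[1, 2]),
         call. = FALSE)
  }
  rowMeans(m)
}

score_summary <- function(x) {
  # sample skewness needs n >= 3, sample excess kurtosis n >= 4
  data.frame(mean = mean(x), median = stats::median(x),
             sd = stats::sd(x), min = min(x), max = max(x),
             skewness = if (length(x) >= 3) e1071::skewness(x, type = 2)
                        else NA_real_,
             kurtosis = if (length(x) >= 4) e1071::kurtosis(x, type = 2)
                        else NA_real_)
}

#' @export
print.caregap_group_scores <- function(x, ...) {
  cat("TOPSIS closeness scores for", nrow(x$scores), "districts\n")
  print(utils::head(x$scores[order(x$scores$rank_MT), ]), row.names = FALSE)
  cat("...\nSummary:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
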