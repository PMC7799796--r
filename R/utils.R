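#' Specify a random draw
#'
#' A draw spec names a distribution and its parameters, and is used by the
#' synthetic-region generator for recipient counts, facility capacities and
#' road-edge travel times. Supported distributions: `"nbinom"` (`mu`, `size`),
#' `"pois"` (`lambda`), `"unif"` (`min`, `max`), `"lnorm"` (`meanlog`,
#' `sdlog`), `"const"` (`value`).
#'
#' @param dist distribution name.
#' @param ... named distribution parameters.
#' @return An object of class `caregap_draw_spec`.
#' @examples
#' draw_spec("unif", min = 5, max = 15)
#' @export
draw_spec <- function(dist, ...) {
  spec <- list(dist = dist, params = list(...))
  class(spec) <- "caregap_draw_spec"
  spec
}

.draw_required <- list(
  nbinom = c("mu", "size"),
  pois   = "lambda",
  unif   = c("min", "max"),
  lnorm  = c("meanlog", "sdlog"),
  const  = "value"
)

validate_draw_spec <- function(spec, field) {
  if (!inherits(spec, "caregap_draw_spec"))
    stop(sprintf("'%s' must be a draw_spec()", field), call. = FALSE)
  need <- .draw_required[[spec$dist]]
  if (is.null(need))
    stop(sprintf("'%s': unknown distribution '%s'", field, spec$dist),
         call. = FALSE)
  missing <- setdiff(need, names(spec$params))
  if (length(missing))
    stop(sprintf("'%s': missing parameter(s) %s for '%s'",
                 field, paste(missing, collapse = ", "), spec$dist),
         call. = FALSE)
  bad <- !vapply(spec$params[need], function(p)
    is.numeric(p) && length(p) == 1 && is.finite(p), logical(1))
  if (any(bad))
    stop(sprintf("'%s': non-numeric parameter(s) %s",
                 field, paste(need[bad], collapse = ", ")), call. = FALSE)
  if (spec$dist == "nbinom" && (spec$params$mu < 0 || spec$params$size <= 0))
    stop(sprintf("'%s': nbinom requires mu >= 0 and size > 0", field),
         call. = FALSE)
  if (spec$dist == "pois" && spec$params$lambda < 0)
    stop(sprintf("'%s': pois requires lambda >= 0", field), call. = FALSE)
  if (spec$dist == "unif" && spec$params$min > spec$params$max)
    stop(sprintf("'%s': unif requires min <= max", field), call. = FALSE)
  invisible(spec)
}

#' @noRd
draw_values <- function(spec, n) {
  p <- spec$params
  switch(spec$dist,
    nbinom = stats::rnbinom(n, mu = p$mu, size = p$size),
    pois   = stats::rpois(n, p$lambda),
    unif   = stats::runif(n, p$min, p$max),
    lnorm  = stats::rlnorm(n, p$meanlog, p$sdlog),
    const  = rep(p$value, n)
  )
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Convert minutes-of-day to "HH:MM" and back
#'
#' Timetable files store departure and arrival times as `HH:MM`; internally
#' the package works in minutes after midnight.
#'
#' @param minutes integer vector of minutes after midnight (0--1439).
#' @param hhmm character vector like `"07:30"`.
#' @return `minutes_to_hhmm` returns a character vector; `hhmm_to_minutes`
#'   an integer vector.
#' @examples
#' minutes_to_hhmm(c(420, 840))
#' hhmm_to_minutes("14:00")
#' @export
minutes_to_hhmm <- function(minutes) {
  sprintf("%02d:%02d", minutes %/% 60, minutes %% 60)
}

#' @rdname minutes_to_hhmm
#' @export
hhmm_to_minutes <- function(hhmm) {
  parts <- strsplit(hhmm, ":", fixed = TRUE)
  vapply(parts, function(p) as.integer(p[1]) * 60L + as.integer(p[2]),
         integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
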