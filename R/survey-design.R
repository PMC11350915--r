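#' Define a passive-acoustic-monitoring survey design
#'
#' A survey design names the monitored sites (wetlands), the study months
#' available at each site, and the partition of the 24 clock hours into
#' daylight and night. The default partition places dawn and dusk with
#' daylight (06:00-18:00 inclusive) and assigns 19:00-23:00 and 00:00-05:00
#' to night, the convention used throughout for acoustic-presence and
#' rarefaction period splits.
#'
#' @param sites Character vector of site identifiers.
#' @param months Months available per site: either a character vector of
#'   `"YYYY-MM"` labels applied to every site, or a named list with one
#'   such vector per site. Month labels double as the seasonal resource
#'   classes, so their number may differ between sites.
#' @param altitudes Optional numeric vector of site altitudes (m a.s.l.),
#'   recycled/matched to `sites`.
#' @param daylight_hours Integer hours (0-23) counted as daylight.
#' @param night_hours Integer hours counted as night. Together with
#'   `daylight_hours` these must partition 0-23.
#' @return An object of class `survey_design`.
#' @examples
#' survey_design(c("sandi", "malalo"),
#'               months = sprintf("2019-%02d", 9:12))
#' @export
survey_design <- function(sites, months,
                          altitudes = NULL,
                          daylight_hours = 6:18,
                          night_hours = c(19:23, 0:5)) {
  if (length(sites) < 1L) stopf("at least one site is required")
  if (anyDuplicated(sites)) stopf("duplicated site identifiers")
  daylight_hours <- as.integer(daylight_hours)
  night_hours <- as.integer(night_hours)
  both <- sort(c(daylight_hours, night_hours))
  if (!identical(both, 0:23)) {
    stopf("daylight_hours and night_hours must partition hours 0-23")
  }
  if (!is.list(months)) months <- stats::setNames(rep(list(months), length(sites)), sites)
  if (!all(sites %in% names(months))) stopf("`months` must name every site")
  months <- months[sites]
  ok <- vapply(months, function(m) {
    length(m) >= 1L && all(grepl("^\\d{4}-\\d{2}$", m)) && !anyDuplicated(m)
  }, logical(1))
  if (!all(ok)) stopf("months per site must be non-empty, unique 'YYYY-MM' labels")
  if (!is.null(altitudes)) {
    if (length(altitudes) != length(sites)) stopf("one altitude per site required")
    altitudes <- stats::setNames(as.numeric(altitudes), sites)
  }
  structure(
    list(sites = sites, months = months, altitudes = altitudes,
         daylight_hours = daylight_hours, night_hours = night_hours),
    class = "survey_design"
  )
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:", length(x$sites), "site(s)\n")
  for (s in x$sites) {
    alt <- if (!is.null(x$altitudes)) sprintf(" (%g m a.s.l.)", x$altitudes[[s]]) else ""
    cat(sprintf("  %s%s: %d month(s) [%s..%s]\n", s, alt, length(x$months[[s]]),
                min(x$months[[s]]), max(x$months[[s]])))
  }
  cat("  daylight hours:", paste(x$daylight_hours, collapse = ","), "\n")
  invisible(x)
}

period_hours <- function(design, period = c("daylight", "night")) {
  period <- match.arg(period)
  if (period == "daylight") design$daylight_hours else design$night_hours
}

#' Split annotation records into daylight and night subsets
#'
#' Partitions a record table by hour membership in the design's daylight
#' and night hour sets. Every record lands in exactly one part, in its
#' original order.
#'
#' @param records A validated annotation record table
#'   (see [read_annotations()]).
#' @param design A [survey_design()].
#' @return A list with elements `daylight` and `night`.
#' @export
split_period <- function(records, design) {
  stopifnot(inherits(design, "survey_design"))
  day <- records$hour %in% design$daylight_hours
  list(daylight = records[day, , drop = FALSE],
       night = records[!day, , drop = FALSE])
}
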