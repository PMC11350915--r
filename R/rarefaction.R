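# Sample-based rarefaction of acoustic species richness.

#' Build a samples-by-species incidence matrix
#'
#' Codes species as incidence (presence = 1, absence = 0) per sample
#' unit — either calendar days or recorded minutes — within one diel
#' period. A day unit is the calendar date at a site; records are first
#' filtered to the period's hours, then grouped into units.
#'
#' @param records Validated annotation records.
#' @param design A [survey_design()].
#' @param unit Sampling unit: `"day"` or `"minute"`.
#' @param period `"daylight"` or `"night"`.
#' @param site Optional site filter (recommended: rarefaction curves are
#'   per community).
#' @param species Optional species set for the columns; default all
#'   species observed in `records`.
#' @return A binary `incidence_matrix` (rows = sample units, columns =
#'   species) with attributes `unit` and `period`.
#' @export
build_incidence <- function(records, design, unit = c("day", "minute"),
                            period = c("daylight", "night"),
                            site = NULL, species = NULL) {
  unit <- match.arg(unit)
  period <- match.arg(period)
  if (!is.null(site)) records <- records[records$site == site, , drop = FALSE]
  if (nrow(records) == 0L) stopf("no records to build incidence from")
  records <- records[records$hour %in% period_hours(design, period), , drop = FALSE]
  if (nrow(records) == 0L) stopf("no records in the %s period", period)
  if (is.null(species)) {
    species <- sort(unique(records$species[!is.na(records$species)]))
  }
  key <- if (unit == "day") {
    paste(records$site, records$date, sep = "|")
  } else {
    paste(records$site, records$date, records$hour, records$minute_index,
          sep = "|")
  }
  units <- sort(unique(key))
  m <- matrix(0L, length(units), length(species),
              dimnames = list(units, species))
  calling <- !is.na(records$species) & records$call_rate > 0L &
    records$species %in% species
  if (any(calling)) {
    ij <- unique(cbind(match(key[calling], units),
                       match(records$species[calling], species)))
    m[ij] <- 1L
  }
  structure(m, unit = unit, period = period, class = c("incidence_matrix", "matrix"))
}

#' Sample-based rarefaction (species accumulation) curve
#'
#' For each sample count k, the expected species richness in the first k
#' sample units is estimated as the mean over randomized orderings of
#' the units; 95% bounds are the randomization mean plus/minus 1.96
#' standard deviations of the per-ordering richness. At k = n every
#' ordering contains all samples, so the curve ends exactly at the
#' observed richness with zero spread.
#'
#' @param m An incidence matrix from [build_incidence()] (or any binary
#'   samples-by-species matrix).
#' @param n_randomizations Number of randomized sample orders
#'   (default 100).
#' @param seed Integer seed; deterministic output.
#' @return A `rarefaction_curve` data.frame with columns `k`,
#'   `richness`, `sd`, `lower`, `upper`.
#' @export
rarefy_incidence <- function(m, n_randomizations = 100, seed = 1) {
  m <- unclass(as.matrix(m))
  if (nrow(m) < 1L) stopf("incidence matrix has no samples")
  if (!all(m %in% c(0L, 1L))) stopf("incidence matrix must be binary")
  n <- nrow(m); s <- ncol(m)
  rich <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(rep) {
      ord <- sample.int(n)
      # richness at k = number of species whose first occurrence is <= k
      first <- apply(m[ord, , drop = FALSE], 2, function(col) {
        w <- which(col > 0L)
        if (length(w) == 0L) NA_integer_ else w[1]
      })
      vapply(seq_len(n), function(k) sum(!is.na(first) & first <= k),
             numeric(1))
    }, numeric(n))
  })
  rich <- matrix(rich, nrow = n)
  mean_r <- rowMeans(rich)
  sd_r <- apply(rich, 1, stats::sd)
  out <- data.frame(k = seq_len(n), richness = mean_r, sd = sd_r,
                    lower = mean_r - 1.96 * sd_r,
                    upper = mean_r + 1.96 * sd_r)
  attr(out, "n_randomizations") <- n_randomizations
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}
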