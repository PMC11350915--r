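# Annotation data model
#
# One row per (recorded minute, species) observation. A silent minute (no
# anuran detected) is kept as a row with an empty species and call_rate 0:
# acoustic-presence and activity-profile denominators need those minutes.
# Per-call features are carried in a single `calls` cell as a
# semicolon-separated list of freq:notes:pulses triples, so a record table
# is one flat CSV with no side table.

ANNOTATION_COLUMNS <- c("site", "date", "month", "hour", "minute_index",
                        "species", "call_rate", "calls",
                        "spl_1k", "spl_2k", "spl_3k", "spl_4k", "spl_5k",
                        "rain_index")

#' Serialize per-call features to the annotation cell format
#'
#' @param features A data.frame with columns `dominant_freq` (Hz),
#'   `n_notes`, `n_pulses`, or `NULL`/zero rows for no annotated calls.
#' @return A single string, `""` when there are no calls.
#' @seealso [parse_calls()]
#' @export
serialize_calls <- function(features) {
  if (is.null(features) || nrow(features) == 0L) return("")
  paste(sprintf("%s:%d:%d",
                format(features$dominant_freq, trim = TRUE, scientific = FALSE),
                as.integer(features$n_notes),
                as.integer(features$n_pulses)),
        collapse = ";")
}

#' Parse an annotation calls cell into per-call features
#'
#' @param x Character vector of serialized calls cells
#'   (`"freq:notes:pulses;..."`).
#' @return A data.frame with columns `dominant_freq`, `n_notes`,
#'   `n_pulses`, one row per call across all cells of `x`.
#' @export
parse_calls <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x) == 0L) {
    return(data.frame(dominant_freq = numeric(0), n_notes = integer(0),
                      n_pulses = integer(0)))
  }
  triples <- unlist(strsplit(x, ";", fixed = TRUE), use.names = FALSE)
  parts <- strsplit(triples, ":", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stopf("malformed call feature '%s'", triples[which(bad)[1]])
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  data.frame(dominant_freq = as.numeric(m[, 1]),
             n_notes = as.integer(m[, 2]),
             n_pulses = as.integer(m[, 3]))
}

n_calls_in_cell <- function(x) {
  ifelse(is.na(x) | !nzchar(x), 0L,
         lengths(strsplit(x, ";", fixed = TRUE)))
}

#' Validate an annotation record table
#'
#' Checks the row-level invariants of the annotation data model: hours in
#' 0-23, minute index 1-5, non-negative integer call rates at least as
#' large as the number of annotated calls, rain index in \{0,1,2\}, band
#' SPL values (when present) in \[-120, 0\] dBFS, parseable call-feature
#' cells with positive dominant frequency, at least one note and a
#' non-negative pulse count, and consistent `month`/`date` fields. All
#' violations are reported together with their row numbers.
#'
#' @param records A data.frame with the annotation columns.
#' @param design Optional [survey_design()]; when supplied, sites and
#'   months must belong to it.
#' @return `records`, invisibly, with `date` as `Date` and integer-typed
#'   count columns.
#' @export
validate_records <- function(records, design = NULL) {
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  records$species <- as.character(records$species)
  records$species[!is.na(records$species) & !nzchar(records$species)] <- NA_character_
  records$calls <- as.character(records$calls)
  records$calls[is.na(records$calls)] <- ""
  if (!inherits(records$date, "Date")) {
    d <- as.Date(as.character(records$date), format = "%Y-%m-%d")
    if (anyNA(d)) {
      stopf("unparseable ISO date in row(s): %s",
            paste(utils::head(which(is.na(d)), 5), collapse = ", "))
    }
    records$date <- d
  }
  for (col in c("hour", "minute_index", "call_rate", "rain_index")) {
    v <- records[[col]]
    if (!all(is_whole(v))) {
      stopf("non-integer value in column '%s', row(s): %s", col,
            paste(utils::head(which(!is_whole(v)), 5), collapse = ", "))
    }
    records[[col]] <- as.integer(round(v))
  }

  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, sprintf(
        "%s in row(s): %s", what,
        paste(utils::head(which(bad), 5), collapse = ", ")))
    }
  }
  flag(records$hour < 0L | records$hour > 23L, "hour outside 0-23")
  flag(records$minute_index < 1L | records$minute_index > 5L,
       "minute_index outside 1-5")
  flag(records$call_rate < 0L, "negative call_rate")
  flag(!records$rain_index %in% 0:2, "rain_index outside {0,1,2}")
  flag(is.na(records$species) & records$call_rate > 0L,
       "call_rate > 0 for empty species")
  flag(records$call_rate < n_calls_in_cell(records$calls),
       "call_rate smaller than number of annotated calls")
  for (col in c("spl_1k", "spl_2k", "spl_3k", "spl_4k", "spl_5k")) {
    v <- suppressWarnings(as.numeric(records[[col]]))
    flag(!is.na(records[[col]]) & (is.na(v) | v < -120 | v > 0),
         sprintf("%s outside [-120, 0] dBFS", col))
    records[[col]] <- v
  }
  flag(records$month != format(records$date, "%Y-%m"),
       "month label inconsistent with date")
  if (!is.null(design)) {
    stopifnot(inherits(design, "survey_design"))
    flag(!records$site %in% design$sites, "site not in survey design")
    allowed <- unlist(lapply(design$sites, function(s) {
      paste(s, design$months[[s]])
    }))
    known <- records$site %in% design$sites
    bad <- known & !paste(records$site, records$month) %in% allowed
    flag(bad, "month not in the site's study months")
  }
  has_calls <- which(nzchar(records$calls))
  if (length(has_calls) > 0L) {
    # fast global check first; locate offending rows only on failure
    cell_ok <- function(i) {
      f <- tryCatch(parse_calls(records$calls[i]), error = function(e) NULL)
      !is.null(f) && !anyNA(f) && all(f$dominant_freq > 0) &&
        all(f$n_notes >= 1L) && all(f$n_pulses >= 0L)
    }
    all_ok <- cell_ok(has_calls)
    if (!all_ok) {
      bad_rows <- has_calls[!vapply(has_calls, cell_ok, logical(1))]
      problems <- c(problems, sprintf(
        "invalid or unparseable call features in row(s): %s",
        paste(utils::head(bad_rows, 5), collapse = ", ")))
    }
  }
  if (length(problems) > 0L) {
    stopf("invalid annotation records:\n  - %s",
          paste(problems, collapse = "\n  - "))
  }
  invisible(records)
}

#' Read a call-annotation table
#'
#' Reads a UTF-8, comma-delimited annotation file (header mandatory) and
#' validates every row against the data-model invariants; violating rows
#' are reported with their row numbers. Rows with an empty species cell
#' (silent minutes) are retained — they carry the denominators for
#' acoustic presence and activity profiles.
#'
#' @param path Path to the CSV file.
#' @param design Optional [survey_design()] used for site/month checks.
#' @return A validated annotation record data.frame.
#' @export
read_annotations <- function(path, design = NULL) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = character(0))
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stopf("missing required column(s) in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, ANNOTATION_COLUMNS]
  for (col in c("hour", "minute_index", "call_rate", "rain_index")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      stopf("unparseable numeric cell in column '%s', row(s): %s", col,
            paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    }
    raw[[col]] <- v
  }
  for (col in c("spl_1k", "spl_2k", "spl_3k", "spl_4k", "spl_5k")) {
    raw[[col]][!nzchar(raw[[col]])] <- NA_character_
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  records <- validate_records(raw, design)
  records
}

#' Write a call-annotation table
#'
#' Writes records in the canonical column order as UTF-8 CSV, one row per
#' (minute, species) observation; lossless counterpart of
#' [read_annotations()].
#'
#' @param records A validated annotation record data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  records <- validate_records(records)
  out <- records[, ANNOTATION_COLUMNS]
  out$date <- format(out$date, "%Y-%m-%d")
  out$species[is.na(out$species)] <- ""
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Distinct recorded minutes with one species' call rate (0 where the
# species has no row), joined with the minute context (hour, month,
# rain_index). This is the common denominator expansion behind diel and
# seasonal profiles and the rain contrast.
species_minute_rates <- function(records, species, site = NULL) {
  if (!is.null(site)) records <- records[records$site == site, , drop = FALSE]
  if (nrow(records) == 0L) stopf("no records%s",
                                 if (is.null(site)) "" else sprintf(" for site '%s'", site))
  key <- paste(records$site, records$date, records$hour, records$minute_index,
               sep = "\r")
  minutes <- records[!duplicated(key),
                     c("site", "date", "month", "hour", "minute_index", "rain_index")]
  mkey <- key[!duplicated(key)]
  sp <- records[!is.na(records$species) & records$species == species, , drop = FALSE]
  rate <- stats::setNames(rep(0L, length(mkey)), mkey)
  if (nrow(sp) > 0L) {
    skey <- paste(sp$site, sp$date, sp$hour, sp$minute_index, sep = "\r")
    rate[skey] <- sp$call_rate
  }
  minutes$call_rate <- as.integer(rate)
  rownames(minutes) <- NULL
  minutes
}
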