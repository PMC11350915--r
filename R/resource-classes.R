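# Resource-class schemes for the three acoustic niche dimensions.
#
# Call structure pools three feature blocks into one 25-class space:
#   9 dominant-frequency classes (width 500 Hz, range 500-5000 Hz),
#   5 call-composition classes (1-5 notes),
#  11 pulse classes (class 1 = tonal/0 pulses, then nine classes of
#     width 3 covering 1-27 pulses, class 11 = more than 27 pulses).
# The diel dimension has 24 hourly classes; the seasonal dimension one
# class per study month at the site (so r can differ between sites).

FREQ_CLASS_LABELS <- sprintf("freq_%d_%d", seq(500, 4500, 500), seq(1000, 5000, 500))
NOTE_CLASS_LABELS <- sprintf("notes_%d", 1:5)
PULSE_CLASS_LABELS <- c("pulses_tonal",
                        sprintf("pulses_%d_%d", seq(1, 25, 3), seq(3, 27, 3)),
                        "pulses_gt27")

#' Resource-class scheme for a niche dimension
#'
#' @param dimension One of `"call_structure"`, `"diel"`, `"seasonal"`.
#' @param months Character vector of `"YYYY-MM"` study months; required
#'   for the seasonal dimension, where the class count equals the number
#'   of months recorded at the site.
#' @return A `resource_scheme` object with `dimension`, `n_classes` and
#'   ordered `labels`.
#' @examples
#' resource_scheme("call_structure")$n_classes  # 25 = 9 + 5 + 11
#' @export
resource_scheme <- function(dimension = c("call_structure", "diel", "seasonal"),
                            months = NULL) {
  dimension <- match.arg(dimension)
  labels <- switch(dimension,
    call_structure = c(FREQ_CLASS_LABELS, NOTE_CLASS_LABELS, PULSE_CLASS_LABELS),
    diel = sprintf("h%02d", 0:23),
    seasonal = {
      if (is.null(months) || length(months) < 1L) {
        stopf("the seasonal scheme needs the site's study months")
      }
      as.character(months)
    })
  structure(list(dimension = dimension, n_classes = length(labels),
                 labels = labels),
            class = "resource_scheme")
}

#' Bin a dominant frequency into its 500-Hz resource class
#'
#' Frequencies in \[500, 5000) Hz map to classes 1-9 by 500-Hz width.
#' Out-of-range values are clamped to the nearest edge class with a
#' warning rather than dropped: the annotation protocol already filters
#' 400-6000 Hz, and silent truncation would bias profiles invisibly.
#'
#' @param f Numeric vector of dominant frequencies (Hz), all > 0.
#' @return Integer class indices in 1-9.
#' @export
bin_frequency <- function(f) {
  if (any(is.na(f)) || any(f <= 0)) stopf("dominant frequency must be > 0")
  low <- f < 500
  high <- f >= 5000
  if (any(low)) warnf("%d dominant frequency value(s) below 500 Hz clamped to the lowest class", sum(low))
  if (any(high)) warnf("%d dominant frequency value(s) at or above 5000 Hz clamped to the highest class", sum(high))
  idx <- floor((f - 500) / 500) + 1L
  idx[low] <- 1L
  idx[high] <- 9L
  as.integer(idx)
}

#' Bin a note count into its call-composition resource class
#'
#' Classes 1-5 correspond to 1-5 notes; counts above 5 are clamped to
#' class 5 with a warning.
#'
#' @param n Integer vector of note counts, all >= 1.
#' @return Integer class indices in 1-5.
#' @export
bin_notes <- function(n) {
  if (any(is.na(n)) || any(n < 1)) stopf("note count must be >= 1")
  n <- as.integer(round(n))
  high <- n > 5L
  if (any(high)) warnf("%d note count(s) above 5 clamped to the highest class", sum(high))
  idx <- n
  idx[high] <- 5L
  idx
}

#' Bin a pulse count into its pulse resource class
#'
#' Class 1 holds tonal calls (0 pulses); pulse counts 1-27 fall into nine
#' classes of width 3; counts above 27 fall into class 11.
#'
#' @param n Integer vector of pulse counts, all >= 0.
#' @return Integer class indices in 1-11.
#' @export
bin_pulses <- function(n) {
  if (any(is.na(n)) || any(n < 0)) stopf("pulse count must be >= 0")
  n <- as.integer(round(n))
  idx <- ifelse(n == 0L, 1L,
                ifelse(n > 27L, 11L, 2L + (n - 1L) %/% 3L))
  as.integer(idx)
}
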