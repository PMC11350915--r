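# Niche profiles: normalized resource-use proportion vectors per species,
# site and dimension. A species with zero recorded activity in a dimension
# has no defined proportions; such profiles are flagged undefined and
# propagate as errors in breadth/overlap rather than silently as zeros.

new_niche_profile <- function(species, site, dimension, p, labels,
                              undefined = FALSE) {
  structure(list(species = species, site = site, dimension = dimension,
                 p = as.numeric(p), labels = labels, undefined = undefined),
            class = "niche_profile")
}

#' @export
print.niche_profile <- function(x, ...) {
  cat(sprintf("Niche profile: %s @ %s [%s, r = %d]%s\n",
              x$species, x$site, x$dimension, length(x$p),
              if (x$undefined) " (undefined: no activity)" else ""))
  if (!x$undefined) {
    top <- order(x$p, decreasing = TRUE)[seq_len(min(3, sum(x$p > 0)))]
    cat("  top classes:",
        paste(sprintf("%s=%.3f", x$labels[top], x$p[top]), collapse = ", "), "\n")
  }
  invisible(x)
}

check_defined <- function(p) {
  if (!inherits(p, "niche_profile")) stopf("expected a niche_profile")
  if (p$undefined) {
    stopf("undefined niche profile (%s @ %s, %s): no recorded activity",
          p$species, p$site, p$dimension)
  }
  invisible(p)
}

#' Call-structure niche profile (25 resource classes)
#'
#' Every annotated call contributes one count to its dominant-frequency
#' class, one to its note class and one to its pulse class. The three
#' blocks (9 + 5 + 11 classes) are each normalized to mass 1/3 and
#' concatenated, so no block dominates the 25-class profile merely by
#' having more classes.
#'
#' @param records Validated annotation records.
#' @param species Species identifier.
#' @param site Site identifier.
#' @return A `niche_profile` with `r = 25`; flagged undefined when the
#'   species has no annotated call features at the site.
#' @export
call_structure_profile <- function(records, species, site) {
  scheme <- resource_scheme("call_structure")
  rows <- records[records$site == site &
                    !is.na(records$species) & records$species == species, ,
                  drop = FALSE]
  feats <- parse_calls(rows$calls)
  if (nrow(feats) == 0L) {
    return(new_niche_profile(species, site, "call_structure",
                             rep(NA_real_, 25), scheme$labels, undefined = TRUE))
  }
  fcounts <- tabulate(bin_frequency(feats$dominant_freq), 9L)
  ncounts <- tabulate(bin_notes(feats$n_notes), 5L)
  pcounts <- tabulate(bin_pulses(feats$n_pulses) , 11L)
  p <- c(fcounts / sum(fcounts), ncounts / sum(ncounts),
         pcounts / sum(pcounts)) / 3
  new_niche_profile(species, site, "call_structure", p, scheme$labels)
}

activity_profile <- function(records, species, site, classes, class_of) {
  minutes <- species_minute_rates(records, species, site)
  cls <- factor(class_of(minutes), levels = classes)
  if (anyNA(cls)) stopf("records contain classes outside the scheme")
  m <- tapply(minutes$call_rate, cls, mean, default = 0)
  m[is.na(m)] <- 0
  total <- sum(m)
  if (total <= 0) {
    return(list(p = rep(NA_real_, length(classes)), undefined = TRUE))
  }
  list(p = as.numeric(m / total), undefined = FALSE)
}

#' Diel niche profile (24 hourly resource classes)
#'
#' For each clock hour the mean call rate over all recorded minutes at
#' the site in that hour (silent minutes included) is computed; the 24
#' means are normalized to proportions.
#'
#' @inheritParams call_structure_profile
#' @return A `niche_profile` with `r = 24`; undefined when the species
#'   never called at the site.
#' @export
diel_profile <- function(records, species, site) {
  scheme <- resource_scheme("diel")
  a <- activity_profile(records, species, site, scheme$labels,
                        function(m) sprintf("h%02d", m$hour))
  new_niche_profile(species, site, "diel", a$p, scheme$labels, a$undefined)
}

#' Seasonal niche profile (one resource class per study month)
#'
#' As [diel_profile()], with study months as classes. The class count is
#' taken from the site's month list in the survey design, so sites with
#' different coverage standardize against different r.
#'
#' @inheritParams call_structure_profile
#' @param design A [survey_design()] providing the site's study months.
#' @return A `niche_profile` with `r` = number of study months at the site.
#' @export
seasonal_profile <- function(records, species, site, design) {
  stopifnot(inherits(design, "survey_design"))
  if (!site %in% design$sites) stopf("site '%s' not in survey design", site)
  scheme <- resource_scheme("seasonal", months = design$months[[site]])
  a <- activity_profile(records, species, site, scheme$labels,
                        function(m) m$month)
  new_niche_profile(species, site, "seasonal", a$p, scheme$labels, a$undefined)
}

#' Combined total niche profile (additive model)
#'
#' Concatenates the call-structure, diel and seasonal profiles, each
#' scaled by its weight (default equal thirds), into one profile over
#' r_total = 25 + 24 + r_seasonal classes.
#'
#' @param call_structure,diel,seasonal Defined `niche_profile`s of one
#'   species at one site.
#' @param weights Numeric length-3 weights summing to 1.
#' @return A `niche_profile` with dimension `"total"`.
#' @export
total_niche_profile <- function(call_structure, diel, seasonal,
                                weights = c(1, 1, 1) / 3) {
  check_defined(call_structure); check_defined(diel); check_defined(seasonal)
  stopifnot(call_structure$dimension == "call_structure",
            diel$dimension == "diel", seasonal$dimension == "seasonal")
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stopf("weights must be 3 non-negative values summing to 1")
  }
  if (!identical(call_structure$species, diel$species) ||
      !identical(call_structure$species, seasonal$species) ||
      !identical(call_structure$site, diel$site) ||
      !identical(call_structure$site, seasonal$site)) {
    stopf("total profile requires the three dimensions of one species at one site")
  }
  p <- c(weights[1] * call_structure$p, weights[2] * diel$p,
         weights[3] * seasonal$p)
  labels <- c(paste0("call.", call_structure$labels),
              paste0("diel.", diel$labels),
              paste0("seasonal.", seasonal$labels))
  new_niche_profile(call_structure$species, call_structure$site, "total",
                    p, labels)
}

#' All niche profiles of a site's species
#'
#' Convenience wrapper building call-structure, diel, seasonal and total
#' profiles for each species at a site. Species for which any dimension
#' is undefined get `NULL` as their total profile (with a warning) rather
#' than a zero-filled one.
#'
#' @param records Validated annotation records.
#' @param design A [survey_design()].
#' @param site Site identifier.
#' @param species Optional character vector; defaults to all species
#'   observed at the site.
#' @param weights Passed to [total_niche_profile()].
#' @return A named list (by species) of lists with elements
#'   `call_structure`, `diel`, `seasonal`, `total`.
#' @export
species_niche_profiles <- function(records, design, site, species = NULL,
                                   weights = c(1, 1, 1) / 3) {
  at_site <- records[records$site == site, , drop = FALSE]
  if (nrow(at_site) == 0L) stopf("no records for site '%s'", site)
  if (is.null(species)) {
    species <- sort(unique(at_site$species[!is.na(at_site$species)]))
  }
  out <- lapply(species, function(sp) {
    cs <- call_structure_profile(records, sp, site)
    di <- diel_profile(records, sp, site)
    se <- seasonal_profile(records, sp, site, design)
    tot <- if (cs$undefined || di$undefined || se$undefined) {
      warnf("species '%s' at '%s' has an undefined dimension; no total profile", sp, site)
      NULL
    } else {
      total_niche_profile(cs, di, se, weights)
    }
    list(call_structure = cs, diel = di, seasonal = se, total = tot)
  })
  stats::setNames(out, species)
}
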