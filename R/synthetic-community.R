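# Synthetic acoustic-community generator.
#
# Emulates the statistical structure of passive-acoustic-monitoring
# annotation tables: hourly recording blocks of consecutive minutes,
# species-specific call-feature distributions (truncated-normal dominant
# frequency, categorical note and pulse counts), diel/seasonal/site rate
# surfaces with Poisson per-minute call counts, i.i.d. hourly rain with
# heavy-rain suppression, and daylight bird-band noise that modulates
# calling through a mean-neutral signed response. Because every law has a
# closed form, the analytically expected niche profiles are available
# without simulation (expected_profiles), which is what parameter-recovery
# tests compare against.

#' Parameters of one synthetic species
#'
#' @param name Species identifier.
#' @param freq_mean,freq_sd Mean and sd (Hz) of the dominant-frequency
#'   law, a normal truncated to `freq_range`.
#' @param freq_range Length-2 truncation bounds (Hz).
#' @param notes_probs Probability vector over 1-5 notes.
#' @param pulses_values Integer support of the pulse-count law
#'   (0 encodes a tonal call).
#' @param pulses_probs Probabilities over `pulses_values`.
#' @param diel_rate 24-vector of mean calls/min per clock hour (>= 0).
#' @param seasonal_mult Named per-month rate multipliers (>= 0), names
#'   `"YYYY-MM"`.
#' @param site_mult Named per-site rate multipliers (>= 0).
#' @param rain_suppression Factor in \[0, 1\] applied to the mean rate
#'   when the hourly rain index is 2 (heavy rain); 1 = no suppression,
#'   0 = calling stops.
#' @param day_bird_response Signed factor in \[-1, 1\] scaling the
#'   daytime rate with bird-band noise: the rate is multiplied by
#'   `1 + day_bird_response * B` with `B ~ U(-1, 1)` per daylight hour,
#'   and the same `B` raises the 4-5 kHz band SPL. Zero mean, so
#'   expected activity profiles are unaffected.
#' @return A `species_params` object.
#' @export
species_params <- function(name, freq_mean, freq_sd, freq_range,
                           notes_probs, pulses_values, pulses_probs,
                           diel_rate, seasonal_mult, site_mult,
                           rain_suppression = 1, day_bird_response = 0) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stopf("%s of '%s' must be a probability vector summing to 1", what, name)
    }
  }
  stopifnot(length(freq_range) == 2L, freq_range[1] < freq_range[2],
            freq_range[1] > 0, freq_sd > 0)
  if (length(notes_probs) != 5L) stopf("notes_probs must have length 5 (1-5 notes)")
  check_probs(notes_probs, "notes_probs")
  if (length(pulses_values) != length(pulses_probs)) {
    stopf("pulses_values and pulses_probs must have equal length")
  }
  if (any(pulses_values < 0) || any(!is_whole(pulses_values))) {
    stopf("pulses_values must be non-negative integers")
  }
  check_probs(pulses_probs, "pulses_probs")
  if (length(diel_rate) != 24L || any(diel_rate < 0)) {
    stopf("diel_rate must be 24 non-negative mean rates")
  }
  if (any(seasonal_mult < 0) || is.null(names(seasonal_mult))) {
    stopf("seasonal_mult must be non-negative and named by month")
  }
  if (any(site_mult < 0) || is.null(names(site_mult))) {
    stopf("site_mult must be non-negative and named by site")
  }
  if (rain_suppression < 0 || rain_suppression > 1) {
    stopf("rain_suppression must lie in [0, 1]")
  }
  if (abs(day_bird_response) > 1) {
    stopf("day_bird_response must lie in [-1, 1] (keeps the rate multiplier non-negative)")
  }
  structure(list(name = name, freq_mean = freq_mean, freq_sd = freq_sd,
                 freq_range = freq_range, notes_probs = notes_probs,
                 pulses_values = as.integer(pulses_values),
                 pulses_probs = pulses_probs, diel_rate = diel_rate,
                 seasonal_mult = seasonal_mult, site_mult = site_mult,
                 rain_suppression = rain_suppression,
                 day_bird_response = day_bird_response),
            class = "species_params")
}

default_spl_model <- function() {
  list(baseline = c(-86, -82, -79, -77, -75),
       rain_light = c(22, 10, 6, 4, 3),
       rain_heavy = c(44, 24, 15, 11, 9),
       bird_day = c(0, 1, 4, 9, 9),
       jitter_sd = 2)
}

#' Configuration of the synthetic-community generator
#'
#' @param design A [survey_design()].
#' @param species List of [species_params()]; each species'
#'   `seasonal_mult` must cover every study month and `site_mult` every
#'   site of the design.
#' @param rain_prob_per_hour Probability that an hour has light rain
#'   (index 1), drawn i.i.d. per hour.
#' @param heavy_rain_prob Probability that an hour has heavy rain
#'   (index 2; takes precedence over light rain).
#' @param spl_model Band-SPL model: `baseline` (dBFS, 5 bands at
#'   1-5 kHz), additive `rain_light`/`rain_heavy` increments
#'   (concentrated at 1 kHz), daylight `bird_day` increments
#'   (concentrated at 4-5 kHz, scaled by the hourly bird activity), and
#'   a Gaussian `jitter_sd`.
#' @param days_per_month Recording days per study month: an integer
#'   (first k calendar days) or `"all"`.
#' @param minutes_per_hour Minutes recorded at the start of each hour
#'   (default 5, the usual PAM schedule).
#' @param max_annotated_calls Per-minute cap on the number of calls whose
#'   features are annotated (default 1: the first recognizable call, as
#'   in manual annotation protocols). The call *rate* is always the full
#'   Poisson count.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A `generator_config` object.
#' @export
generator_config <- function(design, species,
                             rain_prob_per_hour = 0.12,
                             heavy_rain_prob = 0.05,
                             spl_model = default_spl_model(),
                             days_per_month = 10,
                             minutes_per_hour = 5,
                             max_annotated_calls = 1,
                             seed = 1) {
  stopifnot(inherits(design, "survey_design"))
  if (length(species) < 1L) stopf("at least one species is required")
  if (inherits(species, "species_params")) species <- list(species)
  names(species) <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(names(species))) stopf("duplicated species names")
  all_months <- unique(unlist(design$months))
  for (sp in species) {
    stopifnot(inherits(sp, "species_params"))
    if (!all(all_months %in% names(sp$seasonal_mult))) {
      stopf("seasonal_mult of '%s' must cover every study month", sp$name)
    }
    if (!all(design$sites %in% names(sp$site_mult))) {
      stopf("site_mult of '%s' must cover every site", sp$name)
    }
  }
  for (p in c(rain_prob_per_hour, heavy_rain_prob)) {
    if (p < 0 || p > 1) stopf("rain probabilities must lie in [0, 1]")
  }
  stopifnot(length(spl_model$baseline) == 5L)
  structure(list(design = design, species = species,
                 rain_prob_per_hour = rain_prob_per_hour,
                 heavy_rain_prob = heavy_rain_prob, spl_model = spl_model,
                 days_per_month = days_per_month,
                 minutes_per_hour = as.integer(minutes_per_hour),
                 max_annotated_calls = as.integer(max_annotated_calls),
                 seed = seed),
            class = "generator_config")
}

month_dates <- function(month, days_per_month) {
  first <- as.Date(paste0(month, "-01"))
  n <- as.integer(format(seq(first, by = "1 month", length.out = 2)[2] - 1, "%d"))
  k <- if (identical(days_per_month, "all")) n else min(n, as.integer(days_per_month))
  seq(first, by = "1 day", length.out = k)
}

#' Generate a synthetic annotation dataset
#'
#' Simulates the survey: for every site, study date and hour an i.i.d.
#' rain state and (in daylight) a bird-activity level are drawn; band
#' SPLs follow the config's noise model; for each of the hour's recorded
#' minutes and each species, a Poisson call count is drawn with mean
#' `diel_rate[hour] * seasonal_mult[month] * site_mult[site]`, suppressed
#' under heavy rain and modulated (mean-neutrally) by daylight bird
#' activity; call features are drawn from the species' distributions for
#' up to `max_annotated_calls` calls per minute. Deterministic given the
#' config seed.
#'
#' @param config A [generator_config()].
#' @return A validated-by-construction annotation record data.frame
#'   (see [read_annotations()] for the model), including silent minutes.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  design <- config$design
  mpm <- config$minutes_per_hour

  grids <- lapply(design$sites, function(s) {
    dates <- do.call(c, lapply(design$months[[s]],
                               month_dates, config$days_per_month))
    g <- expand.grid(hour = 0:23, date = dates, KEEP.OUT.ATTRS = FALSE)
    g$site <- s
    g[, c("site", "date", "hour")]
  })
  hours <- do.call(rbind, grids)
  hours <- hours[order(hours$site, hours$date, hours$hour), , drop = FALSE]
  nh <- nrow(hours)
  daylight <- hours$hour %in% design$daylight_hours

  with_seed(config$seed, {
    heavy <- stats::runif(nh) < config$heavy_rain_prob
    light <- stats::runif(nh) < config$rain_prob_per_hour
    rain_index <- ifelse(heavy, 2L, ifelse(light, 1L, 0L))
    bird <- stats::runif(nh, -1, 1)
    bird[!daylight] <- 0

    sm <- config$spl_model
    spl <- matrix(rep(sm$baseline, each = nh), nrow = nh)
    spl <- spl + outer(rain_index == 1L, sm$rain_light) +
      outer(rain_index == 2L, sm$rain_heavy) +
      outer(daylight * (bird + 1) / 2, sm$bird_day)
    spl <- spl + matrix(stats::rnorm(nh * 5, 0, sm$jitter_sd), nrow = nh)
    spl <- pmin(pmax(spl, -120), 0)
    colnames(spl) <- paste0("spl_", 1:5, "k")

    minute_of <- rep(seq_len(mpm), times = nh)
    hidx <- rep(seq_len(nh), each = mpm)
    nmin <- nh * mpm
    month <- format(hours$date, "%Y-%m")

    per_species <- lapply(config$species, function(sp) {
      lam_h <- sp$diel_rate[hours$hour + 1L] *
        sp$seasonal_mult[month] *
        sp$site_mult[hours$site] *
        ifelse(rain_index == 2L, sp$rain_suppression, 1) *
        (1 + sp$day_bird_response * bird)
      counts <- stats::rpois(nmin, rep(lam_h, each = mpm))
      annotated <- pmin(counts, config$max_annotated_calls)
      k <- sum(annotated)
      cells <- character(nmin)
      if (k > 0L) {
        flo <- stats::pnorm(sp$freq_range[1], sp$freq_mean, sp$freq_sd)
        fhi <- stats::pnorm(sp$freq_range[2], sp$freq_mean, sp$freq_sd)
        freq <- stats::qnorm(flo + stats::runif(k) * (fhi - flo),
                             sp$freq_mean, sp$freq_sd)
        notes <- sample.int(5L, k, replace = TRUE, prob = sp$notes_probs)
        pulses <- sp$pulses_values[sample.int(length(sp$pulses_values), k,
                                              replace = TRUE,
                                              prob = sp$pulses_probs)]
        triple <- sprintf("%.1f:%d:%d", freq, notes, pulses)
        owner <- rep(which(annotated > 0L), annotated[annotated > 0L])
        joined <- vapply(split(triple, owner), paste, character(1),
                         collapse = ";")
        cells[as.integer(names(joined))] <- joined
      }
      list(counts = counts, cells = cells)
    })

    counts_mat <- vapply(per_species, `[[`, integer(nmin), "counts")
    any_call <- rowSums(counts_mat) > 0L

    sp_rows <- lapply(seq_along(config$species), function(i) {
      idx <- which(counts_mat[, i] > 0L)
      if (length(idx) == 0L) return(NULL)
      data.frame(site = hours$site[hidx[idx]],
                 date = hours$date[hidx[idx]],
                 month = month[hidx[idx]],
                 hour = hours$hour[hidx[idx]],
                 minute_index = minute_of[idx],
                 species = names(config$species)[i],
                 call_rate = counts_mat[idx, i],
                 calls = per_species[[i]]$cells[idx],
                 spl[hidx[idx], , drop = FALSE],
                 rain_index = rain_index[hidx[idx]])
    })
    silent_idx <- which(!any_call)
    silent <- if (length(silent_idx) > 0L) {
      data.frame(site = hours$site[hidx[silent_idx]],
                 date = hours$date[hidx[silent_idx]],
                 month = month[hidx[silent_idx]],
                 hour = hours$hour[hidx[silent_idx]],
                 minute_index = minute_of[silent_idx],
                 species = NA_character_,
                 call_rate = 0L,
                 calls = "",
                 spl[hidx[silent_idx], , drop = FALSE],
                 rain_index = rain_index[hidx[silent_idx]])
    }
    records <- do.call(rbind, c(sp_rows, list(silent)))
    records <- records[order(records$site, records$date, records$hour,
                             records$minute_index, records$species,
                             na.last = TRUE, method = "radix"), ,
                       drop = FALSE]
    rownames(records) <- NULL
    records$call_rate <- as.integer(records$call_rate)
    records
  })
}

truncnorm_bin_mass <- function(sp) {
  flo <- stats::pnorm(sp$freq_range[1], sp$freq_mean, sp$freq_sd)
  fhi <- stats::pnorm(sp$freq_range[2], sp$freq_mean, sp$freq_sd)
  ft <- function(x) {
    pmin(1, pmax(0, (stats::pnorm(x, sp$freq_mean, sp$freq_sd) - flo) / (fhi - flo)))
  }
  inner_edges <- seq(1000, 4500, 500)
  # bin 1 absorbs all mass below 1000 Hz (incl. the sub-500 clamp),
  # bin 9 all mass at or above 4500 Hz (incl. the >= 5000 clamp)
  diff(c(0, ft(inner_edges), 1))
}

#' Analytically expected niche profiles of a synthetic species
#'
#' Computes, without simulation, the niche profiles the generator's laws
#' imply: the 25-class call-structure profile (frequency-bin mass from
#' the truncated-normal CDF with edge-class clamping, note and pulse
#' masses from the categorical laws, blocks weighted 1/3), the diel
#' profile (normalized `diel_rate`; rain and bird effects cancel in
#' expectation), and the seasonal profile (normalized `seasonal_mult`
#' over the site's study months — the seasonal estimator is a per-month
#' *mean* rate, so month lengths cancel).
#'
#' @param config A [generator_config()].
#' @param species Species name in the config.
#' @param site Site identifier in the design.
#' @param weights Weights for the combined `total` profile.
#' @return A list of `niche_profile`s: `call_structure`, `diel`,
#'   `seasonal`, `total`.
#' @export
expected_profiles <- function(config, species, site,
                              weights = c(1, 1, 1) / 3) {
  stopifnot(inherits(config, "generator_config"))
  sp <- config$species[[species]]
  if (is.null(sp)) stopf("unknown species '%s'", species)
  design <- config$design
  if (!site %in% design$sites) stopf("unknown site '%s'", site)

  fmass <- truncnorm_bin_mass(sp)
  pmass <- as.numeric(tapply(sp$pulses_probs,
                             factor(bin_pulses(sp$pulses_values), levels = 1:11),
                             sum, default = 0))
  p_call <- c(fmass, sp$notes_probs, pmass) / 3
  cs <- new_niche_profile(species, site, "call_structure", p_call,
                          resource_scheme("call_structure")$labels)

  if (sum(sp$diel_rate) <= 0) stopf("species '%s' has zero activity", species)
  di <- new_niche_profile(species, site, "diel",
                          sp$diel_rate / sum(sp$diel_rate),
                          resource_scheme("diel")$labels)

  months <- design$months[[site]]
  smult <- sp$seasonal_mult[months]
  if (sum(smult) <= 0) stopf("species '%s' has zero seasonal activity at '%s'", species, site)
  se <- new_niche_profile(species, site, "seasonal",
                          as.numeric(smult / sum(smult)), months)

  list(call_structure = cs, diel = di, seasonal = se,
       total = total_niche_profile(cs, di, se, weights))
}

#' Example two-site, six-species highland community configuration
#'
#' A packaged configuration qualitatively matching an equatorial highland
#' anuran assemblage surveyed at two wetlands of similar structure but
#' different altitude: a dominant nocturnal high-frequency pulsed caller
#' (more active at the high site), a diurnal tonal caller (more active at
#' the low site), two low-frequency species with long- and short-pulsed
#' calls, a broad-band pulsed species calling day and night at both
#' sites, and a rare nocturnal low-frequency species. Heavy rain
#' suppresses or silences calling; daylight bird-band noise raises one
#' species' calling and lowers others'. The high site is surveyed over
#' seven months, the low site over six.
#'
#' @param seed Integer seed stored in the config.
#' @return A [generator_config()].
#' @export
example_community_config <- function(seed = 1) {
  months7 <- c(sprintf("2019-%02d", 9:12), sprintf("2020-%02d", 1:3))
  months6 <- months7[1:6]
  design <- survey_design(sites = c("highland", "lowland"),
                          months = list(highland = months7, lowland = months6),
                          altitudes = c(3188, 2648))
  m7 <- function(x) stats::setNames(x, months7)
  s2 <- function(hi, lo) c(highland = hi, lowland = lo)
  diel <- function(night, dawn, day, dusk) {
    r <- numeric(24)
    r[1:6] <- night   # 00-05
    r[7] <- dawn      # 06
    r[8:18] <- day    # 07-17
    r[19] <- dusk     # 18
    r[20:24] <- night # 19-23
    r
  }
  species <- list(
    species_params("hyperolius_montanus",
                   freq_mean = 3500, freq_sd = 150, freq_range = c(3000, 4000),
                   notes_probs = c(1, 0, 0, 0, 0),
                   pulses_values = 6:11, pulses_probs = rep(1 / 6, 6),
                   diel_rate = diel(2, 0.3, 0.08, 0.8),
                   seasonal_mult = m7(c(0.3, 0.4, 0.6, 0.8, 1.2, 1.5, 1.6)),
                   site_mult = s2(1.4, 0.6),
                   rain_suppression = 0.6, day_bird_response = -0.6),
    species_params("hyperolius_tonalis",
                   freq_mean = 3000, freq_sd = 120, freq_range = c(2600, 3400),
                   notes_probs = c(1, 0, 0, 0, 0),
                   pulses_values = 0L, pulses_probs = 1,
                   diel_rate = diel(0.01, 0.15, 0.12, 0.05),
                   seasonal_mult = m7(c(1.5, 1.2, 0.9, 0.7, 0.5, 0.4, 0.3)),
                   site_mult = s2(0.3, 1.5),
                   rain_suppression = 0, day_bird_response = 0.6),
    species_params("leptopelis_longipulsus",
                   freq_mean = 1600, freq_sd = 100, freq_range = c(1300, 1900),
                   notes_probs = c(1, 0, 0, 0, 0),
                   pulses_values = c(60L, 90L, 120L, 150L),
                   pulses_probs = c(0.3, 0.3, 0.2, 0.2),
                   diel_rate = diel(0.5, 0, 0, 0.2),
                   seasonal_mult = m7(c(0.5, 0.8, 1.5, 1.5, 0.6, 0.3, 0.2)),
                   site_mult = s2(0.8, 1.2),
                   rain_suppression = 0, day_bird_response = 0),
    species_params("leptopelis_brevipulsus",
                   freq_mean = 1800, freq_sd = 120, freq_range = c(1400, 2200),
                   notes_probs = c(1, 0, 0, 0, 0),
                   pulses_values = 5:12, pulses_probs = rep(1 / 8, 8),
                   diel_rate = diel(1.2, 0.05, 0.02, 0.3),
                   seasonal_mult = m7(c(1.0, 1.2, 1.8, 1.8, 0.8, 0.5, 0.4)),
                   site_mult = s2(0.7, 1.3),
                   rain_suppression = 0.1, day_bird_response = -0.3),
    species_params("phrynobatrachus_latifrons",
                   freq_mean = 3000, freq_sd = 700, freq_range = c(1500, 4500),
                   notes_probs = c(0.2, 0.3, 0.25, 0.15, 0.1),
                   pulses_values = 4:29, pulses_probs = rep(1 / 26, 26),
                   diel_rate = diel(0.4, 0.15, 0.3, 0.5),
                   seasonal_mult = m7(c(0.4, 0.7, 1.4, 1.4, 0.8, 0.5, 0.3)),
                   site_mult = s2(1.0, 1.0),
                   rain_suppression = 0, day_bird_response = 0),
    species_params("amietia_rara",
                   freq_mean = 1200, freq_sd = 80, freq_range = c(1000, 1450),
                   notes_probs = c(1, 0, 0, 0, 0),
                   pulses_values = 5L, pulses_probs = 1,
                   diel_rate = diel(0.4, 0, 0, 0),
                   seasonal_mult = m7(c(1.2, 1.0, 0.3, 0.1, 0.05, 0.05, 0.05)),
                   site_mult = s2(1.0, 0.8),
                   rain_suppression = 0, day_bird_response = 0)
  )
  generator_config(design, species, seed = seed)
}
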