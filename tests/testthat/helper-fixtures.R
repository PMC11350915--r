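# Shared fixtures: all built in code, no stored data.

tiny_design <- function() {
  survey_design(sites = c("siteA", "siteB"),
                months = c("2019-09", "2019-10", "2019-11"),
                altitudes = c(3000, 2600))
}

# Hand-built minimal record table: 2 sites, a few minutes, one multi-call row.
tiny_records <- function() {
  df <- data.frame(
    site = c("siteA", "siteA", "siteA", "siteA", "siteB"),
    date = as.Date(c("2019-09-01", "2019-09-01", "2019-09-01",
                     "2019-09-02", "2019-10-05")),
    month = c("2019-09", "2019-09", "2019-09", "2019-09", "2019-10"),
    hour = c(20L, 20L, 7L, 21L, 6L),
    minute_index = c(1L, 1L, 2L, 3L, 5L),
    species = c("sp1", "sp2", NA, "sp1", "sp2"),
    call_rate = c(12L, 3L, 0L, 5L, 2L),
    calls = c("3400:1:8;3550:1:9", "1700:1:60", "", "3390:1:7", "1650:1:72"),
    spl_1k = c(-80, -80, -60, -85, -70),
    spl_2k = c(-78, -78, -58, -80, -69),
    spl_3k = c(-75, -75, -55, -79, -66),
    spl_4k = c(-74, -74, -50, -78, -60),
    spl_5k = c(-73, -73, -52, -77, -61),
    rain_index = c(0L, 0L, 1L, 0L, 0L),
    stringsAsFactors = FALSE)
  validate_records(df)
}

# Profile object over an arbitrary proportion vector (for breadth/overlap
# unit tests that do not need records).
profile_of <- function(p, dimension = "diel", species = "sp", site = "s") {
  anuraniche:::new_niche_profile(species, site, dimension, p,
                                 paste0("c", seq_along(p)))
}

random_profile <- function(r) {
  x <- stats::rexp(r)
  profile_of(x / sum(x))
}

# Dense-chorus parameter-recovery configuration: the six example species
# with site-consistent parameters (site multipliers 1) and diel rates
# scaled to a mean of 4 calls/min, over two sites x 7 months x all
# calendar days x 24 h x 5 min (> 50,000 recorded minutes). High shared
# abundance makes every per-month profile estimable, so the +/- 0.02
# recovery band probes estimator correctness, not sampling scarcity.
recovery_config <- function(seed = 20) {
  cfg <- example_community_config(seed)
  months7 <- cfg$design$months$highland
  cfg$design <- survey_design(c("highland", "lowland"), months = months7,
                              altitudes = c(3188, 2648))
  cfg$days_per_month <- "all"
  for (nm in names(cfg$species)) {
    cfg$species[[nm]]$site_mult[] <- 1
    d <- cfg$species[[nm]]$diel_rate
    cfg$species[[nm]]$diel_rate <- d * 4 / mean(d)
  }
  cfg
}

# Small fast generator config (one or two species) for oracle tests.
small_config <- function(species, seed = 5, days = 4, ...) {
  design <- survey_design("siteA", months = c("2019-09", "2019-10"))
  generator_config(design, species, days_per_month = days, seed = seed, ...)
}

flat_species <- function(name = "sp1", rate = 2, rain_suppression = 1,
                         site = "siteA") {
  species_params(name, freq_mean = 3000, freq_sd = 200,
                 freq_range = c(2500, 3500),
                 notes_probs = c(1, 0, 0, 0, 0),
                 pulses_values = 6:8, pulses_probs = rep(1 / 3, 3),
                 diel_rate = rep(rate, 24),
                 seasonal_mult = c("2019-09" = 1, "2019-10" = 1),
                 site_mult = stats::setNames(1, site),
                 rain_suppression = rain_suppression)
}
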