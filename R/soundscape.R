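# Band sound-pressure noise proxies and noise-activity relationships.
#
# SPL values are decibels relative to digital full scale (0 dBFS = a
# full-scale sine), since the recorders' absolute gain calibration is
# unknown; 1 kHz serves as the geophony (wind/rain) proxy and the mean of
# the 4 and 5 kHz bands as the daylight bird-chorus proxy.

window_fn <- function(name, n) {
  k <- seq(0, n - 1) / (n - 1)
  switch(name,
    "blackman-harris" = 0.35875 - 0.48829 * cos(2 * pi * k) +
      0.14128 * cos(4 * pi * k) - 0.01168 * cos(6 * pi * k),
    "hann" = 0.5 - 0.5 * cos(2 * pi * k),
    "rectangular" = rep(1, n),
    stopf("unknown window '%s'", name))
}

#' Band sound-pressure levels of a mono signal
#'
#' Computes, for each requested center frequency, the mean over
#' 50%-overlapping windowed FFT frames of the power in the spectrum bin
#' nearest the center, expressed in dB relative to full scale (a
#' full-scale sine at a bin center reads 0 dBFS). Values are floored at
#' -120 dB (digital silence).
#'
#' @param audio Numeric vector, mono PCM samples in \[-1, 1\].
#' @param center_freqs Band centers in Hz (default 1-5 kHz in 1 kHz
#'   steps), each below Nyquist.
#' @param fft_size FFT frame length in samples (power of two).
#' @param window Analysis window: `"blackman-harris"` (default),
#'   `"hann"` or `"rectangular"`.
#' @param sample_rate Sampling rate in Hz.
#' @return Named numeric vector of dBFS values (`spl_1k`, ... for kHz
#'   centers).
#' @export
band_spl <- function(audio, center_freqs = seq(1000, 5000, 1000),
                     fft_size = 1024, window = "blackman-harris",
                     sample_rate = 44100) {
  if (length(audio) == 0L) stopf("empty audio signal")
  if (length(audio) < fft_size) {
    stopf("audio shorter than one FFT frame (%d samples)", fft_size)
  }
  if (bitwAnd(fft_size, fft_size - 1L) != 0L) stopf("fft_size must be a power of two")
  if (any(center_freqs <= 0) || any(center_freqs >= sample_rate / 2)) {
    stopf("center frequencies must lie in (0, sample_rate/2)")
  }
  w <- window_fn(window, fft_size)
  hop <- fft_size %/% 2L
  starts <- seq(1L, length(audio) - fft_size + 1L, by = hop)
  bins <- round(center_freqs * fft_size / sample_rate) + 1L
  acc <- numeric(length(bins))
  for (s in starts) {
    frame_fft <- stats::fft(audio[s:(s + fft_size - 1L)] * w)
    acc <- acc + Mod(frame_fft[bins])^2
  }
  meanpow <- acc / length(starts)
  # full-scale sine at a bin center: |X| = sum(w)/2, hence the factor 4
  db <- 10 * log10(pmax(4 * meanpow / sum(w)^2, 1e-12))
  names(db) <- ifelse(center_freqs %% 1000 == 0,
                      sprintf("spl_%dk", center_freqs %/% 1000),
                      sprintf("spl_%gHz", center_freqs))
  pmax(db, -120)
}

#' Read a RIFF/WAVE PCM file as a mono signal
#'
#' Minimal reader for 16-bit (and 8/32-bit integer) PCM WAV files;
#' stereo/multichannel audio is averaged to mono. Samples are scaled to
#' \[-1, 1\].
#'
#' @param path Path to the .wav file.
#' @return A list with `samples` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav_mono <- function(path) {
  if (!file.exists(path)) stopf("wav file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("not a WAVE file: %s", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stopf("malformed wav: data chunk before fmt")
      bytes <- fmt$bits %/% 8L
      n <- size %/% bytes
      data <- switch(as.character(fmt$bits),
        "8" = (readBin(con, "integer", n, 1, signed = FALSE) - 128) / 128,
        "16" = readBin(con, "integer", n, 2, endian = "little") / 32768,
        "32" = readBin(con, "integer", n, 4, endian = "little") / 2147483648,
        stopf("unsupported bit depth: %d", fmt$bits))
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(fmt) || is.null(data)) stopf("malformed wav file: %s", path)
  if (fmt$audio_format != 1L) stopf("only PCM wav supported (format %d)", fmt$audio_format)
  if (fmt$n_channels > 1L) {
    data <- colMeans(matrix(data, nrow = fmt$n_channels))
  }
  list(samples = as.numeric(data), sample_rate = fmt$sample_rate)
}

#' Acoustic presence as a percentage of hourly records
#'
#' An hourly record (one site, date and hour) counts as present when any
#' of its recorded minutes has a positive call rate — for any species, or
#' for one given species. Returns 100 * present / total over the hourly
#' records in the requested period.
#'
#' @param records Validated annotation records.
#' @param design A [survey_design()] (supplies the period hour sets).
#' @param site Site identifier.
#' @param period `"daylight"` or `"night"`.
#' @param species Optional species identifier; default any species.
#' @return Percentage in \[0, 100\].
#' @export
acoustic_presence <- function(records, design, site,
                              period = c("daylight", "night"),
                              species = NULL) {
  period <- match.arg(period)
  at_site <- records[records$site == site, , drop = FALSE]
  if (nrow(at_site) == 0L) stopf("no records for site '%s'", site)
  hrs <- period_hours(design, period)
  in_period <- at_site[at_site$hour %in% hrs, , drop = FALSE]
  if (nrow(in_period) == 0L) stopf("no hourly records in the %s period at '%s'", period, site)
  key <- paste(in_period$date, in_period$hour)
  calling <- in_period$call_rate > 0L &
    (if (is.null(species)) !is.na(in_period$species)
     else !is.na(in_period$species) & in_period$species == species)
  present <- tapply(calling, key, any)
  100 * sum(present) / length(present)
}

#' Specific acoustic presence table
#'
#' Presence percentages for every site, species and period of a survey.
#'
#' @param records Validated annotation records.
#' @param design A [survey_design()].
#' @return A data.frame with `site`, `species`, `daylight`, `night`
#'   (percentages; `NA` when a site/period has no records).
#' @export
presence_table <- function(records, design) {
  species <- sort(unique(records$species[!is.na(records$species)]))
  rows <- list()
  for (s in design$sites) {
    if (!any(records$site == s)) next
    for (sp in species) {
      pd <- tryCatch(acoustic_presence(records, design, s, "daylight", sp),
                     error = function(e) NA_real_)
      pn <- tryCatch(acoustic_presence(records, design, s, "night", sp),
                     error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(site = s, species = sp,
                                              daylight = pd, night = pn)
    }
  }
  do.call(rbind, rows)
}

#' Regression of calling activity on band noise level
#'
#' Fits either a square-root-y model — ordinary least squares of
#' `sqrt(y)` on `x`, reported as `CA = (a + b * x)^2` with R^2 on the
#' transformed scale — or a plain linear model `CA = a + b * x`. The
#' former is the usual form for right-skewed count-like call activity
#' against the 1 kHz geophony proxy; the latter for the 4-5 kHz bird
#' proxy.
#'
#' @param x Numeric vector of band SPL values (dB).
#' @param y Numeric vector of call activity (calls/min); must be
#'   non-negative for the sqrt_y model.
#' @param model `"sqrt_y"` or `"linear"`.
#' @return A `noise_fit` list: `model`, `intercept`, `slope`, `r2`, `n`,
#'   `p_slope`, and `predict(newx)`.
#' @export
fit_noise_regression <- function(x, y, model = c("sqrt_y", "linear")) {
  model <- match.arg(model)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need at least 3 complete observations")
  if (stats::var(x) == 0) stopf("degenerate predictor: zero variance")
  if (model == "sqrt_y") {
    if (any(y < 0)) stopf("sqrt_y model requires non-negative y")
    fit <- stats::lm(sqrt(y) ~ x)
  } else {
    fit <- stats::lm(y ~ x)
  }
  s <- summary(fit)
  co <- stats::coef(fit)
  structure(list(model = model,
                 intercept = unname(co[1]), slope = unname(co[2]),
                 r2 = s$r.squared, n = length(x),
                 p_slope = s$coefficients[2, 4],
                 predict = if (model == "sqrt_y") {
                   function(newx) unname((co[1] + co[2] * newx)^2)
                 } else {
                   function(newx) unname(co[1] + co[2] * newx)
                 }),
            class = "noise_fit")
}

#' @export
print.noise_fit <- function(x, ...) {
  eqn <- if (x$model == "sqrt_y") {
    sprintf("CA = (%.3f %+.3f * SPL)^2", x$intercept, x$slope)
  } else {
    sprintf("CA = %.3f %+.3f * SPL", x$intercept, x$slope)
  }
  cat(sprintf("%s  (%s model; R^2 = %.1f%%, n = %d, p[slope] = %.3g)\n",
              eqn, x$model, 100 * x$r2, x$n, x$p_slope))
  invisible(x)
}

#' Calling-rate contrast between dry/light-rain and heavy-rain minutes
#'
#' Mean call rate of one species over minutes with rain index < 2 versus
#' minutes with heavy rain (index 2). Minutes where the species is
#' silent count as zero; no test is performed, means only.
#'
#' @param records Validated annotation records.
#' @param species Species identifier.
#' @param site Optional site filter.
#' @return Named numeric: `dry` (rain index 0-1) and `heavy_rain` means.
#' @export
rain_contrast <- function(records, species, site = NULL) {
  minutes <- species_minute_rates(records, species, site)
  heavy <- minutes$rain_index == 2L
  if (!any(heavy) || all(heavy)) {
    stopf("both rain strata must be non-empty")
  }
  c(dry = mean(minutes$call_rate[!heavy]),
    heavy_rain = mean(minutes$call_rate[heavy]))
}
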