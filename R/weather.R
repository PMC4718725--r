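#' Configuration for the synthetic weather generator
#'
#' Describes two growing seasons of tropical field weather on a uniform 5-min
#' grid: diurnal cycles plus seasonal trends plus autocorrelated noise for
#' temperature (`tp`, deg C), relative humidity (`hu`, %), solar radiation
#' (`so`, W/m2), wind speed (`wd`, m/s) and atmospheric pressure (`ps`, hPa),
#' and a marked point process of rain events (`ra`, mm per interval).
#'
#' Season names are free (defaults `dry` and `wet`); each season block carries
#' its own span, sunrise/sunset and first sampling date. Factor settings are
#' per-season named vectors where relevant.
#'
#' @param seasons named list; each element a list with `start`, `end`,
#'   `sunrise`, `sunset` ("HH:MM"), `first_sampling` (date of the first
#'   sampling day).
#' @param resolution_min grid resolution in minutes; must divide 15.
#' @param factors list of per-factor settings (means, diurnal amplitude and
#'   peak hour, per-day trend, noise sd; for `so` a clear-sky maximum and a
#'   log-scale cloud noise sd; for `ra` events/day and mean event size in mm).
#' @param ar1 lag-1 autocorrelation of the noise processes at the grid step.
#' @param seed integer RNG seed.
#' @return object of class `weather_config`.
#' @export
weather_config <- function(
    seasons = list(
      dry = list(start = "2013-01-01", end = "2013-02-20",
                 sunrise = "06:00", sunset = "18:00",
                 first_sampling = "2013-01-16"),
      wet = list(start = "2013-07-01", end = "2013-08-20",
                 sunrise = "05:30", sunset = "18:30",
                 first_sampling = "2013-07-16")),
    resolution_min = 5,
    factors = list(
      tp = list(mean = c(dry = 26.8, wet = 27.6), amplitude = 4,
                peak_hour = 14, trend_per_day = c(dry = 0.03, wet = 0.01),
                noise_sd = 0.8),
      hu = list(mean = c(dry = 78, wet = 86), amplitude = 13,
                peak_hour = 4, trend_per_day = c(dry = -0.15, wet = 0),
                noise_sd = 3),
      so = list(max = c(dry = 850, wet = 800), cloud_sd = 0.3),
      wd = list(mean = c(dry = 2.2, wet = 2.8), amplitude = 1.2,
                peak_hour = 15, trend_per_day = c(dry = 0, wet = 0),
                noise_sd = 0.6),
      ps = list(mean = c(dry = 1010, wet = 1006), amplitude = 1.5,
                peak_hour = 10, trend_per_day = c(dry = 0, wet = 0),
                noise_sd = 0.4),
      ra = list(rate_per_day = c(dry = 0.8, wet = 5),
                mean_mm = c(dry = 1.5, wet = 2.5))),
    ar1 = 0.97,
    seed = 1L) {
  cfg <- list(seasons = seasons, resolution_min = resolution_min,
              factors = factors, ar1 = ar1, seed = as.integer(seed))
  class(cfg) <- "weather_config"
  validate_weather_config(cfg)
  cfg
}

validate_weather_config <- function(cfg) {
  if (15 %% cfg$resolution_min != 0 || cfg$resolution_min <= 0)
    stop_ce("resolution_min must be a positive divisor of 15")
  for (nm in names(cfg$seasons)) {
    s <- cfg$seasons[[nm]]
    if (as_utc(s$end) <= as_utc(s$start))
      stop_ce("season '", nm, "': end must be after start")
  }
  amp_of <- function(f) cfg$factors[[f]]$amplitude
  for (f in c("tp", "hu", "wd", "ps"))
    if (any(amp_of(f) < 0)) stop_ce("negative diurnal amplitude for ", f)
  if (any(cfg$factors$ra$rate_per_day < 0))
    stop_ce("rain rate must be >= 0")
  invisible(cfg)
}

season_value <- function(x, season) {
  if (length(x) == 1 && is.null(names(x))) return(unname(x))
  if (!is.null(names(x)) && season %in% names(x)) return(unname(x[season]))
  unname(x[1])
}

#' Simulate a multivariate weather series
#'
#' Generates a uniformly sampled series per season with all six climatic
#' factors. Solar radiation is exactly zero outside the sunrise--sunset
#' window and nonnegative always; relative humidity is clamped to \[0, 100\];
#' rainfall is a nonnegative event process (mm per interval) whose total
#' equals the sum of generated event magnitudes.
#'
#' @param config a [weather_config()].
#' @return data frame of class `weather_series` with columns `time` (POSIXct,
#'   UTC), `season`, `tp`, `hu`, `so`, `wd`, `ps`, `ra`; attributes
#'   `resolution_min` and `seasons` (the season settings used).
#' @export
simulate_weather <- function(config = weather_config()) {
  validate_weather_config(config)
  set.seed(config$seed)
  res <- config$resolution_min
  steps_per_day <- 24 * 60 / res
  out <- lapply(names(config$seasons), function(sn) {
    s <- config$seasons[[sn]]
    t0 <- as_utc(s$start); t1 <- as_utc(s$end)
    time <- seq(t0, t1, by = res * 60)
    n <- length(time)
    h <- hour_of_day(time)
    days <- as.numeric(difftime(time, t0, units = "days"))
    diurnal <- function(f) {
      fc <- config$factors[[f]]
      season_value(fc$mean, sn) +
        season_value(fc$trend_per_day, sn) * days +
        fc$amplitude * cos(2 * pi * (h - fc$peak_hour) / 24) +
        ar1_noise(n, fc$noise_sd, config$ar1)
    }
    tp <- diurnal("tp")
    hu <- pmin(100, pmax(0, diurnal("hu")))
    wd <- pmax(0, diurnal("wd"))
    ps <- diurnal("ps")
    # solar: clear-sky half-sine between sunrise and sunset, cloud attenuation
    sr <- parse_hm(s$sunrise); ss <- parse_hm(s$sunset)
    elev <- sin(pi * (h - sr) / (ss - sr))
    elev[h <= sr | h >= ss] <- 0
    cloud <- pmin(1, exp(ar1_noise(n, config$factors$so$cloud_sd, config$ar1)))
    so <- season_value(config$factors$so$max, sn) * elev * cloud
    # rain events: Bernoulli thinning of a per-interval rate, Exp magnitudes
    rate <- season_value(config$factors$ra$rate_per_day, sn)
    p_int <- min(1, rate / steps_per_day)
    ev <- if (p_int > 0) rbinom(n, 1L, p_int) else integer(n)
    ra <- numeric(n)
    idx <- which(ev == 1L)
    if (length(idx))
      ra[idx] <- rexp(length(idx), 1 / season_value(config$factors$ra$mean_mm, sn))
    data.frame(time = time, season = sn, tp = tp, hu = hu, so = so,
               wd = wd, ps = ps, ra = ra, stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, out)
  rownames(w) <- NULL
  attr(w, "resolution_min") <- res
  attr(w, "seasons") <- config$seasons
  class(w) <- c("weather_series", "data.frame")
  w
}

#' @export
print.weather_series <- function(x, ...) {
  cat("<weather_series> ", nrow(x), " rows at ",
      attr(x, "resolution_min"), "-min resolution; seasons: ",
      paste(unique(x$season), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a weather series as CSV
#'
#' ISO-8601 timestamp column plus season and the six factor columns.
#'
#' @param weather a `weather_series`.
#' @param path output file path.
#' @export
write_weather_csv <- function(weather, path) {
  out <- weather
  out$time <- fmt_utc(out$time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
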