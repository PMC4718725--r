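#' Soil-moisture model settings
#'
#' Soil moisture is expressed as relative saturation in \[0, 1\] with
#' saturation = 1 (tensiometer units are not modeled). In the irrigated field
#' both depths stay at saturation. In the rainfed field moisture declines
#' exponentially between rains and recharges with rainfall; the 30-cm depth
#' decays more slowly and receives recharge with a lag, so it trails the
#' 15-cm depth.
#'
#' @param saturation saturation value (relative units).
#' @param decay15,decay30 per-grid-step exponential decay rates at 15/30 cm.
#' @param recharge15,recharge30 recharge per mm of rainfall at 15/30 cm.
#' @param lag30_steps grid steps by which recharge at 30 cm lags rainfall.
#' @return object of class `soil_config`.
#' @export
soil_config <- function(saturation = 1, decay15 = 1.1e-4, decay30 = 5e-5,
                        recharge15 = 0.04, recharge30 = 0.02,
                        lag30_steps = 24L) {
  structure(list(saturation = saturation, decay15 = decay15,
                 decay30 = decay30, recharge15 = recharge15,
                 recharge30 = recharge30, lag30_steps = as.integer(lag30_steps)),
            class = "soil_config")
}

#' Simulate soil moisture for one field
#'
#' @param weather a `weather_series` (supplies the time grid and rainfall).
#' @param field `"irrigated"` (constant saturation at both depths) or
#'   `"rainfed"` (decay/recharge dynamics).
#' @param config a [soil_config()].
#' @return data frame of class `soil_moisture` with columns `time`, `season`,
#'   `field`, `sm15`, `sm30`.
#' @export
simulate_soil_moisture <- function(weather, field, config = soil_config()) {
  if (!field %in% c("irrigated", "rainfed"))
    stop_ce("unknown field label: ", field)
  sat <- config$saturation
  if (field == "irrigated") {
    out <- data.frame(time = weather$time, season = weather$season,
                      field = field, sm15 = sat, sm30 = sat)
  } else {
    blocks <- lapply(unique(weather$season), function(sn) {
      wi <- weather[weather$season == sn, ]
      rain <- wi$ra
      rain30 <- c(numeric(min(config$lag30_steps, length(rain))),
                  head(rain, max(0, length(rain) - config$lag30_steps)))
      sm15 <- decay_recharge(rain, sat, config$decay15, config$recharge15)
      sm30 <- decay_recharge(rain30, sat, config$decay30, config$recharge30)
      data.frame(time = wi$time, season = sn, field = field,
                 sm15 = sm15, sm30 = sm30)
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
  }
  class(out) <- c("soil_moisture", "data.frame")
  out
}

# first-order reservoir: one decay step, then recharge, capped at saturation
decay_recharge <- function(rain, sat, decay, recharge) {
  n <- length(rain)
  out <- numeric(n)
  s <- sat
  for (t in seq_len(n)) {
    s <- min(sat, s * (1 - decay) + recharge * rain[t])
    out[t] <- s
  }
  out
}

#' Write soil-moisture series (possibly several fields) as CSV
#' @param soil a `soil_moisture` data frame (rbind several fields if needed).
#' @param path output file path.
#' @export
write_soil_csv <- function(soil, path) {
  out <- soil
  out$time <- fmt_utc(out$time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
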