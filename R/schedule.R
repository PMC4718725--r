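#' Sampling-schedule settings
#'
#' The field design samples leaf tissue at 15 timepoints per series, 48 h
#' apart, always 4 h after sunrise to hold the circadian phase fixed, for
#' every season x field x genotype x replicate combination.
#'
#' @param weather_config a [weather_config()] supplying season spans, sunrise
#'   times and first sampling dates.
#' @param n_timepoints timepoints per series.
#' @param interval_hr hours between consecutive timepoints.
#' @param offset_hr sampling offset after sunrise, hours.
#' @param fields field labels.
#' @param genotypes genotype labels (same pair grown in both seasons in the
#'   synthetic design).
#' @param replicates number of biological replicates.
#' @return object of class `schedule_config`.
#' @export
schedule_config <- function(weather_config = climexpr::weather_config(),
                            n_timepoints = 15L, interval_hr = 48,
                            offset_hr = 4, fields = c("irrigated", "rainfed"),
                            genotypes = c("g1", "g2"), replicates = 2L) {
  structure(list(weather_config = weather_config,
                 n_timepoints = as.integer(n_timepoints),
                 interval_hr = interval_hr, offset_hr = offset_hr,
                 fields = fields, genotypes = genotypes,
                 replicates = as.integer(replicates)),
            class = "schedule_config")
}

#' Build the sampling schedule
#'
#' One row per sample: season, field, genotype, replicate, timepoint (1..n)
#' and timestamp (sunrise + offset on each sampling day).
#'
#' @param config a [schedule_config()].
#' @return data frame of class `sampling_schedule` with columns `sample_id`,
#'   `season`, `field`, `genotype`, `replicate`, `timepoint`, `time`.
#' @export
make_schedule <- function(config = schedule_config()) {
  wc <- config$weather_config
  rows <- list()
  for (sn in names(wc$seasons)) {
    s <- wc$seasons[[sn]]
    day0 <- as_utc(s$first_sampling)
    t_first <- day0 + (parse_hm(s$sunrise) + config$offset_hr) * 3600
    times <- t_first + (seq_len(config$n_timepoints) - 1) *
      config$interval_hr * 3600
    if (max(times) > as_utc(s$end))
      stop_ce("season '", sn, "' span too short for ", config$n_timepoints,
              " timepoints ", config$interval_hr, " h apart")
    grid <- expand.grid(timepoint = seq_len(config$n_timepoints),
                        replicate = seq_len(config$replicates),
                        genotype = config$genotypes,
                        field = config$fields,
                        stringsAsFactors = FALSE)
    grid$season <- sn
    grid$time <- times[grid$timepoint]
    rows[[sn]] <- grid
  }
  sched <- do.call(rbind, rows)
  sched$sample_id <- sprintf("%s_%s_%s_r%d_t%02d", sched$season,
                             substr(sched$field, 1, 4), sched$genotype,
                             sched$replicate, sched$timepoint)
  sched <- sched[, c("sample_id", "season", "field", "genotype", "replicate",
                     "timepoint", "time")]
  rownames(sched) <- NULL
  class(sched) <- c("sampling_schedule", "data.frame")
  sched
}

#' Developmental anchor dates
#'
#' Phenology anchors per season x field: transplanting (stage 0), end of
#' tillering (stage 40) and heading (stage 100). Dates must be strictly
#' increasing. The developmental-stage parameter interpolates linearly
#' between anchors.
#'
#' @param anchors named list `season -> field -> list(transplant,
#'   tillering_end, heading)`. Defaults match the synthetic two-season design.
#' @return object of class `dev_anchors`.
#' @export
dev_anchors <- function(anchors = NULL) {
  if (is.null(anchors)) {
    mk <- function(tr, ti, he)
      list(transplant = tr, tillering_end = ti, heading = he)
    anchors <- list(
      dry = list(irrigated = mk("2013-01-01", "2013-02-08", "2013-03-15"),
                 rainfed   = mk("2013-01-03", "2013-02-10", "2013-03-18")),
      wet = list(irrigated = mk("2013-06-23", "2013-08-03", "2013-09-08"),
                 rainfed   = mk("2013-06-25", "2013-08-05", "2013-09-10")))
  }
  for (sn in names(anchors)) for (fd in names(anchors[[sn]])) {
    a <- anchors[[sn]][[fd]]
    d <- as_utc(c(a$transplant, a$tillering_end, a$heading))
    if (any(diff(as.numeric(d)) <= 0))
      stop_ce("anchor dates must be strictly increasing (", sn, "/", fd, ")")
  }
  structure(anchors, class = "dev_anchors")
}

#' Write a schedule as JSON
#' @param schedule a `sampling_schedule`.
#' @param path output file path.
#' @export
write_schedule_json <- function(schedule, path) {
  out <- schedule
  out$time <- fmt_utc(out$time)
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
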