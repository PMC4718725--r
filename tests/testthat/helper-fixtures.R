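# shared fixtures, built once per session (weather + ED engineering is the
# expensive part; every file reuses the same deterministic objects)

fixture_env <- new.env(parent = emptyenv())

fx <- function() {
  if (!is.null(fixture_env$ed)) return(as.list(fixture_env))
  w <- simulate_weather(weather_config(seed = 1))
  soil <- rbind(simulate_soil_moisture(w, "irrigated"),
                simulate_soil_moisture(w, "rainfed"))
  sched <- make_schedule(schedule_config())
  design <- unique(sched[c("season", "field", "timepoint")])
  design <- design[do.call(order, design), , drop = FALSE]
  rownames(design) <- NULL
  key_d <- do.call(paste, c(design, sep = "|"))
  key_s <- do.call(paste, c(sched[c("season", "field", "timepoint")],
                            sep = "|"))
  design$time <- sched$time[match(key_d, key_s)]
  ed <- build_ed_matrix(w, design, soil = soil, center_keys = "season")
  fixture_env$weather <- w
  fixture_env$soil <- soil
  fixture_env$schedule <- sched
  fixture_env$design <- design
  fixture_env$ed <- ed
  fixture_env$X <- t(ed$values)
  as.list(fixture_env)
}

# noise-free weather: pure sinusoids, no rain, no trend
quiet_weather_config <- function(seed = 1) {
  cfg <- weather_config(seed = seed)
  for (f in c("tp", "hu", "wd", "ps")) {
    cfg$factors[[f]]$noise_sd <- 0
    cfg$factors[[f]]$trend_per_day[] <- 0
  }
  cfg$factors$so$cloud_sd <- 0
  cfg$factors$ra$rate_per_day[] <- 0
  cfg
}

# uniform synthetic weather data frame for closed-form window tests
flat_weather <- function(tp, hours = 48, res_min = 5, season = "dry") {
  n <- hours * 60 / res_min + 1
  time <- as.POSIXct("2013-01-01", tz = "UTC") + (seq_len(n) - 1) * res_min * 60
  if (length(tp) == 1) tp <- rep(tp, n)
  stopifnot(length(tp) == n)
  w <- data.frame(time = time, season = season, tp = tp, hu = 50, so = 0,
                  wd = 1, ps = 1000, ra = 0)
  attr(w, "resolution_min") <- res_min
  class(w) <- c("weather_series", "data.frame")
  w
}

# design with two binary context variables for piecewise tests
toy_design <- function() {
  d <- expand.grid(timepoint = 1:15, field = c("irrigated", "rainfed"),
                   season = c("dry", "wet"), stringsAsFactors = FALSE)
  d[c("season", "field", "timepoint")]
}

# brute-force reference for select_equation: double loop over admissible
# subsets with the same CV folds
brute_force_equation <- function(X, y, candidates, cfg, fold_assignments) {
  n <- length(y)
  if (length(candidates) > 1)
    candidates <- prune_correlated_candidates(candidates, X, y, cfg$corr_cap,
                                              fold_assignments)
  subsets <- list(character(0))
  if (length(candidates)) {
    cc <- cor(X[, candidates, drop = FALSE])
    if (length(candidates) == 1)
      cc <- matrix(1, 1, 1, dimnames = list(candidates, candidates))
    for (k in seq_len(min(cfg$max_terms, length(candidates)))) {
      for (set in combn(candidates, k, simplify = FALSE)) {
        if (length(set) >= 2) {
          cs <- abs(cc[set, set])
          if (any(cs[upper.tri(cs)] > cfg$corr_cap)) next
        }
        subsets[[length(subsets) + 1]] <- set
      }
    }
  }
  score <- sapply(subsets, function(set) {
    mse <- cv_mse(set, X, y, fold_assignments)$mse
    bic(mse, n, length(set))
  })
  ps <- lengths(subsets)
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = "+"), "")
  subsets[[order(score, ps, keys)[1]]]
}
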