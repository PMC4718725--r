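test_that("window averages obey closed forms and match direct summation", {
  w <- flat_weather(25)
  t1 <- as.POSIXct("2013-01-02 12:00", tz = "UTC")
  for (win in c(15, 60, 240, 1440))
    expect_equal(window_average(w, "tp", win, t1), 25)

  # linear ramp: trailing closed-window mean equals the midpoint value
  hrs <- seq(0, 48, by = 5 / 60)
  wr <- flat_weather(hrs * 1.0)          # 1 degree per hour
  v <- window_average(wr, "tp", 240, t1)
  expect_equal(v, (36 - 2) * 1.0, tolerance = 1e-10)

  # random series vs direct summation oracle
  set.seed(10)
  wn <- flat_weather(rnorm(577, 20, 3))
  for (win in c(15, 60, 240)) {
    sel <- wn$time >= t1 - win * 60 & wn$time <= t1
    expect_equal(window_average(wn, "tp", win, t1), mean(wn$tp[sel]),
                 tolerance = 1e-12)
  }
  expect_error(window_average(wn, "tp", 6000,
                              as.POSIXct("2013-01-01 01:00", tz = "UTC")),
               "before the start")
})

test_that("NL transforms match their printed forms and are reciprocal", {
  expect_equal(nl_transform(400, "+"), 1)
  expect_equal(nl_transform(400, "-"), 1)
  expect_equal(nl_transform(600, "+"), exp(1))
  expect_equal(nl_transform(0, "-"), exp(2))
  x <- seq(0, 1200, by = 50)
  expect_equal(nl_transform(x, "+") * nl_transform(x, "-"), rep(1, length(x)),
               tolerance = 1e-12)
  expect_true(all(diff(nl_transform(x, "+")) > 0))
  expect_true(all(diff(nl_transform(x, "-")) < 0))
})

test_that("recent change uses the lag-specific base windows", {
  t1 <- as.POSIXct("2013-01-02 12:00", tz = "UTC")
  expect_equal(recent_change(flat_weather(25), "tp", 60, t1), 0)
  hrs <- seq(0, 48, by = 5 / 60)
  wr <- flat_weather(hrs * 1.0)
  expect_equal(recent_change(wr, "tp", 60, t1), 1.0, tolerance = 1e-10)
  expect_equal(recent_change(wr, "tp", 20, t1), 20 / 60, tolerance = 1e-10)
  expect_equal(recent_change(wr, "tp", 120, t1), 2.0, tolerance = 1e-10)
  # sinusoid vs brute-force two-average computation
  ws <- flat_weather(10 * sin(hrs / 3))
  base <- c(`20` = 5, `60` = 10, `120` = 30)
  for (lag in c(20, 60, 120)) {
    b <- base[as.character(lag)] * 60
    m1 <- mean(ws$tp[ws$time >= t1 - b & ws$time <= t1])
    t0 <- t1 - lag * 60
    m0 <- mean(ws$tp[ws$time >= t0 - b & ws$time <= t0])
    expect_equal(recent_change(ws, "tp", lag, t1), m1 - m0,
                 tolerance = 1e-12)
  }
  expect_error(recent_change(flat_weather(25), "ps", 60, t1), "tp, hu, wd, so")
})

test_that("fluctuation residual vanishes for a clean daily cycle and sees pulses", {
  hrs <- seq(0, 240, by = 5 / 60)
  clean <- flat_weather(27 + 4 * sin(2 * pi * hrs / 24) + 0.05 * hrs,
                        hours = 240)
  t1 <- as.POSIXct("2013-01-09 12:00", tz = "UTC")
  for (win in c(60, 240, 1440))
    expect_lt(abs(fluctuation_residual(clean, win, t1)), 0.05)

  # a 2-degree, 1-hour pulse inside the window shows up as roughly
  # magnitude x duration / window (the decomposition absorbs a little)
  pulse <- clean
  sel <- pulse$time >= t1 - 3 * 3600 & pulse$time < t1 - 2 * 3600
  pulse$tp[sel] <- pulse$tp[sel] + 2
  eps <- fluctuation_residual(pulse, 240, t1)
  expect_lt(abs(eps - 2 * (1 / 4)), 0.35 * 2 * (1 / 4))

  short <- flat_weather(25, hours = 30)
  expect_error(fluctuation_residual(short, 60, t1), "shorter than two days")
})

test_that("fluctuation residual of white noise is unbiased", {
  vals <- vapply(1:300, function(s) {
    set.seed(s)
    w <- flat_weather(rnorm(1153, 25, 1), hours = 96)
    fluctuation_residual(w, 1440, as.POSIXct("2013-01-04 12:00", tz = "UTC"))
  }, 0)
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("developmental stage interpolates through the anchors", {
  a <- list(transplant = "2013-01-01", tillering_end = "2013-02-10",
            heading = "2013-03-22")
  expect_equal(dev_stage(as_dt <- as.POSIXct("2013-01-01", tz = "UTC"), a), 0)
  expect_equal(dev_stage(as.POSIXct("2013-02-10", tz = "UTC"), a), 40)
  expect_equal(dev_stage(as.POSIXct("2013-03-22", tz = "UTC"), a), 100)
  mid <- as.POSIXct("2013-03-02", tz = "UTC")   # halfway tillering -> heading
  expect_equal(dev_stage(mid, a), 70)
  grid <- seq(as.POSIXct("2013-01-01", tz = "UTC"),
              as.POSIXct("2013-04-15", tz = "UTC"), by = "1 day")
  expect_true(all(diff(dev_stage(grid, a)) >= 0))
  expect_error(dev_stage(as.POSIXct("2012-12-31", tz = "UTC"), a),
               "before the transplanting")
})

test_that("field indicator and soil parameters follow the conventions", {
  expect_equal(field_indicator(c("irrigated", "rainfed")), c(0, 1))
  expect_error(field_indicator("upland"), "unknown field")
  f <- fx()
  expect_equal(sum(field_indicator(f$design$field)), nrow(f$design) / 2)
  sm <- soil_moisture_params(f$soil, "irrigated", f$design$time[1:5])
  expect_true(all(sm == 1))
  expect_error(soil_moisture_params(f$soil, "rainfed",
                                    as.POSIXct("2012-01-01", tz = "UTC")),
               "before the first")
  # rainfed moisture is dynamic (decay/recharge), unlike the irrigated field
  dry_t <- f$design$time[f$design$season == "dry"][1:15]
  smr <- soil_moisture_params(f$soil, "rainfed", dry_t)
  expect_gt(sd(smr[, "sm15"]), 0)
  expect_true(all(smr <= 1))
})

test_that("the assembled grid covers the full parameter families", {
  f <- fx()
  originals <- names(f$ed$merge_map)
  for (fac in c("tp", "hu", "so", "wd", "ps", "ra"))
    for (win in c("15min", "1hr", "4hr", "24hr", "3d", "6d", "10d", "15d"))
      expect_true(paste(fac, win, sep = "_") %in% originals)
  for (win in c("15min", "1hr", "4hr")) {
    expect_true(paste0("so_", win, "_NL-") %in% originals)
    expect_true(paste0("so_", win, "_NL+") %in% originals)
  }
  for (fac in c("tp", "hu", "so", "wd"))
    for (lag in c("20min", "1hr", "2hr"))
      expect_true(paste0(fac, "_d", lag) %in% originals)
  for (win in c("1hr", "4hr", "24hr"))
    expect_true(paste0("tp_e", win) %in% originals)
  expect_true(all(c("sm15", "sm30", "field", "dev") %in% originals))
  expect_equal(length(originals), 73)
})

test_that("finalized ED matrix is centered, scaled, decorrelated and idempotent", {
  f <- fx()
  v <- f$ed$values
  grp <- f$ed$samples$season
  for (g in unique(grp))
    expect_lt(max(abs(rowMeans(v[, grp == g]))), 1e-10)
  expect_equal(unname(apply(v, 1, sd)), rep(1, nrow(v)), tolerance = 1e-10)
  cc <- f$ed$corr; diag(cc) <- 0
  expect_lte(max(abs(cc)), 0.98)
  # idempotence
  again <- assemble_and_finalize(v, f$ed$info, f$design,
                                 center_keys = "season", merge_r = 0.98)
  expect_equal(again$values, v, tolerance = 1e-10)
  expect_error(assemble_and_finalize(rbind(v[1:3, ], flat = rep(1, ncol(v))),
                                     f$ed$info[1:4, ], f$design,
                                     center_keys = "season"),
               "constant parameter")
})

test_that("near-duplicate parameters are merged to their mean", {
  set.seed(20)
  design <- data.frame(season = rep(c("dry", "wet"), each = 10),
                       sample_id = paste0("s", 1:20))
  a <- rnorm(20)
  b <- a + rnorm(20, 0, 0.01)    # r > 0.999
  c0 <- rnorm(20)
  vals <- rbind(a = a, b = b, c = c0)
  info <- data.frame(id = c("a", "b", "c"), factor = "x", transform = "L",
                     window_min = 1)
  ed <- assemble_and_finalize(vals, info, design, center_keys = "season",
                              merge_r = 0.98)
  expect_equal(nrow(ed$values), 2)
  expect_equal(unname(ed$merge_map[c("a", "b")]), c("a", "a"))
  expect_equal(unname(ed$merge_map["c"]), "c")
  # duplicate rows merge without changing values
  dup <- rbind(a = a, a2 = a, c = c0)
  info2 <- data.frame(id = c("a", "a2", "c"), factor = "x", transform = "L",
                      window_min = 1)
  ed2 <- assemble_and_finalize(dup, info2, design, center_keys = "season")
  expect_equal(nrow(ed2$values), 2)
  # averaging identical rows leaves the (standardized) values unchanged;
  # the a/b merge is their mean, still correlated ~1 with either member
  expect_gt(cor(ed2$values["a", ], ed$values["a", ]), 0.999)
})
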