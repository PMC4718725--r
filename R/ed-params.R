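#' Trailing window average of a weather factor
#'
#' Arithmetic mean of a factor over the closed trailing window
#' \[t - window, t\] on the recording grid. Windows never cross the gap
#' between seasons; the window must be fully covered by the season containing
#' `t`.
#'
#' @param weather a `weather_series`.
#' @param factor one of `tp`, `hu`, `so`, `wd`, `ps`, `ra`.
#' @param window_min window length in minutes.
#' @param t_sample POSIXct sampling time(s).
#' @return numeric vector, one value per sampling time.
#' @export
window_average <- function(weather, factor, window_min, t_sample) {
  trailing_mean(weather$time, weather[[factor]], weather$season,
                as_utc(t_sample), window_min * 60)
}

# closed-interval trailing mean; errors if the window starts before the
# enclosing season's first record. Sums are taken per query (not via a
# running cumulative sum) so precision does not degrade along long series.
trailing_mean <- function(time, x, season, t, window_sec) {
  tn <- as.numeric(time)
  starts <- tapply(tn, season, min)
  t_num <- as.numeric(t)
  i2 <- findInterval(t_num, tn)
  i0 <- findInterval(t_num - window_sec - 0.5, tn)
  if (any(i2 < 1)) stop_ce("sampling time precedes the weather series")
  s_at <- season[i2]
  if (any(t_num - window_sec < starts[s_at] - 1e-9))
    stop_ce("window extends before the start of the weather series")
  vapply(seq_along(t_num),
         function(j) mean(x[(i0[j] + 1):i2[j]]), 0)
}

#' Non-linear solar-radiation transforms
#'
#' Exponential transforms of short-term solar-radiation averages (W/m2) that
#' amplify sensitivity at high (NL+) or low (NL-) irradiance:
#' `NL+(x) = exp((x - 400) / 200)` and `NL-(x) = exp((400 - x) / 200)`.
#' The two are reciprocal: `NL+(x) * NL-(x) = 1`.
#'
#' @param x solar-radiation average(s), W/m2.
#' @param direction `"+"` or `"-"`.
#' @return transformed value(s).
#' @export
nl_transform <- function(x, direction = c("+", "-")) {
  direction <- match.arg(direction)
  if (direction == "+") exp((x - 400) / 200) else exp((400 - x) / 200)
}

#' Recent change (delta) in a weather factor
#'
#' Difference between a short trailing average ending at the sampling time and
#' the same average ending one lag earlier. Base averaging windows are 5, 10
#' and 30 min for lags of 20 min, 1 h and 2 h respectively.
#'
#' @param weather a `weather_series`.
#' @param factor one of `tp`, `hu`, `so`, `wd` (the dynamic factors).
#' @param lag_min lag in minutes: 20, 60 or 120.
#' @param t_sample POSIXct sampling time(s).
#' @return numeric vector of differences.
#' @export
recent_change <- function(weather, factor, lag_min, t_sample) {
  if (!factor %in% c("tp", "hu", "so", "wd"))
    stop_ce("recent change is defined for tp, hu, wd, so only")
  base <- c(`20` = 5, `60` = 10, `120` = 30)[as.character(lag_min)]
  if (is.na(base)) stop_ce("lag must be 20, 60 or 120 minutes")
  t_sample <- as_utc(t_sample)
  window_average(weather, factor, base, t_sample) -
    window_average(weather, factor, base, t_sample - lag_min * 60)
}

#' Remainder of the daily temperature decomposition
#'
#' Decomposes each season's temperature series into a daily-periodic
#' component, a trend and a remainder (seasonal-trend decomposition by loess,
#' period = samples per day) and returns the remainder aligned to the weather
#' rows.
#'
#' @param weather a `weather_series`.
#' @return numeric vector, same length as `nrow(weather)`.
#' @export
temperature_remainder <- function(weather) {
  res <- attr(weather, "resolution_min")
  period <- 24 * 60 / res
  out <- numeric(nrow(weather))
  for (sn in unique(weather$season)) {
    sel <- weather$season == sn
    x <- weather$tp[sel]
    if (length(x) < 2 * period)
      stop_ce("season '", sn, "' is shorter than two days; cannot decompose")
    dec <- stats::stl(stats::ts(x, frequency = period), s.window = "periodic")
    out[sel] <- as.numeric(dec$time.series[, "remainder"])
  }
  out
}

#' Fluctuation (epsilon) parameter: trailing mean of the temperature remainder
#'
#' @param weather a `weather_series`.
#' @param window_min trailing window in minutes (1 h, 4 h or 24 h in the
#'   standard grid).
#' @param t_sample POSIXct sampling time(s).
#' @param remainder optional precomputed [temperature_remainder()] (the
#'   decomposition is deterministic, so callers engineering many parameters
#'   compute it once).
#' @return numeric vector.
#' @export
fluctuation_residual <- function(weather, window_min, t_sample,
                                 remainder = NULL) {
  if (is.null(remainder)) remainder <- temperature_remainder(weather)
  trailing_mean(weather$time, remainder, weather$season, as_utc(t_sample),
                window_min * 60)
}

#' Developmental stage index
#'
#' Piecewise-linear phenology score through (transplanting, 0),
#' (end of tillering, 40), (heading, 100); extrapolated linearly beyond
#' heading. Monotone nondecreasing. Errors for times before transplanting.
#'
#' @param t_sample POSIXct time(s).
#' @param anchors list with `transplant`, `tillering_end`, `heading` dates
#'   (one season/field entry of [dev_anchors()]).
#' @return numeric stage value(s).
#' @export
dev_stage <- function(t_sample, anchors) {
  tt <- as.numeric(as_utc(c(anchors$transplant, anchors$tillering_end,
                            anchors$heading)))
  vv <- c(0, 40, 100)
  t_num <- as.numeric(as_utc(t_sample))
  if (any(t_num < tt[1])) stop_ce("sampling time before the transplanting anchor")
  out <- numeric(length(t_num))
  mid <- t_num <= tt[3]
  out[mid] <- stats::approx(tt, vv, xout = t_num[mid])$y
  slope <- (vv[3] - vv[2]) / (tt[3] - tt[2])
  out[!mid] <- vv[3] + slope * (t_num[!mid] - tt[3])
  out
}

#' Binary field indicator
#'
#' 0 for the irrigated field, 1 for the rainfed field.
#'
#' @param field character vector of field labels.
#' @return 0/1 numeric vector.
#' @export
field_indicator <- function(field) {
  if (!all(field %in% c("irrigated", "rainfed")))
    stop_ce("unknown field label(s): ",
            paste(setdiff(field, c("irrigated", "rainfed")), collapse = ", "))
  as.numeric(field == "rainfed")
}

#' Soil-moisture parameters at sampling times
#'
#' Series value at (or nearest before) each sampling time, per depth.
#'
#' @param soil a `soil_moisture` data frame (one field, or both stacked).
#' @param field field label of the samples.
#' @param t_sample POSIXct sampling time(s).
#' @return two-column matrix with columns `sm15`, `sm30`.
#' @export
soil_moisture_params <- function(soil, field, t_sample) {
  si <- soil[soil$field == field, ]
  if (!nrow(si)) stop_ce("no soil-moisture series for field ", field)
  idx <- findInterval(as.numeric(as_utc(t_sample)), as.numeric(si$time))
  if (any(idx < 1)) stop_ce("sampling time before the first soil reading")
  cbind(sm15 = si$sm15[idx], sm30 = si$sm30[idx])
}

# the standard parameter grid: factor x transform x window
ed_parameter_grid <- function(extra_l_windows_min = NULL) {
  l_win <- c("15min" = 15, "1hr" = 60, "4hr" = 240, "24hr" = 1440,
             "3d" = 4320, "6d" = 8640, "10d" = 14400, "15d" = 21600)
  if (!is.null(extra_l_windows_min)) {
    l_win <- sort(c(l_win, extra_l_windows_min))
  }
  rows <- list()
  for (f in c("tp", "hu", "so", "wd", "ps", "ra"))
    for (w in names(l_win))
      rows[[length(rows) + 1]] <- data.frame(
        id = paste(f, w, sep = "_"), factor = f, transform = "L",
        window_min = unname(l_win[w]), stringsAsFactors = FALSE)
  for (w in c("15min", "1hr", "4hr"))
    for (d in c("-", "+"))
      rows[[length(rows) + 1]] <- data.frame(
        id = paste0("so_", w, "_NL", d), factor = "so",
        transform = paste0("NL", d), window_min = unname(l_win[w]),
        stringsAsFactors = FALSE)
  d_lag <- c("20min" = 20, "1hr" = 60, "2hr" = 120)
  for (f in c("tp", "hu", "so", "wd"))
    for (w in names(d_lag))
      rows[[length(rows) + 1]] <- data.frame(
        id = paste0(f, "_d", w), factor = f, transform = "D",
        window_min = unname(d_lag[w]), stringsAsFactors = FALSE)
  for (w in c("1hr", "4hr", "24hr"))
    rows[[length(rows) + 1]] <- data.frame(
      id = paste0("tp_e", w), factor = "tp", transform = "R",
      window_min = unname(l_win[w]), stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Build the full ED parameter matrix for an analysis design
#'
#' Engineers every parameter of the standard grid (trailing averages for all
#' six climatic factors; NL transforms of short-term solar averages;
#' recent-change deltas for the dynamic factors; fluctuation residuals of
#' temperature; soil moisture at two depths; the field indicator; the
#' developmental stage), then merges near-duplicate parameters and
#' centers/scales via [assemble_and_finalize()].
#'
#' @param weather a `weather_series`.
#' @param design data frame with one row per analysis column; must contain
#'   `time`, `season`, and (when soil/field parameters are requested) `field`,
#'   plus the columns named in `center_keys`.
#' @param soil optional `soil_moisture` data (both fields stacked) for the
#'   `sm15`/`sm30` parameters.
#' @param anchors a [dev_anchors()] (per season x field), or `NULL` to skip
#'   the developmental-stage parameter.
#' @param transplant single transplanting date; when given, the developmental
#'   covariate is days after transplanting (used for target datasets with a
#'   single cultivation) instead of the anchored stage index.
#' @param include which parameter families to include.
#' @param extra_l_windows_min additional trailing-average windows in minutes
#'   (e.g. `c("8hr" = 480, "12hr" = 720)` for the independent target
#'   analysis).
#' @param center_keys design columns defining the centering subsets
#'   (genotype/season for the field analyses, time of day for targets).
#' @param merge_r merge threshold: parameters correlated above this are
#'   averaged together.
#' @param drop_constant drop parameters that are constant over the design
#'   (e.g. the field indicator in an irrigated-only analysis) instead of
#'   erroring in the finalizer.
#' @return an `ed_matrix` (see [assemble_and_finalize()]).
#' @export
build_ed_matrix <- function(weather, design, soil = NULL,
                            anchors = dev_anchors(), transplant = NULL,
                            include = c("climate", "soil", "field", "dev"),
                            extra_l_windows_min = NULL,
                            center_keys = c("genotype", "season"),
                            merge_r = 0.98, drop_constant = TRUE) {
  check_cols(design, c("time", "season"), "design")
  t_s <- as_utc(design$time)
  n <- nrow(design)
  vals <- list()
  info <- list()
  add <- function(id, factor, transform, window, v) {
    vals[[id]] <<- v
    info[[id]] <<- data.frame(id = id, factor = factor, transform = transform,
                              window_min = window, stringsAsFactors = FALSE)
  }
  if ("climate" %in% include) {
    grid <- ed_parameter_grid(extra_l_windows_min)
    rem <- temperature_remainder(weather)
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      v <- switch(g$transform,
        "L" = window_average(weather, g$factor, g$window_min, t_s),
        "NL+" = nl_transform(window_average(weather, "so", g$window_min, t_s), "+"),
        "NL-" = nl_transform(window_average(weather, "so", g$window_min, t_s), "-"),
        "D" = recent_change(weather, g$factor, g$window_min, t_s),
        "R" = fluctuation_residual(weather, g$window_min, t_s, remainder = rem))
      add(g$id, g$factor, g$transform, g$window_min, v)
    }
  }
  if ("soil" %in% include && !is.null(soil)) {
    check_cols(design, "field", "design")
    sm <- matrix(NA_real_, n, 2)
    for (fd in unique(design$field)) {
      sel <- design$field == fd
      sm[sel, ] <- soil_moisture_params(soil, fd, t_s[sel])
    }
    add("sm15", "sm15", "identity", NA, sm[, 1])
    add("sm30", "sm30", "identity", NA, sm[, 2])
  }
  if ("field" %in% include && "field" %in% names(design))
    add("field", "field", "identity", NA, field_indicator(design$field))
  if ("dev" %in% include) {
    if (!is.null(transplant)) {
      add("dev", "dev", "identity", NA,
          as.numeric(difftime(t_s, as_utc(transplant), units = "days")))
    } else if (!is.null(anchors)) {
      dv <- numeric(n)
      for (sn in unique(design$season)) {
        flds <- if ("field" %in% names(design)) unique(design$field[design$season == sn]) else names(anchors[[sn]])[1]
        for (fd in flds) {
          sel <- design$season == sn &
            (if ("field" %in% names(design)) design$field == fd else TRUE)
          dv[sel] <- dev_stage(t_s[sel], anchors[[sn]][[fd]])
        }
      }
      add("dev", "dev", "identity", NA, dv)
    }
  }
  values <- do.call(rbind, vals)
  colnames(values) <- design$cell_id %||% rownames(design)
  info <- do.call(rbind, info)
  rownames(info) <- NULL
  if (drop_constant) {
    keep <- apply(values, 1, sd) > 0
    if (any(!keep))
      message("dropping constant parameter(s): ",
              paste(info$id[!keep], collapse = ", "))
    values <- values[keep, , drop = FALSE]
    info <- info[keep, , drop = FALSE]
  }
  assemble_and_finalize(values, info, design, center_keys = center_keys,
                        merge_r = merge_r)
}

#' Merge near-duplicate parameters and center/scale the ED matrix
#'
#' Each parameter row is standardized over the whole profile; connected
#' components of the graph of pairs with `|r| > merge_r` are replaced by their
#' mean (members sign-aligned to the first member), and rows are then centered
#' within every centering subset and scaled to unit standard deviation over the
#' whole profile. Merging and centering/scaling are iterated to a fixed point
#' so that no retained pair exceeds the merge threshold after the final
#' centering; this also makes the finalizer idempotent.
#'
#' @param values parameters x samples numeric matrix (rows named by parameter
#'   id).
#' @param info data frame with columns `id`, `factor`, `transform`,
#'   `window_min` describing each row.
#' @param design data frame of per-sample metadata (one row per column of
#'   `values`).
#' @param center_keys design columns defining centering subsets.
#' @param merge_r merge threshold on absolute Pearson correlation.
#' @return object of class `ed_matrix`: list with `values` (finalized matrix),
#'   `info`, `samples` (the design), `merge_map` (original id -> merged id)
#'   and `corr` (pairwise correlation of the retained rows).
#' @export
assemble_and_finalize <- function(values, info, design,
                                  center_keys = c("genotype", "season"),
                                  merge_r = 0.98) {
  if (is.null(rownames(values))) rownames(values) <- info$id
  rsd <- apply(values, 1, sd)
  if (any(rsd == 0))
    stop_ce("constant parameter row(s): ",
            paste(rownames(values)[rsd == 0], collapse = ", "))
  ck <- intersect(center_keys, names(design))
  grp <- if (length(ck)) interaction(design[ck], drop = TRUE)
         else factor(rep(1, nrow(design)))
  merge_map <- setNames(rownames(values), rownames(values))
  # initial standardization over the whole profile
  values <- (values - rowMeans(values)) / apply(values, 1, sd)
  for (iter in 1:10) {
    # center within subsets, rescale whole rows to sd 1
    for (g in levels(grp)) {
      sel <- grp == g
      values[, sel] <- values[, sel, drop = FALSE] -
        rowMeans(values[, sel, drop = FALSE])
    }
    rsd <- apply(values, 1, sd)
    if (any(rsd == 0))
      stop_ce("parameter row(s) constant within centering subsets: ",
              paste(rownames(values)[rsd == 0], collapse = ", "))
    values <- values / rsd
    cc <- cor(t(values))
    diag(cc) <- 0
    if (max(abs(cc)) <= merge_r) break
    # merge connected components of the |r| > merge_r graph
    adj <- abs(cc) > merge_r
    comp <- graph_components(adj)
    newv <- list(); newi <- list()
    for (cmp in comp) {
      ids <- rownames(values)[cmp]
      if (length(cmp) == 1) {
        newv[[ids]] <- values[cmp, ]
        newi[[ids]] <- info[cmp, , drop = FALSE]
        next
      }
      signs <- sign(cc[cmp, cmp[1]]); signs[1] <- 1
      merged <- colMeans(values[cmp, , drop = FALSE] * signs)
      mid <- ids[1]
      newv[[mid]] <- merged
      newi[[mid]] <- info[cmp[1], , drop = FALSE]
      merge_map[merge_map %in% ids] <- mid
    }
    values <- do.call(rbind, newv)
    info <- do.call(rbind, newi)
    info$id <- rownames(values)
    rownames(info) <- NULL
  }
  cc <- cor(t(values))
  structure(list(values = values, info = info, samples = design,
                 merge_map = merge_map, corr = cc),
            class = "ed_matrix")
}

# connected components of a logical adjacency matrix (tiny n; BFS)
graph_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i; frontier <- i; seen[i] <- TRUE
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Resolve parameter ids through an ED matrix's merge map
#'
#' Maps original parameter ids to the row ids of the finalized matrix
#' (merged parameters are reachable through the id of any member); ids that
#' cannot be resolved yield `NA`.
#'
#' @param ed an `ed_matrix`.
#' @param params character vector of parameter ids.
#' @return character vector of row ids (possibly with `NA`s).
#' @export
resolve_param_ids <- function(ed, params) {
  out <- ifelse(params %in% rownames(ed$values), params,
                unname(ed$merge_map[params]))
  ifelse(out %in% rownames(ed$values), out, NA_character_)
}

#' @export
print.ed_matrix <- function(x, ...) {
  cat("<ed_matrix> ", nrow(x$values), " parameters x ", ncol(x$values),
      " samples (", sum(x$merge_map != names(x$merge_map)),
      " originals absorbed by merging)\n", sep = "")
  invisible(x)
}

#' Write an ED matrix as TSV plus metadata JSON
#' @param ed an `ed_matrix`.
#' @param path_tsv output TSV path (parameters x samples).
#' @param path_json output JSON path (parameter metadata + merge map).
#' @export
write_ed_matrix <- function(ed, path_tsv, path_json) {
  write.table(format(ed$values, digits = 10, trim = TRUE), path_tsv,
              sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(list(parameters = ed$info,
                            merge_map = as.list(ed$merge_map)),
                       path_json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(ed)
}
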