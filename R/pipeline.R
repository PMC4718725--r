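#' Default ground-truth cluster specifications
#'
#' Ten clusters whose means follow known 1-3-term ED equations of the kinds
#' the field analyses select (short-term solar NL transforms, temperature
#' deltas and fluctuations, soil moisture, developmental stage, long-term
#' wind/humidity/pressure averages), at a nominal cluster-mean
#' signal-to-noise ratio of 4.
#'
#' @param n_clusters how many of the ten specifications to use.
#' @param genes_per_cluster genes per cluster.
#' @param snr nominal cluster-mean signal-to-noise (variance) ratio.
#' @param genotype_sd genotype-distortion sd.
#' @param loading_sd per-gene loading spread.
#' @return list of [cluster_spec()]s.
#' @export
default_cluster_specs <- function(n_clusters = 10, genes_per_cluster = 20,
                                  snr = 4, genotype_sd = 0.05,
                                  loading_sd = 0.1) {
  eq <- function(params, coefs) list(all = list(params = params, coefs = coefs))
  eqs <- list(
    eq("so_1hr_NL-", 0.8),
    eq(c("tp_d2hr", "sm15"), c(0.7, -0.6)),
    eq("dev", 0.9),
    eq("wd_15d", 0.8),
    eq("hu_24hr", -0.8),
    eq("tp_e4hr", 0.8),
    eq(c("ra_3d", "tp_15min"), c(0.6, 0.5)),
    eq(c("so_4hr_NL+", "dev"), c(0.7, 0.5)),
    eq("ps_6d", -0.7),
    eq(c("tp_1hr", "hu_4hr", "wd_1hr"), c(0.5, -0.5, 0.4)))
  lapply(seq_len(n_clusters), function(i)
    cluster_spec(paste0("truth", i), genes_per_cluster,
                 eqs[[((i - 1) %% length(eqs)) + 1]], snr = snr,
                 loading_sd = loading_sd, genotype_sd = genotype_sd))
}

#' Ground-truth specifications for the piecewise-composition scenarios
#'
#' Three canonical context structures: a single global equation; a
#' field-specific response with opposite signs in the two fields; and the
#' mixed structure where both fields share one equation in the wet season
#' but respond differently in the dry season (solar-driven when irrigated,
#' soil-moisture-driven when rainfed).
#'
#' @param scenario which structure to generate.
#' @param n_genes genes in the cluster.
#' @param snr cluster-level signal-to-noise ratio.
#' @return a [cluster_spec()].
#' @export
scenario_cluster_spec <- function(scenario = c("global", "field_specific",
                                               "mixed"),
                                  n_genes = 20, snr = 4) {
  scenario <- match.arg(scenario)
  eqs <- switch(scenario,
    global = list(all = list(params = "so_1hr_NL-", coefs = 0.8)),
    field_specific = list(
      irrigated = list(params = "so_1hr_NL-", coefs = 0.8),
      rainfed = list(params = "so_1hr_NL-", coefs = -0.8)),
    mixed = list(
      wet = list(params = "tp_d2hr", coefs = 0.8),
      dry.irrigated = list(params = "so_1hr_NL-", coefs = 0.8),
      dry.rainfed = list(params = "sm15", coefs = -0.8)))
  cluster_spec(paste0("scenario_", scenario), n_genes, eqs, snr = snr)
}

#' Pipeline configuration
#'
#' Bundles every threshold of the analysis (all defaults are the standard
#' settings of the method), the stability-selection configurations for the
#' global and subset passes, the synthetic-data settings, and the analysis
#' mode.
#'
#' @param mode analysis mode.
#' @param seed master RNG seed; every stage derives its seed from it.
#' @param synthetic synthetic-data settings: `specs` (list of
#'   [cluster_spec()]; default [default_cluster_specs()]), `n_low_cv`,
#'   `n_low_mean`, `n_undetected`, `mode` ("counts" or "continuous").
#' @param thresholds list of analysis thresholds (detection tolerance, CV and
#'   mean cutoffs, merge and co-selection correlation caps, genotype/field
#'   correlation cutoffs, the small-cluster k rule, `k_max`).
#' @param selection,selection_subset [selection_config()]s for the global and
#'   subset stability passes.
#' @param target settings for `target-transfer` mode (see
#'   [make_target_design()]); `NULL` otherwise.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("two-season-averaged",
                                     "dry-season-two-genotype",
                                     "irrigated-two-season",
                                     "target-transfer"),
                            seed = 1L,
                            synthetic = list(),
                            thresholds = list(),
                            selection = selection_config(seed = seed),
                            selection_subset = subset_selection_config(seed = seed),
                            target = NULL) {
  mode <- match.arg(mode)
  spec_idx <- if (mode %in% c("irrigated-two-season", "target-transfer"))
    c(1, 3, 4) else 1:3   # soil-moisture truth terms need both fields
  # stable background genes outnumber the signal genes so that
  # median-of-ratios normalization sees a majority of non-changing genes
  syn_def <- list(specs = default_cluster_specs(genes_per_cluster = 15)[spec_idx],
                  n_low_cv = 60L, n_low_mean = 10L, n_undetected = 5L,
                  mode = "counts")
  synthetic <- utils::modifyList(syn_def, synthetic)
  thr_def <- list(detection = 40, cv = 0.01, mean = 1, merge_r = 0.98,
                  corr_cap = 0.85, genotype_r = 0.9, field_r = 0.8,
                  k_small_frac = 0.01, k_small_mass = 0.05, k_max = 10)
  thresholds <- utils::modifyList(thr_def, thresholds)
  structure(list(mode = mode, seed = as.integer(seed), synthetic = synthetic,
                 thresholds = thresholds, selection = selection,
                 selection_subset = selection_subset, target = target),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Lists all violated invariants without running anything; an empty result
#' means [run_pipeline()] will start.
#'
#' @param config a [pipeline_config()].
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  thr <- config$thresholds
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(inherits(config, "pipeline_config"), "not a pipeline_config")
  chk(thr$corr_cap > 0 && thr$corr_cap <= 1, "corr_cap must be in (0, 1]")
  chk(thr$merge_r > 0 && thr$merge_r <= 1, "merge_r must be in (0, 1]")
  chk(thr$cv >= 0, "cv threshold must be >= 0")
  chk(thr$detection >= 0, "detection tolerance must be >= 0")
  chk(thr$k_max >= 2, "k_max must be >= 2")
  chk(thr$k_small_frac > 0 && thr$k_small_frac < 1,
      "k_small_frac must be in (0, 1)")
  chk(thr$k_small_mass >= 0 && thr$k_small_mass <= 1,
      "k_small_mass must be in [0, 1]")
  chk(thr$field_r >= -1 && thr$field_r <= 1, "field_r must be in [-1, 1]")
  chk(thr$genotype_r >= -1 && thr$genotype_r <= 1,
      "genotype_r must be in [-1, 1]")
  for (nm in c("selection", "selection_subset")) {
    sc <- config[[nm]]
    ok <- tryCatch({
      selection_config(B = sc$B, EV = sc$EV, threshold = sc$threshold,
                       fraction = sc$fraction, max_terms = sc$max_terms,
                       corr_cap = sc$corr_cap, cv_folds = sc$cv_folds,
                       cv_repeats = sc$cv_repeats, seed = sc$seed)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) v <- c(v, paste0(nm, ": ", ok))
  }
  if (identical(config$mode, "target-transfer") && is.null(config$target))
    v <- c(v, "target-transfer mode requires target settings")
  v
}

#' Sampling design of a synthetic independent target dataset
#'
#' Daytime sampling occasions at fixed times of day over a span of
#' vegetative growth in a single irrigated cultivation; replicate-free slots.
#'
#' @param start first sampling date.
#' @param n_days number of sampling days (every other day).
#' @param times_of_day sampling hours.
#' @return data frame with `slot`, `season`, `time_of_day`, `time`.
#' @export
make_target_design <- function(start = "2013-05-20", n_days = 10,
                               times_of_day = c(8, 10, 12, 14, 16)) {
  days <- as_utc(start) + (seq_len(n_days) - 1) * 2 * 86400
  grid <- expand.grid(day = days, tod = times_of_day)
  grid <- grid[order(grid$day, grid$tod), ]
  data.frame(slot = sprintf("d%02d_h%02d",
                            match(grid$day, days), grid$tod),
             season = "target", time_of_day = grid$tod,
             time = grid$day + grid$tod * 3600,
             stringsAsFactors = FALSE)
}

#' Weather settings for a synthetic temperate target site
#' @param seed RNG seed.
#' @return a [weather_config()] with a single season covering the target span.
#' @export
target_weather_config <- function(seed = 1L) {
  weather_config(
    seasons = list(target = list(start = "2013-05-01", end = "2013-07-01",
                                 sunrise = "04:30", sunset = "19:00",
                                 first_sampling = "2013-05-20")),
    factors = list(
      tp = list(mean = c(target = 21), amplitude = 6, peak_hour = 14,
                trend_per_day = c(target = 0.05), noise_sd = 1.2),
      hu = list(mean = c(target = 70), amplitude = 15, peak_hour = 4,
                trend_per_day = c(target = 0), noise_sd = 4),
      so = list(max = c(target = 900), cloud_sd = 0.35),
      wd = list(mean = c(target = 3), amplitude = 1.5, peak_hour = 15,
                trend_per_day = c(target = 0), noise_sd = 0.8),
      ps = list(mean = c(target = 1012), amplitude = 2, peak_hour = 10,
                trend_per_day = c(target = 0), noise_sd = 0.6),
      ra = list(rate_per_day = c(target = 2), mean_mm = c(target = 1.5))),
    seed = seed)
}

#' Build the ED matrix for a target design
#'
#' Standard parameter grid extended with 8-h and 12-h short-term averages,
#' developmental covariate as days after transplanting, centered per time of
#' day to match the target expression.
#'
#' @param weather target `weather_series`.
#' @param design a [make_target_design()] result (with `time_of_day`).
#' @param transplant transplanting date.
#' @param merge_r merge threshold.
#' @return an `ed_matrix`.
#' @export
build_target_ed <- function(weather, design, transplant = "2013-05-05",
                            merge_r = 0.98) {
  build_ed_matrix(weather, design, soil = NULL, anchors = NULL,
                  transplant = transplant,
                  include = c("climate", "dev"),
                  extra_l_windows_min = c("8hr" = 480, "12hr" = 720),
                  center_keys = "time_of_day", merge_r = merge_r)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages: weather -> soil moisture -> schedule -> ED parameter matrix ->
#' simulated counts -> preprocessing -> clustering -> piecewise model
#' selection -> context summary (two-season mode) or transfer analysis
#' (target-transfer mode). All stage outputs are written under `outdir` as
#' TSV/CSV/JSON, plus a manifest with the seed, thresholds and file
#' checksums. Deterministic: two runs with the same config produce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with the main in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, quiet = FALSE) {
  viol <- validate_config(config)
  if (length(viol))
    stop_ce("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[climexpr] ", ...)
  thr <- config$thresholds
  mode <- config$mode

  say("stage weather: simulating")
  wcfg <- weather_config(seed = config$seed)
  weather <- simulate_weather(wcfg)
  soil <- rbind(simulate_soil_moisture(weather, "irrigated"),
                simulate_soil_moisture(weather, "rainfed"))
  schedule <- make_schedule(schedule_config(weather_config = wcfg))
  anchors <- dev_anchors()
  if (mode %in% c("irrigated-two-season", "target-transfer"))
    schedule <- schedule[schedule$field == "irrigated", ]
  if (mode == "dry-season-two-genotype")
    schedule <- schedule[schedule$season == "dry", ]
  write_weather_csv(weather, file.path(outdir, "weather.csv"))
  write_soil_csv(soil, file.path(outdir, "soil.csv"))
  write_schedule_json(schedule, file.path(outdir, "schedule.json"))

  say("stage edparams: engineering parameter matrix")
  collapse_geno <- mode %in% c("two-season-averaged", "irrigated-two-season",
                               "target-transfer")
  design_keys <- if (collapse_geno) c("season", "field", "timepoint")
                 else c("season", "field", "genotype", "timepoint")
  design <- unique(schedule[design_keys])
  design <- design[do.call(order, design), , drop = FALSE]
  rownames(design) <- NULL
  key_d <- do.call(paste, c(design[c("season", "field", "timepoint")],
                            sep = "|"))
  key_s <- do.call(paste, c(schedule[c("season", "field", "timepoint")],
                            sep = "|"))
  design$time <- schedule$time[match(key_d, key_s)]
  ed <- build_ed_matrix(weather, design, soil = soil, anchors = anchors,
                        center_keys = if (collapse_geno) "season"
                                      else c("genotype", "season"),
                        merge_r = thr$merge_r)
  write_ed_matrix(ed, file.path(outdir, "ed_matrix.tsv"),
                  file.path(outdir, "ed_metadata.json"))

  say("stage simulate: generating expression (",
      length(config$synthetic$specs), " clusters)")
  truth <- ground_truth(config$synthetic$specs,
                        n_low_cv = config$synthetic$n_low_cv,
                        n_low_mean = config$synthetic$n_low_mean,
                        n_undetected = config$synthetic$n_undetected,
                        seed = config$seed + 1L)
  sim <- simulate_expression(ed, truth, schedule,
                             mode = config$synthetic$mode)
  write.table(sim$counts, file.path(outdir, "counts.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write_ground_truth_json(sim, file.path(outdir, "ground_truth.json"))

  say("stage preprocess: ", nrow(sim$counts), " genes in")
  prep <- preprocess_pipeline(sim$counts, schedule,
                              max_undetected = thr$detection,
                              cv_threshold = thr$cv,
                              mean_threshold = thr$mean,
                              collapse_genotypes = collapse_geno)
  say("filter funnel: ",
      paste(sprintf("%s -%d", prep$report$stage, prep$report$removed),
            collapse = ", "), "; ", nrow(prep$profiles$values), " genes kept")
  jsonlite::write_json(prep$report, file.path(outdir, "filter_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  say("stage cluster: PAM with the representativeness k rule")
  d <- correlation_distance(prep$profiles)
  ks <- select_k(d, k_max = min(thr$k_max, nrow(d) - 1),
                 small_frac = thr$k_small_frac,
                 small_mass = thr$k_small_mass)
  means <- cluster_means(ks$clustering, prep$profiles)
  say("k = ", ks$k, "; sizes: ",
      paste(ks$clustering$sizes, collapse = ", "))
  write.table(data.frame(gene_id = names(ks$clustering$labels),
                         cluster = ks$clustering$labels),
              file.path(outdir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(means, file.path(outdir, "cluster_means.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  jsonlite::write_json(list(k = ks$k, admissible = ks$admissible,
                            sizes = ks$clustering$sizes,
                            medoids = ks$clustering$medoids),
                       file.path(outdir, "cluster_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("stage select: piecewise ED models per cluster")
  split <- switch(mode,
                  "two-season-averaged" = c("season", "field"),
                  "dry-season-two-genotype" = c("genotype", "field"),
                  "irrigated-two-season" = "season",
                  "target-transfer" = "season")
  X <- t(ed$values)
  results <- list()
  model_rows <- list()
  for (cl in rownames(means)) {
    res <- select_piecewise(X, means[cl, ], design, cfg = config$selection,
                            cfg_subset = config$selection_subset,
                            split = split,
                            seed = config$seed + 1000L +
                              match(cl, rownames(means)))
    results[[cl]] <- res
    model_rows[[cl]] <- data.frame(
      cluster = cl, composition = res$model$composition,
      pass = res$model$pass, p = res$model$p, mse = res$model$mse,
      bic = res$model$bic, r2 = res$model$r2,
      params = paste(selected_params(res), collapse = ","),
      stringsAsFactors = FALSE)
  }
  models_tab <- do.call(rbind, model_rows)
  write.table(models_tab, file.path(outdir, "models.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(results, function(r) list(
      composition = r$model$composition, pass = r$model$pass,
      bic = r$model$bic, mse = r$model$mse, r2 = r$model$r2,
      segments = lapply(r$model$segments, function(e)
        list(params = e$params, coef = as.list(e$coef))),
      flags = r$flags)),
    file.path(outdir, "models.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  ctx <- NULL
  if (mode == "two-season-averaged") {
    say("stage context: genotype/field replicability summary")
    means_g <- cluster_means(ks$clustering, prep$profiles_by_genotype)
    ctx <- context_summary(means_g, prep$profiles_by_genotype$samples,
                           means, prep$profiles$samples,
                           genotype_r_cutoff = thr$genotype_r,
                           field_r_cutoff = thr$field_r)
    write.table(ctx, file.path(outdir, "context.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  transfer <- NULL
  if (mode == "target-transfer") {
    say("stage transfer: sign-constrained transfer to synthetic target")
    tcfg <- config$target
    tdesign <- tcfg$design %||% make_target_design()
    tweather <- simulate_weather(tcfg$weather_config %||%
                                   target_weather_config(seed = config$seed + 7L))
    ted <- build_target_ed(tweather, tdesign,
                           transplant = tcfg$transplant %||% "2013-05-05",
                           merge_r = thr$merge_r)
    Xt <- t(ted$values)
    eligible <- eligible_source_models(results)
    set.seed(config$seed + 8L)
    transfer <- list()
    for (cl in eligible) {
      eq <- results[[cl]]$model$segments[["all"]]
      src <- resolve_param_ids(ted, eq$params)
      if (anyNA(src) || !length(src)) next
      signal <- as.numeric(Xt[, src, drop = FALSE] %*% eq$coef)
      y_t <- signal + rnorm(nrow(Xt), 0,
                            (tcfg$noise_frac %||% 0.5) * sd(signal))
      y_t <- center_by_time_of_day(y_t, tdesign$time_of_day)
      eq_t <- eq; eq_t$params <- src; names(eq_t$coef) <- src
      transfer[[cl]] <- transfer_model(eq_t, Xt, y_t)
    }
    jsonlite::write_json(
      lapply(transfer, function(tr) list(tested = tr$tested,
                                         retained = tr$retained,
                                         coef = as.list(tr$coef),
                                         r2 = tr$r2, null = tr$null)),
      file.path(outdir, "transfer.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  say("stage manifest")
  files <- sort(list.files(outdir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = "climexpr",
    version = as.character(utils::packageVersion("climexpr")),
    mode = mode, seed = config$seed, thresholds = thr,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(weather = weather, soil = soil, schedule = schedule,
                 ed = ed, sim = sim, prep = prep, clustering = ks,
                 means = means, results = results, models = models_tab,
                 context = ctx, transfer = transfer, manifest = manifest))
}
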