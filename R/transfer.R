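#' Center expression by time of day
#'
#' Per gene, subtracts the mean of each time-of-day stratum, removing
#' circadian-phase offsets between sampling times so that only within-stratum
#' (weather-driven) variation remains. Idempotent.
#'
#' @param values genes x samples matrix (or a vector for one gene).
#' @param time_of_day stratum label per sample.
#' @return centered values of the same shape.
#' @export
center_by_time_of_day <- function(values, time_of_day) {
  vec <- is.null(dim(values))
  if (vec) values <- matrix(values, nrow = 1)
  tod <- as.factor(time_of_day)
  for (s in levels(tod)) {
    sel <- tod == s
    values[, sel] <- values[, sel, drop = FALSE] -
      rowMeans(values[, sel, drop = FALSE])
  }
  if (vec) values[1, ] else values
}

#' Source models eligible for transfer
#'
#' Only season-independent models (single-equation composition) that explain
#' more than half of the cluster-mean variance are worth testing on an
#' independent target.
#'
#' @param results named list of `selection_result`s (one per cluster).
#' @param r2_min variance-explained threshold (strict >).
#' @return character vector of eligible cluster names.
#' @export
eligible_source_models <- function(results, r2_min = 0.5) {
  keep <- vapply(results, function(r)
    r$model$composition == "one_piece" && !is.na(r$model$r2) &&
      r$model$r2 > r2_min, TRUE)
  names(results)[keep]
}

#' Sign-constrained transfer of a source equation to a target dataset
#'
#' Fits no-intercept least squares for every subset of the source equation's
#' parameters (including the null model), discards subsets in which any
#' fitted coefficient's sign differs from the source sign, and returns the
#' BIC argmin among the admissible fits. Variance explained is reported over
#' all target points.
#'
#' @param source_eq an `ed_equation` (or list with `params` and `coef`).
#' @param X_target target samples x parameters matrix, containing at least
#'   the source parameters (computed with the same definitions and centered
#'   like the target expression).
#' @param y_target target cluster mean (centered by time of day).
#' @return object of class `transfer_result`: `tested`, `retained`, `coef`,
#'   `r2`, `bic`, `null` flag.
#' @export
transfer_model <- function(source_eq, X_target, y_target) {
  params <- source_eq$params
  miss <- setdiff(params, colnames(X_target))
  if (length(miss))
    stop_ce("source parameter(s) absent from the target matrix: ",
            paste(miss, collapse = ", "))
  src_sign <- sign(source_eq$coef[params])
  n <- length(y_target)
  subsets <- list(character(0))
  for (k in seq_along(params))
    subsets <- c(subsets, utils::combn(params, k, simplify = FALSE))
  best <- NULL
  for (set in subsets) {
    if (length(set)) {
      cf <- setNames(ols_coef(X_target[, set, drop = FALSE], y_target), set)
      if (any(sign(cf) != src_sign[set])) next
      pred <- as.numeric(X_target[, set, drop = FALSE] %*% cf)
    } else {
      cf <- numeric(0); pred <- numeric(n)
    }
    mse <- mean((y_target - pred)^2)
    b <- bic(mse, n, length(set))
    key <- paste(sort(set), collapse = "+")
    if (is.null(best) || b < best$bic - 1e-12 ||
        (abs(b - best$bic) <= 1e-12 &&
         (length(set) < length(best$retained) ||
          (length(set) == length(best$retained) && key < best$key)))) {
      sst <- sum((y_target - mean(y_target))^2)
      best <- list(retained = set, coef = cf, bic = b, key = key,
                   r2 = if (sst > 0) 1 - sum((y_target - pred)^2) / sst
                        else NA_real_)
    }
  }
  structure(list(tested = params, retained = best$retained, coef = best$coef,
                 r2 = best$r2, bic = best$bic,
                 null = length(best$retained) == 0),
            class = "transfer_result")
}

#' Filter and average a target expression dataset
#'
#' Applies the low-expression filter (value below `low_value` in more than
#' `max_low` samples removes the gene), averages replicate samples sharing a
#' (day, time-of-day) slot, and centers each gene by time of day.
#'
#' @param values genes x samples matrix of normalized log expression.
#' @param samples metadata with columns `time_of_day` and `slot` (one slot
#'   per distinct sampling occasion; replicates share a slot).
#' @param low_value expression floor used by the filter.
#' @param max_low maximum tolerated samples below the floor (strict >).
#' @return list: `values` (filtered, averaged, centered), `samples` (one row
#'   per slot), `n_removed`.
#' @export
prepare_target <- function(values, samples, low_value = -7, max_low = 17) {
  low <- rowSums(values < low_value)
  keep <- low <= max_low
  values <- values[keep, , drop = FALSE]
  grp <- factor(samples$slot, levels = unique(samples$slot))
  agg <- values %*% sapply(levels(grp), function(g) (grp == g) / sum(grp == g))
  meta <- samples[!duplicated(grp), , drop = FALSE]
  meta <- meta[match(levels(grp), meta$slot), , drop = FALSE]
  rownames(meta) <- NULL
  colnames(agg) <- meta$slot
  list(values = center_by_time_of_day(agg, meta$time_of_day),
       samples = meta, n_removed = sum(!keep))
}

#' Independent model selection on a target dataset
#'
#' Runs the clustering plus single-composition model-selection pipeline on a
#' (time-of-day-centered) target: clusters the gene profiles, and for each
#' cluster mean stability-selects candidates on the whole profile and picks
#' the best single equation by BIC — no piecewise compositions, one set of
#' parameters common to all time-of-day strata.
#'
#' @param values genes x samples centered target expression.
#' @param X_target target samples x parameters matrix (with the extended
#'   short-term windows).
#' @param k_max largest cluster count considered.
#' @param cfg a [selection_config()].
#' @param seed RNG seed.
#' @return list: `clustering`, `means`, `models` (one `ed_equation` per
#'   cluster).
#' @export
independent_target_analysis <- function(values, X_target, k_max = 20,
                                        cfg = selection_config(),
                                        seed = cfg$seed) {
  sel <- select_k(correlation_distance(values), k_max = k_max)
  means <- cluster_means(sel$clustering, values)
  models <- list()
  for (cl in rownames(means)) {
    y <- means[cl, ]
    cand <- tryCatch(
      stability_select(X_target, y, cfg, seed = seed + 1L)$selected,
      error = function(e) character(0))
    models[[cl]] <- select_equation(X_target, y, cand, cfg,
                                    seed = seed + 2L)
  }
  list(clustering = sel$clustering, means = means, models = models)
}
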