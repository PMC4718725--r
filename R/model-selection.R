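#' Settings for stability selection and model search
#'
#' @param B number of subsamples for stability selection.
#' @param EV expected-false-selection bound; together with `threshold` it
#'   fixes the number of variables kept per subsample lasso path (q) through
#'   the stability-selection bound `q^2 <= EV * (2*threshold - 1) * p`.
#' @param threshold selection-frequency cutoff in (0.5, 1\].
#' @param fraction subsample fraction in (0, 1\].
#' @param max_terms maximum parameters per linear equation.
#' @param corr_cap two parameters more correlated than this (absolute Pearson
#'   r, strict >) cannot enter the same equation.
#' @param cv_folds,cv_repeats cross-validation layout for model MSEs.
#' @param seed RNG seed threaded through subsampling and fold assignment.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(B = 300L, EV = 2, threshold = 0.65,
                             fraction = 0.85, max_terms = 3L,
                             corr_cap = 0.85, cv_folds = 5L, cv_repeats = 5L,
                             seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop_ce("fraction must be in (0, 1]")
  if (threshold <= 0.5 || threshold > 1)
    stop_ce("threshold must be in (0.5, 1]")
  if (B < 1) stop_ce("B must be >= 1")
  structure(list(B = as.integer(B), EV = EV, threshold = threshold,
                 fraction = fraction, max_terms = as.integer(max_terms),
                 corr_cap = corr_cap, cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats), seed = as.integer(seed)),
            class = "selection_config")
}

#' Subset-pass defaults for stability selection
#'
#' The season/field subset reruns use a laxer subsample fraction and a
#' stricter frequency threshold than the global pass.
#' @param seed RNG seed.
#' @param ... overrides passed to [selection_config()].
#' @return a `selection_config`.
#' @export
subset_selection_config <- function(seed = 1L, ...) {
  selection_config(threshold = 0.7, fraction = 0.7, seed = seed, ...)
}

#' Lasso stability selection
#'
#' Repeatedly subsamples the data, runs the lasso path on each subsample
#' truncated at q active variables (q from the expected-false-selection
#' bound), and retains parameters whose selection frequency reaches the
#' threshold.
#'
#' @param X samples x parameters matrix (columns named).
#' @param y response vector aligned with rows of `X`.
#' @param cfg a [selection_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return list: `selected` (parameter ids), `freq` (selection frequencies),
#'   `q` (variables kept per subsample).
#' @export
stability_select <- function(X, y, cfg = selection_config(),
                             seed = cfg$seed) {
  n <- nrow(X); p <- ncol(X)
  m <- round(cfg$fraction * n)
  if (m < cfg$max_terms + 2)
    stop_ce("subsample size ", m, " too small for ", cfg$max_terms, "-term models")
  q <- stability_q(cfg, p)
  if (!is.null(seed)) set.seed(seed)
  hits <- numeric(p)
  for (b in seq_len(cfg$B)) {
    idx <- sample.int(n, m)
    sel <- lasso_first_q(X[idx, , drop = FALSE], y[idx], q)
    hits[sel] <- hits[sel] + 1
  }
  freq <- setNames(hits / cfg$B, colnames(X))
  list(selected = names(freq)[freq >= cfg$threshold], freq = freq, q = q)
}

# per-subsample sparsity from the expected-false-selection bound
stability_q <- function(cfg, p) {
  max(1L, floor(sqrt(cfg$EV * (2 * cfg$threshold - 1) * p)))
}

# indices of the first q variables to enter the lasso path (compiled
# least-angle implementation with the lasso drop modification)
lasso_first_q <- function(X, y, q) {
  .lars_first_q(X, y, as.integer(q))
}

#' Stratified repeated cross-validation folds
#'
#' @param n number of observations.
#' @param folds,repeats layout.
#' @param strata optional factor; folds are balanced within strata so that
#'   every fold spans all design cells.
#' @param seed RNG seed.
#' @return list of `repeats` integer vectors of fold labels.
#' @export
make_cv_folds <- function(n, folds = 5, repeats = 5, strata = NULL,
                          seed = NULL) {
  if (n < folds) stop_ce("need at least as many observations as folds")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(strata)) strata <- factor(rep(1, n))
  strata <- as.factor(strata)
  lapply(seq_len(repeats), function(r) {
    f <- integer(n)
    for (s in levels(strata)) {
      idx <- which(strata == s)
      f[idx[sample.int(length(idx))]] <-
        rep_len(sample.int(folds), length(idx))
    }
    f
  })
}

# no-intercept least squares; NA coefficients (rank deficiency) become 0
ols_coef <- function(X, y) {
  cf <- .lm.fit(X, y)$coefficients
  cf[is.na(cf)] <- 0
  cf
}

#' Cross-validated MSE of one linear equation
#'
#' No-intercept least squares on centered data; the MSE is the mean of the
#' squared out-of-fold residuals pooled over all folds and repeats. The
#' pooled squared-residual vector is returned so piecewise models can
#' assemble a composite MSE.
#'
#' @param cols parameter ids (possibly empty: the null equation predicts 0).
#' @param X samples x parameters matrix.
#' @param y response.
#' @param fold_assignments from [make_cv_folds()].
#' @return list: `mse`, `resid2` (pooled squared residuals, length
#'   `n * repeats`).
#' @export
cv_mse <- function(cols, X, y, fold_assignments) {
  n <- length(y)
  if (!length(cols)) {
    r2 <- rep(y^2, times = length(fold_assignments))
    return(list(mse = mean(r2), resid2 = r2))
  }
  Xs <- X[, cols, drop = FALSE]
  out <- numeric(0)
  for (f in fold_assignments) {
    res <- numeric(n)
    for (k in unique(f)) {
      test <- f == k
      cf <- ols_coef(Xs[!test, , drop = FALSE], y[!test])
      res[test] <- y[test] - Xs[test, , drop = FALSE] %*% cf
    }
    out <- c(out, res^2)
  }
  list(mse = mean(out), resid2 = out)
}

#' Bayesian information criterion from a model MSE
#'
#' `n * ln(MSE) + p * ln(n)`; no intercept terms are counted because all
#' data are centered and equations have no intercept.
#'
#' @param mse mean squared error.
#' @param n number of observations.
#' @param p number of parameters.
#' @return BIC value.
#' @export
bic <- function(mse, n, p) {
  n * log(max(mse, 1e-300)) + p * log(n)
}

#' Enumerate admissible parameter subsets
#'
#' All subsets of 1..`max_terms` candidates that contain no pair of
#' parameters with `|r| > corr_cap`.
#'
#' @param candidates parameter ids.
#' @param corr correlation matrix covering the candidates (dimnames = ids).
#' @param max_terms maximum subset size.
#' @param corr_cap collinearity ban threshold (strict >).
#' @return list of character vectors.
#' @export
enumerate_equations <- function(candidates, corr, max_terms = 3,
                                corr_cap = 0.85) {
  banned <- function(set) {
    if (length(set) < 2) return(FALSE)
    cc <- abs(corr[set, set])
    any(cc[upper.tri(cc)] > corr_cap)
  }
  out <- list()
  for (k in seq_len(min(max_terms, length(candidates)))) {
    for (set in utils::combn(candidates, k, simplify = FALSE)) {
      if (!banned(set)) out[[length(out) + 1]] <- set
    }
  }
  out
}

#' Resolve correlated candidate pairs before enumeration
#'
#' When two candidates are correlated above the cap, only the one whose best
#' single-parameter model has the lower cross-validated MSE is kept. Pairs
#' are resolved in descending |r| order; ties on MSE go to the
#' lexicographically smaller id.
#'
#' @param candidates parameter ids.
#' @param X samples x parameters matrix.
#' @param y response.
#' @param corr_cap ban threshold.
#' @param fold_assignments CV layout shared with the subsequent enumeration.
#' @return retained candidate ids (original order).
#' @export
prune_correlated_candidates <- function(candidates, X, y, corr_cap = 0.85,
                                        fold_assignments) {
  if (length(candidates) < 2) return(candidates)
  cc <- cor(X[, candidates, drop = FALSE])
  pairs <- which(upper.tri(cc) & abs(cc) > corr_cap, arr.ind = TRUE)
  if (!nrow(pairs)) return(candidates)
  pairs <- pairs[order(-abs(cc[pairs]), pairs[, 1], pairs[, 2]), ,
                 drop = FALSE]
  alive <- setNames(rep(TRUE, length(candidates)), candidates)
  mse1 <- sapply(candidates, function(id)
    cv_mse(id, X, y, fold_assignments)$mse)
  for (r in seq_len(nrow(pairs))) {
    a <- candidates[pairs[r, 1]]; b <- candidates[pairs[r, 2]]
    if (!alive[a] || !alive[b]) next
    drop <- if (mse1[a] < mse1[b]) b
            else if (mse1[b] < mse1[a]) a
            else max(a, b)
    alive[drop] <- FALSE
  }
  candidates[alive[candidates]]
}

#' Select the best linear equation for one segment
#'
#' Prunes correlated candidates, enumerates all admissible subsets of at most
#' `max_terms` parameters (plus the null equation predicting zero), scores
#' each by BIC on its cross-validated MSE, and refits the winner on the full
#' segment. Ties are broken toward fewer parameters, then lexicographic
#' parameter ids.
#'
#' @param X samples x parameters matrix for the segment.
#' @param y segment response (centered).
#' @param candidates candidate parameter ids.
#' @param cfg a [selection_config()].
#' @param strata optional stratification factor for the CV folds.
#' @param seed RNG seed for fold assignment.
#' @param fold_assignments optional precomputed folds (overrides `seed`).
#' @param penalty_n observation count used in the complexity penalty
#'   (`p * ln(penalty_n)`). Defaults to the segment length; piecewise model
#'   selection anchors it to the full design so that segment equations face
#'   the same per-parameter cost as the composite comparison they feed.
#' @return object of class `ed_equation`: `params`, `coef` (full-segment
#'   least squares), `mse`, `bic`, `resid2`, `r2`, `n`.
#' @export
select_equation <- function(X, y, candidates, cfg = selection_config(),
                            strata = NULL, seed = cfg$seed,
                            fold_assignments = NULL, penalty_n = NULL) {
  n <- length(y)
  penalty_n <- penalty_n %||% n
  if (is.null(fold_assignments))
    fold_assignments <- make_cv_folds(n, cfg$cv_folds, cfg$cv_repeats,
                                      strata, seed)
  candidates <- intersect(candidates, colnames(X))
  if (length(candidates)) {
    # parameters constant on this segment (e.g. the field indicator inside a
    # single-field segment) carry no information and break correlations
    keep <- vapply(candidates, function(id) sd(X[, id]) > 0, TRUE)
    candidates <- candidates[keep]
  }
  if (length(candidates) > 1)
    candidates <- prune_correlated_candidates(candidates, X, y, cfg$corr_cap,
                                              fold_assignments)
  subsets <- list(character(0))
  if (length(candidates)) {
    cc <- cor(X[, candidates, drop = FALSE])
    if (length(candidates) == 1) cc <- matrix(1, 1, 1,
                                              dimnames = list(candidates,
                                                              candidates))
    subsets <- c(subsets,
                 enumerate_equations(candidates, cc, cfg$max_terms,
                                     cfg$corr_cap))
  }
  best <- NULL
  for (set in subsets) {
    cvr <- cv_mse(set, X, y, fold_assignments)
    b <- n * log(max(cvr$mse, 1e-300)) + length(set) * log(penalty_n)
    key <- paste(sort(set), collapse = "+")
    if (is.null(best) || b < best$bic - 1e-12 ||
        (abs(b - best$bic) <= 1e-12 &&
         (length(set) < length(best$params) ||
          (length(set) == length(best$params) && key < best$key)))) {
      best <- list(params = set, bic = b, mse = cvr$mse, resid2 = cvr$resid2,
                   key = key)
    }
  }
  cf <- if (length(best$params))
    setNames(ols_coef(X[, best$params, drop = FALSE], y), best$params)
  else numeric(0)
  pred <- if (length(best$params))
    as.numeric(X[, best$params, drop = FALSE] %*% cf) else numeric(n)
  sst <- sum((y - mean(y))^2)
  structure(list(params = best$params, coef = cf, mse = best$mse,
                 bic = best$bic, resid2 = best$resid2,
                 r2 = if (sst > 0) 1 - sum((y - pred)^2) / sst else NA_real_,
                 n = n),
            class = "ed_equation")
}

#' Composite MSE of a piecewise model
#'
#' Mean of the concatenated squared cross-validation residuals of the
#' segment equations; equals the segment-size-weighted mean of the segment
#' MSEs.
#'
#' @param resid2_list list of pooled squared-residual vectors.
#' @return composite MSE.
#' @export
composite_mse <- function(resid2_list) {
  mean(unlist(resid2_list, use.names = FALSE))
}
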