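# segment and composition definitions for piecewise models

# segments for a design split by one or two binary context variables
piecewise_segments <- function(samples, split) {
  segs <- list(all = rep(TRUE, nrow(samples)))
  lv <- lapply(split, function(v) sort(unique(samples[[v]])))
  for (i in seq_along(split))
    for (l in lv[[i]]) segs[[l]] <- samples[[split[i]]] == l
  if (length(split) == 2) {
    for (a in lv[[1]]) for (b in lv[[2]])
      segs[[paste(a, b, sep = ".")]] <-
        samples[[split[1]]] == a & samples[[split[2]]] == b
  }
  segs
}

# the compositions compared by BIC: one piece; split by either variable;
# the three mixed three-piece models; the four-cell model
piecewise_compositions <- function(samples, split) {
  lv <- lapply(split, function(v) sort(unique(samples[[v]])))
  if (length(split) == 1) {
    return(list(one_piece = "all",
                by_var1 = lv[[1]]))
  }
  a1 <- lv[[1]][1]; a2 <- lv[[1]][2]
  b1 <- lv[[2]][1]; b2 <- lv[[2]][2]
  cell <- function(a, b) paste(a, b, sep = ".")
  list(
    one_piece = "all",
    by_var1 = c(a1, a2),
    by_var2 = c(b1, b2),
    mixed_var1_first = c(a1, cell(a2, b1), cell(a2, b2)),
    mixed_var1_second = c(a2, cell(a1, b1), cell(a1, b2)),
    mixed_var2_first = c(b1, cell(a1, b2), cell(a2, b2)),
    mixed_var2_second = c(b2, cell(a1, b1), cell(a2, b1)),
    four_cells = c(cell(a1, b1), cell(a1, b2), cell(a2, b1), cell(a2, b2)))
}

#' Select the best piecewise ED model for a cluster mean
#'
#' Runs three candidate-selection passes (global stability selection; a pool
#' of stability selections on the subsets of the first split variable; a pool
#' on the subsets of the second), fits the best equation for every segment
#' type from each pass's candidates, assembles the candidate compositions
#' (one piece; split by either context variable; the three-piece mixtures;
#' all four cells), scores each by BIC on the composite cross-validated MSE
#' with the parameter count summed over segment equations, and returns the
#' overall BIC argmin.
#'
#' @param X samples x parameters matrix (finalized ED values), rows aligned
#'   with `y`.
#' @param y cluster-mean response over the full design.
#' @param samples design metadata (one row per element of `y`) containing the
#'   split columns.
#' @param cfg global-pass [selection_config()].
#' @param cfg_subset subset-pass configuration
#'   ([subset_selection_config()]).
#' @param split one or two design columns defining the piecewise contexts
#'   (default season and field).
#' @param seed RNG seed; all subsampling and fold assignment derives from it.
#' @return object of class `selection_result`: `model` (composition name,
#'   per-segment `ed_equation`s, composite `mse`, `p`, `bic`, `r2`, the pass
#'   it came from), `passes` (per-pass candidates and per-composition BICs),
#'   `flags` (`null_model` when every pass yielded no stable candidates).
#' @export
select_piecewise <- function(X, y, samples, cfg = selection_config(),
                             cfg_subset = subset_selection_config(),
                             split = c("season", "field"),
                             seed = cfg$seed) {
  check_cols(samples, split, "design")
  n <- length(y)
  segs <- piecewise_segments(samples, split)
  comps <- piecewise_compositions(samples, split)
  cell_strata <- interaction(samples[split], drop = TRUE)
  missing_cells <- if (length(split) == 2) length(levels(cell_strata)) < 4
                   else length(levels(cell_strata)) < 2
  if (missing_cells) stop_ce("design is missing context cells")

  # candidate passes
  passes <- list(global = tryCatch(
    stability_select(X, y, cfg, seed = seed + 1L)$selected,
    error = function(e) character(0)))
  off <- 1L
  for (i in seq_along(split)) {
    pool <- character(0)
    for (l in sort(unique(samples[[split[i]]]))) {
      off <- off + 1L
      sel <- samples[[split[i]]] == l
      pool <- union(pool, tryCatch(
        stability_select(X[sel, , drop = FALSE], y[sel], cfg_subset,
                         seed = seed + off)$selected,
        error = function(e) character(0)))
    }
    passes[[paste0(split[i], "_pool")]] <- sort(pool)
  }

  # one CV layout per segment, shared by every pass and every candidate
  # subset, so BIC differences reflect the models rather than fold noise
  seg_folds <- lapply(seq_along(segs), function(si) {
    mask <- segs[[si]]
    make_cv_folds(sum(mask), cfg$cv_folds, cfg$cv_repeats,
                  strata = droplevels(cell_strata[mask]),
                  seed = seed + 100L + si)
  })

  pass_results <- list()
  for (pi in seq_along(passes)) {
    cand <- passes[[pi]]
    eqs <- list()
    for (si in seq_along(segs)) {
      mask <- segs[[si]]
      eqs[[names(segs)[si]]] <- select_equation(
        X[mask, , drop = FALSE], y[mask], cand, cfg,
        fold_assignments = seg_folds[[si]], penalty_n = n)
    }
    comp_tab <- lapply(comps, function(segnames) {
      mse <- composite_mse(lapply(eqs[segnames], `[[`, "resid2"))
      p <- sum(vapply(eqs[segnames], function(e) length(e$params), 0L))
      list(mse = mse, p = p, bic = bic(mse, n, p))
    })
    bics <- vapply(comp_tab, `[[`, 0, "bic")
    ps <- vapply(comp_tab, `[[`, 0L, "p")
    win <- order(bics, ps)[1]
    pass_results[[names(passes)[pi]]] <- list(
      candidates = cand,
      composition = names(comps)[win],
      segments = eqs[comps[[win]]],
      mse = comp_tab[[win]]$mse, p = comp_tab[[win]]$p,
      bic = comp_tab[[win]]$bic,
      all_bics = bics)
  }

  wb <- vapply(pass_results, `[[`, 0, "bic")
  winner <- pass_results[[order(wb)[1]]]
  winner$pass <- names(pass_results)[order(wb)[1]]

  # full-fit variance explained of the winning piecewise model
  pred <- numeric(n)
  for (segname in comps[[winner$composition]]) {
    mask <- segs[[segname]]
    eq <- winner$segments[[segname]]
    if (length(eq$params))
      pred[mask] <- as.numeric(X[mask, eq$params, drop = FALSE] %*% eq$coef)
  }
  sst <- sum((y - mean(y))^2)
  winner$r2 <- if (sst > 0) 1 - sum((y - pred)^2) / sst else NA_real_

  structure(list(
    model = winner[c("composition", "segments", "mse", "p", "bic", "r2",
                     "pass")],
    passes = lapply(pass_results, function(pr)
      pr[c("candidates", "composition", "bic", "all_bics")]),
    flags = list(null_model = all(!vapply(passes, length, 0L)))),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> composition: ", x$model$composition,
      " (pass ", x$model$pass, "), BIC ", round(x$model$bic, 2),
      ", R2 ", round(x$model$r2, 3), "\n", sep = "")
  for (nm in names(x$model$segments)) {
    eq <- x$model$segments[[nm]]
    cat("  ", nm, ": ",
        if (length(eq$params))
          paste(sprintf("%+.3f*%s", eq$coef, eq$params), collapse = " ")
        else "(null)", "\n", sep = "")
  }
  invisible(x)
}

#' Extract the union of selected parameters of a selection result
#' @param result a `selection_result`.
#' @return character vector of parameter ids.
#' @export
selected_params <- function(result) {
  sort(unique(unlist(lapply(result$model$segments, `[[`, "params"),
                     use.names = FALSE)))
}
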