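#' Expression matrix with sample metadata and stage tracking
#'
#' A genes x samples matrix plus aligned sample metadata, tagged with the
#' processing stage it has reached (`counts`, `normalized`, `log`,
#' `replicate-averaged`, `genotype-averaged`, `centered`, `scaled`).
#'
#' @param values numeric matrix, rows named by gene id.
#' @param samples data frame with one row per column of `values`.
#' @param stage processing-stage tag.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples, stage = "counts") {
  if (is.null(rownames(values))) stop_ce("gene ids (rownames) are required")
  if (anyDuplicated(rownames(values))) stop_ce("duplicate gene ids")
  if (nrow(samples) != ncol(values))
    stop_ce("metadata rows must match matrix columns")
  structure(list(values = values, samples = samples, stage = stage),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples; stage: ", x$stage, "\n", sep = "")
  invisible(x)
}

new_report <- function() {
  data.frame(stage = character(), removed = integer(), retained = integer(),
             stringsAsFactors = FALSE)
}

add_report <- function(report, stage, removed, retained) {
  rbind(report, data.frame(stage = stage, removed = removed,
                           retained = retained, stringsAsFactors = FALSE))
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factor: the median, over genes with a positive geometric
#' mean across samples, of the ratio of the gene's count in the sample to its
#' geometric mean. Genes with any zero count are excluded by the positive
#' geometric-mean condition.
#'
#' @param counts nonnegative genes x samples matrix.
#' @return numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) stop_ce("counts must be nonnegative")
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use))
    stop_ce("cannot normalize: no gene has positive counts in all samples")
  apply(counts[use, , drop = FALSE], 2,
        function(cnt) exp(median(log(cnt) - log_gm[use])))
}

#' Detection filter per genotype x season subset
#'
#' Removes genes undetected (count == 0) in more than `max_undetected`
#' samples of any genotype x season subset; "more than" is strict, so a gene
#' with exactly `max_undetected` zeros everywhere is retained.
#'
#' @param em `expression_matrix` at the counts or normalized stage.
#' @param max_undetected maximum tolerated zeros per subset.
#' @return list with `em` (filtered) and `report` (one-row filter report).
#' @export
detection_filter <- function(em, max_undetected = 40) {
  check_cols(em$samples, c("genotype", "season"), "sample metadata")
  subs <- interaction(em$samples$genotype, em$samples$season, drop = TRUE)
  zeros <- sapply(levels(subs), function(ss)
    rowSums(em$values[, subs == ss, drop = FALSE] == 0))
  keep <- apply(zeros <= max_undetected, 1, all)
  out <- expression_matrix(em$values[keep, , drop = FALSE], em$samples,
                           em$stage)
  list(em = out,
       report = add_report(new_report(), "detection", sum(!keep), sum(keep)))
}

#' Log transform: log2(x + 1)
#'
#' @param x nonnegative matrix or `expression_matrix`.
#' @return same shape, transformed; stage becomes `log`.
#' @export
log_transform <- function(x) {
  if (inherits(x, "expression_matrix")) {
    x$values <- log_transform(x$values)
    x$stage <- "log"
    return(x)
  }
  if (any(x < 0)) stop_ce("log transform requires nonnegative values")
  log2(x + 1)
}

# collapse columns by key columns, averaging values
collapse_columns <- function(em, keys, stage) {
  check_cols(em$samples, keys, "sample metadata")
  grp <- interaction(em$samples[keys], drop = TRUE, lex.order = TRUE)
  counts_per <- table(grp)
  vals <- em$values %*%
    sapply(levels(grp), function(g) (grp == g) / sum(grp == g))
  meta <- em$samples[!duplicated(grp), keys, drop = FALSE]
  meta <- meta[match(levels(grp), interaction(meta, drop = TRUE,
                                              lex.order = TRUE)), ,
               drop = FALSE]
  meta$sample_id <- do.call(paste, c(meta[keys], sep = "."))
  rownames(meta) <- NULL
  colnames(vals) <- meta$sample_id
  expression_matrix(vals, meta, stage)
}

#' Average biological replicates
#'
#' Collapses samples to one column per (season, field, genotype, timepoint).
#'
#' @param em `expression_matrix` (log stage).
#' @return `expression_matrix` at the replicate-averaged stage.
#' @export
average_replicates <- function(em) {
  collapse_columns(em, c("season", "field", "genotype", "timepoint"),
                   "replicate-averaged")
}

#' Average genotypes (treating them as biological replicates)
#'
#' Collapses to one column per (season, field, timepoint).
#'
#' @param em `expression_matrix`.
#' @return `expression_matrix` at the genotype-averaged stage.
#' @export
average_genotypes <- function(em) {
  collapse_columns(em, c("season", "field", "timepoint"), "genotype-averaged")
}

#' Coefficient-of-variation filter
#'
#' Removes genes whose CV (sample sd over mean, across all retained columns)
#' is below the threshold; such genes are considered stably expressed and
#' carry no usable dynamic signal.
#'
#' @param em `expression_matrix` (log stage, replicate-averaged).
#' @param threshold CV cutoff (strict `<`).
#' @return list with `em` and `report`.
#' @export
cv_filter <- function(em, threshold = 0.01) {
  m <- rowMeans(em$values)
  s <- apply(em$values, 1, sd)
  keep <- s / m >= threshold
  list(em = expression_matrix(em$values[keep, , drop = FALSE], em$samples,
                              em$stage),
       report = add_report(new_report(), "cv", sum(!keep), sum(keep)))
}

#' Mean-expression filter
#'
#' Removes genes with overall mean log expression below the threshold
#' (strict `<`); weakly expressed genes correlate poorly with cluster
#' centers.
#'
#' @param em `expression_matrix`.
#' @param threshold mean cutoff.
#' @return list with `em` and `report`.
#' @export
mean_filter <- function(em, threshold = 1) {
  keep <- rowMeans(em$values) >= threshold
  list(em = expression_matrix(em$values[keep, , drop = FALSE], em$samples,
                              em$stage),
       report = add_report(new_report(), "mean", sum(!keep), sum(keep)))
}

#' Center expression within metadata subsets
#'
#' Per gene, subtracts the mean within every subset defined by the key
#' columns (genotype x season by default), removing absolute level
#' differences between contexts that are not modeled.
#'
#' @param em `expression_matrix`.
#' @param keys metadata columns defining the subsets.
#' @return `expression_matrix` at the centered stage.
#' @export
center_subsets <- function(em, keys = c("genotype", "season")) {
  ck <- intersect(keys, names(em$samples))
  grp <- interaction(em$samples[ck], drop = TRUE)
  v <- em$values
  for (g in levels(grp)) {
    sel <- grp == g
    v[, sel] <- v[, sel, drop = FALSE] - rowMeans(v[, sel, drop = FALSE])
  }
  expression_matrix(v, em$samples, "centered")
}

#' Scale each gene to unit standard deviation over the whole profile
#'
#' @param em `expression_matrix` (centered stage).
#' @return `expression_matrix` at the scaled stage.
#' @export
scale_genes <- function(em) {
  s <- apply(em$values, 1, sd)
  if (any(s == 0))
    stop_ce("zero-variance gene(s) cannot be scaled: ",
            paste(head(rownames(em$values)[s == 0]), collapse = ", "))
  expression_matrix(em$values / s, em$samples, "scaled")
}

#' Full preprocessing pipeline
#'
#' counts -> size-factor normalization -> detection filter -> log2(x+1) ->
#' replicate averaging -> CV filter -> mean filter -> per-context centering
#' (-> optional genotype averaging) -> per-gene scaling.
#'
#' @param counts genes x samples counts matrix (rownames = gene ids).
#' @param samples sample metadata (sample_id, season, field, genotype,
#'   replicate, timepoint, time).
#' @param max_undetected detection-filter tolerance per genotype x season
#'   subset.
#' @param cv_threshold CV-filter cutoff.
#' @param mean_threshold mean-filter cutoff.
#' @param collapse_genotypes collapse genotypes after centering (the
#'   two-season analysis mode).
#' @param center_keys subsets for centering.
#' @return list with `profiles` (scaled `expression_matrix` for clustering),
#'   `profiles_by_genotype` (scaled matrix before genotype averaging, for
#'   genotype-correlation metrics; `NULL` unless genotypes were averaged),
#'   `report` (filter accounting), `size_factors`.
#' @export
preprocess_pipeline <- function(counts, samples, max_undetected = 40,
                                cv_threshold = 0.01, mean_threshold = 1,
                                collapse_genotypes = TRUE,
                                center_keys = c("genotype", "season")) {
  report <- new_report()
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  em <- expression_matrix(norm, samples, "normalized")
  det <- detection_filter(em, max_undetected)
  report <- rbind(report, det$report)
  em <- log_transform(det$em)
  em <- average_replicates(em)
  cvf <- cv_filter(em, cv_threshold)
  report <- rbind(report, cvf$report)
  mf <- mean_filter(cvf$em, mean_threshold)
  report <- rbind(report, mf$report)
  em <- center_subsets(mf$em, center_keys)
  by_geno <- NULL
  if (collapse_genotypes) {
    by_geno <- scale_genes(em)
    em <- average_genotypes(em)
    em$stage <- "centered"
  }
  profiles <- scale_genes(em)
  list(profiles = profiles, profiles_by_genotype = by_geno,
       report = report, size_factors = sf)
}
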