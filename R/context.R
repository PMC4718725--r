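#' Genotype correlation of a cluster mean
#'
#' Pearson correlation between the two genotype-specific sub-profiles of a
#' cluster mean, aligned by (season, field, timepoint); a replicability
#' measure for the modeled ED effects.
#'
#' @param values cluster-mean vector over genotype-resolved columns.
#' @param samples metadata for those columns (`genotype`, `season`, `field`,
#'   `timepoint`).
#' @return Pearson r.
#' @export
genotype_correlation <- function(values, samples) {
  g <- sort(unique(samples$genotype))
  if (length(g) != 2) stop_ce("exactly two genotypes are required")
  key <- paste(samples$season, samples$field, samples$timepoint, sep = "|")
  i1 <- which(samples$genotype == g[1])
  i2 <- which(samples$genotype == g[2])
  i2 <- i2[match(key[i1], key[i2])]
  if (anyNA(i2)) stop_ce("genotype sub-profiles are not aligned")
  cor(values[i1], values[i2])
}

#' Field correlation of a cluster mean within a season
#'
#' Pearson correlation between the irrigated and rainfed timepoint profiles
#' of the (genotype-averaged) cluster mean within one season.
#'
#' @param values cluster-mean vector over the analysis columns.
#' @param samples metadata (`season`, `field`, `timepoint`).
#' @param season season label.
#' @return Pearson r.
#' @export
field_correlation <- function(values, samples, season) {
  sel <- samples$season == season
  v <- values[sel]; s <- samples[sel, ]
  ir <- v[s$field == "irrigated"][order(s$timepoint[s$field == "irrigated"])]
  ra <- v[s$field == "rainfed"][order(s$timepoint[s$field == "rainfed"])]
  if (length(ir) != length(ra)) stop_ce("unbalanced field profiles")
  cor(ir, ra)
}

#' Field mean difference of a cluster mean within a season
#'
#' Mean over rainfed columns minus mean over irrigated columns.
#'
#' @inheritParams field_correlation
#' @return numeric difference.
#' @export
field_difference <- function(values, samples, season) {
  sel <- samples$season == season
  mean(values[sel & samples$field == "rainfed"]) -
    mean(values[sel & samples$field == "irrigated"])
}

#' Classify a cluster's field response into groups 1-4
#'
#' Group 1: field correlation at or above the cutoff in both seasons; group
#' 2: high in the wet season only; group 3: high in the dry season only;
#' group 4: low in both. A correlation exactly at the cutoff counts as high.
#'
#' @param field_r_dry,field_r_wet per-season field correlations.
#' @param cutoff high/low boundary.
#' @return integer group in 1..4.
#' @export
classify_group <- function(field_r_dry, field_r_wet, cutoff = 0.8) {
  hd <- field_r_dry >= cutoff
  hw <- field_r_wet >= cutoff
  if (hd && hw) 1L else if (hw) 2L else if (hd) 3L else 4L
}

#' Context summary for every cluster
#'
#' Per cluster: genotype correlation, per-season field correlations and mean
#' differences, group classification and the high-replicability flag.
#'
#' @param means_by_genotype clusters x columns matrix of cluster means on the
#'   genotype-resolved design.
#' @param samples_by_genotype metadata for those columns.
#' @param means clusters x columns matrix on the genotype-averaged design.
#' @param samples metadata for those columns.
#' @param genotype_r_cutoff high-replicability threshold on genotype r.
#' @param field_r_cutoff group-classification threshold on field r.
#' @param seasons the (dry, wet) season labels, in that order.
#' @return data frame of class `cluster_context_summary`.
#' @export
context_summary <- function(means_by_genotype, samples_by_genotype,
                            means, samples, genotype_r_cutoff = 0.9,
                            field_r_cutoff = 0.8,
                            seasons = c("dry", "wet")) {
  rows <- lapply(rownames(means), function(cl) {
    gr <- genotype_correlation(means_by_genotype[cl, ], samples_by_genotype)
    frd <- field_correlation(means[cl, ], samples, seasons[1])
    frw <- field_correlation(means[cl, ], samples, seasons[2])
    data.frame(cluster = cl, genotype_r = gr,
               field_r_dry = frd, field_r_wet = frw,
               field_diff_dry = field_difference(means[cl, ], samples,
                                                 seasons[1]),
               field_diff_wet = field_difference(means[cl, ], samples,
                                                 seasons[2]),
               group = classify_group(frd, frw, field_r_cutoff),
               high_replicability = gr > genotype_r_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_context_summary", "data.frame")
  out
}
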