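#' Ground-truth cluster specification
#'
#' Describes one simulated co-expression cluster: its size and the
#' ground-truth linear ED equation per segment of the design. Segment names
#' follow the piecewise-model segmentations: `all`, `dry`, `wet`,
#' `irrigated`, `rainfed`, or season.field cells such as `dry.rainfed`. The
#' named segments must partition the design columns.
#'
#' @param id cluster identifier.
#' @param n_genes number of member genes (>= 1).
#' @param equations named list mapping segment name to
#'   `list(params = <ids>, coefs = <numeric>)`, at most 3 terms per segment.
#' @param snr cluster-level signal-to-noise ratio: variance of the
#'   ground-truth signal over the variance of a cluster-wide noise profile
#'   shared by all member genes. This noise does not average out across genes,
#'   so it sets the irreducible MSE of the cluster-mean regression.
#' @param gene_snr per-gene signal-to-noise ratio governing how tightly member
#'   genes co-express (and hence cluster recovery); this noise averages out in
#'   the cluster mean.
#' @param noise_sd per-gene, per-sample expression noise sd (log2 scale);
#'   overrides `gene_snr`.
#' @param cluster_noise_sd cluster-wide noise sd; overrides `snr`.
#' @param loading_sd spread of per-gene loadings around 1.
#' @param genotype_sd sd of the genotype-specific profile distortion shared by
#'   the cluster's genes.
#' @return object of class `cluster_spec`.
#' @export
cluster_spec <- function(id, n_genes, equations, snr = 4, gene_snr = 4,
                         noise_sd = NULL, cluster_noise_sd = NULL,
                         loading_sd = 0.1, genotype_sd = 0) {
  if (n_genes < 1) stop_ce("cluster ", id, ": gene count must be >= 1")
  for (seg in names(equations)) {
    eq <- equations[[seg]]
    if (length(eq$params) != length(eq$coefs))
      stop_ce("cluster ", id, ", segment ", seg, ": params/coefs mismatch")
    if (length(eq$params) > 3)
      stop_ce("cluster ", id, ", segment ", seg, ": more than 3 terms")
    if (any(!is.finite(eq$coefs)))
      stop_ce("cluster ", id, ", segment ", seg, ": non-finite coefficient")
  }
  structure(list(id = id, n_genes = as.integer(n_genes),
                 equations = equations, snr = snr, gene_snr = gene_snr,
                 noise_sd = noise_sd, cluster_noise_sd = cluster_noise_sd,
                 loading_sd = loading_sd, genotype_sd = genotype_sd),
            class = "cluster_spec")
}

#' Ground truth for a simulated expression dataset
#'
#' @param clusters list of [cluster_spec()]s.
#' @param n_low_cv number of spiked-in stable (low-CV) genes.
#' @param n_low_mean number of spiked-in low-abundance genes.
#' @param n_undetected number of spiked-in mostly-undetected genes.
#' @param seed RNG seed for the noise realization.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(clusters, n_low_cv = 20L, n_low_mean = 20L,
                         n_undetected = 10L, seed = 1L) {
  ids <- vapply(clusters, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_ce("duplicate cluster ids")
  structure(list(clusters = clusters, n_low_cv = as.integer(n_low_cv),
                 n_low_mean = as.integer(n_low_mean),
                 n_undetected = as.integer(n_undetected),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# logical mask of design columns belonging to a named segment
segment_mask <- function(samples, name) {
  if (name == "all") return(rep(TRUE, nrow(samples)))
  if (name %in% unique(samples$season)) return(samples$season == name)
  if ("field" %in% names(samples) && name %in% unique(samples$field))
    return(samples$field == name)
  if ("genotype" %in% names(samples) && name %in% unique(samples$genotype))
    return(samples$genotype == name)
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2) {
    m1 <- segment_mask(samples, parts[1])
    m2 <- segment_mask(samples, parts[2])
    return(m1 & m2)
  }
  stop_ce("unknown segment name: ", name)
}

# ground-truth signal per ED design column for one cluster spec
truth_signal <- function(spec, ed) {
  n <- ncol(ed$values)
  signal <- numeric(n)
  covered <- logical(n)
  for (seg in names(spec$equations)) {
    eq <- spec$equations[[seg]]
    eq$params <- resolve_param_ids(ed, eq$params)
    if (anyNA(eq$params))
      stop_ce("cluster ", spec$id, ": unknown parameter id(s): ",
              paste(spec$equations[[seg]]$params[is.na(eq$params)],
                    collapse = ", "))
    mask <- segment_mask(ed$samples, seg)
    if (any(covered & mask))
      stop_ce("cluster ", spec$id, ": segments overlap")
    covered <- covered | mask
    if (length(eq$params))
      signal[mask] <- as.numeric(
        crossprod(ed$values[eq$params, mask, drop = FALSE], eq$coefs))
  }
  if (!all(covered))
    stop_ce("cluster ", spec$id, ": segments do not cover the design")
  signal
}

#' Simulate a cluster-structured counts matrix with known ground truth
#'
#' Gene expression is generated on the log2 scale as
#' `base + loading * signal(cell) + genotype effect + noise`, where the signal
#' of each cluster is its ground-truth linear combination of finalized ED
#' parameters on the analysis design. In `counts` mode the log2 signal is
#' exponentiated to an abundance, multiplied by a per-sample depth factor and
#' Poisson-sampled; `continuous` mode returns the abundances themselves so
#' that the downstream pipeline is exactly invertible. Spiked-in stable
#' (low-CV), low-abundance and mostly-undetected genes exercise the
#' preprocessing filters.
#'
#' @param ed finalized `ed_matrix` on the analysis design (one column per
#'   season/field/timepoint cell).
#' @param truth a [ground_truth()].
#' @param schedule a `sampling_schedule`; its rows map to ED design columns by
#'   (season, field, timepoint).
#' @param mode `"counts"` (Poisson) or `"continuous"`.
#' @param depth per-sample depth multipliers; default drawn from
#'   `runif(0.7, 1.4)`.
#' @param base_range range of per-gene baseline log2 expression.
#' @return list of class `sim_expression`: `counts` (genes x samples matrix),
#'   `genes` (gene -> cluster table), `signals` (clusters x design cells),
#'   `noise_sd` (per cluster), `depth`, `mode`.
#' @export
simulate_expression <- function(ed, truth, schedule,
                                mode = c("counts", "continuous"),
                                depth = NULL, base_range = c(4, 9)) {
  mode <- match.arg(mode)
  set.seed(truth$seed)
  key <- function(df) paste(df$season, df$field, df$timepoint, sep = "|")
  cell_of <- match(key(schedule), key(ed$samples))
  if (anyNA(cell_of))
    stop_ce("schedule contains samples outside the ED design")
  ns <- nrow(schedule)
  if (is.null(depth)) depth <- runif(ns, 0.7, 1.4)
  sigs <- list(); rows <- list(); gene_tab <- list(); noise_sds <- c()
  gi <- 0
  for (spec in truth$clusters) {
    signal <- truth_signal(spec, ed)
    noise_sd <- spec$noise_sd %||% (sd(signal) / sqrt(spec$gene_snr))
    cl_noise_sd <- spec$cluster_noise_sd %||% (sd(signal) / sqrt(spec$snr))
    noise_sds[spec$id] <- noise_sd
    sigs[[spec$id]] <- signal
    cl_noise <- rnorm(ncol(ed$values), 0, cl_noise_sd)
    geno_levels <- unique(schedule$genotype)
    geno_eff <- matrix(rnorm(length(geno_levels) * ncol(ed$values),
                             0, spec$genotype_sd),
                       nrow = length(geno_levels),
                       dimnames = list(geno_levels, NULL))
    s_sample <- signal[cell_of] + cl_noise[cell_of] +
      geno_eff[cbind(match(schedule$genotype, geno_levels), cell_of)]
    for (g in seq_len(spec$n_genes)) {
      gi <- gi + 1
      base <- runif(1, base_range[1], base_range[2])
      loading <- rnorm(1, 1, spec$loading_sd)
      x <- base + loading * s_sample + rnorm(ns, 0, noise_sd)
      rows[[gi]] <- pmax(x, 0)
      gene_tab[[gi]] <- spec$id
    }
  }
  # filter fodder: stable, low-abundance, mostly-undetected genes
  for (g in seq_len(truth$n_low_cv)) {
    gi <- gi + 1
    rows[[gi]] <- rep(12, ns) + rnorm(ns, 0, 1e-5)
    gene_tab[[gi]] <- "low_cv"
  }
  for (g in seq_len(truth$n_low_mean)) {
    gi <- gi + 1
    rows[[gi]] <- pmax(runif(1, 0.3, 0.9) + rnorm(ns, 0, 0.05), 0)
    gene_tab[[gi]] <- "low_mean"
  }
  for (g in seq_len(truth$n_undetected)) {
    gi <- gi + 1
    x <- numeric(ns)
    subs <- interaction(schedule$genotype, schedule$season, drop = TRUE)
    for (ss in levels(subs)) {
      idx <- which(subs == ss)
      on <- sample(idx, min(10, length(idx)))
      x[on] <- runif(1, 4, 6)
    }
    rows[[gi]] <- x
    gene_tab[[gi]] <- "undetected"
  }
  xlog <- do.call(rbind, rows)
  abundance <- sweep(2^xlog - 1, 2, depth, `*`)
  counts <- if (mode == "counts") {
    matrix(rpois(length(abundance), abundance), nrow = nrow(abundance))
  } else abundance
  gene_ids <- sprintf("g%04d", seq_len(gi))
  dimnames(counts) <- list(gene_ids, schedule$sample_id)
  structure(list(counts = counts,
                 genes = data.frame(gene_id = gene_ids,
                                    cluster = unlist(gene_tab),
                                    stringsAsFactors = FALSE),
                 signals = do.call(rbind, sigs),
                 noise_sd = noise_sds, depth = depth, mode = mode),
            class = "sim_expression")
}

#' Write ground truth (gene memberships and signals) as JSON
#' @param sim a `sim_expression`.
#' @param path output file path.
#' @export
write_ground_truth_json <- function(sim, path) {
  jsonlite::write_json(list(genes = sim$genes,
                            noise_sd = as.list(sim$noise_sd),
                            mode = sim$mode),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
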