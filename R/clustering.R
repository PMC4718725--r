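#' Correlation distance between gene profiles
#'
#' `1 - r` with `r` the Pearson correlation between row profiles; symmetric,
#' zero diagonal, entries in \[0, 2\].
#'
#' @param profiles genes x samples matrix (or `expression_matrix`).
#' @return symmetric distance matrix.
#' @export
correlation_distance <- function(profiles) {
  if (inherits(profiles, "expression_matrix")) profiles <- profiles$values
  if (ncol(profiles) < 2) stop_ce("profiles need at least 2 columns")
  s <- apply(profiles, 1, sd)
  if (any(s == 0))
    stop_ce("zero-variance profile(s): ",
            paste(head(rownames(profiles)[s == 0]), collapse = ", "))
  d <- 1 - cor(t(profiles))
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Partitioning around medoids on a precomputed distance matrix
#'
#' Classical BUILD + SWAP. Deterministic: assignment ties go to the medoid
#' with the lowest index; among improving swaps the largest cost reduction
#' wins, ties broken by lowest medoid index then lowest candidate index.
#' Returned clusters are relabeled by decreasing size (label 1 = biggest),
#' size ties broken by lowest medoid index.
#'
#' @param d symmetric distance matrix.
#' @param k number of clusters, `2 <= k <= n` (k = n puts every point in its
#'   own cluster at cost 0).
#' @return list of class `gene_clustering`: `k`, `labels` (named by row),
#'   `medoids` (ids), `sizes`, `objective` (total distance to medoids).
#' @export
pam_cluster <- function(d, k) {
  n <- nrow(d)
  if (k < 1 || k > n) stop_ce("k must be between 1 and n")
  ids <- rownames(d) %||% as.character(seq_len(n))
  # BUILD
  med <- which.min(colSums(d))
  dn <- d[, med]
  while (length(med) < k) {
    gain <- vapply(seq_len(n), function(h) {
      if (h %in% med) return(-Inf)
      sum(pmax(dn - d[, h], 0))
    }, 0)
    med <- c(med, which.max(gain))
    dn <- pmin(dn, d[, med[length(med)]])
  }
  # SWAP
  repeat {
    dm <- d[, med, drop = FALSE]
    if (k == 1) {
      nearest <- rep(1L, n)
      dn <- dm[, 1]
      ds <- rep(Inf, n)
    } else {
      ord <- apply(dm, 1, order)        # k x n: medoid slots by distance
      nearest <- ord[1, ]
      dn <- dm[cbind(seq_len(n), nearest)]
      ds <- dm[cbind(seq_len(n), ord[2, ])]
    }
    best <- list(delta = -1e-12, m = NA, h = NA)
    nonmed <- setdiff(seq_len(n), med)
    for (h in nonmed) {
      Dh <- d[, h]
      a <- pmin(0, Dh - dn)             # points whose nearest is not m
      b <- pmin(ds, Dh) - dn            # points whose nearest is m
      Ta <- sum(a)
      Sa <- vapply(seq_len(k), function(m) sum(a[nearest == m]), 0)
      Sb <- vapply(seq_len(k), function(m) sum(b[nearest == m]), 0)
      delta <- (Ta - Sa) + Sb
      m_best <- which.min(delta)
      if (delta[m_best] < best$delta - 1e-12 ||
          (abs(delta[m_best] - best$delta) <= 1e-12 && !is.na(best$m) &&
           (med[m_best] < med[best$m] ||
            (med[m_best] == med[best$m] && h < best$h)))) {
        best <- list(delta = delta[m_best], m = m_best, h = h)
      }
    }
    if (is.na(best$m) || best$delta >= -1e-12) break
    med[best$m] <- best$h
  }
  med <- med[order(med)]
  dm <- d[, med, drop = FALSE]
  nearest <- apply(dm, 1, which.min)
  sizes <- tabulate(nearest, k)
  # order clusters by decreasing size, ties by medoid index
  ord <- order(-sizes, med)
  relabel <- match(seq_len(k), ord)
  labels <- setNames(relabel[nearest], ids)
  structure(list(k = k, labels = labels, medoids = ids[med[ord]],
                 sizes = sizes[ord],
                 objective = sum(dm[cbind(seq_len(n), nearest)])),
            class = "gene_clustering")
}

#' @export
print.gene_clustering <- function(x, ...) {
  cat("<gene_clustering> k = ", x$k, "; sizes: ",
      paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Choose the number of clusters by the representativeness rule
#'
#' Scans k downward from `k_max` and returns the highest k for which genes in
#' "non-representative" small clusters (size below `small_frac` of all genes)
#' make up no more than `small_mass` of all genes; both bounds are inclusive.
#' If no k in \[2, k_max\] satisfies the constraint, returns k = 2 with a
#' warning flag.
#'
#' @param d distance matrix (see [correlation_distance()]).
#' @param k_max largest k to consider.
#' @param small_frac size fraction below which a cluster is small (strict <).
#' @param small_mass maximum tolerated fraction of genes in small clusters.
#' @return list: `k`, `clustering` (the PAM solution at the chosen k),
#'   `admissible` (FALSE when the fallback k = 2 was forced).
#' @export
select_k <- function(d, k_max = 80, small_frac = 0.01, small_mass = 0.05) {
  n <- nrow(d)
  if (k_max >= n) stop_ce("k_max must be below the number of genes")
  for (k in seq(min(k_max, n - 1), 2)) {
    cl <- pam_cluster(d, k)
    if (small_cluster_mass(cl$sizes, n, small_frac) <= small_mass)
      return(list(k = k, clustering = cl, admissible = TRUE))
  }
  warning("no k in [2, k_max] satisfies the small-cluster constraint; using k = 2")
  list(k = 2, clustering = pam_cluster(d, 2), admissible = FALSE)
}

small_cluster_mass <- function(sizes, n, small_frac = 0.01) {
  sum(sizes[sizes < small_frac * n]) / n
}

#' Cluster means
#'
#' Column-wise mean of the (scaled) profiles of each cluster's member genes;
#' the regression target of the ED models.
#'
#' @param clustering a `gene_clustering`.
#' @param profiles genes x samples matrix (or `expression_matrix`) whose rows
#'   match the clustering's labels by name.
#' @return clusters x samples matrix, row `i` for cluster label `i`.
#' @export
cluster_means <- function(clustering, profiles) {
  if (inherits(profiles, "expression_matrix")) profiles <- profiles$values
  lab <- clustering$labels[rownames(profiles)]
  if (anyNA(lab)) stop_ce("profiles contain genes absent from the clustering")
  out <- rowsum(profiles, lab) / as.vector(table(lab))
  rownames(out) <- paste0("cluster", rownames(out))
  out
}
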