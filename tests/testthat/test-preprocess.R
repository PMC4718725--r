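test_that("median-of-ratios size factors match hand-derived and oracle values", {
  counts <- matrix(c(2, 8, 4, 16), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(size_factors(counts)), c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-6)
  # identical samples -> unit factors
  same <- matrix(rpois(40, 20), nrow = 10)
  same[, 2] <- same[, 1]
  rownames(same) <- paste0("g", 1:10)
  expect_equal(unname(size_factors(same[, 1:2])), c(1, 1))
  # zero-geomean genes are excluded by definition
  with_zero <- rbind(counts, gz = c(0, 100))
  expect_equal(size_factors(with_zero), size_factors(counts))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2,
                                   dimnames = list(c("a", "b"), NULL))),
               "cannot normalize")
  # independent oracle
  set.seed(1)
  m <- matrix(rpois(600, 50), nrow = 30)
  rownames(m) <- paste0("g", 1:30)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("detection filter applies the strict more-than rule per subset", {
  set.seed(2)
  samples <- expand.grid(replicate = 1:2, timepoint = 1:15,
                         field = c("irrigated", "rainfed"),
                         genotype = c("g1", "g2"),
                         season = c("dry", "wet"),
                         stringsAsFactors = FALSE)
  n <- nrow(samples)                      # 240; 60 per genotype x season
  sub1 <- which(samples$genotype == "g1" & samples$season == "dry")
  m <- matrix(10, 3, n, dimnames = list(c("gone", "boundary", "kept"), NULL))
  m["gone", sub1[1:41]] <- 0              # 41 zeros in one subset -> removed
  subs <- interaction(samples$genotype, samples$season)
  for (ss in levels(subs))                # exactly 40 zeros everywhere -> kept
    m["boundary", which(subs == ss)[1:40]] <- 0
  res <- detection_filter(expression_matrix(m, samples), max_undetected = 40)
  expect_setequal(rownames(res$em$values), c("boundary", "kept"))
  expect_equal(res$report$removed, 1)
  expect_equal(res$report$retained, 2)
})

test_that("log transform and replicate averaging follow their closed forms", {
  expect_equal(log_transform(c(0, 1, 3)), c(0, 1, 2))
  expect_error(log_transform(-1), "nonnegative")

  samples <- expand.grid(replicate = 1:2, timepoint = 1:15,
                         field = c("irrigated", "rainfed"),
                         genotype = c("g1", "g2"),
                         season = c("dry", "wet"),
                         stringsAsFactors = FALSE)
  m <- matrix(0, 1, 240, dimnames = list("g", NULL))
  m[1, samples$replicate == 1] <- 1
  m[1, samples$replicate == 2] <- 3
  em <- average_replicates(expression_matrix(m, samples, "log"))
  expect_equal(ncol(em$values), 120)
  expect_true(all(em$values == 2))
  em2 <- average_genotypes(em)
  expect_equal(ncol(em2$values), 60)
})

test_that("CV and mean filters use strict thresholds and commute", {
  samples <- data.frame(sample_id = paste0("s", 1:10))
  vals <- rbind(const = rep(5, 10),
                low = 2 + c(rep(0.004, 5), rep(-0.004, 5)),
                kept = 2 + seq(-0.5, 0.5, length.out = 10),
                weak = rep(0.99, 10) + c(rep(0.3, 5), rep(-0.3, 5)))
  em <- expression_matrix(vals, samples, "log")
  cvf <- cv_filter(em, 0.01)
  expect_setequal(rownames(cvf$em$values), c("kept", "weak"))
  mf <- mean_filter(cvf$em, 1)
  expect_setequal(rownames(mf$em$values), "kept")
  # order invariance of the retained set
  mf_first <- mean_filter(em, 1)
  cv_second <- cv_filter(mf_first$em, 0.01)
  both_a <- rownames(cv_second$em$values)
  both_b <- rownames(mf$em$values)
  expect_setequal(intersect(both_a, both_b), both_a)
  # filter accounting
  expect_equal(cvf$report$removed + cvf$report$retained, nrow(vals))
})

test_that("subset centering zeroes context means and preserves contrasts", {
  samples <- data.frame(genotype = rep(c("g1", "g2"), each = 4),
                        season = "dry", sample_id = paste0("s", 1:8))
  vals <- matrix(c(5, 5, 5, 5, 1, 2, 3, 4), 1)
  rownames(vals) <- "g"
  em <- center_subsets(expression_matrix(vals, samples, "log"),
                       c("genotype", "season"))
  expect_equal(unname(em$values[1, 1:4]), rep(0, 4))
  expect_equal(mean(em$values[1, 5:8]), 0, tolerance = 1e-12)
  expect_equal(diff(em$values[1, 5:8]), diff(vals[1, 5:8]))
  # idempotent
  em2 <- center_subsets(em, c("genotype", "season"))
  expect_equal(em$values, em2$values)
})

test_that("gene scaling gives unit sd and is idempotent; zero variance errors", {
  samples <- data.frame(sample_id = paste0("s", 1:6))
  vals <- matrix(rnorm(12), 2, dimnames = list(c("a", "b"), NULL))
  vals <- vals - rowMeans(vals)
  em <- scale_genes(expression_matrix(vals, samples, "centered"))
  expect_equal(unname(apply(em$values, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(scale_genes(em)$values, em$values, tolerance = 1e-12)
  bad <- expression_matrix(rbind(vals, z = rep(0, 6)), samples, "centered")
  expect_error(scale_genes(bad), "zero-variance")
})

test_that("size-factor normalization recovers known depth multipliers", {
  set.seed(4)
  depth <- runif(12, 0.5, 2)
  abundance <- matrix(rexp(50, 1 / 100), 50, 1) %*% t(rep(1, 12))
  counts <- sweep(abundance, 2, depth, `*`)
  rownames(counts) <- paste0("g", 1:50)
  sf <- size_factors(counts)
  ratio <- sf / depth
  expect_lt(max(abs(ratio / ratio[1] - 1)), 1e-6)
})
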