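test_that("PCA reduction centers, imputes, and reports variance fractions", {
  g <- cbind(c(0L, 1L, 2L, 1L), rep(1L, 4), rep(2L, 4))
  ds <- make_two_sample_ds(g[1:2, ], g[3:4, ])
  pc <- pca_reduce(ds, 1)
  expect_equal(pc$cum_var_fraction, 1)
  expect_error(pca_reduce(ds, 4), "n_axes")

  set.seed(2)
  g2 <- matrix(rbinom(50 * 200, 2, 0.4), 50, 200)
  ds2 <- make_two_sample_ds(g2[1:25, ], g2[26:50, ])
  pc2 <- pca_reduce(ds2, 10)
  expect_equal(crossprod(pc2$rotation), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  # independent eigendecomposition oracle for the variance fractions
  xc <- scale(g2, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pc2$var_fraction, (ev / sum(ev))[1:10], tolerance = 1e-8)
})

test_that("BIC scan separates two well-separated blobs and handles W = 0", {
  hits <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    x <- rbind(matrix(rnorm(30 * 30, 0), ncol = 30),
               matrix(rnorm(30 * 30, 10), ncol = 30))
    scan <- kmeans_bic_scan(x, 1:6, n_starts = 10, seed = r)
    hits <- hits + (scan$best_k == 2)
  }
  expect_gte(hits, 19)

  set.seed(5)
  x <- matrix(rnorm(12), 6, 2)
  scan <- kmeans_bic_scan(x, 1:6, seed = 1)
  expect_equal(scan$table$BIC[6], -Inf)   # K = n, W = 0 sentinel
  expect_true(scan$best_k < 6)
})

test_that("two groups yield one DF carrying all discriminating power", {
  set.seed(8)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 3), ncol = 2))
  model <- fit_dapc(x, rep(c("a", "b"), each = 20))
  expect_equal(model$n_dfs, 1)
  expect_equal(model$power_fraction, 1)
})

test_that("planted discriminating-power fractions are recovered", {
  set.seed(10)
  shares <- c(0.62, 0.27, 0.11)
  n_per <- 100
  d <- 5
  # Helmert-contrast group means: columns orthogonal to each other and to
  # the intercept, scaled so the between-scatter eigenvalues carry the
  # planted shares; tight within-group noise
  h <- stats::contr.helmert(4)
  m <- cbind(h %*% diag(sqrt(shares / colSums(h^2))), matrix(0, 4, d - 3))
  x <- m[rep(1:4, each = n_per), ] + matrix(rnorm(4 * n_per * d, 0, 0.02),
                                            ncol = d)
  labels <- rep(1:4, each = n_per)
  model <- fit_dapc(x, labels)
  expect_true(all(abs(model$power_fraction - shares) < 0.05))
  # invariance to group relabeling
  relab <- c("d", "c", "b", "a")[labels]
  model2 <- fit_dapc(x, relab)
  expect_equal(model2$power_fraction, model$power_fraction,
               tolerance = 1e-6)
})

test_that("posterior membership is a proper, sharp classifier at centroids", {
  set.seed(12)
  x <- rbind(matrix(rnorm(100, 0, 0.5), ncol = 2),
             matrix(rnorm(100, 20, 0.5), ncol = 2))
  labels <- rep(c("g1", "g2"), each = 50)
  model <- fit_dapc(x, labels)
  memb <- posterior_membership(model, x)
  expect_equal(unname(rowSums(memb$prob)), rep(1, 100), tolerance = 1e-9)
  at_centroid <- matrix(colMeans(x[1:50, ]), 1)
  m0 <- posterior_membership(model, at_centroid)
  expect_gt(m0$prob[1, "g1"], 0.999)
})

test_that("a sample exactly at the purity threshold is 'mixed' (strict >)", {
  set.seed(14)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 4), ncol = 2))
  labels <- rep(c("g1", "g2"), each = 30)
  model <- fit_dapc(x, labels)
  codes <- rep(c("S1", "S2"), each = 30)
  memb <- posterior_membership(model, x, sample_codes = codes)
  max_mean <- max(memb$sample_means["S1", ])
  at_thresh <- posterior_membership(model, x, sample_codes = codes,
                                    purity_threshold = max_mean)
  expect_equal(unname(at_thresh$purity["S1"]), "mixed")
  below <- posterior_membership(model, x, sample_codes = codes,
                                purity_threshold = max_mean - 1e-9)
  expect_equal(unname(below$purity["S1"]), "pure")
})

test_that("hold-out cross-validation recovers strongly separated clusters", {
  cfg <- sim_config(
    n_clusters = 2, background_fst = 0.10, n_loci = 200,
    outlier_blocks = list(),
    missing_rates = c(historical = 0.02, contemporary = 0.02),
    genotype_error = 0, seed = 55)
  sim <- simulate_dataset(cfg)
  cv <- holdout_crossvalidate(sim$dataset, fraction = 0.5, n_pcs = 20,
                              k = 2, seed = 99)
  expect_gt(cv$agreement, 0.95)
  expect_gt(cv$high_confidence, 0.5)
  expect_equal(cv$n_holdout, length(cv$holdout_assign))
})

test_that("permuted group labels cannot produce confident assignments", {
  set.seed(16)
  g <- matrix(rbinom(80 * 300, 2, 0.5), 80, 300)
  ds <- make_two_sample_ds(g[1:40, ], g[41:80, ])
  pca <- pca_reduce(ds, 8)
  labels <- sample(rep(1:4, each = 20))
  model <- fit_dapc(pca$scores, labels)
  memb <- posterior_membership(model, pca$scores)
  expect_lte(mean(apply(memb$prob, 1, max)), 0.5)
})

test_that("a-score rewards real structure and penalizes overfitting", {
  cfg <- sim_config(
    n_clusters = 3, background_fst = 0.15, n_loci = 150,
    outlier_blocks = list(),
    samples = data.frame(sample_code = c("P1", "P2", "P3"),
                         location = c("a", "b", "c"), year = 2008,
                         era = "contemporary", region = "coastal", n = 20),
    mixture = diag(3),
    missing_rates = c(historical = 0, contemporary = 0),
    genotype_error = 0, seed = 61)
  sim <- simulate_dataset(cfg)
  truth <- sim$truth$source_cluster
  asc <- a_score_optimize(sim$dataset, truth, pc_grid = c(5, 10),
                          n_perm = 10, seed = 3)
  expect_gt(max(asc$curve$a_score), (1 - 1 / 3) - 0.15)

  # noise-only data: a-score shrinks as n_pcs approaches n
  set.seed(18)
  gn <- matrix(rbinom(40 * 120, 2, 0.5), 40, 120)
  dsn <- make_two_sample_ds(gn[1:20, ], gn[21:40, ])
  labs <- rep(1:4, each = 10)
  ascn <- a_score_optimize(dsn, labs, pc_grid = c(5, 35), n_perm = 10,
                           seed = 4)
  expect_lt(ascn$curve$a_score[2], ascn$curve$a_score[1] + 0.05)
  # random labels give an a-score near zero
  expect_lt(abs(ascn$curve$a_score[1]), 0.35)
})

test_that("red/green recoding min-max scales sample DF coordinates", {
  coords <- rbind(s1 = c(-2, 0), s2 = c(1, 5), s3 = c(4, 2.5))
  rgb <- df_to_rgb(coords)
  expect_equal(rgb["s3", "red"], 1)
  expect_equal(rgb["s1", "red"], 0)
  expect_equal(rgb["s2", "green"], 1)
  # affine transformations of the DF axes do not change intensities
  rgb2 <- df_to_rgb(sweep(coords * 3.7, 2, c(11, -4), "+"))
  expect_equal(rgb2, rgb)
  # two samples -> {0, 1}; constant axis -> 0.5
  expect_equal(sort(df_to_rgb(coords[1:2, ])$red), c(0, 1))
  expect_equal(df_to_rgb(cbind(c(1, 1), c(0, 2)))$red, c(0.5, 0.5))
})

test_that("allele loadings are normalized and find the informative locus", {
  set.seed(20)
  informative <- rep(c(0L, 2L), each = 20)
  noise <- matrix(rbinom(40 * 9, 2, 0.5), 40, 9)
  g <- cbind(informative, noise)
  ds <- make_two_sample_ds(g[1:20, ], g[21:40, ])
  pca <- pca_reduce(ds, 5)
  model <- fit_dapc(pca$scores, rep(c("a", "b"), each = 20), pca = pca)
  lo <- allele_loadings(model)
  expect_equal(unname(colSums(lo)), rep(1, ncol(lo)), tolerance = 1e-9)
  expect_gt(lo[1, 1], 0.8)
})

test_that("a planted high-divergence block dominates the DF loadings", {
  # a genomic island: 10 linked loci diverging coherently between the two
  # clusters against a near-undifferentiated background
  set.seed(71)
  nl <- 230
  loci <- data.frame(locus_id = sprintf("L%04d", 1:nl),
                     linkage_group = c(rep(1, 10), rep(2, 220)),
                     cm_position = 1:nl,
                     block = c(rep(1L, 10), rep(0L, 220)))
  anc <- runif(220, 0.2, 0.8)
  f <- 0.002
  bg <- vapply(anc, function(p)
    rbeta(2, p * (1 - f) / f, (1 - p) * (1 - f) / f), numeric(2))
  freqs <- cbind(matrix(rep(c(0.1, 0.9), 10), 2), bg)
  dimnames(freqs) <- list(c("cluster1", "cluster2"), loci$locus_id)
  cfg <- sim_config(
    n_clusters = 2, n_loci = nl,
    outlier_blocks = list(list(lg = 1, n_loci = 10, fst = 0.45, rho = 0.05)),
    samples = data.frame(sample_code = c("P1", "P2"),
                         location = c("a", "b"), year = 1950,
                         era = "historical", region = "coastal", n = 60),
    mixture = rbind(c(1, 0), c(0, 1)),
    missing_rates = c(historical = 0, contemporary = 0),
    genotype_error = 0, seed = 72)
  drawn <- sample_individuals(list(historical = freqs, contemporary = freqs),
                              loci, cfg)
  pca <- pca_reduce(drawn$dataset, 5)
  model <- fit_dapc(pca$scores, drawn$truth$source_cluster, pca = pca)
  lo <- allele_loadings(model)
  expect_gt(sum(lo[1:10, 1]), 0.8)
})

test_that("the clustering pipeline is deterministic given a seed", {
  set.seed(24)
  g <- matrix(rbinom(60 * 100, 2, 0.5), 60, 100)
  ds <- make_two_sample_ds(g[1:30, ], g[31:60, ])
  pca <- pca_reduce(ds, 10)
  s1 <- kmeans_bic_scan(pca$scores, 1:5, seed = 7)
  s2 <- kmeans_bic_scan(pca$scores, 1:5, seed = 7)
  expect_identical(s1, s2)
})
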