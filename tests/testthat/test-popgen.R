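test_that("allele frequencies use missing-aware denominators", {
  ds <- make_two_sample_ds(c(0L, 1L, 2L, 2L), c(NA, NA, NA, NA))
  fq <- allele_frequencies(ds)
  expect_equal(unname(fq$p["A", 1]), 5 / 8)
  expect_true(is.na(fq$p["B", 1]))
  expect_equal(unname(fq$n_obs["A", 1]), 4L)
  expect_error(allele_frequencies(ds, grouping = "A"), "every individual")
})

test_that("frequency estimates are unbiased at binomial-sampling scale", {
  set.seed(5)
  n <- 500
  g <- matrix(rbinom(n, 2, 0.3), n, 1)
  ds <- genotype_dataset(
    g, data.frame(individual_id = sprintf("i%03d", 1:n), sample_code = "A",
                  year = 2008))
  p_hat <- allele_frequencies(ds)$p[1, 1]
  se <- sqrt(0.3 * 0.7 / (2 * n))
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("HWE Monte-Carlo test: exact proportions give statistic 0, p 1", {
  ds <- make_two_sample_ds(c(0L, 1L, 1L, 2L), c(0L, 0L, 0L, 0L))
  res <- hwe_test_mc(ds, "A", "L01", n_perm = 500, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("HWE test rejects an all-heterozygote sample and skips monomorphic", {
  ds <- make_two_sample_ds(rep(1L, 20), rep(0L, 20))
  res <- hwe_test_mc(ds, "A", "L01", n_perm = 1e4, seed = 2)
  expect_lt(res$p_value, 0.01)
  mono <- hwe_test_mc(ds, "B", "L01", n_perm = 100, seed = 3)
  expect_true(mono$untestable)
  expect_true(is.na(mono$p_value))
})

test_that("HWE Monte-Carlo p-values are valid and calibrated under the null", {
  # the chi-square statistic is discrete at small n (a large atom of samples
  # sits exactly at the HW expectation, hence at p = 1), so the p-values are
  # sub-uniform: never anti-conservative, and close to nominal at the
  # rejection levels that matter
  set.seed(9)
  n_rep <- 400
  pvals <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    dos <- rbinom(20, 2, 0.5)
    if (sum(dos) %in% c(0, 40)) next
    ds <- make_two_sample_ds(dos, rep(0L, 2))
    pvals[r] <- hwe_test_mc(ds, "A", "L01", n_perm = 199)$p_value
  }
  pvals <- pvals[!is.na(pvals)]
  for (alpha in c(0.05, 0.1, 0.2, 0.5)) {
    frac <- mean(pvals <= alpha)
    expect_lte(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / length(pvals)))
  }
  expect_gt(mean(pvals <= 0.05), 0.01)
  expect_gt(mean(pvals <= 0.2), 0.08)
})

test_that("composite LD r2 behaves at its limits", {
  dos <- c(0L, 1L, 2L, 1L, 0L, 2L)
  ds <- make_two_sample_ds(cbind(dos, dos, 2L - dos), matrix(0L, 2, 3))
  expect_equal(ld_r2(ds, "A", 1, 2), 1)
  expect_equal(ld_r2(ds, "A", 1, 3), 1)  # perfect negative correlation
  # fewer than 3 complete pairs -> NA
  g <- cbind(c(0L, 1L, NA, NA), c(1L, NA, 0L, 2L))
  ds2 <- make_two_sample_ds(g, matrix(0L, 2, 2))
  expect_true(is.na(ld_r2(ds2, "A", 1, 2)))
})

test_that("null mean r2 matches the 1/(n-1) expectation", {
  set.seed(13)
  n <- 30
  r2 <- replicate(1000, {
    a <- rbinom(n, 2, 0.5)
    b <- rbinom(n, 2, 0.5)
    if (var(a) == 0 || var(b) == 0) NA_real_ else cor(a, b)^2
  })
  expect_lt(abs(mean(r2, na.rm = TRUE) - 1 / (n - 1)), 0.006)
})

test_that("LD pruning resolves a perfect-LD block minimally", {
  set.seed(3)
  base <- rbinom(40, 2, 0.5)
  other1 <- rbinom(40, 2, 0.4)
  other2 <- rbinom(40, 2, 0.6)
  g <- cbind(base, base, base, other1, other2)
  ds <- make_two_sample_ds(g[1:20, ], g[21:40, ])
  res <- high_ld_prune(ds, pure_samples = c("A", "B"), threshold = 0.1)
  block <- c("L01", "L02", "L03")
  expect_equal(sort(res$dropped), sort(setdiff(block, res$kept)))
  expect_length(res$dropped, 2)       # minimal: keep one of three
  expect_true(all(c("L04", "L05") %in% res$kept))
  # kept set has no flagged pair left
  kept_pairs <- res$pairs[res$pairs$locus_i %in% res$kept &
                            res$pairs$locus_j %in% res$kept, ]
  expect_equal(nrow(kept_pairs), 0)
})

test_that("pruning keeps everything when no pair is in high LD", {
  set.seed(4)
  g <- matrix(rbinom(200, 2, 0.5), 20, 10)
  ds <- make_two_sample_ds(g[1:10, ], g[11:20, ])
  res <- high_ld_prune(ds, c("A", "B"), threshold = 0.9)
  expect_length(res$dropped, 0)
  expect_length(res$kept, 10)
})

test_that("Weir-Cockerham theta hits its boundary cases", {
  ds <- make_two_sample_ds(rep(2L, 10), rep(0L, 10))
  expect_equal(pairwise_fst_wc(ds, "A", "B")$theta, 1)
  # identical genotype counts: no between-sample variance beyond sampling
  dos <- c(rep(0L, 4), rep(1L, 4), rep(2L, 2))
  ds2 <- make_two_sample_ds(dos, dos)
  expect_lte(pairwise_fst_wc(ds2, "A", "B")$theta, 0)
})

test_that("theta equals the independent ANOVA oracle on all tiny configs", {
  compositions <- function(n) {
    out <- list()
    for (n0 in 0:n) for (n1 in 0:(n - n0)) {
      out[[length(out) + 1]] <- c(n0, n1, n - n0 - n1)
    }
    out
  }
  for (n1 in 2:4) {
    for (n2 in 2:4) {
      for (c1 in compositions(n1)) {
        for (c2 in compositions(n2)) {
          d1 <- rep(0:2, c1)
          d2 <- rep(0:2, c2)
          pooled <- sum(d1) + sum(d2)
          if (pooled == 0 || pooled == 2 * (n1 + n2)) next
          ds <- make_two_sample_ds(d1, d2)
          expect_equal(pairwise_fst_wc(ds, "A", "B")$theta,
                       wc_anova_theta(d1, d2), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("theta is symmetric and ignores jointly monomorphic loci", {
  set.seed(17)
  g1 <- matrix(rbinom(150, 2, 0.3), 15, 10)
  g2 <- matrix(rbinom(150, 2, 0.6), 15, 10)
  ds <- make_two_sample_ds(g1, g2)
  t_ab <- pairwise_fst_wc(ds, "A", "B")$theta
  t_ba <- pairwise_fst_wc(ds, "B", "A")$theta
  expect_equal(t_ab, t_ba, tolerance = 1e-12)
  ds_plus <- make_two_sample_ds(cbind(g1, 2L), cbind(g2, 2L))
  expect_equal(pairwise_fst_wc(ds_plus, "A", "B")$theta, t_ab,
               tolerance = 1e-12)
})

test_that("multilocus theta recovers the generating F within jackknife error", {
  cfg <- sim_config(
    n_clusters = 2, background_fst = 0.03, n_loci = 900,
    outlier_blocks = list(),
    samples = data.frame(sample_code = c("P1", "P2"), location = c("a", "b"),
                         year = 1950, era = "historical",
                         region = "coastal", n = 30),
    mixture = rbind(c(1, 0), c(0, 1)),
    missing_rates = c(historical = 0, contemporary = 0),
    genotype_error = 0, seed = 77)
  sim <- simulate_dataset(cfg)
  est <- theta_with_jackknife_se(sim$dataset, "P1", "P2")
  expect_lt(abs(est$theta - 0.03), 3 * est$se)
})

test_that("summed chi-square test matches hand arithmetic and is additive", {
  ds_same <- make_two_sample_ds(c(rep(0L, 5), rep(2L, 5)),
                                c(rep(0L, 5), rep(2L, 5)))
  res_same <- chifish_test(ds_same, "A", "B")
  expect_equal(res_same$statistic, 0)
  expect_equal(res_same$p_value, 1)

  ds_opp <- make_two_sample_ds(rep(2L, 10), rep(0L, 10))
  res_opp <- chifish_test(ds_opp, "A", "B")
  expect_equal(res_opp$statistic, 40)
  expect_equal(res_opp$df, 1)

  set.seed(19)
  g1 <- matrix(rbinom(30, 2, 0.3), 10, 3)
  g2 <- matrix(rbinom(30, 2, 0.7), 10, 3)
  ds3 <- make_two_sample_ds(g1, g2)
  full <- chifish_test(ds3, "A", "B")
  parts <- vapply(1:3, function(j) {
    sub <- subset_dataset(ds3, loci = j)
    r <- chifish_test(sub, "A", "B")
    c(r$statistic, r$df)
  }, numeric(2))
  expect_equal(full$statistic, sum(parts[1, ]), tolerance = 1e-12)
  expect_equal(full$df, sum(parts[2, ]))
})

test_that("q-values reproduce Benjamini-Hochberg with pi0 fixed at 1", {
  expect_equal(qvalues(1), 1)
  expect_equal(qvalues(c(0.001, 0.5, 0.9), pi0 = 1), c(0.003, 0.75, 0.9))
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("q-values preserve the p-value ordering", {
  set.seed(23)
  p <- runif(500)
  q <- qvalues(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("uniform p-values yield essentially no q < 0.05 discoveries", {
  set.seed(29)
  p <- runif(1e4)
  q <- qvalues(p)
  expect_lt(mean(q < 0.05), 0.001)
})
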