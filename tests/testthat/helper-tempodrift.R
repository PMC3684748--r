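# shared fixtures and independent oracles for the test suite

# two-sample dataset from dosage vectors at a single locus (or matrices)
make_two_sample_ds <- function(d1, d2, years = c(1950, 2008)) {
  g1 <- if (is.matrix(d1)) d1 else matrix(d1, ncol = 1)
  g2 <- if (is.matrix(d2)) d2 else matrix(d2, ncol = 1)
  g <- rbind(g1, g2)
  n1 <- nrow(g1)
  n2 <- nrow(g2)
  genotype_dataset(
    g,
    data.frame(
      individual_id = sprintf("i%03d", seq_len(n1 + n2)),
      sample_code = rep(c("A", "B"), c(n1, n2)),
      location = rep(c("locA", "locB"), c(n1, n2)),
      year = rep(years, c(n1, n2)),
      stringsAsFactors = FALSE),
    data.frame(locus_id = sprintf("L%02d", seq_len(ncol(g))),
               stringsAsFactors = FALSE)
  )
}

# independent route to the Weir-Cockerham components: hierarchical ANOVA
# sums of squares on allele indicators (populations / individuals / alleles)
wc_anova_theta <- function(dos1, dos2) {
  dos <- list(dos1[!is.na(dos1)], dos2[!is.na(dos2)])
  n <- vapply(dos, length, 0L)
  r <- 2
  ntot <- sum(n)
  nc <- (ntot - sum(n^2) / ntot) / (r - 1)
  ybar_i <- vapply(dos, mean, 0) / 2
  ybar <- sum(vapply(dos, sum, 0)) / (2 * ntot)
  ssg <- sum(vapply(dos, function(d) sum(d == 1) / 2, 0))
  msg <- ssg / ntot
  ssi <- 2 * sum(unlist(mapply(function(d, m) (d / 2 - m)^2, dos, ybar_i,
                               SIMPLIFY = FALSE)))
  msi <- ssi / (ntot - r)
  msp <- 2 * sum(n * (ybar_i - ybar)^2) / (r - 1)
  a <- (msp - msi) / (2 * nc)
  b <- (msi - msg) / 2
  cc <- msg
  a / (a + b + cc)
}

# independent fixed-point oracle for the iterative call-rate filter: apply
# one margin at a time, in a chosen order, until stable
call_rate_fixed_point <- function(g, sample_min, locus_min,
                                  sample_first = TRUE) {
  keep_i <- seq_len(nrow(g))
  keep_j <- seq_len(ncol(g))
  repeat {
    changed <- FALSE
    for (margin in if (sample_first) c("s", "l") else c("l", "s")) {
      sub <- g[keep_i, keep_j, drop = FALSE]
      if (margin == "s") {
        bad <- rowMeans(!is.na(sub)) <= sample_min
        if (any(bad)) { keep_i <- keep_i[!bad]; changed <- TRUE }
      } else {
        bad <- colMeans(!is.na(sub)) <= locus_min
        if (any(bad)) { keep_j <- keep_j[!bad]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  list(rows = keep_i, cols = keep_j)
}

# multilocus WC theta with a delete-one-locus jackknife standard error
theta_with_jackknife_se <- function(ds, s1, s2) {
  comp <- wc_components(ds, s1, s2)
  denom <- comp$a + comp$b + comp$c
  use <- comp$usable & !is.na(denom) & denom > 0
  a <- comp$a[use]
  d <- denom[use]
  theta <- sum(a) / sum(d)
  loo <- (sum(a) - a) / (sum(d) - d)
  L <- length(a)
  se <- sqrt((L - 1) / L * sum((loo - mean(loo))^2))
  list(theta = theta, se = se, n_loci = L)
}
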