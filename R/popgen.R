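#' Per-group allele frequencies
#'
#' Alternate-allele frequency per (group, locus) with missing-aware
#' denominators: \eqn{p = \sum dosage / (2 n_{obs})} over non-missing calls.
#' Groups with no observed call at a locus get \code{NA}.
#'
#' @param ds A \code{genotype_dataset}.
#' @param grouping Character vector mapping each individual (in row order) to
#'   a group label; defaults to the population sample codes.
#' @return A list of class \code{freq_table} with matrices \code{p}
#'   (groups x loci), \code{n_obs} (diploid individuals with calls) and
#'   \code{polymorphic} (logical, 0 < p < 1).
#' @export
allele_frequencies <- function(ds, grouping = ds$samples$sample_code) {
  if (length(grouping) != nrow(ds$genotypes)) {
    stop("grouping must map every individual")
  }
  groups <- unique(grouping)
  g <- ds$genotypes
  p <- matrix(NA_real_, length(groups), ncol(g),
              dimnames = list(groups, ds$loci$locus_id))
  n_obs <- matrix(0L, length(groups), ncol(g),
                  dimnames = dimnames(p))
  for (k in seq_along(groups)) {
    sub <- g[grouping == groups[k], , drop = FALSE]
    n <- colSums(!is.na(sub))
    p[k, ] <- ifelse(n > 0, colSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
    n_obs[k, ] <- n
  }
  structure(list(p = p, n_obs = n_obs,
                 polymorphic = !is.na(p) & p > 0 & p < 1),
            class = "freq_table")
}

#' Hardy-Weinberg Monte-Carlo test
#'
#' Chi-square statistic of observed genotype counts against the
#' Hardy-Weinberg expectation computed from the observed allele counts, with
#' a Monte-Carlo p-value obtained by shuffling the 2n observed alleles into
#' random diploid pairs. The p-value uses the add-one estimator
#' \eqn{(1 + \#\{stat_{perm} \ge stat_{obs}\}) / (1 + n_{perm})}.
#'
#' @param ds A \code{genotype_dataset}.
#' @param sample_code Population sample to test.
#' @param locus_id Locus to test.
#' @param n_perm Number of Monte-Carlo permutations (study default 1e5).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class \code{test_result} with \code{statistic},
#'   \code{df} (NA for the Monte-Carlo test), \code{p_value} and counts. A
#'   monomorphic locus yields \code{p_value = NA} and
#'   \code{untestable = TRUE}.
#' @export
hwe_test_mc <- function(ds, sample_code, locus_id, n_perm = 1e5,
                        seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample_rows(ds, sample_code)
  dos <- ds$genotypes[idx, match(locus_id, ds$loci$locus_id)]
  dos <- dos[!is.na(dos)]
  counts <- c(sum(dos == 0), sum(dos == 1), sum(dos == 2))
  n <- length(dos)
  n_alt <- sum(dos)
  if (n == 0 || n_alt == 0 || n_alt == 2 * n) {
    return(structure(list(statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, untestable = TRUE,
                          genotype_counts = counts),
                     class = "test_result"))
  }
  stat <- hwe_chisq(counts, n, n_alt)
  alleles <- c(rep(1L, n_alt), rep(0L, 2 * n - n_alt))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(alleles)
    dosp <- perm[seq_len(n)] + perm[n + seq_len(n)]
    cp <- c(sum(dosp == 0L), sum(dosp == 1L), sum(dosp == 2L))
    if (hwe_chisq(cp, n, n_alt) >= stat - 1e-12) exceed <- exceed + 1L
  }
  structure(list(statistic = stat, df = NA_real_,
                 p_value = (1 + exceed) / (1 + n_perm),
                 untestable = FALSE, genotype_counts = counts,
                 n_perm = n_perm),
            class = "test_result")
}

hwe_chisq <- function(counts, n, n_alt) {
  p <- n_alt / (2 * n)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  sum((counts - expd)^2 / expd)
}

#' @export
print.test_result <- function(x, ...) {
  cat("test_result: statistic =", format(x$statistic),
      "df =", format(x$df), "p =", format(x$p_value))
  if (!is.null(x$q_value)) cat(" q =", format(x$q_value))
  cat("\n")
  invisible(x)
}

#' Composite genotypic linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between the dosage vectors of two loci within
#' one population sample, after listwise deletion of individuals missing at
#' either locus (Burrows-style composite LD: missing-robust and free of the
#' Hardy-Weinberg assumption).
#'
#' @param ds A \code{genotype_dataset}.
#' @param sample_code Population sample.
#' @param locus_i,locus_j Locus ids or column indices.
#' @return r-squared in [0, 1], or \code{NA} when fewer than 3 complete
#'   genotype pairs remain or either locus is monomorphic among them.
#' @export
ld_r2 <- function(ds, sample_code, locus_i, locus_j) {
  idx <- sample_rows(ds, sample_code)
  ji <- if (is.character(locus_i)) match(locus_i, ds$loci$locus_id) else locus_i
  jj <- if (is.character(locus_j)) match(locus_j, ds$loci$locus_id) else locus_j
  a <- ds$genotypes[idx, ji]
  b <- ds$genotypes[idx, jj]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Prune loci in high linkage disequilibrium
#'
#' Mean composite r-squared per locus pair, averaged over the 'pure' samples
#' where it is defined. Pairs exceeding \code{threshold} are flagged and one
#' locus per flagged pair is discarded, repeatedly removing the locus with
#' the most flagged partners (ties broken toward the lower column index)
#' until no flagged pair remains among the kept loci.
#'
#' @param ds A \code{genotype_dataset}.
#' @param pure_samples Character vector of sample codes over which pairwise
#'   r-squared is averaged.
#' @param threshold Flagging threshold on mean r-squared (study value 0.1,
#'   strict \code{>}).
#' @return A list with \code{kept} and \code{dropped} locus ids and
#'   \code{pairs}, a data frame of the flagged pairs with their mean
#'   r-squared.
#' @export
high_ld_prune <- function(ds, pure_samples, threshold = 0.1) {
  if (!length(pure_samples)) stop("pure_samples must be non-empty")
  nl <- ncol(ds$genotypes)
  acc <- matrix(0, nl, nl)
  cnt <- matrix(0L, nl, nl)
  for (sc in pure_samples) {
    idx <- sample_rows(ds, sc)
    g <- ds$genotypes[idx, , drop = FALSE]
    r2 <- pairwise_r2_matrix(g)
    ok <- !is.na(r2)
    acc[ok] <- acc[ok] + r2[ok]
    cnt <- cnt + ok
  }
  meanr2 <- ifelse(cnt > 0, acc / cnt, NA_real_)
  flagged <- !is.na(meanr2) & meanr2 > threshold
  flagged[lower.tri(flagged, diag = TRUE)] <- FALSE
  adj <- flagged | t(flagged)
  keep <- rep(TRUE, nl)
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE]) * keep
    if (!any(deg > 0)) break
    drop <- which.max(deg)  # ties -> lower index (which.max takes first)
    keep[drop] <- FALSE
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  pair_idx <- which(flagged, arr.ind = TRUE)
  list(
    kept = ds$loci$locus_id[keep],
    dropped = ds$loci$locus_id[!keep],
    pairs = data.frame(
      locus_i = ds$loci$locus_id[pair_idx[, 1]],
      locus_j = ds$loci$locus_id[pair_idx[, 2]],
      mean_r2 = meanr2[pair_idx],
      stringsAsFactors = FALSE
    )
  )
}

# all-pairs composite r2 within one sample's dosage matrix; NA where fewer
# than 3 complete pairs or a locus is monomorphic among them
pairwise_r2_matrix <- function(g) {
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  n_pair <- crossprod(!is.na(g))
  r2 <- r^2
  r2[n_pair < 3] <- NA_real_
  diag(r2) <- NA_real_
  r2
}

#' Weir-Cockerham variance components for two samples, per locus
#'
#' The 1984 method-of-moments components a (between populations), b (between
#' individuals within populations) and c (within individuals), computed per
#' locus from genotype counts of two population samples.
#'
#' @param ds A \code{genotype_dataset}.
#' @param s1,s2 Sample codes.
#' @return Data frame with one row per locus: \code{a}, \code{b}, \code{c},
#'   \code{usable} (both samples have calls and the locus is not monomorphic
#'   across the pooled pair).
#' @export
wc_components <- function(ds, s1, s2) {
  g1 <- ds$genotypes[sample_rows(ds, s1), , drop = FALSE]
  g2 <- ds$genotypes[sample_rows(ds, s2), , drop = FALSE]
  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- colMeans(g1 == 1, na.rm = TRUE)
  h2 <- colMeans(g2 == 1, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - ((r - 1) / r) * s2v - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2v -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  usable <- n1 > 0 & n2 > 0 & !is.na(pbar) & pbar > 0 & pbar < 1 &
    nbar > 1 & nc > 0
  data.frame(locus_id = ds$loci$locus_id, a = a, b = b, c = cc,
             usable = usable, stringsAsFactors = FALSE)
}

#' Pairwise Weir-Cockerham FST between two samples
#'
#' Multilocus theta as the ratio of sums of the per-locus variance
#' components, \eqn{\theta = \sum a / \sum (a+b+c)}, over loci polymorphic
#' across the pooled pair with a positive denominator.
#'
#' @param ds A \code{genotype_dataset}.
#' @param s1,s2 Sample codes.
#' @return A list with \code{theta} (multilocus), \code{per_locus} theta
#'   (NA where unusable), \code{n_loci} used, and the \code{components}
#'   data frame.
#' @export
pairwise_fst_wc <- function(ds, s1, s2) {
  comp <- wc_components(ds, s1, s2)
  denom <- comp$a + comp$b + comp$c
  use <- comp$usable & !is.na(denom) & denom > 0
  per_locus <- ifelse(use, comp$a / denom, NA_real_)
  theta <- if (any(use)) sum(comp$a[use]) / sum(denom[use]) else NA_real_
  list(theta = theta,
       per_locus = stats::setNames(per_locus, comp$locus_id),
       n_loci = sum(use), components = comp)
}

#' FST matrix over all population samples
#'
#' @param ds A \code{genotype_dataset}.
#' @param codes Sample codes to include (default all).
#' @return Symmetric matrix of pairwise multilocus theta.
#' @export
fst_matrix <- function(ds, codes = unique(ds$samples$sample_code)) {
  k <- length(codes)
  m <- matrix(NA_real_, k, k, dimnames = list(codes, codes))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      th <- pairwise_fst_wc(ds, codes[i], codes[j])$theta
      m[i, j] <- m[j, i] <- th
    }
  }
  diag(m) <- 0
  m
}

#' Summed chi-square test of allele-frequency homogeneity
#'
#' Per locus, a 2x2 Pearson chi-square on allele counts of the two samples
#' (df 1); the statistic and df are summed over loci polymorphic in the
#' pooled pair and referred to the chi-square distribution.
#'
#' @param ds A \code{genotype_dataset}.
#' @param s1,s2 Sample codes.
#' @return A \code{test_result} with summed \code{statistic}, \code{df} and
#'   \code{p_value}; NA when no locus is testable.
#' @export
chifish_test <- function(ds, s1, s2) {
  fq <- allele_frequencies(subset_dataset(
    ds, individuals = c(sample_rows(ds, s1), sample_rows(ds, s2))))
  a1 <- 2 * fq$n_obs[s1, ] * fq$p[s1, ]   # alt allele counts
  r1 <- 2 * fq$n_obs[s1, ] * (1 - fq$p[s1, ])
  a2 <- 2 * fq$n_obs[s2, ] * fq$p[s2, ]
  r2 <- 2 * fq$n_obs[s2, ] * (1 - fq$p[s2, ])
  tot <- a1 + r1 + a2 + r2
  pooled_alt <- a1 + a2
  testable <- !is.na(tot) & tot > 0 & pooled_alt > 0 & pooled_alt < tot &
    (a1 + r1) > 0 & (a2 + r2) > 0
  if (!any(testable)) {
    return(structure(list(statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_), class = "test_result"))
  }
  chi <- rep(NA_real_, length(tot))
  n <- tot
  det <- a1 * r2 - a2 * r1
  chi <- n * det^2 / ((a1 + r1) * (a2 + r2) * (a1 + a2) * (r1 + r2))
  stat <- sum(chi[testable])
  df <- sum(testable)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 per_locus = stats::setNames(ifelse(testable, chi, NA_real_),
                                             colnames(fq$p))),
            class = "test_result")
}

#' Storey q-values with Benjamini-Hochberg fallback
#'
#' False-discovery-rate q-values. With at least 100 tests, \eqn{\pi_0} is
#' estimated by the natural-spline smoother of \eqn{\hat\pi_0(\lambda) =
#' \#\{p > \lambda\} / (m (1 - \lambda))} over the grid
#' \eqn{\lambda = 0.05, 0.10, \ldots, 0.95}, evaluated at the largest
#' \eqn{\lambda}. When the estimate exceeds 1, is non-positive, or fewer than
#' 100 tests are supplied, \eqn{\pi_0 = 1}, which reduces to
#' Benjamini-Hochberg. Output q-values are step-up monotone in p and returned
#' in input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param pi0 Optional: force a \eqn{\pi_0} value (e.g. 1 for plain BH).
#' @return Numeric vector of q-values, same length and order as the input.
#' @export
qvalues <- function(p_values, pi0 = NULL) {
  p <- p_values
  if (anyNA(p)) stop("p-values must not be NA")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- if (m < 100) 1 else estimate_pi0(p)
  }
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Storey & Tibshirani smoother estimate of the null proportion
estimate_pi0 <- function(p) {
  lambda <- seq(0.05, 0.95, by = 0.05)
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), 0)
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 > 1 || pi0 <= 0) pi0 <- 1
  pi0
}
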