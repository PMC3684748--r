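#' PCA reduction of a genotype matrix
#'
#' Missing dosages are mean-imputed per locus, the matrix is column-centered
#' (not scaled), and the leading principal axes are extracted by singular
#' value decomposition.
#'
#' @param ds A \code{genotype_dataset}.
#' @param n_axes Number of principal components to retain; must not exceed
#'   \code{min(individuals - 1, loci)}.
#' @return A list of class \code{pca_reduction}: \code{scores}
#'   (individuals x axes), \code{rotation} (loci x axes), \code{center}
#'   (per-locus means used for centering and imputation), \code{var_fraction}
#'   and \code{cum_var_fraction} per retained axis.
#' @export
pca_reduce <- function(ds, n_axes) {
  g <- ds$genotypes
  n <- nrow(g)
  if (n_axes > min(n - 1, ncol(g))) {
    stop("n_axes must be <= min(individuals - 1, loci)")
  }
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  x <- sweep(g, 2, mu)
  x[is.na(x)] <- 0
  sv <- svd(x, nu = n_axes, nv = n_axes)
  ev <- sv$d^2
  scores <- sv$u %*% diag(sv$d[seq_len(n_axes)], n_axes, n_axes)
  rownames(scores) <- ds$samples$individual_id
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  rotation <- sv$v
  dimnames(rotation) <- list(ds$loci$locus_id, colnames(scores))
  structure(list(
    scores = scores, rotation = rotation, center = mu,
    var_fraction = ev[seq_len(n_axes)] / sum(ev),
    cum_var_fraction = cumsum(ev[seq_len(n_axes)]) / sum(ev)
  ), class = "pca_reduction")
}

#' Project new individuals onto an existing PCA basis
#'
#' @param pca A \code{pca_reduction}.
#' @param genotypes Dosage matrix (individuals x the same loci); missing
#'   calls are imputed with the training per-locus means.
#' @return Score matrix in the training PC space.
#' @export
pca_project <- function(pca, genotypes) {
  x <- sweep(genotypes, 2, pca$center)
  x[is.na(x)] <- 0
  x %*% pca$rotation
}

# k-means++ seeding: spread initial centers by squared-distance sampling;
# returns fewer than k rows when the data hold fewer distinct points
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  filled <- 1L
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) break  # no distinct point left
      centers[j, ] <- x[sample.int(n, 1, prob = d2 / sum(d2)), ]
      filled <- j
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers[seq_len(filled), , drop = FALSE]
}

#' K-means scan with BIC model selection
#'
#' Runs K-means for each K in \code{k_range} (best of \code{n_starts}
#' k-means++-seeded starts) and scores each solution with the
#' spherical-Gaussian criterion \eqn{BIC = n \ln(W/n) + K \ln(n)}, where W is
#' the total within-cluster sum of squares. Degenerate solutions with W = 0
#' get \code{-Inf} and are excluded from the argmin; BIC ties resolve to the
#' smaller K.
#'
#' @param scores Numeric matrix (individuals x retained PCs).
#' @param k_range Integer vector of K values (study convention 1:20).
#' @param n_starts Random restarts per K.
#' @param seed Optional seed.
#' @return A list: \code{table} (K, BIC, W), \code{best_k}, and
#'   \code{assignments}, a list of cluster vectors indexed by K.
#' @export
kmeans_bic_scan <- function(scores, k_range = 1:20, n_starts = 20,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(scores)
  n <- nrow(x)
  if (max(k_range) > n) stop("max(k_range) must be <= number of individuals")
  distinct <- x[!duplicated(x), , drop = FALSE]
  res <- lapply(k_range, function(k) {
    if (k == 1) {
      w <- sum(sweep(x, 2, colMeans(x))^2)
      return(list(w = w, cluster = rep(1L, n)))
    }
    if (k >= nrow(distinct)) {
      # every distinct point its own cluster: W = 0 by construction
      key <- do.call(paste, as.data.frame(x))
      cl <- match(key, unique(key))
      return(list(w = 0, cluster = cl))
    }
    best <- NULL
    for (s in seq_len(n_starts)) {
      cen <- kmeanspp_centers(x, k)
      if (nrow(cen) < k) next
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = cen, iter.max = 100)),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$w) {
        best <- list(w = km$tot.withinss, cluster = km$cluster)
      }
    }
    if (is.null(best)) list(w = NA_real_, cluster = rep(1L, n)) else best
  })
  w <- vapply(res, `[[`, 0, "w")
  bic <- ifelse(!is.na(w) & w > 0, n * log(w / n) + k_range * log(n), -Inf)
  finite <- is.finite(bic)
  best_k <- if (any(finite)) k_range[finite][which.min(bic[finite])] else
    min(k_range)
  list(
    table = data.frame(K = k_range, BIC = bic, W = w),
    best_k = best_k,
    assignments = stats::setNames(lapply(res, `[[`, "cluster"),
                                  paste0("K", k_range))
  )
}

#' Fit discriminant functions on retained principal components
#'
#' Discriminant functions (DFs) are the leading generalized eigenvectors of
#' the between-group scatter against the pooled within-group scatter in the
#' retained-PC space, computed through the symmetric whitening
#' \eqn{W^{-1/2} B W^{-1/2}}. Axes are scaled so the pooled within-group
#' variance along each DF is 1. A singular within-group scatter is
#' ridge-regularized with \eqn{10^{-6} \cdot tr(W)} on the diagonal.
#'
#' @param scores Numeric matrix (individuals x retained PCs).
#' @param group_labels Group assignment per individual (>= 2 groups, each
#'   with >= 2 members).
#' @param n_dfs Number of DFs to keep; capped at
#'   \code{min(groups - 1, ncol(scores))}.
#' @param pca Optional \code{pca_reduction} used to build \code{scores};
#'   stored so loadings can be mapped back to loci.
#' @return A list of class \code{dapc_model}: \code{df_axes} (PCs x DFs),
#'   \code{power_fraction} per DF, \code{group_means} in DF space,
#'   \code{within_cov} (pooled, DF space), \code{groups}, \code{pca}.
#' @export
fit_dapc <- function(scores, group_labels, n_dfs = NULL, pca = NULL) {
  x <- as.matrix(scores)
  f <- factor(group_labels)
  if (nlevels(f) < 2) stop("need at least 2 groups")
  if (any(table(f) < 2)) stop("every group needs at least 2 members")
  d <- ncol(x)
  max_dfs <- min(nlevels(f) - 1, d)
  if (is.null(n_dfs)) n_dfs <- max_dfs
  n_dfs <- min(n_dfs, max_dfs)
  n <- nrow(x)
  grand <- colMeans(x)
  means <- apply(x, 2, tapply, f, mean)
  if (is.null(dim(means))) means <- matrix(means, ncol = d)
  nk <- as.vector(table(f))
  centered <- x - means[as.integer(f), , drop = FALSE]
  W <- crossprod(centered) / (n - nlevels(f))
  dev <- sweep(means, 2, grand)
  B <- crossprod(dev * sqrt(nk)) / n
  ew <- eigen(W, symmetric = TRUE)
  tol <- 1e-10 * max(ew$values, 1e-300)
  ridged <- any(ew$values < tol)
  if (ridged) {
    W <- W + diag(1e-6 * sum(diag(W)), d)
    ew <- eigen(W, symmetric = TRUE)
  }
  w_half_inv <- ew$vectors %*% diag(1 / sqrt(ew$values), d) %*% t(ew$vectors)
  eb <- eigen(w_half_inv %*% B %*% w_half_inv, symmetric = TRUE)
  keep <- seq_len(n_dfs)
  axes <- w_half_inv %*% eb$vectors[, keep, drop = FALSE]
  colnames(axes) <- paste0("DF", keep)
  rownames(axes) <- colnames(x)
  ev <- pmax(eb$values[keep], 0)
  mu_df <- means %*% axes
  z <- x %*% axes
  zc <- z - mu_df[as.integer(f), , drop = FALSE]
  structure(list(
    df_axes = axes,
    power_fraction = if (sum(ev) > 0) ev / sum(ev) else rep(1 / n_dfs, n_dfs),
    eigenvalues = ev,
    group_means = mu_df,
    within_cov = crossprod(zc) / (n - nlevels(f)),
    groups = levels(f),
    n_dfs = n_dfs,
    ridged = ridged,
    pca = pca
  ), class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat("dapc_model:", length(x$groups), "groups,", x$n_dfs, "DFs\n")
  cat("  discriminating power:",
      paste(sprintf("%.1f%%", 100 * x$power_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior cluster membership probabilities
#'
#' Individuals are positioned on the discriminant functions and assigned a
#' Gaussian density per group (shared pooled within-group covariance, uniform
#' priors), normalized to posterior membership probabilities. Sample means
#' and the pure/mixed label (strictly greater than the purity threshold)
#' are computed when sample codes are supplied.
#'
#' @param model A \code{dapc_model}.
#' @param scores Score matrix in the model's PC space.
#' @param sample_codes Optional per-individual population sample codes.
#' @param purity_threshold Mean-membership threshold for calling a sample
#'   'pure' (study convention 0.6, strict \code{>}).
#' @return A list of class \code{membership_matrix}: \code{prob}
#'   (individuals x groups, rows sum to 1), \code{assigned} (argmax group),
#'   and when sample codes are given, \code{sample_means} and \code{purity}.
#' @export
posterior_membership <- function(model, scores, sample_codes = NULL,
                                 purity_threshold = 0.6) {
  z <- as.matrix(scores) %*% model$df_axes
  S <- model$within_cov
  Sinv <- solve(S + diag(1e-12 * sum(diag(S)), ncol(S)))
  loglik <- vapply(seq_along(model$groups), function(k) {
    d <- sweep(z, 2, model$group_means[k, ])
    -0.5 * rowSums((d %*% Sinv) * d)
  }, numeric(nrow(z)))
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1)
  loglik <- loglik - apply(loglik, 1, max)
  prob <- exp(loglik)
  prob <- prob / rowSums(prob)
  colnames(prob) <- model$groups
  rownames(prob) <- rownames(scores)
  out <- list(prob = prob,
              assigned = model$groups[max.col(prob, ties.method = "first")],
              df_coords = z)
  if (!is.null(sample_codes)) {
    codes <- unique(sample_codes)
    sm <- t(vapply(codes, function(sc)
      colMeans(prob[sample_codes == sc, , drop = FALSE]),
      numeric(ncol(prob))))
    rownames(sm) <- codes
    out$sample_means <- sm
    out$purity <- ifelse(apply(sm, 1, max) > purity_threshold,
                         "pure", "mixed")
  }
  structure(out, class = "membership_matrix")
}

#' Hold-out cross-validation of the clustering + DAPC pipeline
#'
#' Splits each population sample into training and hold-out halves
#' (stratified), re-runs K-means clustering and the DAPC fit on the training
#' half alone, projects the hold-out individuals onto the training axes, and
#' compares their assignments with the full-data assignments (cluster labels
#' matched greedily on the confusion matrix).
#'
#' @param ds A \code{genotype_dataset}.
#' @param fraction Training fraction per sample (study convention 0.5).
#' @param n_pcs Retained PCs.
#' @param k Number of clusters; \code{NULL} scans 1:\code{k_max} by BIC.
#' @param k_max Upper end of the BIC scan when \code{k} is NULL.
#' @param seed Seed controlling the split and all K-means starts.
#' @return A list: \code{agreement} (hold-out vs full-data assignment rate),
#'   \code{high_confidence} (fraction of hold-out individuals with max
#'   membership > 0.95), \code{n_holdout}, and the two assignment vectors.
#' @export
holdout_crossvalidate <- function(ds, fraction = 0.5, n_pcs = 20, k = NULL,
                                  k_max = 10, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ds$genotypes)
  pca_full <- pca_reduce(ds, n_pcs)
  scan_full <- kmeans_bic_scan(pca_full$scores,
                               k_range = if (is.null(k)) 1:k_max else k)
  k_use <- if (is.null(k)) scan_full$best_k else k
  full_groups <- scan_full$assignments[[paste0("K", k_use)]]
  model_full <- fit_dapc(pca_full$scores, full_groups, pca = pca_full)
  full_assign <- posterior_membership(model_full, pca_full$scores)$assigned
  train <- logical(n)
  for (sc in unique(ds$samples$sample_code)) {
    idx <- which(ds$samples$sample_code == sc)
    n_train <- max(1, round(length(idx) * fraction))
    if (length(idx) == 1) {
      train[idx] <- TRUE  # too small to split; goes to training
      next
    }
    train[sample(idx, n_train)] <- TRUE
  }
  ds_train <- subset_dataset(ds, individuals = which(train))
  pca_tr <- pca_reduce(ds_train, min(n_pcs, sum(train) - 1))
  scan_tr <- kmeans_bic_scan(pca_tr$scores, k_range = k_use)
  groups_tr <- scan_tr$assignments[[paste0("K", k_use)]]
  model_tr <- fit_dapc(pca_tr$scores, groups_tr, pca = pca_tr)
  hold <- which(!train)
  z_hold <- pca_project(pca_tr, ds$genotypes[hold, , drop = FALSE])
  memb <- posterior_membership(model_tr, z_hold)
  # match training-run cluster labels to full-run labels via confusion counts
  z_tr_on_full <- full_assign[train]
  map <- match_labels(model_tr$groups, groups_tr, z_tr_on_full)
  holdout_assign <- map[memb$assigned]
  agreement <- mean(holdout_assign == full_assign[hold])
  list(
    agreement = agreement,
    high_confidence = mean(apply(memb$prob, 1, max) > 0.95),
    n_holdout = length(hold),
    holdout_assign = holdout_assign,
    full_assign = full_assign[hold],
    k = k_use
  )
}

# greedy confusion-matrix matching of one labelling onto another
match_labels <- function(from_levels, from, to) {
  tab <- table(factor(from, levels = from_levels), to)
  map <- stats::setNames(rep(NA_character_, length(from_levels)),
                         from_levels)
  tab_work <- tab
  for (step in seq_len(min(dim(tab)))) {
    idx <- which(tab_work == max(tab_work), arr.ind = TRUE)[1, , drop = TRUE]
    map[rownames(tab_work)[idx[1]]] <- colnames(tab_work)[idx[2]]
    tab_work[idx[1], ] <- -1
    tab_work[, idx[2]] <- -1
  }
  unmapped <- is.na(map)
  if (any(unmapped)) map[unmapped] <- colnames(tab)[seq_len(sum(unmapped))]
  map
}

#' Choose the number of retained PCs by a-score optimization
#'
#' The a-score of a DAPC fit is the observed reassignment success (fraction
#' of individuals whose posterior argmax matches their group) minus the mean
#' success over fits with permuted group labels, penalizing the spurious
#' discrimination that comes from retaining too many PCs.
#'
#' @param ds A \code{genotype_dataset}.
#' @param group_labels Group per individual.
#' @param pc_grid Candidate numbers of retained PCs.
#' @param n_perm Label permutations per grid point.
#' @param seed Optional seed.
#' @return A list: \code{best_n_pcs} (argmax of the a-score) and
#'   \code{curve} (data frame with n_pcs, observed success, null success,
#'   a_score).
#' @export
a_score_optimize <- function(ds, group_labels, pc_grid, n_perm = 10,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ds$genotypes)
  pc_grid <- pc_grid[pc_grid <= min(n - 1, ncol(ds$genotypes))]
  pca_max <- pca_reduce(ds, max(pc_grid))
  success <- function(scores, labels) {
    model <- fit_dapc(scores, labels)
    mean(posterior_membership(model, scores)$assigned ==
           as.character(factor(labels, labels = model$groups)))
  }
  rows <- lapply(pc_grid, function(np) {
    sc <- pca_max$scores[, seq_len(np), drop = FALSE]
    obs <- success(sc, group_labels)
    null <- vapply(seq_len(n_perm), function(b)
      success(sc, sample(group_labels)), 0)
    data.frame(n_pcs = np, observed = obs, null_mean = mean(null),
               a_score = obs - mean(null))
  })
  curve <- do.call(rbind, rows)
  list(best_n_pcs = curve$n_pcs[which.max(curve$a_score)], curve = curve)
}

#' Recode sample positions on two discriminant functions as red/green
#'
#' Min-max scales the sample mean coordinates on DF1 to a red intensity and
#' DF2 to a green intensity across samples, for map-style visualization of
#' the genetic continuum. An axis on which all samples coincide maps to 0.5.
#'
#' @param coords Matrix or data frame of per-sample mean DF coordinates
#'   (samples x at least 2 columns).
#' @return Data frame with \code{red} and \code{green} in [0, 1].
#' @export
df_to_rgb <- function(coords) {
  coords <- as.matrix(coords)
  if (!nrow(coords)) stop("need at least one sample")
  scale01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0.5, length(v)))
    (v - rng[1]) / diff(rng)
  }
  data.frame(red = scale01(coords[, 1]), green = scale01(coords[, 2]),
             row.names = rownames(coords))
}

#' Per-locus allele loadings on the discriminant functions
#'
#' Composes the DF axes back through the PCA rotation to per-locus squared
#' loadings, normalized to sum to 1 within each DF. Loci with large loadings
#' drive the discrimination along that function.
#'
#' @param model A \code{dapc_model} fitted with its \code{pca} attached.
#' @return Matrix (loci x DFs) of squared, per-DF-normalized loadings.
#' @export
allele_loadings <- function(model) {
  if (is.null(model$pca)) {
    stop("model must carry its pca_reduction (fit_dapc(..., pca = ))")
  }
  raw <- model$pca$rotation %*% model$df_axes
  sq <- raw^2
  sweep(sq, 2, colSums(sq), "/")
}
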