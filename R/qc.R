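#' Iterative call-rate filter
#'
#' Drops individuals with call rate at or below \code{sample_min} and loci
#' with call rate at or below \code{locus_min}, re-computing rates after each
#' pass until no further drops occur. The fixed point is order-independent,
#' so it does not matter whether samples or loci are filtered first. The
#' retention rule is strict (call rate must exceed the threshold).
#'
#' @param ds A \code{genotype_dataset}.
#' @param sample_min,locus_min Call-rate thresholds in [0, 1]; the study
#'   convention is 0.7 for both.
#' @return A list with the filtered \code{dataset} and a \code{report} of
#'   class \code{qc_report} listing every dropped individual and locus with
#'   the call rate that triggered the drop.
#' @export
filter_call_rate <- function(ds, sample_min = 0.7, locus_min = 0.7) {
  stopifnot(sample_min >= 0, sample_min <= 1, locus_min >= 0, locus_min <= 1)
  g <- ds$genotypes
  keep_i <- seq_len(nrow(g))
  keep_j <- seq_len(ncol(g))
  dropped_samples <- data.frame(individual_id = character(0),
                                call_rate = numeric(0))
  dropped_loci <- data.frame(locus_id = character(0), call_rate = numeric(0))
  repeat {
    sub <- g[keep_i, keep_j, drop = FALSE]
    if (!length(sub)) break
    cr_i <- rowMeans(!is.na(sub))
    cr_j <- colMeans(!is.na(sub))
    bad_i <- cr_i <= sample_min
    bad_j <- cr_j <= locus_min
    if (!any(bad_i) && !any(bad_j)) break
    if (any(bad_i)) {
      dropped_samples <- rbind(dropped_samples, data.frame(
        individual_id = ds$samples$individual_id[keep_i[bad_i]],
        call_rate = unname(cr_i[bad_i])))
    }
    if (any(bad_j)) {
      dropped_loci <- rbind(dropped_loci, data.frame(
        locus_id = ds$loci$locus_id[keep_j[bad_j]],
        call_rate = unname(cr_j[bad_j])))
    }
    keep_i <- keep_i[!bad_i]
    keep_j <- keep_j[!bad_j]
  }
  if (!length(keep_i) || !length(keep_j)) {
    stop("call-rate filter removed all data")
  }
  out <- subset_dataset(ds, individuals = keep_i, loci = keep_j)
  report <- structure(list(
    rule = sprintf("call rate > %g (samples), > %g (loci), iterated",
                   sample_min, locus_min),
    sample_call_rate = rowMeans(!is.na(out$genotypes)),
    locus_call_rate = colMeans(!is.na(out$genotypes)),
    dropped_samples = dropped_samples,
    dropped_loci = dropped_loci
  ), class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$rule, "\n")
  cat("  dropped individuals:", nrow(x$dropped_samples),
      "| dropped loci:", nrow(x$dropped_loci), "\n")
  invisible(x)
}

#' Replicate-concordance filter
#'
#' Per-locus genotyping concordance over replicate assay pairs: the number of
#' identical calls divided by the number of pairs where both members were
#' successfully genotyped at the locus. Loci with concordance strictly below
#' \code{min_concordance} are discarded; loci with no informative pair cannot
#' be judged and are retained (flagged \code{NA}). The second member of every
#' replicate pair is removed from the analysis dataset so that replicated
#' individuals are not double-counted downstream.
#'
#' @param ds A \code{genotype_dataset}.
#' @param replicate_pairs Two-column matrix or data frame of individual ids;
#'   each row one replicate pair.
#' @param min_concordance Discard threshold; loci at exactly the threshold
#'   are retained (strict \code{<} rule, study convention 0.9).
#' @return A list with the filtered \code{dataset}, the \code{report}
#'   (\code{qc_report} with per-locus \code{concordance}), and the
#'   \code{concordance} vector itself.
#' @export
concordance_filter <- function(ds, replicate_pairs, min_concordance = 0.9) {
  pairs <- as.matrix(replicate_pairs)
  if (ncol(pairs) != 2) stop("replicate_pairs must have two columns")
  i1 <- match(pairs[, 1], ds$samples$individual_id)
  i2 <- match(pairs[, 2], ds$samples$individual_id)
  if (anyNA(i1) || anyNA(i2)) {
    missing <- c(pairs[, 1][is.na(i1)], pairs[, 2][is.na(i2)])
    stop("replicate pair names absent individual(s): ",
         paste(unique(missing), collapse = ", "))
  }
  g <- ds$genotypes
  a <- g[i1, , drop = FALSE]
  b <- g[i2, , drop = FALSE]
  both <- !is.na(a) & !is.na(b)
  agree <- both & (a == b)
  n_inf <- colSums(both)
  conc <- ifelse(n_inf > 0, colSums(agree) / n_inf, NA_real_)
  drop_loci <- which(!is.na(conc) & conc < min_concordance)
  keep_loci <- setdiff(seq_len(ncol(g)), drop_loci)
  keep_inds <- setdiff(seq_len(nrow(g)), i2)
  out <- subset_dataset(ds, individuals = keep_inds, loci = keep_loci)
  report <- structure(list(
    rule = sprintf("replicate concordance >= %g; second pair member removed",
                   min_concordance),
    concordance = stats::setNames(conc, ds$loci$locus_id),
    informative_pairs = stats::setNames(n_inf, ds$loci$locus_id),
    dropped_samples = data.frame(individual_id =
                                   ds$samples$individual_id[i2]),
    dropped_loci = data.frame(locus_id = ds$loci$locus_id[drop_loci],
                              concordance = unname(conc[drop_loci]))
  ), class = "qc_report")
  list(dataset = out, report = report, concordance = conc)
}

#' Per-sample summary statistics
#'
#' One row per population sample: number of individuals, number of variable
#' loci (loci showing at least two observed genotype classes in the sample),
#' percent missing calls, and mean observed and expected heterozygosity over
#' the loci variable in that sample. Expected heterozygosity uses the
#' small-sample unbiased estimator \eqn{2p(1-p) \cdot 2n/(2n-1)} from the
#' non-missing calls at each locus.
#'
#' @param ds A \code{genotype_dataset}.
#' @return Data frame with columns \code{sample_code}, \code{location},
#'   \code{year}, \code{era}, \code{n}, \code{var_loci}, \code{missing_pct},
#'   \code{hobs}, \code{hexp}.
#' @export
summarize_samples <- function(ds) {
  if (!nrow(ds$genotypes)) stop("empty dataset")
  codes <- unique(ds$samples$sample_code)
  rows <- lapply(codes, function(sc) {
    idx <- sample_rows(ds, sc)
    g <- ds$genotypes[idx, , drop = FALSE]
    n_obs <- colSums(!is.na(g))
    n_classes <- apply(g, 2, function(col) length(unique(col[!is.na(col)])))
    variable <- n_classes >= 2
    p <- colSums(g, na.rm = TRUE) / (2 * n_obs)
    hobs <- colMeans(g == 1, na.rm = TRUE)
    hexp <- 2 * p * (1 - p) * (2 * n_obs) / (2 * n_obs - 1)
    meta <- ds$samples[idx[1], ]
    data.frame(
      sample_code = sc,
      location = meta$location,
      year = meta$year,
      era = meta$era,
      n = length(idx),
      var_loci = sum(variable),
      missing_pct = 100 * mean(is.na(g)),
      hobs = if (any(variable)) mean(hobs[variable]) else NA_real_,
      hexp = if (any(variable)) mean(hexp[variable]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
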