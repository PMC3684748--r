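#' Construct a genotype dataset
#'
#' The central container for all analyses: a diploid biallelic SNP genotype
#' matrix coded as alternate-allele dosage (0, 1, 2, or \code{NA} for a
#' missing call), with per-individual sample metadata and per-locus metadata.
#'
#' @param genotypes Integer matrix, individuals in rows and loci in columns.
#'   Values must be 0, 1, 2 or \code{NA}.
#' @param samples Data frame with one row per individual and columns
#'   \code{individual_id}, \code{sample_code}, \code{location}, \code{year},
#'   \code{era} (\code{"historical"} or \code{"contemporary"}) and
#'   \code{region}.
#' @param loci Data frame with one row per locus and columns \code{locus_id},
#'   \code{linkage_group} (integer 1-23 or \code{NA}), \code{cm_position},
#'   \code{ref_allele}, \code{alt_allele}. Missing columns are filled with
#'   \code{NA}.
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(genotypes, samples, loci = NULL) {
  genotypes <- as.matrix(genotypes)
  mode(genotypes) <- "integer"
  if (is.null(loci)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- sprintf("locus%04d", seq_len(ncol(genotypes)))
    loci <- data.frame(locus_id = ids, stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  for (col in c("sample_code", "location", "region")) {
    if (is.null(samples[[col]])) samples[[col]] <- NA_character_
  }
  if (is.null(samples$year)) samples$year <- NA_integer_
  samples$year <- as.integer(samples$year)
  if (is.null(samples$era)) {
    samples$era <- ifelse(samples$year < 2000, "historical", "contemporary")
  }
  for (col in c("linkage_group", "cm_position")) {
    if (is.null(loci[[col]])) loci[[col]] <- NA_real_
  }
  for (col in c("ref_allele", "alt_allele")) {
    if (is.null(loci[[col]])) loci[[col]] <- NA_character_
  }
  rownames(genotypes) <- samples$individual_id
  colnames(genotypes) <- loci$locus_id
  ds <- structure(
    list(genotypes = genotypes, samples = samples, loci = loci),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(ds)
  ds
}

#' Validate a genotype dataset
#'
#' Checks the container invariants: dosage values in \{0, 1, 2, NA\},
#' matching dimensions between the matrix and the metadata tables, unique
#' individual ids, and linkage groups (when known) in 1..23.
#'
#' @param ds A \code{genotype_dataset}.
#' @return The dataset, invisibly; errors describe the violated invariant.
#' @export
validate_genotype_dataset <- function(ds) {
  g <- ds$genotypes
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype values must be 0, 1, 2 or NA")
  }
  if (nrow(g) != nrow(ds$samples)) {
    stop("genotype rows (", nrow(g), ") != sample metadata rows (",
         nrow(ds$samples), ")")
  }
  if (ncol(g) != nrow(ds$loci)) {
    stop("genotype columns (", ncol(g), ") != locus metadata rows (",
         nrow(ds$loci), ")")
  }
  if (anyDuplicated(ds$samples$individual_id)) {
    stop("duplicated individual_id in sample metadata")
  }
  lg <- ds$loci$linkage_group
  lg <- lg[!is.na(lg)]
  if (length(lg) && (any(lg < 1) || any(lg > 23))) {
    stop("linkage_group must be in 1..23 when known")
  }
  bad <- !ds$samples$era %in% c("historical", "contemporary") &
    !is.na(ds$samples$era)
  if (any(bad)) stop("era must be 'historical' or 'contemporary'")
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  g <- x$genotypes
  miss <- if (length(g)) mean(is.na(g)) else 0
  cat("genotype_dataset:", nrow(g), "individuals x", ncol(g), "loci\n")
  cat("  population samples:", length(unique(x$samples$sample_code)), "\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a dataset by individuals and/or loci
#'
#' @param ds A \code{genotype_dataset}.
#' @param individuals Indices, logical mask or individual ids to keep.
#' @param loci Indices, logical mask or locus ids to keep.
#' @return The subsetted \code{genotype_dataset}.
#' @export
subset_dataset <- function(ds, individuals = NULL, loci = NULL) {
  ri <- seq_len(nrow(ds$genotypes))
  ci <- seq_len(ncol(ds$genotypes))
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) {
      match(individuals, ds$samples$individual_id)
    } else ri[individuals]
    if (anyNA(ri)) stop("unknown individual id in subset")
  }
  if (!is.null(loci)) {
    ci <- if (is.character(loci)) match(loci, ds$loci$locus_id) else ci[loci]
    if (anyNA(ci)) stop("unknown locus id in subset")
  }
  genotype_dataset(
    ds$genotypes[ri, ci, drop = FALSE],
    ds$samples[ri, , drop = FALSE],
    ds$loci[ci, , drop = FALSE]
  )
}

#' Individuals belonging to one population sample
#'
#' @param ds A \code{genotype_dataset}.
#' @param sample_code A population sample code (e.g. \code{"DAB34"}).
#' @return Integer row indices into the genotype matrix.
#' @export
sample_rows <- function(ds, sample_code) {
  idx <- which(ds$samples$sample_code == sample_code)
  if (!length(idx)) stop("unknown sample_code: ", sample_code)
  idx
}

# per-column (locus) or per-row (individual) call rates
call_rates <- function(g, margin) {
  ok <- !is.na(g)
  if (margin == 1) rowMeans(ok) else colMeans(ok)
}
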