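#' Sample inventory and SNP-panel constants of the emulated survey
#'
#' The package's synthetic-data defaults emulate a spatiotemporal survey of
#' Atlantic cod spawning grounds around Greenland and Iceland: 29 population
#' samples of 20-39 individuals collected between 1932 and 2010 (plus a
#' western-Atlantic reference sample from Canada), genotyped on a panel of
#' 1152 transcriptome-derived SNPs of which 935 passed quality control; 766
#' panel SNPs carried linkage-map positions and a further 133 were anchored
#' to linkage groups by flanking-sequence alignment, spreading the panel over
#' all 23 cod linkage groups. This function returns that design as data.
#'
#' @return A list: \code{samples} (the per-sample inventory: country,
#'   location, year, sample_code, region, cluster of maximum membership, mean
#'   membership probability, n, variable loci, percent missing, Hobs, He),
#'   \code{panel} (SNP-panel constants), \code{stable_locations} (location
#'   prefixes whose cluster composition stayed stable across eras, used for
#'   the temporal tests), and \code{reference_sample}.
#' @export
study_design <- function() {
  path <- system.file("extdata", "study_samples.tsv", package = "tempodrift",
                      mustWork = TRUE)
  samples <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(
    samples = samples,
    panel = list(
      n_snps_assayed = 1152L,
      n_snps_genotyped = 1011L,
      n_snps_passing = 935L,
      n_mapped = 766L,
      n_blast_anchored = 133L,
      n_linkage_groups = 23L
    ),
    stable_locations = c("DAB", "KAP", "ILL", "UMM"),
    reference_sample = "CAN08"
  )
}

#' Convert elapsed calendar years to Wright-Fisher generations
#'
#' @param year0,year1 Calendar years of the two samples.
#' @param generation_length Years per generation (base case 5).
#' @return Integer generation count, \code{round(|year1 - year0| /
#'   generation_length)}, floored at 1.
#' @export
generations_between <- function(year0, year1, generation_length = 5) {
  max(1L, as.integer(round(abs(year1 - year0) / generation_length)))
}

#' Bookkeeping summary of a study design
#'
#' Derives the design-level quantities the analysis pipeline relies on: the
#' number of pairwise sample comparisons, the number of analyzed individuals
#' excluding the reference sample, the linkage-group-anchored SNP total and
#' its per-group mean, the calendar span of the sampling, and the range of
#' drift generations separating the temporal replicates at the stable
#' locations.
#'
#' @param design A design list as returned by \code{\link{study_design}}.
#' @param generation_length Years per generation for the temporal pairs.
#' @return A list of named scalars: \code{n_samples},
#'   \code{n_pairwise_comparisons}, \code{n_individuals_analyzed},
#'   \code{anchored_snps}, \code{mean_snps_per_lg}, \code{study_span_years},
#'   \code{generations_min}, \code{generations_max}, and
#'   \code{temporal_pairs} (a data frame of the stable-location pairs).
#' @export
study_design_stats <- function(design = study_design(),
                               generation_length = 5) {
  s <- design$samples
  n_samples <- nrow(s)
  not_ref <- s$sample_code != design$reference_sample
  anchored <- design$panel$n_mapped + design$panel$n_blast_anchored
  prefix <- substr(s$sample_code, 1, 3)
  pairs <- lapply(design$stable_locations, function(loc) {
    yrs <- sort(s$year[prefix == loc])
    data.frame(location = loc, year0 = yrs[1], yeart = yrs[length(yrs)],
               t_generations = generations_between(yrs[1], yrs[length(yrs)],
                                                   generation_length))
  })
  pairs <- do.call(rbind, pairs)
  list(
    n_samples = n_samples,
    n_pairwise_comparisons = choose(n_samples, 2),
    n_individuals_analyzed = sum(s$n[not_ref]),
    anchored_snps = anchored,
    mean_snps_per_lg = round(anchored / design$panel$n_linkage_groups),
    study_span_years = max(s$year) - min(s$year),
    generations_min = min(pairs$t_generations),
    generations_max = max(pairs$t_generations),
    temporal_pairs = pairs
  )
}
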