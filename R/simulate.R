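#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study design the analysis pipeline assumes: four
#' weakly diverged genetic clusters (background multilocus FST 0.03) typed at
#' 935 biallelic loci spread over 23 linkage groups, with three
#' strongly diverged outlier blocks (on linkage groups 1, 2 and 7), samples
#' of 20-39 individuals per location and year across two eras separated by
#' about 13 generations of drift at Ne = 500, and era-dependent missingness
#' (elevated in historical material).
#'
#' @param n_clusters Number of genetic clusters.
#' @param background_fst F-model divergence of neutral loci.
#' @param n_loci Number of biallelic loci.
#' @param n_linkage_groups Number of linkage groups loci are spread over.
#' @param outlier_blocks List of blocks, each
#'   \code{list(lg =, n_loci =, fst =, rho =)}: a run of contiguous loci on
#'   one linkage group redrawn at elevated divergence and genotyped as a
#'   haplotype block with per-adjacent-pair recombination probability rho.
#' @param selected_loci Data frame (\code{locus}, \code{cluster}, \code{s})
#'   of loci under genic selection in one cluster during the temporal
#'   interval; empty by default.
#' @param samples Data frame (\code{sample_code}, \code{location},
#'   \code{year}, \code{era}, \code{region}, \code{n}) of population samples;
#'   NULL uses the default two-era, pure + mixed design.
#' @param mixture Matrix (samples x clusters) of cluster mixture proportions,
#'   rows summing to 1; NULL uses the default design.
#' @param ne Effective size of every cluster during the temporal interval.
#' @param generation_length Years per generation.
#' @param t_generations Drift generations between the eras.
#' @param missing_rates Named vector: missing-call probability per era.
#' @param genotype_error Per-call probability of a single-step dosage error.
#' @param seed Seed used by every generator stage.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_clusters = 4, background_fst = 0.03, n_loci = 935,
                       n_linkage_groups = 23,
                       outlier_blocks = list(
                         list(lg = 1, n_loci = 20, fst = 0.30, rho = 0.05),
                         list(lg = 2, n_loci = 8, fst = 0.25, rho = 0.05),
                         list(lg = 7, n_loci = 8, fst = 0.25, rho = 0.05)),
                       selected_loci = NULL,
                       samples = NULL, mixture = NULL,
                       ne = 500, generation_length = 5, t_generations = 13,
                       missing_rates = c(historical = 0.046,
                                         contemporary = 0.015),
                       genotype_error = 0.005, seed = 1234) {
  if (is.null(samples)) {
    design <- default_sample_design(n_clusters)
    samples <- design$samples
    mixture <- design$mixture
  }
  if (is.null(mixture)) stop("mixture matrix required with custom samples")
  mixture <- as.matrix(mixture)
  if (nrow(mixture) != nrow(samples) || ncol(mixture) != n_clusters) {
    stop("mixture must be samples x clusters")
  }
  if (any(abs(rowSums(mixture) - 1) > 1e-9)) {
    stop("mixture proportions must sum to 1 per sample")
  }
  if (is.null(selected_loci)) {
    selected_loci <- data.frame(locus = integer(0), cluster = integer(0),
                                s = numeric(0))
  }
  stopifnot(background_fst > 0, background_fst < 0.5,
            all(missing_rates >= 0 & missing_rates <= 1),
            genotype_error >= 0, genotype_error <= 1)
  structure(list(
    n_clusters = n_clusters, background_fst = background_fst,
    n_loci = n_loci, n_linkage_groups = n_linkage_groups,
    outlier_blocks = outlier_blocks, selected_loci = selected_loci,
    samples = samples, mixture = mixture, ne = ne,
    generation_length = generation_length, t_generations = t_generations,
    missing_rates = missing_rates, genotype_error = genotype_error,
    seed = seed
  ), class = "sim_config")
}

# two-era design: one historical and one contemporary pure sample per
# cluster, plus two 50/50 mixed 'offshore' samples; n = 30 per sample
default_sample_design <- function(n_clusters) {
  rows <- list()
  mix <- list()
  for (cl in seq_len(n_clusters)) {
    rows[[length(rows) + 1]] <- data.frame(
      sample_code = sprintf("PUR%d45", cl), location = sprintf("loc%d", cl),
      year = 1945, era = "historical", region = "coastal", n = 30)
    mix[[length(mix) + 1]] <- replace(numeric(n_clusters), cl, 1)
    rows[[length(rows) + 1]] <- data.frame(
      sample_code = sprintf("PUR%d08", cl), location = sprintf("loc%d", cl),
      year = 2008, era = "contemporary", region = "coastal", n = 30)
    mix[[length(mix) + 1]] <- replace(numeric(n_clusters), cl, 1)
  }
  if (n_clusters >= 2) {
    for (spec in list(c("MIX50", 1950, "historical"),
                      c("MIX08", 2008, "contemporary"))) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_code = spec[1], location = "offshore",
        year = as.integer(spec[2]), era = spec[3], region = "offshore",
        n = 30)
      m <- numeric(n_clusters)
      m[1:2] <- 0.5
      mix[[length(mix) + 1]] <- m
    }
  }
  list(samples = do.call(rbind, rows), mixture = do.call(rbind, mix))
}

#' Simulate per-cluster allele frequencies under the F-model
#'
#' Ancestral frequencies are uniform on (0.05, 0.95); each cluster draws its
#' frequency from \eqn{Beta(p(1-F)/F, (1-p)(1-F)/F)} independently, with
#' \eqn{F} the background FST for neutral loci and the elevated block FST for
#' loci inside outlier blocks.
#'
#' @param config A \code{sim_config}.
#' @param seed Seed (defaults to \code{config$seed}).
#' @return A list: \code{freqs} (clusters x loci), \code{loci} (metadata with
#'   linkage groups and block membership), \code{truth} (ancestral
#'   frequencies, block locus indices, parameters).
#' @export
simulate_cluster_frequencies <- function(config, seed = config$seed) {
  set.seed(seed)
  nl <- config$n_loci
  k <- config$n_clusters
  lg <- sort(rep_len(seq_len(config$n_linkage_groups), nl))
  loci <- data.frame(
    locus_id = sprintf("L%04d", seq_len(nl)),
    linkage_group = lg,
    cm_position = stats::ave(seq_len(nl), lg, FUN = seq_along) * 1.5,
    block = 0L,
    stringsAsFactors = FALSE
  )
  fst_per_locus <- rep(config$background_fst, nl)
  for (b in seq_along(config$outlier_blocks)) {
    blk <- config$outlier_blocks[[b]]
    cand <- which(lg == blk$lg)
    if (!length(cand)) {
      stop("linkage group ", blk$lg, " has no loci for its outlier block")
    }
    # cap at the loci the linkage group actually holds
    idx <- cand[seq_len(min(blk$n_loci, length(cand)))]
    loci$block[idx] <- b
    fst_per_locus[idx] <- blk$fst
  }
  anc <- stats::runif(nl, 0.05, 0.95)
  freqs <- matrix(NA_real_, k, nl,
                  dimnames = list(paste0("cluster", seq_len(k)),
                                  loci$locus_id))
  for (j in seq_len(nl)) {
    f <- fst_per_locus[j]
    freqs[, j] <- stats::rbeta(k, anc[j] * (1 - f) / f,
                               (1 - anc[j]) * (1 - f) / f)
  }
  list(freqs = freqs, loci = loci,
       truth = list(ancestral_p = anc, fst_per_locus = fst_per_locus,
                    block_loci = which(loci$block > 0)))
}

# one generation of genic selection favouring the alternate allele
selection_update <- function(p, s) p * (1 + s) / (1 + s * p)

#' Evolve cluster frequencies across the temporal interval
#'
#' Neutral loci drift as binomial resampling of \code{2 ne} allele copies per
#' generation within each cluster; selected loci apply the deterministic
#' genic-selection update \eqn{p' = p(1+s)/(1+sp)} in their cluster before
#' each drift step.
#'
#' @param freqs Clusters x loci frequency matrix (the historical era).
#' @param config A \code{sim_config} (uses \code{ne}, \code{t_generations},
#'   \code{selected_loci}).
#' @param seed Seed (defaults to \code{config$seed + 1}).
#' @return A list: \code{historical} (the input), \code{contemporary} (the
#'   evolved matrix), \code{t_generations}.
#' @export
evolve_temporal <- function(freqs, config, seed = config$seed + 1) {
  stopifnot(config$ne >= 50, config$t_generations >= 1)
  set.seed(seed)
  k <- nrow(freqs)
  p <- freqs
  sel <- config$selected_loci
  for (g in seq_len(config$t_generations)) {
    if (nrow(sel)) {
      for (r in seq_len(nrow(sel))) {
        p[sel$cluster[r], sel$locus[r]] <-
          selection_update(p[sel$cluster[r], sel$locus[r]], sel$s[r])
      }
    }
    for (cl in seq_len(k)) {
      p[cl, ] <- stats::rbinom(ncol(p), 2 * config$ne, p[cl, ]) /
        (2 * config$ne)
    }
  }
  list(historical = freqs, contemporary = p,
       t_generations = config$t_generations)
}

#' Draw individual genotypes for every configured sample
#'
#' Each individual's source cluster is drawn from its sample's mixture
#' proportions; genotypes are binomial(2, p) at the source cluster's
#' era-specific frequencies (Hardy-Weinberg within cluster). Loci inside an
#' outlier block are generated as a haplotype block: per haplotype a latent
#' uniform deviate is carried along the block and redrawn with the block's
#' recombination probability at each adjacent locus pair, so that alleles at
#' neighbouring block loci are correlated.
#'
#' @param era_freqs Output of \code{\link{evolve_temporal}} (or a list with
#'   \code{historical} and \code{contemporary} matrices).
#' @param loci Locus metadata from
#'   \code{\link{simulate_cluster_frequencies}}.
#' @param config A \code{sim_config}.
#' @param seed Seed (defaults to \code{config$seed + 2}).
#' @return A list: \code{dataset} (a clean \code{genotype_dataset}) and
#'   \code{truth} (per-individual source cluster).
#' @export
sample_individuals <- function(era_freqs, loci, config,
                               seed = config$seed + 2) {
  set.seed(seed)
  samples <- config$samples
  nl <- nrow(loci)
  all_g <- list()
  meta <- list()
  source_cluster <- integer(0)
  blocks <- split(seq_len(nl), loci$block)
  blocks[["0"]] <- NULL
  for (i in seq_len(nrow(samples))) {
    info <- samples[i, ]
    freqs <- if (info$era == "historical") era_freqs$historical else
      era_freqs$contemporary
    n <- info$n
    src <- sample.int(config$n_clusters, n, replace = TRUE,
                      prob = config$mixture[i, ])
    g <- matrix(NA_integer_, n, nl)
    for (ind in seq_len(n)) {
      p <- freqs[src[ind], ]
      row <- stats::rbinom(nl, 2, p)
      for (bname in names(blocks)) {
        idx <- blocks[[bname]]
        rho <- config$outlier_blocks[[as.integer(bname)]]$rho
        hap <- matrix(0L, 2, length(idx))
        for (hp in 1:2) {
          u <- stats::runif(1)
          for (jj in seq_along(idx)) {
            if (jj > 1 && stats::runif(1) < rho) u <- stats::runif(1)
            hap[hp, jj] <- as.integer(u < p[idx[jj]])
          }
        }
        row[idx] <- hap[1, ] + hap[2, ]
      }
      g[ind, ] <- row
    }
    ids <- sprintf("%s_%03d", info$sample_code, seq_len(n))
    all_g[[i]] <- g
    meta[[i]] <- data.frame(
      individual_id = ids, sample_code = info$sample_code,
      location = info$location, year = info$year, era = info$era,
      region = info$region, stringsAsFactors = FALSE)
    source_cluster <- c(source_cluster, src)
  }
  g <- do.call(rbind, all_g)
  sample_meta <- do.call(rbind, meta)
  ds <- genotype_dataset(g, sample_meta,
                         loci[, c("locus_id", "linkage_group",
                                  "cm_position")])
  list(dataset = ds,
       truth = list(source_cluster = stats::setNames(
         source_cluster, sample_meta$individual_id)))
}

#' Degrade a clean dataset with missingness and genotyping error
#'
#' Each call is set missing independently at its sample's era-specific rate;
#' each surviving call is perturbed by a single dosage step (0 and 2 move to
#' 1; 1 moves to 0 or 2 with equal probability) at the genotype error rate.
#'
#' @param ds A \code{genotype_dataset}.
#' @param config A \code{sim_config} (uses \code{missing_rates} and
#'   \code{genotype_error}).
#' @param seed Seed (defaults to \code{config$seed + 3}).
#' @return The degraded \code{genotype_dataset}.
#' @export
degrade <- function(ds, config, seed = config$seed + 3) {
  set.seed(seed)
  g <- ds$genotypes
  rate <- config$missing_rates[ds$samples$era]
  miss <- matrix(stats::runif(length(g)), nrow(g)) < rate
  g[miss] <- NA_integer_
  if (config$genotype_error > 0) {
    err <- matrix(stats::runif(length(g)), nrow(g)) < config$genotype_error
    err <- err & !is.na(g)
    up <- matrix(stats::runif(length(g)), nrow(g)) < 0.5
    new <- g
    new[err & g == 0] <- 1L
    new[err & g == 2] <- 1L
    sel1 <- err & g == 1
    new[sel1 & up] <- 2L
    new[sel1 & !up] <- 0L
    g <- new
  }
  genotype_dataset(g, ds$samples, ds$loci)
}

#' Generate a complete synthetic study dataset
#'
#' Runs the full generator: F-model cluster frequencies, temporal drift (and
#' selection, if configured), individual sampling with mixture and haplotype
#' blocks, and era-dependent degradation. Deterministic given
#' \code{config$seed}.
#'
#' @param config A \code{sim_config}.
#' @return A list: \code{dataset} (degraded), \code{clean} (pre-degradation),
#'   \code{truth} (ancestral and era frequencies, per-individual source
#'   clusters, selected loci, parameters), \code{config}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  base <- simulate_cluster_frequencies(config)
  eras <- evolve_temporal(base$freqs, config)
  drawn <- sample_individuals(eras, base$loci, config)
  degraded <- degrade(drawn$dataset, config)
  list(
    dataset = degraded,
    clean = drawn$dataset,
    truth = c(base$truth,
              list(historical_freqs = eras$historical,
                   contemporary_freqs = eras$contemporary,
                   source_cluster = drawn$truth$source_cluster,
                   selected_loci = config$selected_loci)),
    config = config
  )
}
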