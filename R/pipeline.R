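#' Pipeline run configuration
#'
#' Bundles every threshold and parameter the staged pipeline uses, with the
#' study conventions as defaults: call rate > 0.7, replicate concordance
#' >= 0.9, sample purity > 0.6, LD pruning at mean r-squared > 0.1,
#' significance at q < 0.05, generation length 5 years, and 1e5 simulated
#' null loci for the temporal test.
#'
#' @param input Path to the genotype file consumed by the \code{qc} stage
#'   (the \code{simulate} stage writes one).
#' @param format Genotype file format: \code{"tsv"}, \code{"genepop"} or
#'   \code{"vcf"}.
#' @param sample_meta Optional sample-metadata sidecar path.
#' @param out_dir Directory all stage artifacts are written under.
#' @param call_rate,concordance,purity,ld_threshold,q_threshold Analysis
#'   thresholds.
#' @param generation_length,n_sim,window,n_bins Temporal-test parameters.
#' @param n_pcs,k_max Clustering parameters (retained PCs; BIC scan upper K).
#' @param temporal_pairs Optional data frame (\code{s0}, \code{st}) of sample
#'   pairs for the temporal stage; by default every location sampled in both
#'   eras is paired (earliest vs latest year).
#' @param sim A \code{sim_config} for the \code{simulate} stage.
#' @param seed Integer seed recorded in every manifest.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(input = NULL, format = "tsv", sample_meta = NULL,
                       out_dir = "tempodrift_out", call_rate = 0.7,
                       concordance = 0.9, purity = 0.6, ld_threshold = 0.1,
                       q_threshold = 0.05, generation_length = 5,
                       n_sim = 1e5, window = 5000, n_bins = 25, n_pcs = 20,
                       k_max = 10, temporal_pairs = NULL, sim = NULL,
                       seed = 1234L) {
  cfg <- list(input = input, format = format, sample_meta = sample_meta,
              out_dir = out_dir, call_rate = call_rate,
              concordance = concordance, purity = purity,
              ld_threshold = ld_threshold, q_threshold = q_threshold,
              generation_length = generation_length, n_sim = n_sim,
              window = window, n_bins = n_bins, n_pcs = n_pcs,
              k_max = k_max, temporal_pairs = temporal_pairs,
              sim = if (is.null(sim)) sim_config(seed = seed) else sim,
              seed = as.integer(seed))
  for (f in c("call_rate", "concordance", "purity", "ld_threshold",
              "q_threshold")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop(config_error(f))
    }
  }
  if (cfg$generation_length <= 0) stop(config_error("generation_length"))
  if (cfg$n_sim < 1 || cfg$window < 1) stop(config_error("n_sim/window"))
  structure(cfg, class = "run_config")
}

config_error <- function(field) {
  structure(class = c("tempodrift_invalid_config", "error", "condition"),
            list(message = paste0("invalid config field: ", field),
                 call = NULL, field = field))
}

input_error <- function(path) {
  structure(class = c("tempodrift_missing_input", "error", "condition"),
            list(message = paste0("missing input: ", path), call = NULL,
                 path = path))
}

stage_path <- function(config, ...) file.path(config$out_dir, ...)

write_manifest <- function(config, stage, inputs, outputs, parameters) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("tempodrift")),
    seed = config$seed,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = outputs,
    parameters = parameters
  )
  path <- stage_path(config, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

write_stage_tsv <- function(x, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    suppressWarnings(utils::write.table(x, path, sep = "\t",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
  } else {
    utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  path
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (write a synthetic dataset), \code{qc} (call-rate
#' filtering), \code{stats} (per-sample summaries, pairwise FST and
#' allele-frequency chi-square tests with q-values), \code{cluster} (PCA,
#' K-means/BIC, DAPC membership, purity, red/green recoding, loadings),
#' \code{temporal} (temporal outlier test and Ne estimate per temporal
#' sample pair), and \code{report} (aggregate per-sample summary). Every
#' stage writes its artifacts plus a JSON manifest (input hashes, parameters,
#' seed, package version) under \code{config$out_dir} and never mutates its
#' inputs.
#'
#' @param stage One of \code{"simulate"}, \code{"qc"}, \code{"stats"},
#'   \code{"cluster"}, \code{"temporal"}, \code{"report"}.
#' @param config A \code{run_config}.
#' @return Invisibly, a list with the stage's main in-memory results and
#'   \code{manifest} path. Signals a \code{tempodrift_missing_input} or
#'   \code{tempodrift_invalid_config} condition on failure.
#' @export
run_stage <- function(stage = c("simulate", "qc", "stats", "cluster",
                                "temporal", "report"),
                      config = run_config()) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    simulate = stage_simulate(config),
    qc = stage_qc(config),
    stats = stage_stats(config),
    cluster = stage_cluster(config),
    temporal = stage_temporal(config),
    report = stage_report(config)
  )
}

stage_simulate <- function(config) {
  sim <- simulate_dataset(config$sim)
  gpath <- stage_path(config, "genotypes.tsv")
  mpath <- stage_path(config, "samples.tsv")
  write_genotypes(sim$dataset, gpath, "tsv", sample_meta = mpath)
  tpath <- stage_path(config, "truth.json")
  jsonlite::write_json(list(
    source_cluster = as.list(sim$truth$source_cluster),
    selected_loci = sim$truth$selected_loci,
    parameters = config$sim[setdiff(names(config$sim),
                                    c("samples", "mixture"))]
  ), tpath, auto_unbox = TRUE, digits = NA)
  manifest <- write_manifest(config, "simulate", character(0),
                             c(gpath, mpath, tpath),
                             list(seed = config$sim$seed))
  invisible(list(dataset = sim$dataset, truth = sim$truth,
                 manifest = manifest))
}

load_stage_input <- function(config, preferred) {
  for (p in preferred) if (file.exists(p)) {
    meta <- sub("genotypes", "samples", p)
    return(read_genotypes(p, "tsv", sample_meta =
                            if (file.exists(meta)) meta else NULL))
  }
  if (!is.null(config$input)) {
    if (!file.exists(config$input)) stop(input_error(config$input))
    return(read_genotypes(config$input, config$format,
                          sample_meta = config$sample_meta))
  }
  stop(input_error(preferred[1]))
}

stage_qc <- function(config) {
  ds <- load_stage_input(config, stage_path(config, "genotypes.tsv"))
  filtered <- filter_call_rate(ds, config$call_rate, config$call_rate)
  gpath <- stage_path(config, "genotypes_qc.tsv")
  mpath <- stage_path(config, "samples_qc.tsv")
  write_genotypes(filtered$dataset, gpath, "tsv", sample_meta = mpath)
  ds_drop <- filtered$report$dropped_samples
  dl_drop <- filtered$report$dropped_loci
  rep_path <- write_stage_tsv(
    data.frame(
      item = c(ds_drop$individual_id, dl_drop$locus_id),
      type = c(rep("individual", nrow(ds_drop)), rep("locus", nrow(dl_drop))),
      value = c(ds_drop$call_rate, dl_drop$call_rate),
      rule = rep("call_rate", nrow(ds_drop) + nrow(dl_drop))),
    stage_path(config, "qc_dropped.tsv"))
  inp <- stage_path(config, "genotypes.tsv")
  manifest <- write_manifest(config, "qc",
                             if (file.exists(inp)) inp else config$input,
                             c(gpath, mpath, rep_path),
                             list(call_rate = config$call_rate))
  invisible(list(dataset = filtered$dataset, report = filtered$report,
                 manifest = manifest))
}

stage_stats <- function(config) {
  ds <- load_stage_input(config, stage_path(config, c("genotypes_qc.tsv",
                                                      "genotypes.tsv")))
  summary <- summarize_samples(ds)
  spath <- write_stage_tsv(summary, stage_path(config, "sample_summary.tsv"))
  codes <- unique(ds$samples$sample_code)
  fst <- fst_matrix(ds, codes)
  fpath <- write_stage_tsv(data.frame(sample_code = rownames(fst), fst,
                                      check.names = FALSE),
                           stage_path(config, "fst_matrix.tsv"))
  tests <- list()
  for (i in seq_along(codes)[-length(codes)]) {
    for (j in (i + 1):length(codes)) {
      tr <- chifish_test(ds, codes[i], codes[j])
      tests[[length(tests) + 1]] <- data.frame(
        s1 = codes[i], s2 = codes[j], statistic = tr$statistic, df = tr$df,
        p_value = tr$p_value)
    }
  }
  tests <- do.call(rbind, tests)
  ok <- !is.na(tests$p_value)
  tests$q_value <- NA_real_
  if (any(ok)) tests$q_value[ok] <- qvalues(tests$p_value[ok])
  tpath <- write_stage_tsv(tests, stage_path(config, "pairwise_tests.tsv"))
  manifest <- write_manifest(config, "stats",
                             stage_path(config, "genotypes_qc.tsv"),
                             c(spath, fpath, tpath),
                             list(q_threshold = config$q_threshold))
  invisible(list(summary = summary, fst = fst, tests = tests,
                 manifest = manifest))
}

stage_cluster <- function(config) {
  ds <- load_stage_input(config, stage_path(config, c("genotypes_qc.tsv",
                                                      "genotypes.tsv")))
  set.seed(config$seed)
  n_pcs <- min(config$n_pcs, nrow(ds$genotypes) - 1, ncol(ds$genotypes))
  pca <- pca_reduce(ds, n_pcs)
  scan <- kmeans_bic_scan(pca$scores, k_range = seq_len(config$k_max),
                          seed = config$seed)
  groups <- scan$assignments[[paste0("K", scan$best_k)]]
  model <- fit_dapc(pca$scores, groups, pca = pca)
  memb <- posterior_membership(model, pca$scores,
                               sample_codes = ds$samples$sample_code,
                               purity_threshold = config$purity)
  bpath <- write_stage_tsv(scan$table, stage_path(config, "bic_curve.tsv"))
  mpath <- write_stage_tsv(
    data.frame(individual_id = ds$samples$individual_id,
               sample_code = ds$samples$sample_code, memb$prob,
               assigned = memb$assigned, check.names = FALSE),
    stage_path(config, "membership.tsv"))
  sample_coords <- apply(memb$df_coords, 2, tapply,
                         ds$samples$sample_code, mean)
  if (is.null(dim(sample_coords))) {
    sample_coords <- matrix(sample_coords, nrow = 1)
  }
  rgb <- if (ncol(sample_coords) >= 2) df_to_rgb(sample_coords) else NULL
  spath <- write_stage_tsv(
    data.frame(sample_code = rownames(memb$sample_means),
               memb$sample_means, purity = memb$purity,
               check.names = FALSE),
    stage_path(config, "sample_membership.tsv"))
  lpath <- write_stage_tsv(
    data.frame(locus_id = ds$loci$locus_id, allele_loadings(model),
               check.names = FALSE),
    stage_path(config, "loadings.tsv"))
  outputs <- c(bpath, mpath, spath, lpath)
  if (!is.null(rgb)) {
    outputs <- c(outputs, write_stage_tsv(
      data.frame(sample_code = rownames(sample_coords), rgb),
      stage_path(config, "sample_rgb.tsv")))
  }
  manifest <- write_manifest(config, "cluster",
                             stage_path(config, "genotypes_qc.tsv"),
                             outputs,
                             list(n_pcs = n_pcs, k_max = config$k_max,
                                  best_k = scan$best_k,
                                  purity = config$purity))
  invisible(list(pca = pca, scan = scan, model = model, membership = memb,
                 manifest = manifest))
}

default_temporal_pairs <- function(ds) {
  s <- unique(ds$samples[, c("sample_code", "location", "year")])
  out <- list()
  for (loc in unique(s$location)) {
    sub <- s[s$location == loc, ]
    if (length(unique(sub$year)) < 2) next
    sub <- sub[order(sub$year), ]
    out[[loc]] <- data.frame(s0 = sub$sample_code[1],
                             st = sub$sample_code[nrow(sub)])
  }
  do.call(rbind, out)
}

stage_temporal <- function(config) {
  ds <- load_stage_input(config, stage_path(config, c("genotypes_qc.tsv",
                                                      "genotypes.tsv")))
  pairs <- config$temporal_pairs
  if (is.null(pairs)) pairs <- default_temporal_pairs(ds)
  if (is.null(pairs) || !nrow(pairs)) {
    stop(input_error("no temporal sample pairs available"))
  }
  results <- list()
  outputs <- character(0)
  ne_rows <- list()
  for (r in seq_len(nrow(pairs))) {
    res <- temporal_outlier_test(
      ds, pairs$s0[r], pairs$st[r],
      generation_length = config$generation_length, n_sim = config$n_sim,
      window = config$window, n_bins = config$n_bins, seed = config$seed + r)
    tag <- paste0(pairs$s0[r], "_", pairs$st[r])
    header <- sprintf(
      "ne=%.0f t=%d s0=%d st=%d n_sim=%d window=%d seed=%d",
      res$ne_used, res$cloud_params$t, res$cloud_params$s0,
      res$cloud_params$st, config$n_sim, config$window, config$seed + r)
    outputs <- c(outputs,
      write_stage_tsv(res$outliers,
                      stage_path(config, paste0("outliers_", tag, ".tsv")),
                      header = header),
      write_stage_tsv(
        data.frame(bin_midpoint = res$envelope$midpoints,
                   res$envelope$quantile_matrix, check.names = FALSE),
        stage_path(config, paste0("envelope_", tag, ".tsv")),
        header = header))
    ne_rows[[tag]] <- data.frame(
      pair = tag,
      ne_point = if (is.null(res$ne)) NA else res$ne$ne_point,
      ne_lower = if (is.null(res$ne)) NA else res$ne$ci95[["lower"]],
      ne_upper = if (is.null(res$ne)) NA else res$ne$ci95[["upper"]],
      fc_mean = if (is.null(res$ne)) NA else res$ne$fc_mean,
      n_loci = if (is.null(res$ne)) NA else res$ne$n_loci_used,
      t_generations = res$pair$t_generations,
      n_outliers_q05 = sum(res$outliers$q_value < config$q_threshold))
    results[[tag]] <- res
  }
  npath <- write_stage_tsv(do.call(rbind, ne_rows),
                           stage_path(config, "ne_report.tsv"),
                           header = sprintf("seed=%d n_sim=%d",
                                            config$seed, config$n_sim))
  manifest <- write_manifest(config, "temporal",
                             stage_path(config, "genotypes_qc.tsv"),
                             c(outputs, npath),
                             list(generation_length =
                                    config$generation_length,
                                  n_sim = config$n_sim,
                                  window = config$window,
                                  q_threshold = config$q_threshold))
  invisible(list(results = results, manifest = manifest))
}

stage_report <- function(config) {
  spath <- stage_path(config, "sample_summary.tsv")
  if (!file.exists(spath)) stop(input_error(spath))
  summary <- utils::read.delim(spath)
  mpath <- stage_path(config, "sample_membership.tsv")
  if (file.exists(mpath)) {
    memb <- utils::read.delim(mpath)
    groups <- setdiff(names(memb), c("sample_code", "purity"))
    summary$membership_prob <- apply(
      memb[match(summary$sample_code, memb$sample_code), groups,
           drop = FALSE], 1, max)
    summary$cluster <- groups[apply(
      memb[match(summary$sample_code, memb$sample_code), groups,
           drop = FALSE], 1, which.max)]
    summary$purity <- memb$purity[match(summary$sample_code,
                                        memb$sample_code)]
  }
  rpath <- write_stage_tsv(summary, stage_path(config, "report.tsv"))
  manifest <- write_manifest(config, "report", spath, rpath, list())
  invisible(list(report = summary, manifest = manifest))
}
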