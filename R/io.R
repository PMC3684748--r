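#' Read a genotype dataset from VCF, Genepop or TSV
#'
#' All formats are reduced to the same internal representation:
#' alternate-allele dosage 0/1/2 with \code{NA} for missing calls; phase is
#' discarded. VCF input is restricted to biallelic SNP records with a GT
#' field; other records are skipped and counted. Formats that carry no sample
#' metadata (all three) take a sidecar metadata table.
#'
#' @param path Path to the genotype file.
#' @param format One of \code{"tsv"}, \code{"genepop"}, \code{"vcf"}.
#' @param sample_meta Optional path to a tab-separated sample metadata table
#'   with columns \code{individual_id}, \code{sample_code}, \code{location},
#'   \code{year}, \code{era}, \code{region}.
#' @param locus_meta Optional path to a tab-separated locus metadata table
#'   with columns \code{locus_id}, \code{linkage_group}, \code{cm_position}.
#' @return A \code{genotype_dataset}. The number of skipped VCF records is
#'   attached as attribute \code{"skipped_records"}.
#' @export
read_genotypes <- function(path, format = c("tsv", "genepop", "vcf"),
                           sample_meta = NULL, locus_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- switch(format,
    tsv = read_genotypes_tsv(path),
    genepop = read_genotypes_genepop(path),
    vcf = read_genotypes_vcf(path)
  )
  samples <- parsed$samples
  if (!is.null(sample_meta)) {
    meta <- read_sample_meta(sample_meta)
    idx <- match(samples$individual_id, meta$individual_id)
    if (anyNA(idx)) {
      stop("sample metadata lacks rows for: ",
           paste(samples$individual_id[is.na(idx)][1:3], collapse = ", "))
    }
    samples <- meta[idx, , drop = FALSE]
    rownames(samples) <- NULL
  }
  loci <- parsed$loci
  if (!is.null(locus_meta)) {
    lmeta <- utils::read.delim(locus_meta, stringsAsFactors = FALSE)
    if (!"locus_id" %in% names(lmeta)) {
      stop("locus metadata table lacks required column: locus_id")
    }
    idx <- match(loci$locus_id, lmeta$locus_id)
    for (col in setdiff(names(lmeta), "locus_id")) {
      loci[[col]] <- lmeta[[col]][idx]
    }
  }
  ds <- genotype_dataset(parsed$genotypes, samples, loci)
  attr(ds, "skipped_records") <- parsed$skipped
  ds
}

read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("individual_id", "sample_code", "location", "year", "era",
                "region")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("sample metadata table missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  meta
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"individual_id" %in% names(tab)) {
    stop("genotype TSV must have an 'individual_id' column: ", path)
  }
  ids <- as.character(tab$individual_id)
  g <- as.matrix(tab[, setdiff(names(tab), "individual_id"), drop = FALSE])
  mode(g) <- "integer"
  bad <- which(!(is.na(g) | g %in% 0:2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid genotype value at row ", bad[1, 1] + 1, ", column ",
         colnames(g)[bad[1, 2]], " of ", path)
  }
  rownames(g) <- ids
  list(
    genotypes = g,
    samples = data.frame(individual_id = ids, stringsAsFactors = FALSE),
    loci = data.frame(locus_id = colnames(g), stringsAsFactors = FALSE),
    skipped = 0L
  )
}

# Genepop with 2-digit allele coding: allele 01 = reference, 02 = alternate,
# "0000" = missing. Dosage is the number of 02 alleles.
read_genotypes_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a parseable Genepop file: ", path)
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_idx)) stop("Genepop file has no POP line: ", path)
  header <- lines[2:(pop_idx[1] - 1)]
  locus_ids <- trimws(unlist(strsplit(paste(header, collapse = ","), ",")))
  locus_ids <- locus_ids[nzchar(locus_ids)]
  ids <- character(0)
  pops <- integer(0)
  rows <- list()
  pop <- 0L
  for (i in seq((pop_idx[1]), length(lines))) {
    line <- lines[i]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop <- pop + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2) {
      stop("unparseable Genepop record at line ", i, ": ", line)
    }
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(locus_ids)) {
      stop("Genepop record at line ", i, " has ", length(codes),
           " genotypes; expected ", length(locus_ids))
    }
    a1 <- substr(codes, 1, 2)
    a2 <- substr(codes, 3, 4)
    dos <- (a1 == "02") + (a2 == "02")
    dos[a1 == "00" | a2 == "00"] <- NA_integer_
    ids <- c(ids, id)
    pops <- c(pops, pop)
    rows[[length(rows) + 1L]] <- dos
  }
  g <- do.call(rbind, rows)
  mode(g) <- "integer"
  rownames(g) <- ids
  colnames(g) <- locus_ids
  list(
    genotypes = g,
    samples = data.frame(individual_id = ids,
                         sample_code = sprintf("pop%02d", pops),
                         stringsAsFactors = FALSE),
    loci = data.frame(locus_id = locus_ids, stringsAsFactors = FALSE),
    skipped = 0L
  )
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  skipped <- sum(!keep)
  if (skipped) {
    message("skipped ", skipped, " non-biallelic-SNP VCF record(s)")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # count alternate alleles in the GT string; any missing allele -> NA
  dosage_of <- function(s) {
    out <- rep(NA_integer_, length(s))
    known <- !is.na(s) & !grepl("\\.", s)
    alleles <- gsub("[^01]", "", s[known])
    out[known] <- vapply(strsplit(alleles, ""),
                         function(a) sum(a == "1"), 0L)
    out
  }
  g <- apply(gt, 2, dosage_of)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  g <- t(g)  # individuals x loci
  ids <- colnames(gt)
  locus_ids <- fix[, "ID"]
  blank <- is.na(locus_ids) | locus_ids == "."
  locus_ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  rownames(g) <- ids
  colnames(g) <- locus_ids
  lg <- suppressWarnings(as.integer(sub("^LG", "", fix[, "CHROM"])))
  list(
    genotypes = g,
    samples = data.frame(individual_id = ids, stringsAsFactors = FALSE),
    loci = data.frame(locus_id = locus_ids,
                      linkage_group = ifelse(lg >= 1 & lg <= 23, lg, NA),
                      ref_allele = ref[keep], alt_allele = alt[keep],
                      stringsAsFactors = FALSE),
    skipped = skipped
  )
}

#' Write a genotype dataset to VCF, Genepop or TSV
#'
#' @param ds A \code{genotype_dataset}.
#' @param path Output file path.
#' @param format One of \code{"tsv"}, \code{"genepop"}, \code{"vcf"}.
#' @param sample_meta Optional path: also write the sample metadata sidecar.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(ds, path, format = c("tsv", "genepop", "vcf"),
                            sample_meta = NULL) {
  format <- match.arg(format)
  switch(format,
    tsv = write_genotypes_tsv(ds, path),
    genepop = write_genotypes_genepop(ds, path),
    vcf = write_genotypes_vcf(ds, path)
  )
  if (!is.null(sample_meta)) {
    utils::write.table(ds$samples, sample_meta, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

write_genotypes_tsv <- function(ds, path) {
  tab <- data.frame(individual_id = ds$samples$individual_id,
                    ds$genotypes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

write_genotypes_genepop <- function(ds, path) {
  g <- ds$genotypes
  code <- matrix("0000", nrow(g), ncol(g))
  code[!is.na(g) & g == 0] <- "0101"
  code[!is.na(g) & g == 1] <- "0102"
  code[!is.na(g) & g == 2] <- "0202"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("tempodrift genepop export", con)
  writeLines(ds$loci$locus_id, con)
  codes <- ds$samples$sample_code
  for (sc in unique(codes)) {
    writeLines("POP", con)
    for (i in which(codes == sc)) {
      writeLines(paste0(ds$samples$individual_id[i], " ,  ",
                        paste(code[i, ], collapse = " ")), con)
    }
  }
}

write_genotypes_vcf <- function(ds, path) {
  g <- ds$genotypes
  ref <- ds$loci$ref_allele
  alt <- ds$loci$alt_allele
  ref[is.na(ref)] <- "A"
  alt[is.na(alt)] <- "C"
  chrom <- ifelse(is.na(ds$loci$linkage_group), ".",
                  paste0("LG", ds$loci$linkage_group))
  pos <- ds$loci$cm_position
  pos <- ifelse(is.na(pos), seq_len(ncol(g)), as.integer(round(pos * 1e4)) + 1)
  gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=tempodrift",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ds$samples$individual_id),
                     collapse = "\t")), con)
  for (j in seq_len(ncol(g))) {
    calls <- ifelse(is.na(g[, j]), "./.", gtmap[as.character(g[, j])])
    writeLines(paste(c(chrom[j], pos[j], ds$loci$locus_id[j], ref[j], alt[j],
                       ".", "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
}
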