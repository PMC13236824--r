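# TSV/VCF/JSON dialects shared by the pipeline stages. Every table is
# written with a provenance comment header (config hash, seed, package
# version) which readers skip.

write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (nm in names(provenance)) {
      writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
    }
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

provenance_header <- function(seed = NULL, config = NULL) {
  h <- list(package = paste0("metaboprs ", as.character(utils::packageVersion("metaboprs"))))
  if (!is.null(seed)) h$seed <- seed
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$out_dir <- NULL
    h$config_hash <- content_hash(cfg)
  }
  h
}

#' Write a dosage matrix as TSV (samples in rows)
#' @param dosages A `dosage_matrix`.
#' @param path Output path.
#' @param provenance Optional named list written as `#` header lines.
#' @return The path, invisibly.
#' @export
write_dosage_tsv <- function(dosages, path, provenance = NULL) {
  df <- data.frame(sample_id = rownames(dosages$dosage),
                   dosages$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, provenance)
}

#' Read a samples-by-variants dosage TSV
#' @param path Input path (first column `sample_id`).
#' @param counted_allele Named allele vector; defaults to `"?"` per variant
#'   (alignment then relies on variant IDs and explicit weights alleles).
#' @return A `dosage_matrix`.
#' @export
read_dosage_tsv <- function(path, counted_allele = NULL) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.null(counted_allele)) {
    counted_allele <- setNames(rep("?", ncol(m)), colnames(m))
  }
  dosage_matrix(m, counted_allele)
}

#' Write genotype dosages as a minimal VCF with a DS FORMAT field
#'
#' REF is the variant's other allele and ALT its risk allele; the DS field
#' stores the ALT (risk-allele) dosage.
#'
#' @param dosages A `dosage_matrix` (risk-allele oriented).
#' @param weights Matching `variant_weights` (for chrom/pos/alleles).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dosage_vcf <- function(dosages, weights, path) {
  ids <- colnames(dosages$dosage)
  w <- weights[match(ids, weights$variant_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alternate allele dosage">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dosages$dosage)),
                     collapse = "\t")), con)
  body <- vapply(seq_along(ids), function(j) {
    paste(c(w$chrom[j], w$pos[j], ids[j], w$other_allele[j], w$risk_allele[j],
            ".", "PASS", ".", "DS",
            formatC(dosages$dosage[, j], format = "g", digits = 6)),
          collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF with per-sample DS dosages
#'
#' Parses the minimal dialect written by [write_dosage_vcf()] (and any VCF
#' whose FORMAT contains a DS field). The counted allele is ALT.
#'
#' @param path VCF path (uncompressed).
#' @return A `dosage_matrix` with `counted_allele` = ALT per variant.
#' @export
read_dosage_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path, call. = FALSE)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t")
  ids <- vapply(parts, `[`, "", 3)
  alt <- vapply(parts, `[`, "", 5)
  dmat <- matrix(NA_real_, length(samples), length(parts),
                 dimnames = list(samples, ids))
  for (v in seq_along(parts)) {
    fmt <- strsplit(parts[[v]][9], ":")[[1]]
    ds_idx <- match("DS", fmt)
    if (is.na(ds_idx)) stop("no DS field for variant ", ids[v], call. = FALSE)
    vals <- parts[[v]][-(1:9)]
    if (length(fmt) > 1) {
      vals <- vapply(strsplit(vals, ":"), `[`, "", ds_idx)
    }
    dmat[, v] <- as.numeric(vals)
  }
  dosage_matrix(dmat, setNames(alt, ids))
}

#' Write a metabolite matrix TSV (empty cell = missing)
#' @param x A `metabolite_matrix`.
#' @param path Output TSV path; a sidecar `<path>.json` records the stage.
#' @param provenance Optional header list.
#' @return The path, invisibly.
#' @export
write_metabolite_tsv <- function(x, path, provenance = NULL) {
  df <- data.frame(sample_id = rownames(x$abundance), x$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  if (!is.null(provenance)) {
    for (nm in names(provenance)) {
      writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
    }
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  close(con)
  jsonlite::write_json(list(stage = x$stage), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a metabolite matrix TSV
#' @param path TSV path; stage read from the sidecar JSON when present.
#' @return A `metabolite_matrix`.
#' @export
read_metabolite_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", ""))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stage <- "raw"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    stage <- jsonlite::read_json(sidecar)$stage
  }
  metabolite_matrix(m, stage)
}

#' Write all synthetic cohort inputs to a directory
#'
#' Emits the five input dialects the pipeline reads (weights, dosage TSV +
#' minimal VCF, metabolite matrix + annotation, covariates, phenotype) and
#' the ground-truth JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_header(cohort$config$seed, cohort$config)
  w <- cohort$weights
  w$OR <- w$odds_ratio
  write_tsv(w[, c("variant_id", "chrom", "pos", "risk_allele",
                  "other_allele", "OR", "cluster")],
            file.path(dir, "weights.tsv"), prov)
  write_dosage_tsv(cohort$dosages, file.path(dir, "dosages.tsv"), prov)
  write_dosage_vcf(cohort$dosages, cohort$weights,
                   file.path(dir, "dosages.vcf"))
  write_metabolite_tsv(cohort$metabolites, file.path(dir, "metabolites.tsv"),
                       prov)
  write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"), prov)
  write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"), prov)
  write_tsv(cohort$phenotype, file.path(dir, "phenotype.tsv"), prov)
  truth <- cohort$truth
  truth$latent <- NULL  # matrices go to TSV, not JSON
  truth$genetic_effects <- lapply(truth$genetic_effects, function(m)
    list(variants = rownames(m), metabolites = colnames(m),
         effects = unname(as.data.frame(m))))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
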