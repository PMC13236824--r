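#' Pipeline run configuration
#'
#' Collects input paths, thresholds, mediation settings, stage switches,
#' the output directory and the master seed. Thresholds must lie in (0,1)
#' and every referenced input path must exist at validation time.
#'
#' @param paths Named list of input paths: `weights`, `dosages` (TSV or
#'   VCF), `metabolites`, `annotation`, `covariates`, `phenotype`. May be
#'   `NULL` when a cohort object is passed to [run_pipeline()] directly.
#' @param out_dir Output directory.
#' @param fdr_threshold Association/mediation FDR threshold.
#' @param het_p_threshold,het_i2_threshold Heterogeneity flag thresholds.
#' @param n_sims Mediation draws per triplet.
#' @param seed Master seed.
#' @param do_subsets Run the sensitivity-subset rescans.
#' @param do_mediation Run the mediation screen.
#' @param do_joint Run elastic-net joint mediation per eligible score.
#' @param do_disease Run prevalent/incident disease associations.
#' @param fdr_family Passed to [scan_associations()].
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(paths = NULL, out_dir = tempfile("metaboprs_run_"),
                       fdr_threshold = 0.05, het_p_threshold = 0.05,
                       het_i2_threshold = 0.75, n_sims = 1000, seed = 1L,
                       do_subsets = TRUE, do_mediation = TRUE,
                       do_joint = TRUE, do_disease = TRUE,
                       fdr_family = "per_score") {
  cfg <- list(paths = paths, out_dir = out_dir,
              fdr_threshold = fdr_threshold,
              het_p_threshold = het_p_threshold,
              het_i2_threshold = het_i2_threshold,
              n_sims = n_sims, seed = as.integer(seed),
              do_subsets = do_subsets, do_mediation = do_mediation,
              do_joint = do_joint, do_disease = do_disease,
              fdr_family = fdr_family)
  for (th in c("fdr_threshold", "het_p_threshold", "het_i2_threshold")) {
    if (cfg[[th]] <= 0 || cfg[[th]] >= 1) {
      stop(th, " must lie in (0,1)", call. = FALSE)
    }
  }
  if (!is.null(paths)) {
    missing_files <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing_files)) {
      stop("input paths do not exist: ",
           paste(missing_files, collapse = ", "), call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

read_cohort_dir_inputs <- function(paths) {
  weights <- load_weights(paths$weights)
  dosages <- if (grepl("\\.vcf$", paths$dosages)) {
    read_dosage_vcf(paths$dosages)
  } else {
    read_dosage_tsv(paths$dosages,
                    setNames(weights$risk_allele, weights$variant_id))
  }
  list(weights = weights, dosages = dosages,
       metabolites = read_metabolite_tsv(paths$metabolites),
       annotation = read_tsv(paths$annotation),
       covariates = read_tsv(paths$covariates),
       phenotype = read_tsv(paths$phenotype))
}

#' Run the three-stage pipeline end to end
#'
#' Stage 1: allele alignment, score construction, metabolite
#' transformation and the metabolome-wide association scan (plus
#' sensitivity subsets and the overall-score-adjusted rescan). Stage 2:
#' cross-cluster heterogeneity and class/pathway enrichment. Stage 3:
#' quasi-Bayesian mediation of score-to-incident-disease associations and
#' the elastic-net joint metabolite score. Writes every table and a
#' summary JSON under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param cohort Optional in-memory cohort (as from [simulate_cohort()]);
#'   when `NULL` the inputs are read from `config$paths`.
#' @return List of class `run_summary` (also written as `summary.json`).
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load_inputs"
  result <- tryCatch({
    if (is.null(cohort)) {
      cohort <- read_cohort_dir_inputs(config$paths)
    }
    prov <- provenance_header(config$seed, config)
    log <- list()

    stage <- "prs_engine"
    aligned <- align_alleles(cohort$dosages, cohort$weights)
    log$variants <- as.list(table(aligned$report$status))
    covars <- cohort$covariates
    complete <- complete.cases(covars[, c("bmi", "smoking", "lipid_med")])
    log$samples_excluded_missing_covariates <- sum(!complete)
    covars <- covars[complete, , drop = FALSE]
    dos <- aligned$dosages
    dos$dosage <- dos$dosage[covars$sample_id, , drop = FALSE]
    pcs <- as.matrix(covars[, paste0("PC", 1:10)])
    scores <- compute_score_set(dos, cohort$weights, pcs = pcs)
    write_tsv(scores, file.path(config$out_dir, "scores.tsv"), prov)
    write_tsv(aligned$report, file.path(config$out_dir, "alignment_report.tsv"),
              prov)

    stage <- "metabolite_prep"
    met_raw <- cohort$metabolites
    met_raw$abundance <- met_raw$abundance[covars$sample_id, , drop = FALSE]
    norm <- prep_metabolites(met_raw, covars, cohort$annotation)
    log$metabolites_removed <- nrow(attr(
      filter_missingness(met_raw, annotation = cohort$annotation),
      "removal_log"))
    write_metabolite_tsv(norm, file.path(config$out_dir,
                                         "metabolites_normalized.tsv"), prov)

    stage <- "association_scan"
    assoc <- scan_associations(scores, norm, subset_tag = "all",
                               fdr_family = config$fdr_family)
    assoc_all <- assoc
    if (config$do_subsets) {
      subsets <- list(
        no_baseline_t2d = covars$baseline_t2d == 0,
        NGT = covars$ngt == 1,
        baseline_t2d = covars$baseline_t2d == 1
      )
      for (tag in names(subsets)) {
        keep <- subsets[[tag]]
        if (sum(keep) < 50) next
        sub_cov <- covars[keep, , drop = FALSE]
        sub_raw <- cohort$metabolites
        sub_raw$abundance <- sub_raw$abundance[sub_cov$sample_id, , drop = FALSE]
        cs <- metabolite_covariate_set()
        if (tag != "all" && length(unique(sub_cov$baseline_t2d)) == 1) {
          cs <- setdiff(cs, "baseline_t2d")
        }
        sub_norm <- prep_metabolites(sub_raw, sub_cov, cohort$annotation,
                                     covariate_set = cs)
        sub_pcs <- as.matrix(sub_cov[, paste0("PC", 1:10)])
        sub_scores <- data.frame(sample_id = sub_cov$sample_id,
                                 stringsAsFactors = FALSE)
        for (nm in c("oPRS", intersect(cluster_labels(),
                                       unique(cohort$weights$cluster)))) {
          sub_scores[[paste0("std_", nm)]] <-
            residual_standardize(scores[[paste0("raw_", nm)]][keep], sub_pcs)
        }
        sub_assoc <- scan_associations(sub_scores, sub_norm, subset_tag = tag,
                                       fdr_family = config$fdr_family)
        assoc_all <- rbind(assoc_all, sub_assoc)
      }
      # partitioned scores re-scanned with the overall score in the model
      oadj <- scan_associations(scores, norm,
                                score_ids = intersect(cluster_labels(),
                                                      unique(cohort$weights$cluster)),
                                subset_tag = "oPRS_adjusted",
                                extra_covariates = matrix(scores$std_oPRS, ncol = 1,
                                                          dimnames = list(scores$sample_id, "oPRS")),
                                fdr_family = config$fdr_family)
      assoc_all <- rbind(assoc_all, oadj)
    }
    write_tsv(assoc_all, file.path(config$out_dir, "associations.tsv"), prov)

    stage <- "heterogeneity"
    het <- heterogeneity_scan(assoc, q_threshold = config$fdr_threshold,
                              p_threshold = config$het_p_threshold,
                              i2_threshold = config$het_i2_threshold)
    write_tsv(het, file.path(config$out_dir, "heterogeneity.tsv"), prov)
    cand <- select_heterogeneity_candidates(assoc, config$fdr_threshold)
    sig_any <- unique(c(cand$single_cluster, cand$multi_cluster))
    pca_out <- NULL
    if (length(sig_any) >= 3) {
      pp <- assoc[assoc$score_id %in% cluster_labels() &
                    assoc$metabolite_id %in% sig_any, ]
      bm <- tapply(pp$beta, list(pp$score_id, pp$metabolite_id), mean)
      bm <- bm[rowSums(is.na(bm)) == 0, , drop = FALSE]
      if (nrow(bm) >= 2) {
        pca_out <- association_pca(bm)
        write_tsv(data.frame(cluster = rownames(pca_out$coordinates),
                             pca_out$coordinates, check.names = FALSE),
                  file.path(config$out_dir, "association_pca.tsv"), prov)
      }
    }

    stage <- "enrichment"
    enr <- enrich_scan(assoc, cohort$annotation,
                       q_threshold = config$fdr_threshold)
    write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"), prov)
    lipid_cor <- lipid_feature_correlation(assoc, cohort$annotation)
    write_tsv(lipid_cor, file.path(config$out_dir, "lipid_features.tsv"), prov)

    stage <- "disease_association"
    disease <- NULL
    if (config$do_disease) {
      sig_ids <- unique(assoc$metabolite_id[!assoc$error & !is.na(assoc$q) &
                                              assoc$q < config$fdr_threshold])
      if (length(sig_ids)) {
        dn <- norm
        dn$abundance <- dn$abundance[, sig_ids, drop = FALSE]
        pheno <- cohort$phenotype[match(covars$sample_id,
                                        cohort$phenotype$sample_id), ]
        disease <- disease_association(dn, pheno, covars)
        write_tsv(disease, file.path(config$out_dir,
                                     "disease_associations.tsv"), prov)
      }
    }

    stage <- "mediation"
    med <- NULL; joint <- list()
    if (config$do_mediation) {
      pheno <- cohort$phenotype[match(covars$sample_id,
                                      cohort$phenotype$sample_id), ]
      med_cohort <- list(covariates = covars, phenotype = pheno,
                         metabolites = met_raw, annotation = cohort$annotation,
                         scores = scores)
      med <- mediation_screen(assoc, med_cohort, n_sims = config$n_sims,
                              seed = config$seed,
                              q_threshold = config$fdr_threshold)
      if (!is.null(med) && nrow(med)) {
        write_tsv(med, file.path(config$out_dir, "mediation.tsv"), prov)
      }
      if (config$do_joint && !is.null(med) && nrow(med)) {
        sig_per_score <- table(assoc$score_id[!assoc$error & !is.na(assoc$q) &
                                                assoc$q < config$fdr_threshold])
        for (sid in names(sig_per_score)[sig_per_score >= 2]) {
          joint[[sid]] <- joint_mediation(sid, assoc, med_cohort,
                                          split_seed = config$seed,
                                          n_sims = config$n_sims,
                                          q_threshold = config$fdr_threshold)
        }
        if (length(joint)) {
          jw <- lapply(joint, function(j) {
            list(score_id = j$score_id,
                 selected_metabolites = j$selected_metabolites,
                 elastic_net_weights = as.list(j$elastic_net_weights),
                 validation_acme = j$validation_acme,
                 validation_total = j$validation_total,
                 validation_prop_pct = j$validation_prop_pct)
          })
          jsonlite::write_json(jw, file.path(config$out_dir,
                                             "joint_mediation.json"),
                               auto_unbox = TRUE, digits = NA)
        }
      }
    }

    stage <- "summary"
    summary <- build_run_summary(config, assoc, het, enr, med, joint, log)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    structure(list(summary = summary, assoc = assoc_all, heterogeneity = het,
                   enrichment = enr, mediation = med, joint = joint,
                   disease = disease, pca = pca_out, scores = scores,
                   out_dir = config$out_dir),
              class = "run_summary")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

build_run_summary <- function(config, assoc, het, enr, med, joint, log) {
  q <- config$fdr_threshold
  sig <- assoc[!assoc$error & !is.na(assoc$q) & assoc$q < q, , drop = FALSE]
  per_score <- as.list(table(sig$score_id))
  overlap <- summarize_overlap(assoc, q_threshold = q)
  med_summary <- NULL
  if (!is.null(med) && nrow(med)) {
    ok <- !is.na(med$prop_mediated_pct) & !med$suppression_flag &
      med$total > 0 & med$acme > 0
    med_summary <- list(
      n_triplets = nrow(med),
      n_suppression = sum(med$suppression_flag, na.rm = TRUE),
      n_significant_acme = sum(med$q_acme < q, na.rm = TRUE),
      median_prop_mediated_pct =
        if (any(ok)) stats::median(med$prop_mediated_pct[ok]) else NA
    )
  }
  joint_summary <- lapply(joint, function(j) {
    list(n_selected = length(j$selected_metabolites),
         validation_prop_pct = j$validation_prop_pct %||% NA)
  })
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL   # analysis parameters only, not run location
  list(
    seed = config$seed,
    config_hash = content_hash(cfg_for_hash),
    log = log,
    n_metabolites_tested = length(unique(assoc$metabolite_id)),
    significant_per_score = per_score,
    overlap = overlap,
    n_heterogeneity_tested = nrow(het),
    n_heterogeneous = sum(het$heterogeneous_flag),
    n_enriched_groups = if (nrow(enr)) sum(enr$significant) else 0L,
    n_enriched_pathways = if (nrow(enr))
      sum(enr$significant & enr$level == "pathway") else 0L,
    mediation = med_summary,
    joint_mediation = joint_summary
  )
}

#' Overlap of significant metabolites across the overall and partitioned scores
#'
#' Counts metabolites significant for the overall score only, for at least
#' one partitioned score only, and for both, plus per-cluster significant
#' counts and the multiplicity distribution across clusters.
#'
#' @param assoc Association records (one subset).
#' @param q_threshold FDR threshold.
#' @return Named list of counts.
#' @export
summarize_overlap <- function(assoc, q_threshold = 0.05) {
  sig <- assoc[!assoc$error & !is.na(assoc$q) & assoc$q < q_threshold, ,
               drop = FALSE]
  o_set <- unique(sig$metabolite_id[sig$score_id == "oPRS"])
  p_sig <- sig[sig$score_id %in% cluster_labels(), , drop = FALSE]
  p_set <- unique(p_sig$metabolite_id)
  per_cluster <- lapply(split(p_sig$metabolite_id, p_sig$score_id), unique)
  multiplicity <- table(table(p_sig$metabolite_id))
  list(
    n_oPRS = length(o_set),
    n_pPRS_any = length(p_set),
    n_total_associated = length(union(o_set, p_set)),
    n_both = length(intersect(o_set, p_set)),
    n_oPRS_only = length(setdiff(o_set, p_set)),
    n_pPRS_only = length(setdiff(p_set, o_set)),
    per_cluster = lapply(per_cluster, length),
    cluster_multiplicity = as.list(setNames(as.integer(multiplicity),
                                            names(multiplicity)))
  )
}

#' @export
print.run_summary <- function(x, ...) {
  s <- x$summary
  cat("<run_summary>\n")
  cat(sprintf("  %d metabolites tested; significant: oPRS %d, any pPRS %d (both %d)\n",
              s$n_metabolites_tested, s$overlap$n_oPRS, s$overlap$n_pPRS_any,
              s$overlap$n_both))
  cat(sprintf("  heterogeneous: %d of %d multi-cluster metabolites; enriched groups: %d\n",
              s$n_heterogeneous, s$n_heterogeneity_tested, s$n_enriched_groups))
  if (!is.null(s$mediation)) {
    cat(sprintf("  mediation: %d triplets, %d significant ACME, median mediated %.2f%%\n",
                s$mediation$n_triplets, s$mediation$n_significant_acme,
                s$mediation$median_prop_mediated_pct))
  }
  invisible(x)
}
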