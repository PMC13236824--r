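#' Enrichment fold of a metabolite group among associated metabolites
#'
#' Ratio of the group's proportion among score-associated metabolites to
#' its proportion in the tested universe:
#' `fold = (n_assoc_in_group / n_assoc_total) /
#'         (n_universe_in_group / n_universe_total)`.
#'
#' @param assoc_ids Character vector of associated metabolite IDs (must be
#'   a subset of the universe).
#' @param universe_ids Character vector: all tested metabolites.
#' @param grouping Named character vector (or factor) mapping every
#'   universe metabolite to its group.
#' @return Data frame per group: counts, `fold`, `direction`.
#' @export
enrichment_fold <- function(assoc_ids, universe_ids, grouping) {
  if (!all(assoc_ids %in% universe_ids)) {
    stop("associated metabolites must be a subset of the universe",
         call. = FALSE)
  }
  grouping <- grouping[universe_ids]
  if (anyNA(grouping)) {
    stop("grouping lacks labels for some universe metabolites", call. = FALSE)
  }
  groups <- sort(unique(as.character(grouping)))
  n_u <- length(universe_ids)
  n_a <- length(assoc_ids)
  in_group_u <- vapply(groups, function(g) sum(grouping == g), 0L)
  in_group_a <- vapply(groups, function(g)
    sum(assoc_ids %in% universe_ids[grouping == g]), 0L)
  fold <- if (n_a == 0) rep(0, length(groups)) else
    (in_group_a / n_a) / (in_group_u / n_u)
  data.frame(group_id = groups,
             n_assoc_in_group = unname(in_group_a),
             n_assoc_total = n_a,
             n_universe_in_group = unname(in_group_u),
             n_universe_total = n_u,
             fold = unname(fold),
             direction = ifelse(fold > 1, "enriched", "depleted"),
             stringsAsFactors = FALSE)
}

#' Goodness-of-fit test of an observed in-group count against expectation
#'
#' One-degree-of-freedom chi-square comparing the observed (in-group,
#' out-group) split of associated metabolites to
#' `n_assoc_total * (expected_prop, 1 - expected_prop)`; when any expected
#' count falls below 5 the exact two-sided binomial test is substituted.
#'
#' @param n_assoc_in_group Observed in-group count.
#' @param n_assoc_total Total associated metabolites.
#' @param expected_prop The group's universe proportion, in (0, 1).
#' @return List with `p`, `statistic` (NA for the exact branch) and
#'   `method`.
#' @export
#' @examples
#' gof_test(20, 100, 0.10)  # chi-square 11.111
gof_test <- function(n_assoc_in_group, n_assoc_total, expected_prop) {
  stopifnot(n_assoc_total > 0, expected_prop > 0, expected_prop < 1,
            n_assoc_in_group >= 0, n_assoc_in_group <= n_assoc_total)
  e_in <- n_assoc_total * expected_prop
  e_out <- n_assoc_total * (1 - expected_prop)
  if (min(e_in, e_out) < 5) {
    bt <- binom.test(n_assoc_in_group, n_assoc_total, p = expected_prop)
    return(list(p = bt$p.value, statistic = NA_real_, method = "binomial"))
  }
  o_in <- n_assoc_in_group
  o_out <- n_assoc_total - n_assoc_in_group
  stat <- (o_in - e_in)^2 / e_in + (o_out - e_out)^2 / e_out
  list(p = pchisq(stat, df = 1, lower.tail = FALSE),
       statistic = stat, method = "chi-square")
}

#' Class and pathway enrichment scan over association results
#'
#' For every score with at least one significant metabolite, computes the
#' enrichment fold and goodness-of-fit p for every biochemical class and
#' every metabolic pathway, with Benjamini-Hochberg FDR within each
#' (score, level) family.
#'
#' @param assoc Association records (one subset tag).
#' @param annotation Annotation with `super_class` and `sub_pathway`
#'   covering the whole tested universe.
#' @param q_threshold Significance threshold on association q-values.
#' @return Data frame of enrichment records: `score_id`, `level`,
#'   `group_id`, counts, `fold`, `p`, `q`, `direction`, `significant`.
#' @export
enrich_scan <- function(assoc, annotation, q_threshold = 0.05) {
  universe <- unique(assoc$metabolite_id)
  ann <- annotation[match(universe, annotation$metabolite_id), , drop = FALSE]
  if (anyNA(ann$super_class)) {
    stop("annotation missing for some tested metabolites", call. = FALSE)
  }
  levels_map <- list(class = setNames(ann$super_class, universe),
                     pathway = setNames(ann$sub_pathway, universe))
  rows <- list()
  for (sid in unique(assoc$score_id)) {
    a <- assoc[assoc$score_id == sid & !assoc$error, , drop = FALSE]
    sig <- a$metabolite_id[!is.na(a$q) & a$q < q_threshold]
    if (!length(sig)) next
    for (lv in names(levels_map)) {
      ef <- enrichment_fold(sig, universe, levels_map[[lv]])
      ps <- mapply(function(o, e_prop) {
        if (e_prop >= 1) return(1)  # group spans the whole universe
        gof_test(o, length(sig), e_prop)$p
      }, ef$n_assoc_in_group, ef$n_universe_in_group / ef$n_universe_total)
      ef$p <- unname(ps)
      ef$q <- bh_fdr(ef$p)
      rows[[length(rows) + 1L]] <- cbind(
        score_id = sid, level = lv, ef[, c("group_id", "n_assoc_in_group",
                                           "n_assoc_total", "n_universe_in_group",
                                           "n_universe_total", "fold",
                                           "direction")],
        p = ef$p, q = ef$q, significant = ef$q < q_threshold)
    }
  }
  if (!length(rows)) {
    return(data.frame(score_id = character(0), level = character(0),
                      group_id = character(0), n_assoc_in_group = integer(0),
                      n_assoc_total = integer(0), n_universe_in_group = integer(0),
                      n_universe_total = integer(0), fold = numeric(0),
                      direction = character(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
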