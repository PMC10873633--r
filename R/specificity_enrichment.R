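# Reactivity propagation, clone-size-stratified specificity enrichment,
# exact contingency testing, antibody index, subclass summaries, BCR
# feature statistics and privacy (closest-identity) search.

REACTIVE_LABELS <- c("LGI1", "CASPR2")

#' Propagate clonal reactivity to untested members
#'
#' Members of a clone share antigen reactivity, so the label of tested
#' members is inherited by untested members of the same clone. Tested
#' members with conflicting labels raise an error naming the clone; clones
#' with no tested member are left unchanged and flagged.
#'
#' @param cells Per-cell table with a `reactivity` column
#'   (`"untested"` for untested cells).
#' @param clones Clone table from [cluster_clones()].
#' @return `cells` with two added columns: `reactivity_resolved` and
#'   `reactivity_source` (`"tested"`, `"propagated"` or `"untested"`);
#'   the `unresolved_clones` attribute lists clones without any tested
#'   member.
#' @export
propagate_reactivity <- function(cells, clones) {
  resolved <- cells$reactivity
  source <- ifelse(cells$reactivity == "untested", "untested", "tested")
  unresolved <- character(0)
  idx <- stats::setNames(seq_len(nrow(cells)), cells$cell_id)
  for (i in seq_len(nrow(clones))) {
    mi <- idx[clones$members[[i]]]
    labels <- unique(cells$reactivity[mi])
    tested <- setdiff(labels, "untested")
    if (length(tested) > 1L) {
      stopf("propagate_reactivity: conflicting tested labels in clone %s (%s)",
            clones$clone_id[i], paste(tested, collapse = ", "))
    }
    if (length(tested) == 0L) {
      unresolved <- c(unresolved, clones$clone_id[i])
      next
    }
    untested <- mi[cells$reactivity[mi] == "untested"]
    resolved[untested] <- tested
    source[untested] <- "propagated"
  }
  cells$reactivity_resolved <- resolved
  cells$reactivity_source <- source
  attr(cells, "unresolved_clones") <- unresolved
  cells
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration with the point-probability rule: the
#' two-sided p-value sums the probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed
#' table (within relative tolerance 1e-7, the usual convention for handling
#' floating-point ties).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A list of class `contingency_result` with `table`,
#'   `p_two_sided` and the sample `odds_ratio` (a d) / (b c), `Inf` when
#'   b c = 0 and a d > 0, `NaN` for 0/0.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stopf("fisher_exact: table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stopf("fisher_exact: counts must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("fisher_exact: zero margin")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c          # column-1 total
  n <- b + d          # column-2 total
  k <- a + b          # row-1 total
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or <- (a * d) / (b * c)
  structure(list(table = tab, p_two_sided = p, odds_ratio = or),
            class = "contingency_result")
}

#' Specificity rates stratified by clone size
#'
#' Computes, per clone-size category (singletons, 2-3 members, >= 4
#' members), the fraction of resolvable cells that are autoantigen
#' reactive, and tests the category-by-reactivity association with an
#' exact test. Untested cells (after propagation) are excluded from the
#' rates.
#'
#' @param cells Per-cell table after [propagate_reactivity()].
#' @param clones Clone table from [cluster_clones()].
#' @param reactive_labels Labels counted as autoantigen-reactive.
#' @return A list of class `enrichment_summary`: `per_category`
#'   (`n_tested`, `n_reactive`, `rate`; rate `NA` for empty categories),
#'   `per_donor` rates, and `p_overall` (exact test on the category x
#'   reactivity table).
#' @export
stratify_by_clone_size <- function(cells, clones,
                                   reactive_labels = REACTIVE_LABELS) {
  if (is.null(cells$reactivity_resolved)) {
    stopf("stratify_by_clone_size: run propagate_reactivity() first")
  }
  mem <- clone_membership(clones)
  cat_of_clone <- stats::setNames(clones$size_category, clones$clone_id)
  cells$size_category <- cat_of_clone[mem$clone_id[match(cells$cell_id, mem$cell_id)]]
  tested <- cells[cells$reactivity_resolved != "untested", ]
  tested$reactive <- tested$reactivity_resolved %in% reactive_labels
  cats <- c("singleton", "small", "large")
  per_category <- do.call(rbind, lapply(cats, function(cc) {
    sub <- tested[tested$size_category == cc, ]
    data.frame(size_category = cc, n_tested = nrow(sub),
               n_reactive = sum(sub$reactive),
               rate = if (nrow(sub)) sum(sub$reactive) / nrow(sub) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  per_donor <- tapply(tested$reactive, tested$donor, mean)
  ct <- table(factor(tested$size_category, levels = cats), tested$reactive)
  ct <- ct[rowSums(ct) > 0, , drop = FALSE]
  p_overall <- if (nrow(ct) >= 2L && ncol(ct) == 2L) {
    stats::fisher.test(ct)$p.value
  } else NA_real_
  structure(list(per_category = per_category,
                 per_donor = per_donor, p_overall = p_overall),
            class = "enrichment_summary")
}

#' Specificity rate adjusted for untested singletons
#'
#' Extends the observed reactive fraction by assuming untested singleton
#' BCRs are reactive at the measured singleton rate:
#' (n_reactive + rate_singleton x n_untested) / (n_tested + n_untested).
#'
#' @param n_reactive_total Reactive cells among tested (and propagated).
#' @param n_tested_total Cells with a resolved label.
#' @param n_untested_singletons Untested singleton cells.
#' @param singleton_rate Measured reactive rate among tested singletons.
#' @return Adjusted fraction in \[0, 1\].
#' @export
adjusted_specificity <- function(n_reactive_total, n_tested_total,
                                 n_untested_singletons, singleton_rate) {
  if (min(n_reactive_total, n_tested_total, n_untested_singletons) < 0 ||
      singleton_rate < 0 || singleton_rate > 1) {
    stopf("adjusted_specificity: invalid inputs")
  }
  denom <- n_tested_total + n_untested_singletons
  if (denom == 0) stopf("adjusted_specificity: zero denominator")
  (n_reactive_total + singleton_rate * n_untested_singletons) / denom
}

#' Intrathecal antibody index
#'
#' AI = (autoantibody CSF/serum) / (total IgG CSF/serum); values strictly
#' above 4 indicate intrathecal synthesis of the autoantibody.
#'
#' @param auto_csf,auto_serum Autoantibody levels (same arbitrary units).
#' @param igg_csf,igg_serum Total IgG (mg/L).
#' @param cutoff Intrathecal-synthesis cutoff (strict `>`).
#' @return List with `index` and logical `intrathecal`.
#' @export
antibody_index <- function(auto_csf, auto_serum, igg_csf, igg_serum, cutoff = 4) {
  vals <- c(auto_csf, auto_serum, igg_csf, igg_serum)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stopf("antibody_index: all inputs must be strictly positive")
  }
  ai <- (auto_csf / auto_serum) / (igg_csf / igg_serum)
  list(index = ai, intrathecal = ai > cutoff)
}

#' IgG4 to total IgG ratio
#'
#' @param subclass_levels Named nonnegative levels for IGHG1..IGHG4.
#' @return IGHG4 / sum(IGHG1..IGHG4).
#' @export
igg4_ratio <- function(subclass_levels) {
  need <- c("IGHG1", "IGHG2", "IGHG3", "IGHG4")
  missing <- setdiff(need, names(subclass_levels))
  if (length(missing)) stopf("igg4_ratio: missing %s", paste(missing, collapse = ", "))
  lv <- as.numeric(subclass_levels[need])
  if (any(lv < 0)) stopf("igg4_ratio: negative level")
  total <- sum(lv)
  if (total == 0) stopf("igg4_ratio: all-zero subclass levels")
  lv[4] / total
}

#' Per-clone IgG subclass usage and switch-order violations
#'
#' Counts the distinct IgG subclasses expressed within each clone and, when
#' the founder is known, flags violations of the one-way constant-gene
#' order IGHG3 < IGHG1 < IGHG2 < IGHG4 (a member whose subclass lies
#' upstream of the founder's cannot arise by class switching).
#'
#' @param clones Clone table; a `founder` column enables violation checks.
#' @param cells Per-cell table with `heavy_c_call` in IGHG1..IGHG4.
#' @return A list of class `subclass_summary`: `per_clone`
#'   (`clone_id`, `n_subclasses`), `n_one`, `n_two`, `n_more`, and
#'   `violations` (clone ids with an upstream switch).
#' @export
subclass_switch_summary <- function(clones, cells) {
  cc <- stats::setNames(cells$heavy_c_call, cells$cell_id)
  bad <- setdiff(unique(cc), IGHG_ORDER)
  if (length(bad)) stopf("subclass_switch_summary: unknown c_call '%s'", bad[1])
  rank_of <- stats::setNames(seq_along(IGHG_ORDER), IGHG_ORDER)
  n_sub <- integer(nrow(clones))
  violations <- character(0)
  for (i in seq_len(nrow(clones))) {
    members <- clones$members[[i]]
    subs <- unique(cc[members])
    n_sub[i] <- length(subs)
    if (!is.null(clones$founder)) {
      f_rank <- rank_of[[cc[[clones$founder[i]]]]]
      if (any(rank_of[cc[members]] < f_rank)) {
        violations <- c(violations, clones$clone_id[i])
      }
    }
  }
  structure(list(
    per_clone = data.frame(clone_id = clones$clone_id, n_subclasses = n_sub,
                           stringsAsFactors = FALSE),
    n_one = sum(n_sub == 1L), n_two = sum(n_sub == 2L), n_more = sum(n_sub > 2L),
    violations = violations
  ), class = "subclass_summary")
}

#' Per-cell BCR feature table
#'
#' Ig subclass, CDR3 amino-acid length and net charge, light-chain locus,
#' heavy/light V family, and total mutation count. Charge counts K/R as +1
#' and D/E as -1; histidine contributes `h_charge` (0 by default,
#' consistent with integer median charges; set 0.1 to count partial
#' protonation).
#'
#' @param cells Per-cell table with `heavy_junction_aa` present.
#' @param mutation_counts Optional named per-cell mutation counts.
#' @param h_charge Charge contribution of histidine.
#' @return `data.frame` with one row per cell.
#' @export
bcr_features <- function(cells, mutation_counts = NULL, h_charge = 0) {
  aa_ok <- "^[ACDEFGHIKLMNPQRSTVWYX*]+$"
  charge_of <- function(aa) {
    if (is.na(aa) || !nzchar(aa)) return(NA_real_)
    if (!grepl(aa_ok, aa)) stopf("bcr_features: invalid junction_aa '%s'", aa)
    ch <- strsplit(aa, "")[[1]]
    sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E")) + h_charge * sum(ch == "H")
  }
  data.frame(
    cell_id = cells$cell_id,
    subclass = cells$heavy_c_call,
    cdr3_length = nchar(cells$heavy_junction_aa),
    cdr3_charge = vapply(cells$heavy_junction_aa, charge_of, numeric(1),
                         USE.NAMES = FALSE),
    light_locus = cells$light_locus,
    vh_family = gene_family(cells$heavy_v_call),
    vl_family = gene_family(cells$light_v_call),
    total_mutations = if (is.null(mutation_counts)) NA_integer_
                      else as.integer(mutation_counts[cells$cell_id]),
    stringsAsFactors = FALSE
  )
}

#' Rank correlation between mutation load and binding strength
#'
#' Spearman correlation between total (heavy plus light) mutation counts
#' and log10 endpoint concentration, using one cell per clone (the
#' founder), since clone members are not independent observations. Lower
#' endpoint concentrations indicate stronger binding, so affinity
#' maturation appears as a negative coefficient.
#'
#' @param cells Per-cell table with `endpoint_conc`.
#' @param clones Clone table with a `founder` column.
#' @param mutation_counts Named per-cell mutation counts.
#' @return List with `rho`, `p_value` and `n`; `rho = NA` (not applicable)
#'   when either vector is constant.
#' @export
correlate_mutations_affinity <- function(cells, clones, mutation_counts) {
  if (is.null(clones$founder)) {
    stopf("correlate_mutations_affinity: clones lack founders")
  }
  idx <- match(clones$founder, cells$cell_id)
  conc <- cells$endpoint_conc[idx]
  keep <- !is.na(conc)
  muts <- as.numeric(mutation_counts[clones$founder[keep]])
  logc <- log10(conc[keep])
  if (length(logc) < 3L) stopf("correlate_mutations_affinity: fewer than 3 cells with endpoint concentration")
  if (length(unique(muts)) < 2L || length(unique(logc)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(logc)))
  }
  ct <- suppressWarnings(stats::cor.test(muts, logc, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(logc))
}

#' Closest identity of heavy CDR sequences to a reference repertoire
#'
#' For a query heavy-CDR amino-acid string, returns the maximum percent
#' identity over all equal-length reference strings (length-mismatched
#' references are skipped, as ungapped identity is undefined for them),
#' plus the "private BCR" flag: closest identity strictly below 80%.
#'
#' @param query Amino-acid string (e.g. concatenated heavy CDRs or CDRH3).
#' @param reference Character vector of reference CDR strings.
#' @param private_cutoff Percent identity below which (strictly) the query
#'   counts as private.
#' @return List with `closest_identity` (percent, `NA` when no
#'   length-compatible reference exists) and `private`.
#' @export
closest_identity <- function(query, reference, private_cutoff = 80) {
  if (!length(reference)) stopf("closest_identity: empty reference")
  len <- nchar(query)
  compat <- reference[nchar(reference) == len]
  if (!length(compat)) {
    return(list(closest_identity = NA_real_, private = NA))
  }
  qc <- strsplit(query, "")[[1]]
  ident <- vapply(strsplit(compat, ""), function(rc) sum(rc == qc), numeric(1))
  best <- 100 * max(ident) / len
  list(closest_identity = best, private = best < private_cutoff)
}

#' Synthetic CDR reference repertoire
#'
#' Random amino-acid strings emulating a public heavy-CDR reference set,
#' for testing privacy searches without bundling any real database.
#'
#' @param n Number of reference sequences.
#' @param lengths Candidate lengths, drawn uniformly.
#' @param seed Integer seed.
#' @return Character vector of amino-acid strings.
#' @export
simulate_cdr_reference <- function(n, lengths = 10:20, seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(aa, sample(lengths, 1L), replace = TRUE), collapse = "")
    }, character(1))
  })
}
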