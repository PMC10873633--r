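# UCA reconstruction by germline reversion, mutation counting, normalized
# lineage distances, and the peripheral-versus-intrathecal compartment
# contrast.

#' Reconstruct the unmutated common ancestor (UCA) of a chain
#'
#' Reverts somatic mutations by replacing observed bases with their
#' germline template at templated positions. In `revert_nonsilent` mode
#' (the default) only substitutions that change the encoded amino acid in
#' the observed reading frame are reverted; `revert_all` restores the
#' germline base at every templated mismatch and corresponds to the
#' conventional UCA definition. N-region (non-templated) positions are
#' never modified, since no germline template exists for them.
#'
#' The reading frame is taken from position 1 of the assembled chain
#' (complete V(D)J sequences start at the V codon boundary).
#'
#' @param sequence Observed nucleotide string.
#' @param assignment A `germline_assignment` for this chain.
#' @param mode `"revert_nonsilent"` or `"revert_all"`.
#' @return A list of class `uca_result` with `uca`, `n_reverted`,
#'   `n_region_preserved` and `mode`; `NULL` (with a message) when the
#'   assignment failed.
#' @export
reconstruct_uca <- function(sequence, assignment,
                            mode = c("revert_nonsilent", "revert_all")) {
  mode <- match.arg(mode)
  if (assignment$failed) {
    message("reconstruct_uca: skipping chain with failed germline assignment")
    return(NULL)
  }
  obs <- seq_chars(sequence)
  ref <- assignment$germline_ref
  if (length(ref) != length(obs)) {
    stopf("reconstruct_uca: assignment length does not match sequence")
  }
  uca <- obs
  n_rev <- 0L
  # Sweep to a fixpoint: reverting one substitution can change the coding
  # context of a second substitution in the same codon, so silent/nonsilent
  # status is re-evaluated against the progressively reverted sequence.
  # This makes the reversion idempotent.
  repeat {
    changed <- FALSE
    for (p in which(!is.na(ref) & ref != uca)) {
      revert <- TRUE
      if (mode == "revert_nonsilent") {
        ci <- (p - 1L) %/% 3L
        lo <- ci * 3L + 1L
        hi <- min(lo + 2L, length(uca))
        if (hi - lo == 2L) {
          codon_cur <- uca[lo:hi]
          codon_rev <- codon_cur
          codon_rev[p - lo + 1L] <- ref[p]
          revert <- !identical(translate_chars(codon_cur), translate_chars(codon_rev))
        }  # partial trailing codon: treat as nonsilent
      }
      if (revert) {
        uca[p] <- ref[p]
        n_rev <- n_rev + 1L
        changed <- TRUE
      }
    }
    if (!changed || mode == "revert_all") break
  }
  structure(list(uca = chars_seq(uca), n_reverted = n_rev,
                 n_region_preserved = length(assignment$n_mask), mode = mode),
            class = "uca_result")
}

#' Reconstruct UCAs for every cell
#'
#' @param cells Per-cell table.
#' @param assignments Output of [assign_repertoire()].
#' @param mode Reversion mode, see [reconstruct_uca()].
#' @return `data.frame` with `cell_id`, `uca_heavy`, `uca_light`
#'   (`NA` without a light chain) and total `n_reverted`; cells whose
#'   assignment failed are dropped with a message.
#' @export
reconstruct_uca_repertoire <- function(cells, assignments,
                                       mode = c("revert_nonsilent", "revert_all")) {
  mode <- match.arg(mode)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    asg <- assignments[[cells$cell_id[i]]]
    uh <- reconstruct_uca(cells$heavy_sequence[i], asg$heavy, mode)
    if (is.null(uh)) next
    ul <- NULL
    if (!is.null(asg$light)) {
      ul <- reconstruct_uca(cells$light_sequence[i], asg$light, mode)
    }
    rows[[i]] <- data.frame(
      cell_id = cells$cell_id[i], uca_heavy = uh$uca,
      uca_light = if (is.null(ul)) NA_character_ else ul$uca,
      n_reverted = uh$n_reverted + if (is.null(ul)) 0L else ul$n_reverted,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stopf("reconstruct_uca_repertoire: no cell could be processed")
  rownames(out) <- NULL
  out
}

#' Count somatic mutations between an observed chain and its UCA
#'
#' Hamming distance over templated positions (N-region positions are
#' excluded from the count even if they differ).
#'
#' @param observed,uca Equal-length nucleotide strings.
#' @param n_mask Integer vector of non-templated positions to exclude.
#' @return Integer mutation count.
#' @export
count_mutations <- function(observed, uca, n_mask = integer(0)) {
  if (nchar(observed) != nchar(uca)) {
    stopf("count_mutations: sequences differ in length")
  }
  templated <- setdiff(seq_len(nchar(observed)), n_mask)
  hamming(observed, uca, templated)
}

#' Per-cell total mutation counts against the germline
#'
#' Counts templated mismatches between each observed chain and its assigned
#' germline template, summing heavy and light (when present). This is the
#' count used to designate clone founders.
#'
#' @param cells Per-cell table.
#' @param assignments Output of [assign_repertoire()].
#' @param chains `"heavy_light"` (default) or `"heavy"`.
#' @return Named integer vector by `cell_id` (`NA` for failed assignments).
#' @export
count_mutations_repertoire <- function(cells, assignments,
                                       chains = c("heavy_light", "heavy")) {
  chains <- match.arg(chains)
  counts <- stats::setNames(rep(NA_integer_, nrow(cells)), cells$cell_id)
  count_chain <- function(sequence, asg) {
    if (is.null(asg) || asg$failed) return(NA_integer_)
    obs <- seq_chars(sequence)
    sum(!is.na(asg$germline_ref) & asg$germline_ref != obs)
  }
  for (i in seq_len(nrow(cells))) {
    asg <- assignments[[cells$cell_id[i]]]
    h <- count_chain(cells$heavy_sequence[i], asg$heavy)
    if (chains == "heavy" || is.null(asg$light)) {
      counts[i] <- h
    } else {
      counts[i] <- h + count_chain(cells$light_sequence[i], asg$light)
    }
  }
  counts
}

#' Normalised lineage distance between two equal-length sequences
#'
#' Fraction of mismatching positions, a documented proxy for
#' phylogenetic BCR sequence distances in a substitution-only pipeline.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings.
#' @return Fraction in \[0, 1\].
#' @export
lineage_distance <- function(seq_a, seq_b) {
  la <- nchar(seq_a)
  if (la != nchar(seq_b)) stopf("lineage_distance: sequences differ in length")
  hamming(seq_a, seq_b) / la
}

#' Peripheral versus intrathecal maturation contrast
#'
#' For every clone, compares the normalised heavy-chain distance from the
#' UCA to the intrathecal founder (`d_peripheral`: maturation acquired
#' before CNS entry) with the maximum distance from the founder to any
#' clone member (`d_intrathecal`: maturation acquired inside the CNS;
#' 0 for singletons). The two per-clone distances are compared with a
#' paired two-sided Wilcoxon signed-rank test, overall and stratified by
#' clone size (< 4 versus >= 4 members).
#'
#' @param clones Clone table with a `founder` column
#'   (see [annotate_founders()]).
#' @param cells Per-cell table.
#' @param ucas Output of [reconstruct_uca_repertoire()].
#' @return A list of class `compartment_contrast`: `per_clone`
#'   (`clone_id`, `size`, `d_peripheral`, `d_intrathecal`), medians and
#'   ranges per compartment, `p_value` (paired Wilcoxon; `NA` when every
#'   pair is tied), and `p_by_size` for the two size strata.
#' @export
compartment_contrast <- function(clones, cells, ucas) {
  if (!nrow(clones)) stopf("compartment_contrast: no clones")
  if (is.null(clones$founder)) {
    stopf("compartment_contrast: clones lack founders; run annotate_founders()")
  }
  seq_of <- stats::setNames(cells$heavy_sequence, cells$cell_id)
  uca_of <- stats::setNames(ucas$uca_heavy, ucas$cell_id)
  rows <- vector("list", nrow(clones))
  for (i in seq_len(nrow(clones))) {
    f <- clones$founder[i]
    if (is.na(uca_of[f])) stopf("compartment_contrast: no UCA for founder %s", f)
    d_p <- lineage_distance(uca_of[[f]], seq_of[[f]])
    members <- clones$members[[i]]
    d_i <- 0
    if (length(members) > 1L) {
      d_i <- max(vapply(setdiff(members, f), function(m) {
        lineage_distance(seq_of[[f]], seq_of[[m]])
      }, numeric(1)))
    }
    rows[[i]] <- data.frame(clone_id = clones$clone_id[i],
                            size = clones$size[i],
                            d_peripheral = d_p, d_intrathecal = d_i,
                            stringsAsFactors = FALSE)
  }
  per_clone <- do.call(rbind, rows)
  paired_p <- function(df) {
    if (nrow(df) < 1L || all(df$d_peripheral == df$d_intrathecal)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(df$d_peripheral, df$d_intrathecal,
                                        paired = TRUE, exact = FALSE)$p.value)
  }
  small <- per_clone[per_clone$size < 4L, ]
  large <- per_clone[per_clone$size >= 4L, ]
  structure(list(
    per_clone = per_clone,
    median_peripheral = stats::median(per_clone$d_peripheral),
    median_intrathecal = stats::median(per_clone$d_intrathecal),
    range_peripheral = range(per_clone$d_peripheral),
    range_intrathecal = range(per_clone$d_intrathecal),
    p_value = paired_p(per_clone),
    p_by_size = c(small = paired_p(small), large = paired_p(large))
  ), class = "compartment_contrast")
}
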