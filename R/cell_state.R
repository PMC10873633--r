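# Reference-correlation cell-state classification (memory B cell ->
# preplasmablast -> plasmablast -> plasma cell), XBP1 positivity, and a
# per-donor pseudobulk fold-change screen for reactive-versus-unreactive
# expression differences.

CELL_STATE_LABELS <- c("MBC", "prePB", "PB", "PC")

#' Classify cells against bulk reference expression profiles
#'
#' Each cell is assigned the reference label (MBC, prePB, PB, PC) with the
#' highest Spearman correlation over the most variable shared genes
#' (top `n_var_genes` by reference variance). Rank correlation makes the
#' classification invariant to monotone per-cell transformations of
#' expression. Ties are broken by the fixed label order MBC < prePB < PB <
#' PC; cells with undefined correlations (constant expression) are labelled
#' `"unknown"`. This is a single-pass nearest-reference classifier without
#' iterative marker fine-tuning.
#'
#' @param expr Numeric genes x cells matrix (log-normalised), with gene
#'   symbols as rownames and cell ids as colnames.
#' @param ref Numeric genes x 4 matrix of reference profiles with column
#'   names MBC, prePB, PB, PC.
#' @param n_var_genes Number of variable genes used (default 500).
#' @return A list with `labels` (named by cell) and `scores` (cells x
#'   labels correlation matrix).
#' @export
classify_cells <- function(expr, ref, n_var_genes = 500L) {
  if (!all(CELL_STATE_LABELS %in% colnames(ref))) {
    stopf("classify_cells: reference must have columns %s",
          paste(CELL_STATE_LABELS, collapse = ", "))
  }
  ref <- ref[, CELL_STATE_LABELS, drop = FALSE]
  if (any(expr < 0, na.rm = TRUE)) stopf("classify_cells: negative expression values")
  shared <- intersect(rownames(expr), rownames(ref))
  if (length(shared) < 50L) {
    stopf("classify_cells: only %d shared genes (need >= 50)", length(shared))
  }
  ref_s <- ref[shared, , drop = FALSE]
  v <- apply(ref_s, 1, stats::var)
  top <- shared[order(v, decreasing = TRUE)][seq_len(min(n_var_genes, length(shared)))]
  e <- expr[top, , drop = FALSE]
  r <- ref_s[top, , drop = FALSE]
  scores <- suppressWarnings(stats::cor(e, r, method = "spearman"))
  labels <- apply(scores, 1, function(s) {
    if (all(is.na(s))) return("unknown")
    CELL_STATE_LABELS[which.max(s)]   # which.max takes the first (fixed order) on ties
  })
  list(labels = stats::setNames(labels, colnames(expr)), scores = scores)
}

#' XBP1 positivity of a cell
#'
#' XBP1 is a canonical plasma-cell transcription factor; expression above
#' the threshold (default 0 on the log-normalised scale) flags cells
#' engaging the secretory program.
#'
#' @param expr Genes x cells expression matrix.
#' @param cell_id Column to test.
#' @param threshold Positivity threshold (strict `>`).
#' @return Logical.
#' @export
xbp1_positive <- function(expr, cell_id, threshold = 0) {
  if (!"XBP1" %in% rownames(expr)) stopf("xbp1_positive: XBP1 not in gene list")
  if (!cell_id %in% colnames(expr)) stopf("xbp1_positive: unknown cell '%s'", cell_id)
  expr["XBP1", cell_id] > threshold
}

#' Per-donor pseudobulk fold-change screen
#'
#' For every donor with both reactive and unreactive cells, computes the
#' mean expression per group on the linear scale and the fold change
#' (reactive + 1) / (unreactive + 1) per gene; the reported up-regulated
#' set contains genes whose fold change exceeds `fold_threshold` in every
#' retained donor and never falls below 1 in any. Donors lacking one group
#' are dropped with a warning. This is a deliberately simple
#' consistency-across-donors screen, not a variance-modelled differential
#' expression test.
#'
#' @param expr Genes x cells matrix. Values are used as given; set
#'   `log_input = TRUE` to back-transform log1p values first.
#' @param donor Named (or ordered as `colnames(expr)`) donor per cell.
#' @param reactive Logical per cell.
#' @param fold_threshold Fold-change threshold (default 100).
#' @param log_input Whether `expr` is on the log1p scale.
#' @return List with `per_donor` (list of per-gene fold-change vectors)
#'   and `up_genes`.
#' @export
pseudobulk_contrast <- function(expr, donor, reactive, fold_threshold = 100,
                                log_input = FALSE) {
  if (length(donor) != ncol(expr) || length(reactive) != ncol(expr)) {
    stopf("pseudobulk_contrast: donor/reactive must match columns of expr")
  }
  if (log_input) expr <- expm1(expr)
  donors <- unique(donor)
  per_donor <- list()
  for (d in donors) {
    in_d <- donor == d
    if (!any(in_d & reactive) || !any(in_d & !reactive)) {
      warnf("pseudobulk_contrast: donor '%s' lacks one group; dropped", d)
      next
    }
    m_r <- rowMeans(expr[, in_d & reactive, drop = FALSE])
    m_u <- rowMeans(expr[, in_d & !reactive, drop = FALSE])
    per_donor[[d]] <- (m_r + 1) / (m_u + 1)
  }
  if (!length(per_donor)) stopf("pseudobulk_contrast: no donor has both groups")
  fc <- do.call(cbind, per_donor)
  up <- rownames(expr)[apply(fc, 1, function(x) all(x > fold_threshold)) &
                         apply(fc, 1, function(x) all(x >= 1))]
  list(per_donor = per_donor, up_genes = up)
}

#' Synthetic bulk reference profiles for B-lineage states
#'
#' Builds four distinct mean expression profiles (MBC, prePB, PB, PC) over
#' `n_genes` genes, including an `XBP1` gene expressed highly in the three
#' secretory states and low in memory B cells. Purely synthetic, for
#' simulation and tests.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @return Genes x 4 numeric matrix (log-normalised scale).
#' @export
make_reference_profiles <- function(n_genes = 2000L, seed = 7) {
  with_seed(seed, {
    genes <- c("XBP1", sprintf("G%04d", seq_len(n_genes - 1L)))
    base <- stats::rexp(n_genes, rate = 0.5)
    ref <- sapply(CELL_STATE_LABELS, function(lbl) {
      specific <- sample(n_genes, round(0.15 * n_genes))
      prof <- base
      prof[specific] <- prof[specific] + stats::rexp(length(specific), rate = 0.4)
      prof
    })
    rownames(ref) <- genes
    ref["XBP1", ] <- c(MBC = 0.2, prePB = 4, PB = 5, PC = 5.5)
    ref
  })
}

#' Simulate single-cell expression from reference profiles
#'
#' Cells are drawn as their state's reference profile plus independent
#' Gaussian noise with standard deviation `noise_sd` times the profile's
#' own standard deviation, truncated at zero.
#'
#' @param ref Genes x labels reference matrix.
#' @param labels Character vector of true state labels, one per cell.
#' @param noise_sd Noise level relative to the profile standard deviation.
#' @param seed Integer seed.
#' @return Genes x cells matrix with cell ids `sc_0001`, ...
#' @export
simulate_expression <- function(ref, labels, noise_sd = 0.3, seed = 11) {
  bad <- setdiff(labels, colnames(ref))
  if (length(bad)) stopf("simulate_expression: unknown label '%s'", bad[1])
  with_seed(seed, {
    n <- length(labels)
    out <- vapply(seq_len(n), function(i) {
      prof <- ref[, labels[i]]
      pmax(0, prof + stats::rnorm(nrow(ref), 0, noise_sd * stats::sd(prof)))
    }, numeric(nrow(ref)))
    rownames(out) <- rownames(ref)
    colnames(out) <- sprintf("sc_%04d", seq_len(n))
    out
  })
}
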