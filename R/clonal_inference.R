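# Germline assignment, clonal clustering by junction Hamming distance,
# founder identification, and clonality summaries.

#' Assign best-matched germline V and J segments to a chain
#'
#' Ungapped sliding-offset alignment of every candidate V (anchored near the
#' 5' end) and J (anchored near the 3' end) segment against the assembled
#' chain; the segment maximising identity (matches / aligned length) wins,
#' with ties broken by lexicographically smallest segment id. When the
#' chain's N-region mask is known (simulated or annotated data) the
#' templated V/D/J regions are delimited exactly by the mask and the D
#' segment is placed by best substring match inside the junction interior;
#' without a mask, positions not covered by the V or J alignment are
#' treated as non-templated, which conservatively leaves junction-interior
#' (D and trimmed) positions unreverted downstream.
#'
#' @param sequence Assembled V(D)J nucleotide string (>= 50 nt).
#' @param library A [segment_library()].
#' @param locus Locus of the chain.
#' @param n_mask Optional integer vector (1-based) of known non-templated
#'   positions.
#' @param window Number of alternative alignment offsets searched on each
#'   side of the canonical segment position.
#' @param min_identity Identity below which assignment fails (chain flagged
#'   and excluded downstream).
#' @return A list of class `germline_assignment` with `v_call`, `d_call`,
#'   `j_call`, `v_identity`, `j_identity`, `germline_ref` (per-position
#'   germline template, `NA` at non-templated/unaligned positions),
#'   `n_mask`, and `failed`.
#' @export
assign_germline <- function(sequence, library, locus = "IGH", n_mask = NULL,
                            window = 8L, min_identity = 0.5) {
  assert_dna(sequence)
  L <- nchar(sequence)
  if (L < 50L) stopf("assign_germline: sequence shorter than 50 nt")
  sq <- seq_chars(sequence)
  seg <- library[library$locus == locus, ]

  score_at <- function(gl, offset) {
    ov <- min(length(gl), L - offset + 1L)
    if (ov < 20L) return(list(matches = -1L, overlap = ov))
    m <- sum(gl[seq_len(ov)] == sq[offset + seq_len(ov) - 1L])
    list(matches = m, overlap = ov)
  }
  best_segment <- function(type, offsets_for) {
    cand <- seg[seg$segment_type == type, ]
    cand <- cand[order(cand$segment_id), ]
    best <- NULL
    for (i in seq_len(nrow(cand))) {
      gl <- seq_chars(cand$sequence[i])
      for (o in offsets_for(length(gl))) {
        sc <- score_at(gl, o)
        if (sc$matches < 0L) next
        idt <- sc$matches / sc$overlap
        if (is.null(best) || idt > best$identity + 1e-12) {
          best <- list(segment = cand[i, ], offset = o, identity = idt,
                       overlap = sc$overlap)
        }
      }
    }
    best
  }
  v_best <- best_segment("V", function(gl_len) seq_len(min(window + 1L, L)))
  j_best <- best_segment("J", function(gl_len) {
    canon <- L - gl_len + 1L
    unique(pmax(1L, seq(canon - window, canon + window)))
  })
  failed <- is.null(v_best) || is.null(j_best) ||
    v_best$identity < min_identity || j_best$identity < min_identity
  if (failed) {
    return(structure(list(v_call = NA_character_, d_call = NA_character_,
                          j_call = NA_character_, v_identity = NA_real_,
                          j_identity = NA_real_, germline_ref = rep(NA_character_, L),
                          n_mask = integer(0), failed = TRUE),
                     class = "germline_assignment"))
  }

  ref <- rep(NA_character_, L)
  v_gl <- seq_chars(v_best$segment$sequence)
  v_span <- v_best$offset + seq_len(v_best$overlap) - 1L
  ref[v_span] <- v_gl[seq_len(v_best$overlap)]
  j_gl <- seq_chars(j_best$segment$sequence)
  j_span <- j_best$offset + seq_len(j_best$overlap) - 1L
  ref[j_span] <- j_gl[seq_len(j_best$overlap)]
  d_call <- NA_character_

  if (!is.null(n_mask) && length(n_mask)) {
    n_mask <- sort(as.integer(n_mask))
    if (min(n_mask) < 1L || max(n_mask) > L) {
      stopf("assign_germline: n_mask positions out of sequence bounds")
    }
    # mask delimits the segments exactly: V prefix, junction interior (D), J suffix
    ref <- rep(NA_character_, L)
    v_end <- min(n_mask) - 1L
    j_start <- max(n_mask) + 1L
    if (v_end >= 1L && v_end <= length(v_gl)) ref[seq_len(v_end)] <- v_gl[seq_len(v_end)]
    j_len <- L - j_start + 1L
    if (j_len >= 1L && j_len <= length(j_gl)) {
      ref[j_start:L] <- j_gl[(length(j_gl) - j_len + 1L):length(j_gl)]
    }
    interior <- setdiff(seq(min(n_mask), max(n_mask)), n_mask)
    if (length(interior) && all(diff(interior) == 1L)) {
      dseg <- seg[seg$segment_type == "D", ]
      dseg <- dseg[order(dseg$segment_id), ]
      Lb <- length(interior)
      obs <- sq[interior]
      best_d <- NULL
      for (i in seq_len(nrow(dseg))) {
        dg <- seq_chars(dseg$sequence[i])
        if (length(dg) < Lb) next
        for (s in seq_len(length(dg) - Lb + 1L)) {
          m <- sum(dg[s + seq_len(Lb) - 1L] == obs)
          if (is.null(best_d) || m > best_d$matches) {
            best_d <- list(matches = m, id = dseg$segment_id[i],
                           sub = dg[s + seq_len(Lb) - 1L])
          }
        }
      }
      if (!is.null(best_d)) {
        ref[interior] <- best_d$sub
        d_call <- best_d$id
      }
    }
    mask_used <- n_mask
  } else {
    mask_used <- which(is.na(ref))
  }
  ref[mask_used] <- NA_character_

  structure(list(
    v_call = v_best$segment$segment_id, d_call = d_call,
    j_call = j_best$segment$segment_id,
    v_identity = v_best$identity, j_identity = j_best$identity,
    germline_ref = ref, n_mask = mask_used, failed = FALSE
  ), class = "germline_assignment")
}

#' Assign germlines to every cell of a repertoire
#'
#' Convenience wrapper running [assign_germline()] on the heavy (and, when
#' present, light) chain of every cell, using each chain's recorded
#' N-region mask when available.
#'
#' @param cells Per-cell table.
#' @param library A [segment_library()].
#' @return Named list (by `cell_id`) of lists with `heavy` and `light`
#'   `germline_assignment` objects (`light` may be `NULL`).
#' @export
assign_repertoire <- function(cells, library) {
  out <- vector("list", nrow(cells))
  names(out) <- cells$cell_id
  for (i in seq_len(nrow(cells))) {
    h <- assign_germline(cells$heavy_sequence[i], library, "IGH",
                         n_mask = mask_from_string(cells$heavy_n_mask[i]))
    l <- NULL
    if (!is.na(cells$light_sequence[i])) {
      l <- assign_germline(cells$light_sequence[i], library, cells$light_locus[i],
                           n_mask = mask_from_string(cells$light_n_mask[i]))
    }
    out[[i]] <- list(heavy = h, light = l)
  }
  out
}

#' Cluster cells into clones by heavy-chain V/J gene and junction distance
#'
#' Cells are first partitioned by allele-stripped heavy V gene, J gene and
#' junction nucleotide length; within each partition, single-linkage
#' clustering links two cells when the nucleotide Hamming distance between
#' their junctions is strictly below the threshold (default 6). The result
#' is a partition: every cell belongs to exactly one clone, and clone ids
#' are deterministic (ordered by decreasing size, then smallest member id).
#'
#' @param cells Per-cell table with `heavy_v_call`, `heavy_j_call`,
#'   `heavy_junction` columns (from simulation or [assign_repertoire()]).
#' @param threshold Hamming distance threshold; members link iff
#'   distance < threshold.
#' @return A `data.frame` with one row per clone: `clone_id`, `v_gene`,
#'   `j_gene`, `junction_length`, `size`, `size_category` (`singleton`,
#'   `small` 2-3, `large` >= 4) and a `members` list-column of cell ids.
#' @export
cluster_clones <- function(cells, threshold = 6L) {
  if (!nrow(cells)) stopf("cluster_clones: no cells")
  if (any(is.na(cells$heavy_v_call) | is.na(cells$heavy_j_call) |
            is.na(cells$heavy_junction))) {
    stopf("cluster_clones: every cell needs heavy v_call, j_call and junction")
  }
  key <- paste(strip_allele(cells$heavy_v_call),
               strip_allele(cells$heavy_j_call),
               nchar(cells$heavy_junction), sep = "|")
  groups <- split(seq_len(nrow(cells)), key)
  clone_members <- list()
  for (idx in groups) {
    juncs <- cells$heavy_junction[idx]
    n <- length(idx)
    if (n == 1L) {
      clone_members[[length(clone_members) + 1L]] <- cells$cell_id[idx]
      next
    }
    jm <- do.call(rbind, strsplit(toupper(juncs), ""))
    edges <- NULL
    for (a in 1:(n - 1L)) {
      d <- rowSums(jm[(a + 1L):n, , drop = FALSE] !=
                     matrix(jm[a, ], nrow = n - a, ncol = ncol(jm), byrow = TRUE))
      hit <- which(d < threshold)
      if (length(hit)) edges <- rbind(edges, cbind(a, a + hit))
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    for (cc in unique(comp)) {
      clone_members[[length(clone_members) + 1L]] <-
        sort(cells$cell_id[idx[comp == cc]])
    }
  }
  sizes <- lengths(clone_members)
  first_member <- vapply(clone_members, min, character(1))
  ord <- order(-sizes, first_member)
  clone_members <- clone_members[ord]
  sizes <- sizes[ord]
  rep_cell <- vapply(clone_members, `[`, character(1), 1L)
  ridx <- match(rep_cell, cells$cell_id)
  out <- data.frame(
    clone_id = sprintf("clone_%04d", seq_along(clone_members)),
    v_gene = strip_allele(cells$heavy_v_call[ridx]),
    j_gene = strip_allele(cells$heavy_j_call[ridx]),
    junction_length = nchar(cells$heavy_junction[ridx]),
    size = sizes,
    size_category = ifelse(sizes == 1L, "singleton",
                           ifelse(sizes <= 3L, "small", "large")),
    stringsAsFactors = FALSE
  )
  out$members <- clone_members
  out
}

#' Map cells to clone ids
#'
#' @param clones Output of [cluster_clones()].
#' @return `data.frame` with `cell_id` and `clone_id`.
#' @export
clone_membership <- function(clones) {
  data.frame(
    cell_id = unlist(clones$members, use.names = FALSE),
    clone_id = rep(clones$clone_id, lengths(clones$members)),
    stringsAsFactors = FALSE
  )
}

#' Identify the founder member of a clone
#'
#' The founder is the observed clone member with the fewest somatic
#' mutations (heavy plus light when both are counted); ties are broken by
#' the lexicographically smallest cell id.
#'
#' @param members Character vector of member cell ids.
#' @param mutation_counts Named integer vector of mutation counts covering
#'   all members.
#' @return The founder cell id.
#' @export
identify_founder <- function(members, mutation_counts) {
  missing <- setdiff(members, names(mutation_counts))
  if (length(missing)) {
    stopf("identify_founder: missing mutation count for %s", missing[1])
  }
  counts <- mutation_counts[members]
  cand <- sort(members[counts == min(counts)])
  cand[1]
}

#' Annotate every clone with its founder
#'
#' @param clones Output of [cluster_clones()].
#' @param mutation_counts Named per-cell mutation counts (see
#'   [count_mutations_repertoire()]).
#' @return `clones` with a `founder` column.
#' @export
annotate_founders <- function(clones, mutation_counts) {
  clones$founder <- vapply(clones$members, identify_founder, character(1),
                           mutation_counts = mutation_counts)
  clones
}

#' Fraction of cells lying in expanded clones
#'
#' Proportion of cells belonging to clones with at least two members, the
#' clonality statistic used for CSF CD4+ T cell and B cell repertoires.
#'
#' @param clones Output of [cluster_clones()] (or [tcr_clones()]).
#' @return Fraction in \[0, 1\].
#' @export
clonality_fraction <- function(clones) {
  if (!nrow(clones)) stopf("clonality_fraction: no clones")
  total <- sum(clones$size)
  sum(clones$size[clones$size >= 2L]) / total
}

#' TCR clone definition by identical junctions
#'
#' T cell clones are defined by identical nucleotide junction sequences of
#' all recovered chains (both chains when the second chain is present).
#'
#' @param cells Per-cell table of T cells with `heavy_junction` (beta) and
#'   optionally `light_junction` (alpha) columns.
#' @return Clone-level `data.frame` as in [cluster_clones()].
#' @export
tcr_clones <- function(cells) {
  if (!nrow(cells)) stopf("tcr_clones: no cells")
  key <- paste(cells$heavy_junction,
               ifelse(is.na(cells$light_junction), "", cells$light_junction),
               sep = "|")
  groups <- split(cells$cell_id, key)
  members <- lapply(unname(groups), sort)
  sizes <- lengths(members)
  ord <- order(-sizes, vapply(members, min, character(1)))
  members <- members[ord]; sizes <- sizes[ord]
  out <- data.frame(
    clone_id = sprintf("tcrclone_%04d", seq_along(members)),
    size = sizes,
    size_category = ifelse(sizes == 1L, "singleton",
                           ifelse(sizes <= 3L, "small", "large")),
    stringsAsFactors = FALSE
  )
  out$members <- members
  out
}
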