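# Synthetic V(D)J repertoire generator with somatic hypermutation (SHM) and
# full ground truth: true clone ids, naive (UCA) sequences, N-region masks,
# and realised peripheral/intrathecal mutation counts. Substitution-only SHM
# by design: the germline-reversion UCA algorithm downstream assumes no
# indels.

IGHG_ORDER <- c("IGHG3", "IGHG1", "IGHG2", "IGHG4")

#' Simulation configuration
#'
#' Parameters of the synthetic CSF IgG repertoire. Defaults emulate the
#' clonal structure reported for LGI1/CASPR2 autoimmune encephalitis CSF:
#' mostly singleton clones with a tail of expansions up to 8 members, a
#' large peripheral (germline to founder) mutation load with only sparse
#' intrathecal (intraclonal) mutation, autoantigen reactivity that is a
#' clone-level property whose frequency rises with clone size
#' (0.6 / 0.8 / 1.0 for singletons, 2-3-member and 4+-member clones), an
#' IgG4-dominated subclass distribution with rare strictly-downstream class
#' switches, and an ASC-dominated cell-state mixture.
#'
#' @param n_clones Number of clones to simulate.
#' @param clone_size_distribution Named weights over size categories
#'   `"1"`, `"2"`, `"3"`, `"4-8"` (sizes 4-8 drawn uniformly).
#' @param mu_peripheral Per-site substitution probability applied once,
#'   germline to clone founder (peripheral affinity maturation).
#' @param mu_intrathecal Per-site substitution probability applied per
#'   intraclonal branching step.
#' @param n_insertion_mean Mean non-templated (N) nucleotides per junction
#'   side (minimum 1 is enforced so every junction has an N region).
#' @param trim_max Maximum exonuclease trimming per segment end (nt).
#' @param p_reactive_by_size Named probabilities (`"1"`, `"2-3"`, `"4+"`)
#'   that a clone of that size category is autoantigen-reactive.
#' @param state_weights Named weights over cell states MBC/prePB/PB/PC.
#' @param subclass_start_weights Named weights over IGHG1..IGHG4 for the
#'   founder subclass.
#' @param p_switch Per-cell probability of one downstream subclass switch.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 200,
                       clone_size_distribution = c("1" = 0.78, "2" = 0.10,
                                                   "3" = 0.05, "4-8" = 0.07),
                       mu_peripheral = 0.05,
                       mu_intrathecal = 0.002,
                       n_insertion_mean = 4,
                       trim_max = 3,
                       p_reactive_by_size = c("1" = 0.6, "2-3" = 0.8, "4+" = 1.0),
                       state_weights = c(MBC = 0.09, prePB = 0.04,
                                         PB = 0.60, PC = 0.27),
                       subclass_start_weights = c(IGHG1 = 0.08, IGHG2 = 0.02,
                                                  IGHG3 = 0.02, IGHG4 = 0.88),
                       p_switch = 0.15,
                       seed = 42) {
  cfg <- list(
    n_clones = as.integer(n_clones),
    clone_size_distribution = clone_size_distribution,
    mu_peripheral = mu_peripheral, mu_intrathecal = mu_intrathecal,
    n_insertion_mean = n_insertion_mean, trim_max = as.integer(trim_max),
    p_reactive_by_size = p_reactive_by_size,
    state_weights = state_weights,
    subclass_start_weights = subclass_start_weights,
    p_switch = p_switch, seed = as.integer(seed)
  )
  if (cfg$n_clones < 1L) stopf("n_clones must be >= 1")
  if (!setequal(names(cfg$clone_size_distribution), c("1", "2", "3", "4-8"))) {
    stopf("clone_size_distribution must be named over '1','2','3','4-8'")
  }
  if (any(cfg$clone_size_distribution < 0) || sum(cfg$clone_size_distribution) <= 0) {
    stopf("clone size weights must be nonnegative and not all zero")
  }
  for (mu in c(cfg$mu_peripheral, cfg$mu_intrathecal)) {
    if (mu < 0 || mu > 0.2) stopf("mutation rates must lie in [0, 0.2]")
  }
  if (!setequal(names(cfg$p_reactive_by_size), c("1", "2-3", "4+"))) {
    stopf("p_reactive_by_size must be named over '1','2-3','4+'")
  }
  if (any(cfg$p_reactive_by_size < 0 | cfg$p_reactive_by_size > 1)) {
    stopf("reactivity probabilities must lie in [0,1]")
  }
  if (cfg$p_switch < 0 || cfg$p_switch > 1) stopf("p_switch must lie in [0,1]")
  for (w in list(cfg$state_weights, cfg$subclass_start_weights)) {
    if (any(w < 0) || sum(w) <= 0) stopf("weights must be nonnegative, not all zero")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Bundled toy germline segment library
#'
#' A small deterministic library (5 V, 3 D, 3 J for IGH; 5 V, 3 J for IGK)
#' with realistic segment lengths, conserved junction-anchor codons (Cys in
#' V, Trp/Phe in J) and stop-free V reading frames. Intended for simulation
#' and tests; it is synthetic and carries IMGT-style names purely for
#' readability.
#'
#' @return A [segment_library()].
#' @export
toy_segment_library <- function() {
  with_seed(902107L, {
    non_stop <- setdiff(
      apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")
    )
    rand_v <- function(n_codons, anchor_codon) {
      cs <- sample(non_stop, n_codons, replace = TRUE)
      cs[anchor_codon] <- "TGT"
      paste(cs, collapse = "")
    }
    rand_nt <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
    # V: 97 codons (291 nt), Cys anchor at codon 96 (1-based nt 286)
    rand_j <- function(prefix_nt, anchor, tail_codons) {
      paste0(rand_nt(prefix_nt), anchor,
             paste(sample(non_stop, tail_codons, replace = TRUE), collapse = ""))
    }
    ids_vh <- c("IGHV1-2*01", "IGHV1-69*01", "IGHV3-7*01", "IGHV3-23*01", "IGHV4-34*01")
    ids_vk <- c("IGKV1-5*01", "IGKV1-39*01", "IGKV2-28*01", "IGKV3-20*01", "IGKV4-1*01")
    segment_library(
      segment_id = c(ids_vh, "IGHD2-2*01", "IGHD3-10*01", "IGHD6-19*01",
                     "IGHJ3*01", "IGHJ4*02", "IGHJ6*02",
                     ids_vk, "IGKJ1*01", "IGKJ2*01", "IGKJ4*01"),
      locus = c(rep("IGH", 11), rep("IGK", 8)),
      segment_type = c(rep("V", 5), rep("D", 3), rep("J", 3), rep("V", 5), rep("J", 3)),
      sequence = c(
        vapply(seq_len(5), function(i) rand_v(97, 96), character(1)),
        rand_nt(15), rand_nt(18), rand_nt(21),
        # IGH J: 48 nt, Trp anchor codon at nt 13-15, 11 in-frame tail codons
        vapply(seq_len(3), function(i) rand_j(12, "TGG", 11), character(1)),
        vapply(seq_len(5), function(i) rand_v(97, 96), character(1)),
        # IGK J: 39 nt, Phe anchor codon at nt 10-12, 9 in-frame tail codons
        vapply(seq_len(3), function(i) rand_j(9, "TTC", 9), character(1))
      ),
      cdr3_anchor = c(rep(286L, 5), rep(NA_integer_, 3), rep(13L, 3),
                      rep(286L, 5), rep(10L, 3))
    )
  })
}

#' Simulate one V(D)J recombination event
#'
#' Draws V (D) J segments for a locus, applies exonuclease trimming,
#' inserts non-templated N nucleotides at each join, and extracts the
#' junction between the conserved V and J anchor codons. The second N
#' region is length-adjusted so the junction length is always a multiple of
#' three (productive reading frame); for light-chain loci without D
#' segments a single N region joins V to J. Uses the current R random
#' number generator state.
#'
#' @param library A [segment_library()].
#' @param locus Locus to recombine (default `"IGH"`).
#' @param n_insertion_mean Mean N nucleotides per junction side (min 1).
#' @param trim_max Maximum trimming per segment end.
#' @return A list with `sequence`, `junction`, `junction_aa`, `n_mask`
#'   (1-based positions of non-templated nucleotides), `v_call`, `d_call`,
#'   `j_call`, and `junction_start`/`junction_end` (1-based, inclusive).
#' @export
recombine <- function(library, locus = "IGH", n_insertion_mean = 4, trim_max = 3) {
  seg <- library[library$locus == locus, ]
  vs <- seg[seg$segment_type == "V", ]
  ds <- seg[seg$segment_type == "D", ]
  js <- seg[seg$segment_type == "J", ]
  if (nrow(vs) == 0L || nrow(js) == 0L) {
    stopf("recombine: library has no V or no J segment for locus %s", locus)
  }
  if (locus %in% c("IGH", "TRB") && nrow(ds) == 0L) {
    stopf("recombine: library has no D segment for heavy locus %s", locus)
  }
  v <- vs[sample.int(nrow(vs), 1L), ]
  j <- js[sample.int(nrow(js), 1L), ]
  use_d <- nrow(ds) > 0L
  d <- if (use_d) ds[sample.int(nrow(ds), 1L), ] else NULL

  v_len <- nchar(v$sequence)
  v_tail <- v_len - (v$cdr3_anchor + 2L)          # nt 3' of the anchor codon
  v_trim <- sample.int(min(trim_max, v_tail) + 1L, 1L) - 1L
  v_eff <- v_len - v_trim
  v_part <- substr(v$sequence, 1L, v_eff)

  draw_n <- function() max(1L, stats::rpois(1L, max(0, n_insertion_mean - 1)) + 1L)
  n1 <- if (n_insertion_mean == 0) 0L else draw_n()

  if (use_d) {
    d_len <- nchar(d$sequence)
    max_d_trim <- max(0L, (d_len - 8L) %/% 2L)    # keep >= 8 nt of D
    d5 <- sample.int(min(trim_max, max_d_trim) + 1L, 1L) - 1L
    d3 <- sample.int(min(trim_max, max_d_trim) + 1L, 1L) - 1L
    d_part <- substr(d$sequence, d5 + 1L, d_len - d3)
  } else {
    d_part <- ""
  }
  d_eff <- nchar(d_part)

  j_trim <- sample.int(min(trim_max, j$cdr3_anchor - 1L) + 1L, 1L) - 1L
  j_part <- substr(j$sequence, j_trim + 1L, nchar(j$sequence))
  j_anchor_off <- j$cdr3_anchor - j_trim          # anchor pos within j_part

  n2 <- if (n_insertion_mean == 0 && !use_d) 0L else draw_n()
  if (n_insertion_mean == 0 && use_d) n2 <- 0L
  # enforce junction length %% 3 == 0 by growing the last N region
  junction_len <- function(n2x) {
    (v_eff + n1 + d_eff + n2x + j_anchor_off + 2L) - v$cdr3_anchor + 1L
  }
  pad <- (3L - junction_len(n2) %% 3L) %% 3L
  n2 <- n2 + pad
  if (n_insertion_mean == 0 && n2 > 0L && !use_d) n1 <- n1  # degenerate configs keep pad in n2

  rand_nt <- function(n) {
    if (n == 0L) "" else paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  }
  n1_seq <- rand_nt(n1)
  n2_seq <- rand_nt(n2)
  sequence <- paste0(v_part, n1_seq, d_part, n2_seq, j_part)

  n_mask <- integer(0)
  if (n1 > 0L) n_mask <- c(n_mask, v_eff + seq_len(n1))
  if (n2 > 0L) n_mask <- c(n_mask, v_eff + n1 + d_eff + seq_len(n2))

  junction_start <- v$cdr3_anchor
  junction_end <- v_eff + n1 + d_eff + n2 + j_anchor_off + 2L
  junction <- substr(sequence, junction_start, junction_end)
  list(
    sequence = sequence, junction = junction,
    junction_aa = translate_seq(junction),
    n_mask = n_mask, v_call = v$segment_id,
    d_call = if (use_d) d$segment_id else NA_character_,
    j_call = j$segment_id,
    junction_start = junction_start, junction_end = junction_end
  )
}

#' Point-substitution somatic hypermutation
#'
#' Substitutes each eligible position independently with probability `mu`
#' to a uniformly chosen different base. No insertions or deletions. By
#' default N-region positions are mutable too (real SHM does not spare
#' them); pass `protect = TRUE` to spare `protected` positions.
#'
#' @param seq Nucleotide string.
#' @param mu Per-site substitution probability in \[0, 0.2\] (or exactly 1
#'   for forced full mutation in tests).
#' @param protected Integer positions (1-based) spared when
#'   `protect = TRUE`.
#' @param protect Whether to spare `protected` positions.
#' @return Mutated sequence of identical length.
#' @export
mutate_seq <- function(seq, mu, protected = integer(0), protect = FALSE) {
  if (mu < 0 || (mu > 0.2 && mu != 1)) stopf("mu must lie in [0, 0.2]")
  if (mu == 0) return(seq)
  chars <- seq_chars(seq)
  eligible <- seq_along(chars)
  if (protect && length(protected)) eligible <- setdiff(eligible, protected)
  hit <- eligible[stats::runif(length(eligible)) < mu]
  for (p in hit) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  chars_seq(chars)
}

size_category_of <- function(size) {
  if (size == 1L) "1" else if (size <= 3L) "2-3" else "4+"
}

draw_markers <- function(state) {
  u <- function(lo, hi) stats::runif(1, lo, hi)
  base <- c(CD3 = u(0, 0.25), CD4 = u(0, 0.3), CD8 = u(0, 0.3),
            CD14 = u(0, 0.2), CD19 = u(0.55, 0.95), CD20 = u(0, 0.3),
            CD27 = u(0.4, 0.9), CD38 = u(0.7, 1), CD138 = u(0, 0.35))
  if (state == "MBC") {
    base["CD20"] <- u(0.6, 0.95); base["CD38"] <- u(0, 0.4)
  } else if (state == "PC") {
    base["CD138"] <- u(0.6, 0.95); base["CD20"] <- u(0, 0.2)
  }
  base
}

# Subclass usage is a clone-level property: the clone starts from one
# constant gene (carried by the founder) and may additionally express a
# single downstream target gene, which each non-founder member adopts with
# probability p_switch. Clones therefore express one or two subclasses,
# never more, and never an upstream one.
draw_clone_subclasses <- function(start_weights, p_switch, size) {
  start <- sample(names(start_weights), 1L, prob = start_weights)
  pos <- match(start, IGHG_ORDER)
  target <- if (pos < length(IGHG_ORDER)) {
    sample(IGHG_ORDER[(pos + 1L):length(IGHG_ORDER)], 1L)
  } else NA_character_
  paths <- vector("list", size)
  paths[[1]] <- start
  if (size > 1L) {
    for (k in 2:size) {
      switched <- !is.na(target) && stats::runif(1) < p_switch
      paths[[k]] <- if (switched) c(start, target) else start
    }
  }
  paths
}

#' Simulate a clonally structured CSF BCR repertoire with ground truth
#'
#' Generates `n_clones` B cell clones. Each clone recombines one naive
#' (unmutated common ancestor) heavy/light pair, derives its intrathecal
#' founder by applying `mu_peripheral` substitutions, and grows further
#' members along a random branching tree at `mu_intrathecal` per branch.
#' Autoantigen reactivity is drawn once per clone (probability increasing
#' with clone size) and shared by all members; IgG subclass switches are
#' downstream-only on the IGHG3 < IGHG1 < IGHG2 < IGHG4 constant-gene
#' order; endpoint concentrations of reactive cells decrease log-normally
#' with total mutation load. Clones are re-drawn until, within every
#' (V gene, J gene, junction length) group, junctions of different clones
#' differ by Hamming distance of at least 6 while intraclonal junction
#' distances stay below 6, so true clones are exactly recoverable by the
#' clustering contract.
#'
#' @param library A [segment_library()] with IGH (V, D, J) and IGK (V, J)
#'   segments, e.g. [toy_segment_library()].
#' @param cfg A [sim_config()].
#' @return A list with `cells` (per-cell table as documented in
#'   [read_airr()]) and `truth` (per-cell ground truth: true clone id,
#'   naive sequences, N-region masks, founder flag, peripheral and
#'   intrathecal mutation counts, reactivity, state, subclass path).
#' @export
simulate_repertoire <- function(library, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    size_cats <- sample(names(cfg$clone_size_distribution), cfg$n_clones,
                        replace = TRUE, prob = cfg$clone_size_distribution)
    sizes <- vapply(size_cats, function(s) {
      switch(s, "1" = 1L, "2" = 2L, "3" = 3L, "4-8" = sample(4:8, 1L))
    }, integer(1))
    donors <- sample(c("P1", "P2", "P3"), cfg$n_clones, replace = TRUE,
                     prob = c(0.40, 0.17, 0.43))
    antigen <- ifelse(donors == "P3", "CASPR2", "LGI1")
    reactive <- stats::runif(cfg$n_clones) <
      cfg$p_reactive_by_size[vapply(sizes, size_category_of, character(1))]
    labels <- ifelse(reactive, antigen, "negative")

    registry <- new.env(parent = emptyenv())   # junction registry per V/J/len
    cell_rows <- list()
    truth_rows <- list()
    cell_n <- 0L

    for (ci in seq_len(cfg$n_clones)) {
      size <- sizes[ci]
      for (attempt in seq_len(200L)) {
        hv <- recombine(library, "IGH", cfg$n_insertion_mean, cfg$trim_max)
        lv <- recombine(library, "IGK", cfg$n_insertion_mean, cfg$trim_max)
        founder_h <- mutate_seq(hv$sequence, cfg$mu_peripheral)
        founder_l <- mutate_seq(lv$sequence, cfg$mu_peripheral)
        mem_h <- vector("list", size); mem_l <- vector("list", size)
        mem_h[[1]] <- founder_h; mem_l[[1]] <- founder_l
        if (size > 1L) {
          for (k in 2:size) {
            parent <- sample.int(k - 1L, 1L)
            mem_h[[k]] <- mutate_seq(mem_h[[parent]], cfg$mu_intrathecal)
            mem_l[[k]] <- mutate_seq(mem_l[[parent]], cfg$mu_intrathecal)
          }
        }
        juncs <- vapply(mem_h, substr, character(1),
                        start = hv$junction_start, stop = hv$junction_end)
        key <- paste(strip_allele(hv$v_call), strip_allele(hv$j_call),
                     nchar(juncs[1]), sep = "|")
        prior <- if (exists(key, envir = registry)) get(key, envir = registry)
                 else character(0)
        ok <- TRUE
        if (length(prior)) {
          for (jq in juncs) {
            if (any(vapply(prior, hamming, integer(1), b = jq) < 6L)) {
              ok <- FALSE; break
            }
          }
        }
        if (ok && size > 1L) {
          for (a in 1:(size - 1L)) {
            if (!ok) break
            for (b in (a + 1L):size) {
              if (hamming(juncs[a], juncs[b]) >= 6L) { ok <- FALSE; break }
            }
          }
        }
        if (ok) break
        if (attempt == 200L) {
          stopf("simulate_repertoire: could not place clone %d with the required junction separation", ci)
        }
      }
      assign(key, c(prior, juncs), envir = registry)

      templ_h <- setdiff(seq_len(nchar(hv$sequence)), hv$n_mask)
      templ_l <- setdiff(seq_len(nchar(lv$sequence)), lv$n_mask)
      mut_p <- hamming(hv$sequence, founder_h, templ_h) +
        hamming(lv$sequence, founder_l, templ_l)

      paths <- draw_clone_subclasses(cfg$subclass_start_weights, cfg$p_switch, size)
      for (k in seq_len(size)) {
        cell_n <- cell_n + 1L
        id <- sprintf("cell_%05d", cell_n)
        state <- sample(names(cfg$state_weights), 1L, prob = cfg$state_weights)
        markers <- draw_markers(state)
        path <- paths[[k]]
        mut_i <- hamming(founder_h, mem_h[[k]], templ_h) +
          hamming(founder_l, mem_l[[k]], templ_l)
        conc <- NA_real_
        if (labels[ci] != "negative") {
          conc <- 10 ^ (1.5 - 0.06 * (mut_p + mut_i) + stats::rnorm(1, 0, 0.35))
        }
        jh <- substr(mem_h[[k]], hv$junction_start, hv$junction_end)
        jl <- substr(mem_l[[k]], lv$junction_start, lv$junction_end)
        cell_rows[[cell_n]] <- data.frame(
          cell_id = id, donor = donors[ci],
          heavy_sequence = mem_h[[k]], heavy_v_call = hv$v_call,
          heavy_d_call = hv$d_call, heavy_j_call = hv$j_call,
          heavy_junction = jh, heavy_junction_aa = translate_seq(jh),
          heavy_c_call = path[length(path)],
          heavy_n_mask = mask_to_string(hv$n_mask),
          light_locus = "IGK", light_sequence = mem_l[[k]],
          light_v_call = lv$v_call, light_j_call = lv$j_call,
          light_junction = jl, light_junction_aa = translate_seq(jl),
          light_c_call = "IGKC", light_n_mask = mask_to_string(lv$n_mask),
          CD3 = markers[["CD3"]], CD4 = markers[["CD4"]], CD8 = markers[["CD8"]],
          CD14 = markers[["CD14"]], CD19 = markers[["CD19"]],
          CD20 = markers[["CD20"]], CD27 = markers[["CD27"]],
          CD38 = markers[["CD38"]], CD138 = markers[["CD138"]],
          cell_state = state, reactivity = labels[ci], endpoint_conc = conc,
          stringsAsFactors = FALSE
        )
        truth_rows[[cell_n]] <- data.frame(
          cell_id = id, true_clone_id = sprintf("tclone_%04d", ci),
          naive_heavy = hv$sequence, naive_light = lv$sequence,
          heavy_n_mask = mask_to_string(hv$n_mask),
          light_n_mask = mask_to_string(lv$n_mask),
          is_founder = (k == 1L),
          true_mut_peripheral = mut_p, true_mut_intrathecal = mut_i,
          true_reactivity = labels[ci], true_state = state,
          true_subclass_path = paste(path, collapse = ">"),
          stringsAsFactors = FALSE
        )
      }
    }
    cells <- do.call(rbind, cell_rows)
    truth <- do.call(rbind, truth_rows)
    rownames(cells) <- rownames(truth) <- NULL
    list(cells = cells, truth = truth)
  })
}
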