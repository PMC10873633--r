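# Shared fixtures, all built in code.

toy_lib <- toy_segment_library()

# minimal library: 2 V, 1 D, 1 J (IGH only)
mini_library <- function() {
  segment_library(
    segment_id = c("V1*01", "V2*01", "D1*01", "J1*01"),
    locus = "IGH",
    segment_type = c("V", "V", "D", "J"),
    sequence = c(
      paste(rep("ACG", 30), collapse = ""),
      paste(rep("GTT", 30), collapse = ""),
      "GGGTTTCCCAAAGGG",
      paste0("ACACAC", "TGG", paste(rep("GCA", 10), collapse = ""))
    ),
    cdr3_anchor = c(82L, 82L, NA, 7L)
  )
}

# small cached default simulation used by several suites
small_sim <- simulate_repertoire(toy_lib, sim_config(n_clones = 50, seed = 3))

# manual germline assignment for controlled reversion tests
manual_assignment <- function(germline, n_mask = integer(0)) {
  ref <- strsplit(germline, "")[[1]]
  ref[n_mask] <- NA_character_
  structure(list(v_call = "V", d_call = NA_character_, j_call = "J",
                 v_identity = 1, j_identity = 1, germline_ref = ref,
                 n_mask = n_mask, failed = FALSE),
            class = "germline_assignment")
}

# full inference pipeline on a fresh simulation, returning the compartment
# contrast
pipeline_contrast <- function(seed, n_clones = 30, mu_p = 0.05, mu_i = 0.002,
                              sizes = c("1" = 0, "2" = 0, "3" = 1, "4-8" = 0)) {
  sim <- simulate_repertoire(toy_lib, sim_config(
    n_clones = n_clones, mu_peripheral = mu_p, mu_intrathecal = mu_i,
    clone_size_distribution = sizes, seed = seed
  ))
  cl <- cluster_clones(sim$cells)
  asg <- assign_repertoire(sim$cells, toy_lib)
  counts <- count_mutations_repertoire(sim$cells, asg)
  cl <- annotate_founders(cl, counts)
  ucas <- reconstruct_uca_repertoire(sim$cells, asg, mode = "revert_all")
  compartment_contrast(cl, sim$cells, ucas)
}

# brute-force connected components of the thresholded junction distance graph
brute_force_clones <- function(junctions, ids, threshold = 6L) {
  n <- length(junctions)
  adj <- diag(TRUE, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b && nchar(junctions[a]) == nchar(junctions[b]) &&
          hamming(junctions[a], junctions[b]) < threshold) {
        adj[a, b] <- TRUE
      }
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(apply(adj, 1, function(r) paste(sort(ids[r]), collapse = ",")))
  sort(comps)
}

# turn a clone table into a canonical membership signature
clone_signature <- function(clones) {
  sort(vapply(clones$members, function(m) paste(sort(m), collapse = ","), character(1)))
}
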