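make_cells <- function(junctions, v = "IGHV1-1*01", j = "IGHJ1*01",
                       ids = sprintf("c%02d", seq_along(junctions))) {
  data.frame(cell_id = ids, heavy_v_call = v, heavy_j_call = j,
             heavy_junction = junctions, stringsAsFactors = FALSE)
}

test_that("germline assignment maximises identity and breaks ties lexicographically", {
  lib <- mini_library()
  v1 <- lib$sequence[lib$segment_id == "V1*01"]
  j1 <- lib$sequence[lib$segment_id == "J1*01"]
  asg <- assign_germline(paste0(v1, j1), lib, "IGH")
  expect_equal(asg$v_call, "V1*01")
  expect_equal(asg$j_call, "J1*01")
  expect_equal(asg$v_identity, 1.0)
  expect_equal(asg$j_identity, 1.0)
  expect_false(asg$failed)

  # 2 substitutions in a 200-nt V -> identity 0.99
  set.seed(8)
  v200 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  lib200 <- segment_library(c("VX*01", "J1*01"), "IGH", c("V", "J"),
                            c(v200, j1), c(190L, 7L))
  mut <- bcrcsf:::seq_chars(v200)
  mut[c(10, 20)] <- ifelse(mut[c(10, 20)] == "A", "C", "A")
  asg2 <- assign_germline(paste0(bcrcsf:::chars_seq(mut), j1), lib200, "IGH")
  expect_equal(asg2$v_identity, 0.99)

  # identical alleles: lexicographically smallest id wins
  lib_tie <- segment_library(c("V1*02", "V1*01", "J1*01"), "IGH",
                             c("V", "V", "J"), c(v1, v1, j1), c(82L, 82L, 7L))
  asg3 <- assign_germline(paste0(v1, j1), lib_tie, "IGH")
  expect_equal(asg3$v_call, "V1*01")
})

test_that("assignment fails gracefully below the identity floor", {
  set.seed(9)
  junk <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  asg <- assign_germline(junk, mini_library(), "IGH")
  expect_true(asg$failed)
  expect_error(assign_germline("ACGT", mini_library(), "IGH"), "50 nt")
})

test_that("assignment with the N-region mask recovers the exact germline template", {
  cells <- small_sim$cells[1:10, ]
  tr <- small_sim$truth[1:10, ]
  asg <- assign_repertoire(cells, toy_lib)
  for (i in seq_len(10)) {
    ref <- asg[[cells$cell_id[i]]]$heavy$germline_ref
    naive <- bcrcsf:::seq_chars(tr$naive_heavy[i])
    templ <- which(!is.na(ref))
    expect_identical(ref[templ], naive[templ])
    expect_identical(which(is.na(ref)),
                     bcrcsf:::mask_from_string(tr$heavy_n_mask[i]))
  }
})

test_that("clone clustering respects the strict Hamming < 6 rule", {
  # identical junctions -> one clone of 2
  cl <- cluster_clones(make_cells(c("TGTAAAGGGTGG", "TGTAAAGGGTGG")))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size, 2L)

  # distance exactly 6 -> two singletons (strict inequality)
  a <- "TGTAAAGGGTGG"
  b <- "ACACCCGGGTGG"  # differs at positions 1-6
  expect_equal(hamming(a, b), 6L)
  cl2 <- cluster_clones(make_cells(c(a, b)))
  expect_equal(nrow(cl2), 2L)

  # transitive closure: A-B 3, B-C 3, A-C 6 -> one clone of 3
  aj <- "TGTAAAGGGTGG"
  bj <- "ACCAAAGGGTGG"  # 3 changes at 1-3
  cj <- "ACCTTTGGGTGG"  # 3 further changes at 4-6
  expect_equal(hamming(aj, bj), 3L)
  expect_equal(hamming(bj, cj), 3L)
  expect_equal(hamming(aj, cj), 6L)
  cl3 <- cluster_clones(make_cells(c(aj, bj, cj)))
  expect_equal(nrow(cl3), 1L)
  expect_equal(cl3$size, 3L)

  # different V gene splits otherwise identical junctions
  cells <- make_cells(c(a, a), v = c("IGHV1-1*01", "IGHV2-5*01"))
  expect_equal(nrow(cluster_clones(cells)), 2L)
  # same gene, different allele does not split
  cells2 <- make_cells(c(a, a), v = c("IGHV1-1*01", "IGHV1-1*02"))
  expect_equal(nrow(cluster_clones(cells2)), 1L)
})

test_that("single linkage equals brute-force connected components (oracle, n <= 50)", {
  set.seed(21)
  for (rep in 1:5) {
    juncs <- vapply(seq_len(40), function(i) {
      paste(sample(c("A", "C"), 9, replace = TRUE), collapse = "")
    }, character(1))
    cells <- make_cells(juncs)
    cl <- cluster_clones(cells)
    expect_identical(clone_signature(cl),
                     brute_force_clones(juncs, cells$cell_id))
    # partition: disjoint and covering
    all_members <- unlist(cl$members)
    expect_equal(sort(all_members), sort(cells$cell_id))
  }
})

test_that("clustering is invariant to input order", {
  set.seed(22)
  juncs <- vapply(seq_len(30), function(i) {
    paste(sample(c("A", "G"), 9, replace = TRUE), collapse = "")
  }, character(1))
  cells <- make_cells(juncs)
  shuffled <- cells[sample(nrow(cells)), ]
  expect_identical(clone_signature(cluster_clones(cells)),
                   clone_signature(cluster_clones(shuffled)))
})

test_that("inferred clones match simulated truth exactly", {
  skip_if_not_installed("mclust")
  cl <- cluster_clones(small_sim$cells)
  mem <- clone_membership(cl)
  inferred <- mem$clone_id[match(small_sim$truth$cell_id, mem$cell_id)]
  expect_equal(mclust::adjustedRandIndex(inferred, small_sim$truth$true_clone_id), 1.0)
})

test_that("founder identification picks the least mutated member", {
  expect_equal(identify_founder(c("a", "b", "c"), c(a = 5, b = 2, c = 9)), "b")
  expect_equal(identify_founder(c("b", "a"), c(a = 3, b = 3)), "a")   # tie-break
  expect_equal(identify_founder("z", c(z = 4)), "z")                  # singleton
  expect_error(identify_founder(c("a", "b"), c(a = 1)), "missing")
})

test_that("clonality fraction counts cells in expanded clones", {
  cl <- data.frame(size = c(2L, rep(1L, 8)))
  expect_equal(clonality_fraction(cl), 0.2)
  expect_equal(clonality_fraction(data.frame(size = rep(1L, 5))), 0)
  expect_error(clonality_fraction(data.frame(size = integer(0))), "no clones")
})

test_that("TCR clones require identical junction pairs", {
  cells <- data.frame(
    cell_id = c("t1", "t2", "t3"),
    heavy_junction = c("TGTAAA", "TGTAAA", "TGTCCC"),
    light_junction = c("TGCGGG", "TGCGGG", "TGCGGG"),
    stringsAsFactors = FALSE
  )
  cl <- tcr_clones(cells)
  expect_equal(sort(cl$size), c(1L, 2L))
  expect_equal(clonality_fraction(cl), 2 / 3)
})
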