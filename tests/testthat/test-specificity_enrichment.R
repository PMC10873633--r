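label_cells <- function(ids, labels) {
  data.frame(cell_id = ids, reactivity = labels, stringsAsFactors = FALSE)
}
one_clone <- function(ids, id = "cl1") {
  cl <- data.frame(clone_id = id, size = length(ids), stringsAsFactors = FALSE)
  cl$members <- list(ids)
  cl
}

test_that("reactivity propagates from tested to untested clone members", {
  cells <- label_cells(c("a", "b", "c"), c("LGI1", "untested", "untested"))
  out <- propagate_reactivity(cells, one_clone(c("a", "b", "c")))
  expect_equal(out$reactivity_resolved, rep("LGI1", 3))
  expect_equal(out$reactivity_source, c("tested", "propagated", "propagated"))

  # untested clones stay unchanged but are flagged
  cells2 <- label_cells(c("x", "y"), c("untested", "untested"))
  out2 <- propagate_reactivity(cells2, one_clone(c("x", "y"), "cl9"))
  expect_equal(out2$reactivity_resolved, c("untested", "untested"))
  expect_equal(attr(out2, "unresolved_clones"), "cl9")

  # conflicting tested labels raise an error naming the clone
  cells3 <- label_cells(c("p", "q"), c("LGI1", "negative"))
  expect_error(propagate_reactivity(cells3, one_clone(c("p", "q"), "cl7")), "cl7")
})

test_that("propagation never changes a tested cell's label", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    lab <- sample(c("LGI1", "untested"), n, replace = TRUE)
    if (all(lab == "untested")) lab[1] <- "LGI1"
    cells <- label_cells(sprintf("m%d", 1:n), lab)
    out <- propagate_reactivity(cells, one_clone(cells$cell_id))
    tested <- lab != "untested"
    expect_equal(out$reactivity_resolved[tested], lab[tested])
  }
})

test_that("two-sided Fisher p follows the point-probability enumeration", {
  r <- fisher_exact(matrix(c(3, 1, 1, 9), 2, byrow = TRUE))
  expect_equal(r$p_two_sided, 41 / 1001, tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_two_sided, 1.0)
  expect_lt(fisher_exact(matrix(c(114, 17, 4, 10), 2, byrow = TRUE))$p_two_sided, 0.001)

  expect_equal(fisher_exact(matrix(c(3, 1, 1, 9), 2, byrow = TRUE))$odds_ratio, 27)
  expect_equal(fisher_exact(matrix(c(2, 0, 1, 3), 2, byrow = TRUE))$odds_ratio, Inf)
  expect_error(fisher_exact(matrix(c(0, 0, 1, 3), 2, byrow = TRUE)), "margin")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("clone-size stratified rates and the overall exact test behave", {
  ids <- sprintf("s%02d", 1:14)
  # 10 singletons (6 reactive), one clone of 4 all reactive
  cells <- label_cells(ids, c(rep("LGI1", 6), rep("negative", 4), rep("CASPR2", 4)))
  cells$donor <- rep(c("P1", "P2"), 7)
  clones <- data.frame(clone_id = c(sprintf("cl%02d", 1:10), "cl11"),
                       size = c(rep(1L, 10), 4L),
                       size_category = c(rep("singleton", 10), "large"),
                       stringsAsFactors = FALSE)
  clones$members <- c(as.list(ids[1:10]), list(ids[11:14]))
  cells <- propagate_reactivity(cells, clones)
  summ <- stratify_by_clone_size(cells, clones)
  pc <- summ$per_category
  expect_equal(pc$rate[pc$size_category == "singleton"], 0.6)
  expect_equal(pc$rate[pc$size_category == "large"], 1.0)
  expect_true(is.na(pc$rate[pc$size_category == "small"]))  # absent, not zero
  expect_true(summ$p_overall >= 0 && summ$p_overall <= 1)
})

test_that("adjusted specificity follows the stated formula and is monotone", {
  expect_equal(adjusted_specificity(100, 120, 40, 0.60), 124 / 160)
  expect_equal(adjusted_specificity(90, 120, 0, 0.60), 90 / 120)  # no untested
  r0 <- adjusted_specificity(90, 120, 40, 0)
  expect_lt(r0, 90 / 120)                                         # dilution to 0
  prev <- -1
  for (s in seq(0, 1, by = 0.1)) {
    r <- adjusted_specificity(90, 120, 40, s)
    expect_gte(r, prev)
    expect_gte(r, min(90 / 120, s) - 1e-12)
    expect_lte(r, max(90 / 120, s) + 1e-12)
    prev <- r
  }
  expect_error(adjusted_specificity(1, 0, 0, 0.5), "denominator")
})

test_that("antibody index arithmetic, strict cutoff and scale invariance", {
  r <- antibody_index(10, 2, 5, 500)
  expect_equal(r$index, 500)
  expect_true(r$intrathecal)
  r2 <- antibody_index(5, 5, 100, 100)   # equal CSF:serum ratios
  expect_equal(r2$index, 1)
  expect_false(r2$intrathecal)
  r4 <- antibody_index(4, 1, 100, 400)   # index exactly 4: strict cutoff
  expect_equal(r4$index, 16)             # (4/1)/(100/400)
  r4 <- antibody_index(1, 1, 100, 400)
  expect_equal(r4$index, 4)
  expect_false(r4$intrathecal)
  expect_error(antibody_index(0, 1, 1, 1), "positive")

  set.seed(42)
  for (i in 1:10) {
    x <- runif(4, 0.1, 10)
    k <- runif(1, 0.01, 100)
    expect_equal(antibody_index(x[1], x[2], x[3], x[4])$index,
                 antibody_index(k * x[1], k * x[2], x[3], x[4])$index)
  }
})

test_that("IgG4:IgG ratio", {
  expect_equal(igg4_ratio(c(IGHG1 = 3, IGHG2 = 0, IGHG3 = 0, IGHG4 = 97)), 0.97)
  expect_equal(igg4_ratio(c(IGHG1 = 0, IGHG2 = 0, IGHG3 = 0, IGHG4 = 5)), 1.0)
  expect_equal(igg4_ratio(c(IGHG1 = 2, IGHG2 = 1, IGHG3 = 1, IGHG4 = 0)), 0.0)
  expect_error(igg4_ratio(c(IGHG1 = 0, IGHG2 = 0, IGHG3 = 0, IGHG4 = 0)), "zero")
})

test_that("subclass usage counts and downstream-order violations", {
  cells <- data.frame(cell_id = c("a", "b", "c", "d"),
                      heavy_c_call = c("IGHG4", "IGHG4", "IGHG1", "IGHG4"),
                      stringsAsFactors = FALSE)
  clones <- data.frame(clone_id = c("cl1", "cl2"), size = 2L,
                       founder = c("a", "c"), stringsAsFactors = FALSE)
  clones$members <- list(c("a", "b"), c("c", "d"))
  s <- subclass_switch_summary(clones, cells)
  expect_equal(s$n_one, 1L)              # cl1 all IGHG4
  expect_equal(s$n_two, 1L)              # cl2 IGHG1 founder -> IGHG4 member
  expect_length(s$violations, 0L)

  clones$founder <- c("a", "d")          # IGHG4 founder with IGHG1 member
  s2 <- subclass_switch_summary(clones, cells)
  expect_equal(s2$violations, "cl2")

  cells$heavy_c_call[1] <- "IGHM"
  expect_error(subclass_switch_summary(clones, cells), "unknown c_call")
})

test_that("simulated repertoires never violate subclass switch order", {
  # true lineage direction from the simulator's founder flag
  tr <- small_sim$truth
  members <- split(tr$cell_id, tr$true_clone_id)
  founders <- tapply(seq_len(nrow(tr)), tr$true_clone_id,
                     function(i) tr$cell_id[i][tr$is_founder[i]])
  clones <- data.frame(clone_id = names(members),
                       size = lengths(members),
                       founder = unlist(founders[names(members)]),
                       stringsAsFactors = FALSE)
  clones$members <- unname(members)
  s <- subclass_switch_summary(clones, small_sim$cells)
  expect_length(s$violations, 0L)
  expect_equal(s$n_more, 0L)
  expect_equal(s$n_one + s$n_two, nrow(clones))
})

test_that("BCR feature table computes CDR3 charge and families", {
  cells <- data.frame(
    cell_id = c("a", "b", "c"),
    heavy_c_call = "IGHG4",
    heavy_junction_aa = c("CARDRW", "CAKDEW", "GGGGGG"),
    light_locus = "IGK",
    heavy_v_call = "IGHV3-23*01", light_v_call = "IGKV1-39*01",
    stringsAsFactors = FALSE
  )
  ft <- bcr_features(cells)
  expect_equal(ft$cdr3_charge, c(1, -1, 0))
  expect_equal(ft$cdr3_length, c(6L, 6L, 6L))
  expect_equal(ft$vh_family, rep("IGHV3", 3))
  expect_equal(ft$vl_family, rep("IGKV1", 3))
  cells$heavy_junction_aa[1] <- "CARB1W"
  expect_error(bcr_features(cells), "invalid junction_aa")
})

test_that("mutation-affinity correlation: perfect, null and simulated cases", {
  cells <- data.frame(cell_id = sprintf("f%d", 1:5),
                      endpoint_conc = 10 ^ (5:1), stringsAsFactors = FALSE)
  clones <- data.frame(clone_id = sprintf("cl%d", 1:5), size = 1L,
                       founder = cells$cell_id, stringsAsFactors = FALSE)
  clones$members <- as.list(cells$cell_id)
  counts <- setNames(1:5, cells$cell_id)
  r <- correlate_mutations_affinity(cells, clones, counts)
  expect_equal(r$rho, -1.0)

  # shuffled independent data stays near zero on average
  set.seed(43)
  rhos <- replicate(200, {
    cells$endpoint_conc <- sample(cells$endpoint_conc)
    big <- data.frame(cell_id = sprintf("g%d", 1:40),
                      endpoint_conc = 10 ^ runif(40, 0, 3))
    bigcl <- data.frame(clone_id = sprintf("bc%d", 1:40), size = 1L,
                        founder = big$cell_id, stringsAsFactors = FALSE)
    bigcl$members <- as.list(big$cell_id)
    correlate_mutations_affinity(big, bigcl, setNames(sample(0:30, 40, TRUE),
                                                      big$cell_id))$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)

  # constant mutation vector: not applicable
  r_na <- correlate_mutations_affinity(cells, clones, setNames(rep(3, 5), cells$cell_id))
  expect_true(is.na(r_na$rho))
})

test_that("simulated affinity structure yields a negative correlation", {
  sim <- simulate_repertoire(toy_lib, sim_config(n_clones = 120, seed = 55))
  cl <- cluster_clones(sim$cells)
  asg <- assign_repertoire(sim$cells, toy_lib)
  counts <- count_mutations_repertoire(sim$cells, asg)
  cl <- annotate_founders(cl, counts)
  r <- correlate_mutations_affinity(sim$cells, cl, counts)
  expect_gte(r$n, 60)
  expect_lt(r$rho, 0)
  expect_lt(r$p_value, 0.05)
})

test_that("closest identity search and the strict 80% privacy threshold", {
  expect_equal(closest_identity("CARDYW", c("CARDYW", "CAAAAA"))$closest_identity, 100)
  r <- closest_identity("AAAAAAAAAA", "AAAAAAAAAC")
  expect_equal(r$closest_identity, 90)
  expect_false(closest_identity(strrep("A", 1000),
                                paste0(strrep("A", 800), strrep("C", 200))
                                )$private)        # exactly 80.0%
  expect_true(closest_identity(strrep("A", 1000),
                               paste0(strrep("A", 799), strrep("C", 201))
                               )$private)         # 79.9%
  r2 <- closest_identity("CARDYW", c("SHORT"))
  expect_true(is.na(r2$closest_identity))
  expect_error(closest_identity("CARDYW", character(0)), "empty")

  ref <- simulate_cdr_reference(50, seed = 6)
  expect_true(all(nchar(ref) %in% 10:20))
  hit <- closest_identity(ref[1], ref)
  expect_equal(hit$closest_identity, 100)
})
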