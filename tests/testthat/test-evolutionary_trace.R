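# hand-checkable 4-row family: A,B differ at 1/10 columns, C,D differ at
# 1/10, the two blocks differ at 5/10
four_row_msa <- function() {
  msa_view(c("A", "B", "C", "D"), c(
    "AAAAAAAAAA",
    "AAAAAAAAAC",
    "TTTTTAAAAA",
    "TTTTTAAAAG"
  ))
}

test_that("p_distance matches hand-computed mismatch fractions", {
  D <- p_distance(four_row_msa())
  expect_equal(D["A", "B"], 0.1)
  expect_equal(D["C", "D"], 0.1)
  expect_equal(D["A", "C"], 0.5)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0, D = 0))
  # gaps excluded from the denominator
  m <- msa_view(c("x", "y"), c("AAAA--", "AAC-A-"))
  # shared non-gap columns: 1,2,3 -> 1 mismatch / 3
  expect_equal(p_distance(m)["x", "y"], 1 / 3)
})

test_that("UPGMA tree joins the near pairs first; partitions follow the cuts", {
  msa <- four_row_msa()
  tree <- build_distance_tree(msa)
  p1 <- partition_at_level(tree, 1)
  expect_equal(length(p1), 1L)
  expect_setequal(p1[[1]], c("A", "B", "C", "D"))
  p2 <- partition_at_level(tree, 2)
  expect_equal(length(p2), 2L)
  classes <- lapply(p2, sort)
  expect_true(any(vapply(classes, identical, logical(1), c("A", "B"))))
  expect_true(any(vapply(classes, identical, logical(1), c("C", "D"))))
  p4 <- partition_at_level(tree, 4)
  expect_equal(lengths(p4), rep(1L, 4))
  expect_error(partition_at_level(tree, 9), "level must be")
})

test_that("identical rows give a tree of height zero", {
  msa <- msa_view(c("a", "b"), c("ACDE", "ACDE"))
  tree <- build_distance_tree(msa)
  expect_equal(max(tree$hclust$height), 0)
})

test_that("NJ trees support the same level-partition interface", {
  skip_if_not_installed("phangorn")
  msa <- four_row_msa()
  tree <- build_distance_tree(msa, method = "nj")
  p2 <- partition_at_level(tree, 2)
  expect_equal(sort(lengths(p2)), c(2L, 2L))
  expect_setequal(unlist(p2), c("A", "B", "C", "D"))
})

test_that("class consensus implements the 90% rule with gap tolerance", {
  m4 <- msa_view(paste0("s", 1:4), c("A", "A", "A", "A"))
  expect_equal(class_consensus_conserved(m4, paste0("s", 1:4), 1), "A")

  m10 <- msa_view(paste0("s", 1:10),
                  c(rep("A", 9), "C"))
  expect_equal(class_consensus_conserved(m10, paste0("s", 1:10), 1,
                                         threshold = 0.90), "A")
  m10b <- msa_view(paste0("s", 1:10), c(rep("A", 8), "C", "C"))
  expect_true(is.na(class_consensus_conserved(m10b, paste0("s", 1:10), 1,
                                              threshold = 0.90)))

  # gaps excluded from the denominator: (A, A, -, -) is conserved at A
  mg <- msa_view(paste0("s", 1:4), c("A", "A", "-", "-"))
  expect_equal(class_consensus_conserved(mg, paste0("s", 1:4), 1), "A")
  # but a nearly-all-gap class is not vacuously conserved
  mg2 <- msa_view(paste0("s", 1:4), c("A", "-", "-", "-"))
  expect_true(is.na(class_consensus_conserved(mg2, paste0("s", 1:4), 1)))
  # singleton class is its own symbol
  expect_equal(class_consensus_conserved(mg, "s1", 1), "A")
  expect_error(class_consensus_conserved(mg, character(0), 1), "empty class")
})

test_that("ET ranks on an 8-row two-clade fixture behave as designed", {
  rows <- c(
    "GAKKWWAC", "GAKKWWAC", "GAKKWWAA", "GAKKWWAG",
    "GCKKYYAC", "GCKKYYAC", "GCKKYYAT", "GCKKYYAW"
  )
  msa <- msa_view(paste0("s", 1:8), rows)
  et <- compute_et_ranks(msa, L = 8)
  # column 1 fully conserved -> rank 1, flagged conserved
  expect_equal(et$ranks[1], 1L)
  expect_equal(et$trace_flags[1, 1], "conserved")
  # column 2 (A vs C by clade) conserved within classes at the 2-class level
  expect_equal(et$ranks[2], 2L)
  expect_equal(et$trace_flags[2, 2], "X")
  # columns 5-6 carry the same clade split
  expect_equal(et$ranks[5], 2L)
  # column 8 is variable within clades: high rank
  expect_gt(et$ranks[8], 2L)
})

test_that("ranks are monotone under a stricter threshold", {
  sim <- simulate_msa(msa_sim_spec(n_seqs = 64, n_cols = 50,
                                   conserved_columns = c(5L, 25L),
                                   trace_columns = c(10L, 40L),
                                   coevolving_pairs = cbind(15L, 20L)),
                      seed = 5)
  tree <- build_distance_tree(sim$msa)
  lax <- compute_et_ranks(sim$msa, tree, L = 10, threshold = 0.90)
  strict <- compute_et_ranks(sim$msa, tree, L = 10, threshold = 1.0)
  expect_true(all(strict$ranks >= lax$ranks))
})

test_that("row order does not change the ranks", {
  sim <- simulate_msa(msa_sim_spec(n_seqs = 32, n_cols = 30,
                                   conserved_columns = 5L,
                                   trace_columns = 10L,
                                   coevolving_pairs = cbind(15L, 20L)),
                      seed = 6)
  et1 <- compute_et_ranks(sim$msa, L = 8)
  set.seed(1)
  perm <- sample(length(sim$msa$ids))
  msa2 <- subset_msa(sim$msa, rows = perm)
  et2 <- compute_et_ranks(msa2, L = 8)
  expect_equal(et2$ranks, et1$ranks)
})

test_that("planted structure is recovered: conserved rank 1, trace at the clade level, noise high", {
  spec <- msa_sim_spec()
  sim <- simulate_msa(spec, seed = 11)
  et <- compute_et_ranks(sim$msa, L = 20)
  expect_true(all(et$ranks[spec$conserved_columns] == 1L))
  expect_true(all(et$ranks[spec$trace_columns] == spec$clades))
  expect_equal(unname(et$trace_flags[spec$clades, spec$trace_columns]),
               rep("X", length(spec$trace_columns)))
})

test_that("trees serialize to Newick", {
  msa <- four_row_msa()
  tree <- build_distance_tree(msa)
  p <- tempfile(fileext = ".nwk")
  write_tree_newick(tree, p)
  ph <- ape::read.tree(p)
  expect_setequal(ph$tip.label, msa$ids)
})
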