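test_that("msa_view validates and normalizes its input", {
  m <- msa_view(c("a", "b"), c("AC-D", "ac.d"))
  expect_equal(m$n_cols, 4L)
  expect_equal(unname(m$mat[2, ]), c("A", "C", "-", "D"))
  expect_error(msa_view(c("a", "a"), c("AC", "AC")), "duplicate")
  expect_error(msa_view(c("a", "b"), c("AC", "ACD")), "differ in length")
  expect_warning(msa_view("a", "AB*D"), "outside")
})

test_that("FASTA and Stockholm round-trips preserve the alignment", {
  m <- msa_view(paste0("s", 1:3), c("ACDE-", "AC-EF", "-CDEF"))
  fa <- tempfile(fileext = ".fasta")
  write_msa_fasta(m, fa)
  expect_equal(read_msa_fasta(fa)$mat, m$mat)
  sto <- tempfile(fileext = ".sto")
  write_msa_stockholm(m, sto)
  expect_equal(read_msa_stockholm(sto)$mat, m$mat)
})

test_that("consensus follows majority, alphabetical ties, and gap rules", {
  expect_equal(consensus_sequence(msa_view("a", "ACDE")), "ACDE")
  m <- msa_view(paste0("s", 1:3), c("AAA-", "ACA-", "CCG-"))
  # col1 A(2) C(1) -> A; col2 C(2) -> C; col3 A(2) -> A; col4 all-gap -> -
  expect_equal(consensus_sequence(m), "ACA-")
  tie <- msa_view(c("a", "b"), c("AG", "CG"))
  expect_equal(consensus_sequence(tie), "AG")  # A before C alphabetically
  expect_error(consensus_sequence(subset_msa(m, rows = integer(0))),
               "empty alignment")
})

test_that("smith_waterman agrees with an independent Gotoh DP oracle", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  cases <- list(
    c("HEAGAWGHEE", "PAWHEAE"),
    c("MKVLAT", "MKVLAT"),
    c("ACDEFGHIKLMNPQRSTVWY", "YWVTSRQPNMLKIHGFEDCA"),
    c("GATTACAWW", "WWGATTACA")
  )
  for (cs in cases) {
    got <- smith_waterman(cs[1], cs[2])
    expect_equal(got$score,
                 sw_oracle(cs[1], cs[2], BLOSUM62, 11, 1),
                 info = paste(cs, collapse = " vs "))
  }
  # identical sequences under a match-only scheme
  alphabet <- c(chaperonemodes:::AA1)
  mm <- matrix(-1, 20, 20, dimnames = list(alphabet, alphabet))
  diag(mm) <- 1
  r <- smith_waterman("MKVLAT", "MKVLAT", substitution_matrix = mm)
  expect_equal(r$score, 6)
  expect_equal(r$identity, 1)
})

test_that("smith_waterman floors at zero when nothing aligns", {
  alphabet <- c("A", "C")
  mm <- matrix(-1, 2, 2, dimnames = list(alphabet, alphabet))
  diag(mm) <- 1
  r <- smith_waterman("AAAA", "CCCC", substitution_matrix = mm)
  expect_equal(r$score, 0)
  expect_equal(r$identity, 0)
})

test_that("refine_msa applies the three screens as specified", {
  cons <- "IIIIIIIIII"
  rows <- c(
    s1 = "IIIIIIIIII",
    s2 = "IIIIIIIILL",     # 80% identity
    s3 = "IIIVIIIIII",     # 90%
    s4 = "IIILVLVLVL",     # 30% identity: dropped at step (i)
    s5 = "IIIIIIII--"      # gaps, still 100% identical where aligned
  )
  raw <- msa_view(names(rows), unname(rows))
  out <- refine_msa(raw, consensus = cons, identity_min = 0.40, max_gaps = 10)
  expect_equal(out$report$sequences_out[1], 4L)
  expect_false("s4" %in% out$msa$ids)

  # insertion columns: 3 gap-majority columns disappear
  with_ins <- msa_view(
    paste0("t", 1:4),
    c("AC-DE--F", "ACWDE--F", "AC-DEA-F", "AC-DE-CF")
  )
  out2 <- refine_msa(with_ins, identity_min = 0, max_gaps = 10)
  expect_equal(out2$msa$n_cols, 5L)
  expect_equal(out2$report$columns_out, c(8L, 5L, 5L))
  # step (ii) never changes row count; (i)/(iii) never change column count
  expect_equal(out2$report$sequences_in[2], out2$report$sequences_out[2])
  expect_equal(out2$report$columns_out[1], with_ins$n_cols)

  # gap screen: a row with 11 gaps is removed at max_gaps = 10
  wide <- msa_view(
    c("u1", "u2"),
    c(strrep("A", 20),
      paste0(strrep("-", 11), strrep("A", 9)))
  )
  out3 <- refine_msa(wide, consensus = strrep("A", 20),
                     identity_min = 0, max_gaps = 10)
  expect_equal(out3$msa$ids, "u1")
  expect_error(refine_msa(wide, consensus = strrep("A", 20),
                          identity_min = 0, max_gaps = 0, ),
               NA)  # u1 has zero gaps, survives
})

test_that("refine_msa is idempotent", {
  sim <- simulate_msa(msa_sim_spec(n_seqs = 48, n_cols = 40,
                                   conserved_columns = c(5L, 20L),
                                   trace_columns = 10L,
                                   coevolving_pairs = cbind(25L, 30L),
                                   gap_rate = 0.02),
                      seed = 17)
  once <- refine_msa(sim$msa)
  twice <- refine_msa(once$msa)
  expect_equal(twice$msa$mat, once$msa$mat)
  expect_equal(twice$msa$ids, once$msa$ids)
})

test_that("survival under random corruption matches the binomial expectation", {
  # rows are the consensus with per-site corruption; identity is binomial
  set.seed(202)
  cons <- paste(sample(chaperonemodes:::AA1, 60, replace = TRUE), collapse = "")
  p_bad <- 0.5
  n_rows <- 200
  rows <- vapply(seq_len(n_rows), function(i) {
    s <- chaperonemodes:::chars(cons)
    hit <- runif(60) < p_bad
    s[hit] <- vapply(which(hit), function(j) {
      sample(setdiff(chaperonemodes:::AA1, s[j]), 1)
    }, character(1))
    paste(s, collapse = "")
  }, character(1))
  raw <- msa_view(sprintf("r%03d", seq_len(n_rows)), rows)
  # local SW trims poorly matching ends, so use full-target identity
  out <- refine_msa(raw, consensus = cons, identity_min = 0.40,
                    max_gaps = 10, identity_on = "target")
  p_keep <- stats::pbinom(0.40 * 60 - 1, 60, 1 - p_bad, lower.tail = FALSE)
  expected <- n_rows * p_keep
  sdev <- sqrt(n_rows * p_keep * (1 - p_keep))
  expect_lt(abs(out$report$sequences_out[1] - expected), 4 * sdev + 1)
})
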