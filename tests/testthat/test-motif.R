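cys_pat <- compile_pattern("CxCxxC", "H:4-6:upstream")

test_that("pattern compilation places literals and validates input", {
  p <- compile_pattern("CxCxxC")
  expect_equal(p$length, 6L)
  expect_equal(p$literal_offsets, c(0L, 2L, 5L))

  expect_equal(compile_pattern("C")$length, 1L)

  err <- tryCatch(compile_pattern("CzC"), error = identity)
  expect_s3_class(err, "sepmotif_pattern_error")
  expect_match(conditionMessage(err), "position 2")

  expect_error(compile_pattern("CxC", "H:6-4:upstream"),
               class = "sepmotif_pattern_error")
  expect_error(compile_pattern("CxC", "H:4-6:sideways"),
               class = "sepmotif_pattern_error")
})

test_that("scanning finds minimal matches and evaluates upstream windows", {
  h <- scan_motif("CACAAC", compile_pattern("CxCxxC"))
  expect_equal(h$start, 1L)
  expect_equal(h$matched, "CACAAC")
  expect_true(h$context_ok)        # no contexts declared

  # H at 1, first C at 7: offset 6 lies in the inclusive 4-6 window
  h2 <- scan_motif("HAAAAACACAAC", cys_pat)
  expect_equal(h2$start, 7L)
  expect_true(h2$context_ok)
  expect_equal(h2$context_positions, "1")

  # H at offset 3 only: outside the window
  h3 <- scan_motif("AAAHAACACAAC", cys_pat)
  expect_equal(h3$start, 7L)
  expect_false(h3$context_ok)
})

test_that("X never matches a literal and never satisfies a context", {
  expect_equal(nrow(scan_motif("CACAAX", compile_pattern("CxCxxC"))), 0L)
  h <- scan_motif("XAAAAACACAAC", cys_pat)   # X where the H would be
  expect_false(h$context_ok)
  # X under a wildcard position is fine
  expect_equal(scan_motif("CXCXXC", compile_pattern("CxCxxC"))$start, 1L)
})

test_that("overlapping matches are all reported in ascending order", {
  h <- scan_motif("CCCCCC", compile_pattern("CxC"))
  expect_equal(h$start, 1:4)
})

test_that("scan agrees with the brute-force matcher on random sequences", {
  withr::local_seed(23)
  pats <- list(compile_pattern("CxCxxC", "H:4-6:upstream"),
               compile_pattern("CxC"),
               compile_pattern("WxxD", "K:2-3:downstream"))
  for (i in 1:40) {
    s <- random_sequence(sample(20:200, 1),
                         letters = c(AA20_T, "X"))
    p <- pats[[sample(length(pats), 1)]]
    got <- scan_motif(s, p)
    ref <- naive_scan(s, p)
    expect_equal(got$start, ref$start)
    expect_equal(got$matched, ref$matched)
    expect_equal(got$context_ok, ref$context_ok)
  }
})

test_that("hits shift by k when a neutral prefix is prepended", {
  withr::local_seed(29)
  neutral <- setdiff(AA20_T, c("C", "H"))
  for (i in 1:15) {
    s <- random_sequence(100)
    k <- sample(1:20, 1)
    s2 <- paste0(paste(sample(neutral, k, TRUE), collapse = ""), s)
    h <- scan_motif(s, cys_pat)
    h2 <- scan_motif(s2, cys_pat)
    expect_equal(h2$start, h$start + k)
  }
})

test_that("clade survey counts motif, uniqueness and context correctly", {
  withr::local_seed(31)
  base <- vapply(1:10, function(i)
    random_sequence(60, letters = setdiff(AA20_T, c("C", "H"))), "")
  planted <- vapply(seq_along(base), function(i) {
    s <- seq_set(paste0("s", i), base[i])
    plant_motif(s, "CxCxxC", 30, with_context = i <= 9)$residues
  }, "")
  seqs <- seq_set(paste0("s", 1:10), planted)
  clades <- group_assignment(seqs$id, "cladeA")
  sv <- motif_survey(seqs, clades, cys_pat)
  expect_equal(sv$n_sequences, 10L)
  expect_equal(sv$frac_motif, 1)
  expect_equal(sv$frac_unique, 1)
  expect_equal(sv$frac_context, 0.9)

  # a clade carrying no motif at all
  seqs2 <- seq_set(c(seqs$id, "t1", "t2"),
                   c(seqs$residues, base[1:2]))
  clades2 <- group_assignment(seqs2$id, c(rep("cladeA", 10), "cladeB",
                                          "cladeB"))
  sv2 <- motif_survey(seqs2, clades2, cys_pat)
  expect_equal(sv2$frac_motif[sv2$clade == "cladeB"], 0)
  expect_true(is.na(sv2$frac_context[sv2$clade == "cladeB"]))
})

test_that("motif column consistency flags shifted rows and missing rows", {
  # all three carry the motif literals at columns 3, 5, 8
  aln <- alignment(c("a", "b", "c"),
                   c("AACACAAC--", "AACACAAC--", "AACACAAC-A"))
  rep1 <- motif_column_consistency(aln, compile_pattern("CxCxxC"))
  expect_true(rep1$consistent)
  expect_equal(rep1$modal_columns, c(3L, 5L, 8L))

  # an unaligned insertion shifts one row's motif columns
  aln2 <- alignment(c("a", "b", "shifted", "empty"),
                    c("-AACACAAC-", "-AACACAAC-", "AACACAAC--",
                      "AAAAAAAAA-"))
  rep2 <- motif_column_consistency(aln2, compile_pattern("CxCxxC"))
  expect_false(rep2$consistent)
  expect_equal(rep2$outliers, "shifted")
  expect_equal(rep2$missing, "empty")
})

test_that("phyletic matrix collapses the survey to presence/absence", {
  seqs <- seq_set(c("a1", "a2", "b1", "b2"),
                  c("AAACACAACAA", "AAAAAAAAAAA", "AAAAAAAAAAA",
                    "AAAAAAAAAAA"))
  clades <- group_assignment(seqs$id, c("A", "A", "B", "B"))
  pm <- phyletic_matrix(seqs, clades, compile_pattern("CxCxxC"),
                        min_length = 5L)
  expect_equal(pm$motif_present[pm$clade == "A"], 1L)
  expect_equal(pm$motif_present[pm$clade == "B"], 0L)
  expect_equal(pm$sequence_truncated, c(0L, 0L))
})
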