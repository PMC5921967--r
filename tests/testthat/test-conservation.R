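test_that("residue classification follows the physicochemical table", {
  expect_equal(classify_residue("D"), "negative")
  expect_equal(classify_residue("W"), "aromatic")
  expect_equal(classify_residue("X"), "other")
  expect_equal(classify_residue(c("k", "S")), c("positive", "alcohol"))
  expect_error(classify_residue("-"), class = "sepmotif_format_error")
})

test_that("column states distinguish universal, group-identical and class columns", {
  aln <- alignment(paste0("s", 1:4),
                   c("WCD", "WCE", "WSD", "WSE"))
  g <- group_assignment(paste0("s", 1:4), c("nem", "nem", "vert", "vert"))
  prof <- column_conservation(aln, g)

  expect_true(prof$universal[1])                   # all W
  expect_false(prof$universal[2])                  # C vs S per group
  st <- prof$states
  expect_equal(st$state[st$column == 2 & st$group == "nem"], "identical")
  expect_equal(st$value[st$column == 2 & st$group == "nem"], "C")
  expect_equal(st$state[st$column == 2 & st$group == "vert"], "identical")
  expect_equal(st$state[st$column == 3 & st$group == "nem"],
               "class_conserved")                  # D/E share 'negative'
  expect_equal(st$value[st$column == 3 & st$group == "nem"], "negative")
  expect_equal(universal_positions(prof), 1L)
})

test_that("gaps and unknown residues block conservation calls", {
  aln <- alignment(paste0("s", 1:4), c("W-X", "WAX", "WAA", "WAA"))
  g <- group_assignment(paste0("s", 1:4), rep(c("a", "b"), each = 2))
  prof <- column_conservation(aln, g)
  st <- prof$states
  expect_equal(st$state[st$column == 2 & st$group == "a"], "gapped")
  expect_equal(st$state[st$column == 3 & st$group == "a"], "unconserved")
  expect_equal(st$state[st$column == 3 & st$group == "b"], "identical")
})

test_that("groups of fewer than 2 members are rejected", {
  aln <- alignment(c("a", "b", "c"), c("AA", "AA", "AA"))
  g <- group_assignment(c("a", "b", "c"), c("g1", "g1", "g2"))
  expect_error(column_conservation(aln, g), class = "sepmotif_config_error")
  expect_error(column_conservation(aln, group_assignment(c("a", "b"), "g1")),
               class = "sepmotif_config_error")
})

test_that("profiles match the naive per-residue oracle on fuzzed alignments", {
  withr::local_seed(101)
  for (i in 1:25) {
    aln <- random_alignment(sample(4:8, 1), sample(10:40, 1))
    g <- random_groups(aln$id, sample(2:3, 1))
    prof <- column_conservation(aln, g)
    ref <- naive_profile(aln, g)
    a <- prof$states[order(prof$states$group, prof$states$column), ]
    b <- ref$states[order(ref$states$group, ref$states$column), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
    expect_equal(prof$universal, ref$universal)
  }
})

test_that("profiles are invariant to row order and duplicated members", {
  withr::local_seed(7)
  aln <- random_alignment(6, 30)
  g <- random_groups(aln$id, 2)
  prof <- column_conservation(aln, g)

  perm <- sample(seq_along(aln$id))
  aln2 <- alignment(aln$id[perm], aln$rows[perm])
  expect_equal(column_conservation(aln2, g)$universal, prof$universal)

  # appending a copy of an existing member cannot change any state
  pick <- 1L
  aln3 <- alignment(c(aln$id, "dup"), c(aln$rows, aln$rows[pick]))
  g3 <- group_assignment(c(names(g), "dup"),
                         c(unclass(g), unclass(g)[aln$id[pick]]))
  prof3 <- column_conservation(aln3, g3)
  expect_equal(prof3$universal, prof$universal)
  expect_equal(prof3$states[prof3$states$group == unclass(g)[[1]] &
                              prof3$states$column <= aln$ncol, "state"],
               prof$states[prof$states$group == unclass(g)[[1]], "state"])
})

test_that("universal columns are identical in every group with one residue", {
  withr::local_seed(11)
  n_checked <- 0L
  for (i in 1:10) {
    aln <- random_alignment(6, 25, gap_p = 0.15)
    # force a handful of identical, gap-free columns into the fuzz
    m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
    m[, c(3, 11, 19)] <- rep(c("W", "D", "L"), each = 6)
    aln <- alignment(aln$id, apply(m, 1, paste, collapse = ""))
    g <- random_groups(aln$id, 2)
    prof <- column_conservation(aln, g)
    ucols <- universal_positions(prof)
    expect_true(all(c(3L, 11L, 19L) %in% ucols))
    for (col in ucols) {
      st <- prof$states[prof$states$column == col, ]
      expect_true(all(st$state == "identical"))
      expect_equal(length(unique(st$value)), 1L)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 30L)
})

test_that("column/residue maps are mutually inverse and handle gaps", {
  aln <- alignment(c("a", "b"), c("A-C", "AAC"))
  expect_equal(column_to_residue(aln, "a", 3), 2L)
  expect_true(is.na(column_to_residue(aln, "a", 2)))
  expect_equal(residue_to_column(aln, "a", 2), 3L)
  expect_error(column_to_residue(aln, "zz", 1), class = "sepmotif_key_error")

  withr::local_seed(13)
  for (i in 1:20) {
    aln <- random_alignment(3, sample(10:50, 1))
    id <- sample(aln$id, 1)
    n_res <- nchar(gsub("-", "", aln_row_for_test(aln, id)))
    res <- sample(n_res, min(5, n_res))
    expect_equal(column_to_residue(aln, id, residue_to_column(aln, id, res)),
                 res)
  }
})

test_that("variant overlap equals set intersection of positions", {
  v <- data.frame(pos = c(10L, 20L), ref = "A", alt = "T", freq = 0.01)
  expect_equal(nrow(variant_overlap(c(754L, 1146L), v)), 0L)

  v2 <- data.frame(pos = 754L, ref = "W", alt = "C", freq = 1e-4)
  expect_equal(variant_overlap(c(754L), v2)$conserved_pos, 754L)

  withr::local_seed(17)
  for (i in 1:20) {
    cons <- sample(1000, sample(5:30, 1))
    vpos <- sample(1000, sample(5:30, 1))
    v3 <- data.frame(pos = vpos, ref = "A", alt = "V",
                     freq = runif(length(vpos)))
    got <- sort(unique(variant_overlap(cons, v3)$pos))
    expect_equal(got, sort(intersect(cons, vpos)))
  }

  expect_error(variant_overlap(1L, data.frame(pos = "x", ref = 1)),
               class = "sepmotif_format_error")
})
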