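small_spec <- function(seed, indel_rate = 0.02) {
  synthetic_spec(
    groups = c(g1 = 4L, g2 = 5L),
    length = 120L,
    universal_columns = data.frame(column = c(10L, 40L, 90L),
                                   residue = c("W", "L", "R")),
    group_columns = list(g1 = data.frame(column = 25L, residue = "D")),
    class_columns = list(g2 = data.frame(column = 60L, class = "aromatic")),
    motif = list(pattern = "CxCxxC", anchor = 75L,
                 fraction_with_context = 1),
    indel_rate = indel_rate,
    seed = seed)
}

test_that("identical seeds reproduce the alignment byte for byte", {
  a <- gen_alignment(small_spec(99))
  b <- gen_alignment(small_spec(99))
  expect_identical(a$aln$rows, b$aln$rows)
  expect_identical(a$truth, b$truth)
  c <- gen_alignment(small_spec(100))
  expect_false(identical(a$aln$rows, c$aln$rows))
})

test_that("zero indel rate keeps the alignment at the ungapped length", {
  sim <- gen_alignment(small_spec(3, indel_rate = 0))
  expect_equal(sim$aln$ncol, 120L)
  expect_false(any(grepl("-", sim$aln$rows, fixed = TRUE)))
})

test_that("planted universal columns are recovered exactly", {
  # four planted universals + three motif cysteines = seven, the column
  # count expected of a seven-position conserved core
  spec <- synthetic_spec(
    groups = c(nem = 5L, vert = 4L),
    length = 700L,
    universal_columns = data.frame(column = c(93L, 158L, 584L, 685L),
                                   residue = c("W", "L", "W", "R")),
    motif = list(pattern = "CxCxxC", anchor = 448L,
                 fraction_with_context = 0.9),
    indel_rate = 0.02, seed = 7)
  sim <- gen_alignment(spec)
  prof <- column_conservation(sim$aln, sim$groups)
  found <- universal_positions(prof)
  expect_equal(found, sort(c(93L, 158L, 584L, 685L, 448L, 450L, 453L)))
  expect_equal(length(found), 7L)
  expect_equal(found, sim$truth$universal_columns)
})

test_that("group and class columns carry their planted states", {
  sim <- gen_alignment(small_spec(21))
  prof <- column_conservation(sim$aln, sim$groups)
  st <- prof$states
  expect_equal(st$state[st$column == 25 & st$group == "g1"], "identical")
  expect_equal(st$value[st$column == 25 & st$group == "g1"], "D")
  expect_false(identical(st$state[st$column == 25 & st$group == "g2"],
                         "identical") &&
                 identical(st$value[st$column == 25 & st$group == "g2"], "D"))
  expect_true(st$state[st$column == 60 & st$group == "g2"] %in%
                c("identical", "class_conserved"))
  if (st$state[st$column == 60 & st$group == "g2"] == "class_conserved")
    expect_equal(st$value[st$column == 60 & st$group == "g2"], "aromatic")
})

test_that("planted motifs are found uniquely with the planted context", {
  sim <- gen_alignment(small_spec(5))
  pat <- compile_pattern("CxCxxC", "H:4-6:upstream")
  seqs <- ungap(sim$aln)
  truth <- sim$truth$motif$starts
  for (i in seq_len(nrow(seqs))) {
    h <- scan_motif(seqs$residues[i], pat, id = seqs$id[i])
    expect_equal(nrow(h), 1L)
    expect_equal(h$start, truth$start[truth$id == seqs$id[i]])
    expect_equal(h$context_ok, truth$context_ok[truth$id == seqs$id[i]])
  }
})

test_that("infeasible specs are rejected up front", {
  expect_error(synthetic_spec(c(g1 = 2L), length = 10L,
                              universal_columns = data.frame(
                                column = c(3L, 3L), residue = c("W", "L")),
                              seed = 1),
               class = "sepmotif_spec_error")
  expect_error(synthetic_spec(c(g1 = 2L), length = 10L,
                              motif = list(pattern = "CxCxxC", anchor = 8L),
                              seed = 1),
               class = "sepmotif_spec_error")
  expect_error(synthetic_spec(c(g1 = 2L), length = 20L,
                              universal_columns = data.frame(column = 12L,
                                                             residue = "W"),
                              motif = list(pattern = "CxCxxC", anchor = 10L),
                              seed = 1),
               class = "sepmotif_spec_error")
  expect_error(synthetic_spec(c(g1 = 2L), length = 50L, seed = NULL),
               class = "sepmotif_spec_error")
})

test_that("plant_motif reproduces the worked C448/H442 geometry", {
  withr::local_seed(55)
  base <- seq_set("ce_synth",
                  random_sequence(700, letters = setdiff(AA20_T,
                                                         c("C", "H"))))
  pat <- compile_pattern("CxCxxC", "H:4-6:upstream")
  s <- plant_motif(base, "CxCxxC", 448, with_context = TRUE, offsets = 6)
  h <- scan_motif(s$residues, pat, id = s$id)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 448L)
  expect_true(h$context_ok)
  expect_equal(h$context_positions, "442")
  expect_equal(substr(s$residues, 442, 442), "H")

  s2 <- plant_motif(base, "CxCxxC", 448, with_context = FALSE)
  h2 <- scan_motif(s2$residues, pat)
  expect_equal(h2$start, 448L)
  expect_false(h2$context_ok)

  expect_error(plant_motif(base, "CxCxxC", 698), class = "sepmotif_spec_error")
  expect_error(plant_motif(base, "CxCxxC", 4), class = "sepmotif_spec_error")
})

test_that("ideal helix geometry yields near-neighbour contacts", {
  m <- gen_structure(10, unresolved = 3L, seed = 2)
  expect_equal(nrow(m), 9L)
  expect_equal(unresolved_positions(3L, m), 3L)

  full <- gen_structure(10, seed = 2)
  ca <- as.matrix(full[, c("ca_x", "ca_y", "ca_z")])
  d_consec <- sqrt(rowSums((ca[-1, ] - ca[-10, ])^2))
  # closed-form chord of the helix: sqrt((2 r sin(t/2))^2 + rise^2)
  chord <- sqrt((2 * 2.3 * sin(100 * pi / 360))^2 + 1.5^2)
  expect_equal(d_consec, rep(chord, 9), tolerance = 1e-9)
  expect_true(all(d_consec < 6))
  # on an all-glycine helix the contact criterion falls back to C-alpha,
  # so every consecutive pair is a contact under the 6 Angstrom cutoff
  gly <- gen_structure(10, seed = 2, aa = rep("G", 10))
  pairs <- contact_pairs(gly, 1:10)
  expect_true(all(paste(1:9, 2:10) %in% paste(pairs$pos_i, pairs$pos_j)))

  # a second helix translated 100 Angstrom away shares no contacts
  far <- gen_structure(2, seed = 2, origin = c(100, 0, 0))
  combined <- structure_model(
    c(full$resnum, far$resnum + 100L),
    c(full$aa, far$aa),
    rbind(as.matrix(full[, c("ca_x", "ca_y", "ca_z")]),
          as.matrix(far[, c("ca_x", "ca_y", "ca_z")])),
    rbind(as.matrix(full[, c("cb_x", "cb_y", "cb_z")]),
          as.matrix(far[, c("cb_x", "cb_y", "cb_z")])))
  cross <- contact_pairs(combined, c(1:10, 101:102))
  expect_false(any(cross$pos_i <= 10 & cross$pos_j > 100))

  expect_error(gen_structure(0), class = "sepmotif_spec_error")
  expect_error(gen_structure(5, unresolved = 9L),
               class = "sepmotif_spec_error")
})
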