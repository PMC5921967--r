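# Seeded generators for grouped alignments with planted conservation,
# sequences with planted context-constrained motifs, and ideal-helix
# structure models — each with machine-readable ground truth, so every
# pipeline stage can be verified offline against known truth.

#' Specification for a synthetic grouped alignment
#'
#' Describes the ground truth to plant: per-group membership counts,
#' universally conserved columns, group-specific identical columns,
#' class-conserved columns, an optional motif with its upstream context
#' residue, and a per-(sequence, column) gap rate. Planted columns must be
#' disjoint from each other and from the motif region (pattern plus
#' context window).
#'
#' @param groups Named integer vector: group label -> number of sequences
#'   (each group needs >= 2 members for conservation calls).
#' @param length Ungapped sequence length (columns before gaps; gaps are
#'   planted as deletions, so the alignment keeps this column count).
#' @param universal_columns Data frame (`column`, `residue`) of columns
#'   identical across *all* rows.
#' @param group_columns Named list (per group label) of data frames
#'   (`column`, `residue`): columns identical within the group and
#'   guaranteed non-identical in other groups.
#' @param class_columns Named list (per group label) of data frames
#'   (`column`, `class`): columns where the group's residues vary within
#'   one physicochemical class.
#' @param motif Optional list: `pattern` (string, e.g. `"CxCxxC"`),
#'   `anchor` (column of the first pattern position), `context_residue`
#'   (default `"H"`), `context_offsets` (default `4:6`, upstream),
#'   `fraction_with_context` in [0, 1] (default 1).
#' @param background Optional named probability vector over residue
#'   letters; by default uniform over the 20 letters, excluding the motif's
#'   literal letters whenever a motif is planted (keeps the planted motif
#'   provably unique, see the package vignette).
#' @param indel_rate Per-(sequence, column) gap probability outside
#'   protected (planted) columns.
#' @param seed Mandatory integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(groups, length,
                           universal_columns = NULL,
                           group_columns = NULL,
                           class_columns = NULL,
                           motif = NULL,
                           background = NULL,
                           indel_rate = 0,
                           seed) {
  if (missing(seed) || is.null(seed))
    abort("synthetic_spec requires an explicit seed", "spec_error")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    abort("groups must be a named vector: label -> n_sequences", "spec_error")
  if (any(groups < 1L))
    abort("every group needs at least one sequence", "spec_error")
  length <- as.integer(length)
  if (length < 1L) abort("length must be >= 1", "spec_error")
  if (indel_rate < 0 || indel_rate >= 1)
    abort("indel_rate must lie in [0, 1)", "spec_error")

  uc <- normalize_planted(universal_columns, c("column", "residue"))
  gc <- lapply(group_columns, normalize_planted, c("column", "residue"))
  cc <- lapply(class_columns, normalize_planted, c("column", "class"))
  if (!is.null(group_columns) &&
      !all(names(gc) %in% names(groups)))
    abort("group_columns must be named by group label", "spec_error")
  if (!is.null(class_columns) &&
      !all(names(cc) %in% names(groups)))
    abort("class_columns must be named by group label", "spec_error")

  motif_region <- integer(0)
  pat <- NULL
  if (!is.null(motif)) {
    motif$context_residue <- motif$context_residue %||% "H"
    motif$context_offsets <- motif$context_offsets %||% 4:6
    motif$fraction_with_context <- motif$fraction_with_context %||% 1
    if (motif$fraction_with_context < 0 || motif$fraction_with_context > 1)
      abort("fraction_with_context must lie in [0, 1]", "spec_error")
    pat <- compile_pattern(motif$pattern)
    if (is.null(motif$anchor)) abort("motif needs an anchor column", "spec_error")
    a <- as.integer(motif$anchor)
    lo <- a - max(motif$context_offsets)
    hi <- a + pat$length - 1L
    if (lo < 1L || hi > length)
      abort(sprintf("motif window %d..%d outside sequence 1..%d",
                    lo, hi, length), "spec_error")
    motif$anchor <- a
    motif_region <- seq.int(lo, hi)
  }

  planted <- c(uc$column,
               unlist(lapply(gc, `[[`, "column"), use.names = FALSE),
               unlist(lapply(cc, `[[`, "column"), use.names = FALSE))
  if (any(planted < 1L) || any(planted > length))
    abort("planted column outside 1..length", "spec_error")
  if (anyDuplicated(planted))
    abort("planted columns must be disjoint", "spec_error")
  if (any(planted %in% motif_region))
    abort("planted columns clash with the motif region", "spec_error")
  if (length(planted) > length)
    abort("more planted columns than sequence length", "spec_error")

  structure(list(groups = groups, length = length,
                 universal_columns = uc, group_columns = gc,
                 class_columns = cc, motif = motif,
                 background = background,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

normalize_planted <- function(x, cols) {
  if (is.null(x))
    return(stats::setNames(data.frame(integer(0), character(0),
                                      stringsAsFactors = FALSE), cols))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(cols %in% names(x)))
    abort(sprintf("planted-column table needs columns %s",
                  paste(cols, collapse = ", ")), "spec_error")
  x[[1L]] <- as.integer(x[[cols[1L]]])
  x
}

# Background sampling pool: uniform over the 20 residues minus `exclude`,
# unless an explicit distribution was supplied.
background_pool <- function(spec, exclude) {
  if (!is.null(spec$background)) {
    p <- spec$background
    return(list(letters = names(p), prob = unname(p) / sum(p)))
  }
  pool <- setdiff(AA20, exclude)
  list(letters = pool, prob = rep(1 / length(pool), length(pool)))
}

#' Generate a grouped alignment with known ground truth
#'
#' Builds an alignment in which planted universal columns are identical
#' across all rows, group columns are identical within their group and
#' forced non-identical outside it, class columns vary within a
#' physicochemical class, and every other column samples the background.
#' When a motif is specified it is planted in every row at the anchor
#' column, with the context residue written at a random upstream offset in
#' the declared range for `fraction_with_context` of the rows; in the
#' remaining rows the context residue is scrubbed from the window. Gaps
#' are planted as per-(row, column) deletions at `indel_rate`, never
#' inside planted columns or the motif region. Fully reproducible from the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `aln` ([alignment()]), `groups` ([group_assignment()]),
#'   `truth` — list with `universal_columns` (planted universals plus the
#'   motif's literal columns, which are identical in all rows by
#'   construction), `motif` (`anchor`, per-row `starts` data frame with
#'   residue-index starts and context flags), and `gaps`.
#' @export
gen_alignment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  labels <- names(spec$groups)
  n <- sum(spec$groups)
  g <- rep(labels, spec$groups)
  ids <- unlist(lapply(labels, function(l)
    paste0(l, "_", seq_len(spec$groups[[l]]))), use.names = FALSE)

  pat <- if (!is.null(spec$motif)) compile_pattern(spec$motif$pattern)
  literal_letters <- if (!is.null(pat))
    unique(pat$elements[pat$elements != "x"]) else character(0)
  bg <- background_pool(spec, literal_letters)

  m <- matrix(sample(bg$letters, n * spec$length, replace = TRUE,
                     prob = bg$prob),
              nrow = n, ncol = spec$length)

  uc <- spec$universal_columns
  for (i in seq_len(nrow(uc))) m[, uc$column[i]] <- uc$residue[i]

  for (lab in names(spec$group_columns)) {
    tab <- spec$group_columns[[lab]]
    for (i in seq_len(nrow(tab))) {
      col <- tab$column[i]; res <- tab$residue[i]
      m[g == lab, col] <- res
      # other groups must not be identical with the same residue there
      clash <- which(g != lab & m[, col] == res)
      if (length(clash) > 0L) {
        alt <- setdiff(bg$letters, res)
        m[clash, col] <- sample(alt, length(clash), replace = TRUE)
      }
    }
  }

  class_members <- split(names(default_class_table()),
                         unname(default_class_table()))
  for (lab in names(spec$class_columns)) {
    tab <- spec$class_columns[[lab]]
    for (i in seq_len(nrow(tab))) {
      pool <- setdiff(class_members[[tab$class[i]]],
                      c(literal_letters, "X"))
      if (length(pool) == 0L)
        abort(sprintf("class '%s' has no residues outside the motif letters",
                      tab$class[i]), "spec_error")
      rows <- which(g == lab)
      m[rows, tab$column[i]] <- sample(pool, length(rows), replace = TRUE)
    }
  }

  protected <- c(uc$column,
                 unlist(lapply(spec$group_columns, `[[`, "column"),
                        use.names = FALSE),
                 unlist(lapply(spec$class_columns, `[[`, "column"),
                        use.names = FALSE))
  motif_truth <- NULL
  if (!is.null(spec$motif)) {
    a <- spec$motif$anchor
    offs <- spec$motif$context_offsets
    ctx_res <- spec$motif$context_residue
    window <- seq.int(a - max(offs), a - min(offs))
    # gap-protect the whole stretch from the context window through the
    # pattern, so residue-coordinate offsets equal column offsets
    protected <- c(protected, seq.int(a - max(offs), a + pat$length - 1L))
    n_ctx <- round(spec$motif$fraction_with_context * n)
    ctx_rows <- sort(sample.int(n, n_ctx))
    ctx_offset <- rep(NA_integer_, n)
    for (r in seq_len(n)) {
      lit <- pat$elements != "x"
      m[r, a + which(lit) - 1L] <- pat$elements[lit]
      # window: scrub stray context residues, then plant one if selected
      stray <- window[m[r, window] == ctx_res]
      if (length(stray) > 0L)
        m[r, stray] <- sample(setdiff(bg$letters, ctx_res),
                              length(stray), replace = TRUE)
      if (r %in% ctx_rows) {
        u <- if (length(offs) == 1L) offs else sample(offs, 1L)
        m[r, a - u] <- ctx_res
        ctx_offset[r] <- u
      }
    }
    motif_truth <- list(anchor = a, pattern = spec$motif$pattern,
                        context_rows = ctx_rows, context_offset = ctx_offset)
  }

  gaps <- NULL
  if (spec$indel_rate > 0) {
    free <- setdiff(seq_len(spec$length), protected)
    hit <- matrix(runif(n * length(free)) < spec$indel_rate,
                  nrow = n)
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      m[cbind(idx[, 1L], free[idx[, 2L]])] <- "-"
      gaps <- data.frame(id = ids[idx[, 1L]], column = free[idx[, 2L]],
                         stringsAsFactors = FALSE)
      gaps <- gaps[order(gaps$id, gaps$column), ]
      rownames(gaps) <- NULL
    }
  }

  aln <- alignment(ids, apply(m, 1L, paste, collapse = ""))

  truth_universal <- sort(unique(c(
    uc$column,
    if (!is.null(pat)) spec$motif$anchor + pat$literal_offsets,
    # degenerate context settings pin the context residue to one column
    if (!is.null(spec$motif) &&
        spec$motif$fraction_with_context == 1 &&
        length(unique(spec$motif$context_offsets)) == 1L)
      spec$motif$anchor - spec$motif$context_offsets[1L]
  )))

  starts <- NULL
  if (!is.null(motif_truth)) {
    a <- motif_truth$anchor
    start_res <- vapply(seq_len(n), function(r) {
      sum(m[r, seq_len(a)] != "-")   # residue index of the anchor column
    }, integer(1L))
    starts <- data.frame(id = ids, start = start_res,
                         context_ok = seq_len(n) %in% motif_truth$context_rows,
                         context_offset = motif_truth$context_offset,
                         stringsAsFactors = FALSE)
    motif_truth$starts <- starts
  }

  list(aln = aln,
       groups = group_assignment(ids, g),
       truth = list(universal_columns = truth_universal,
                    universal_planted = uc,
                    group_columns = spec$group_columns,
                    class_columns = spec$class_columns,
                    motif = motif_truth,
                    gaps = gaps))
}

#' Plant a motif (with optional upstream context) into a sequence
#'
#' Writes the pattern literals at their offsets from `start`; wildcard
#' positions keep the original residue unless it equals a pattern literal
#' (which could create a spurious overlapping match), in which case it is
#' resampled. With `with_context` the context residue is written at a
#' uniformly chosen upstream offset from `offsets`; without it, any copy of
#' the context residue inside the window is replaced. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param seq A single-row [seq_set()].
#' @param pattern Pattern string or [compile_pattern()] result.
#' @param start 1-based residue index for the first pattern position.
#' @param with_context Plant the context residue?
#' @param context_residue Context residue letter (default `"H"`).
#' @param offsets Inclusive upstream offset range (default `4:6`).
#' @return The modified single-row [seq_set()].
#' @export
plant_motif <- function(seq, pattern, start, with_context = TRUE,
                        context_residue = "H", offsets = 4:6) {
  stopifnot(inherits(seq, "seq_set"), nrow(seq) == 1L)
  pat <- if (inherits(pattern, "motif_pattern")) pattern
         else compile_pattern(pattern)
  start <- as.integer(start)
  chars <- strsplit(seq$residues[1L], "")[[1L]]
  L <- length(chars)
  if (start < 1L || start + pat$length - 1L > L)
    abort(sprintf("motif at %d..%d does not fit in sequence of length %d",
                  start, start + pat$length - 1L, L), "spec_error")
  if (with_context && start - max(offsets) < 1L)
    abort("context window extends beyond the sequence start", "spec_error")
  literals <- unique(pat$elements[pat$elements != "x"])
  pool <- setdiff(AA20, c(literals, context_residue))
  for (k in seq_len(pat$length)) {
    e <- pat$elements[k]
    i <- start + k - 1L
    if (e != "x") chars[i] <- e
    else if (chars[i] %in% literals) chars[i] <- sample(pool, 1L)
  }
  window <- seq2(start - max(offsets), start - min(offsets))
  window <- window[window >= 1L]
  if (with_context) {
    u <- if (length(offsets) == 1L) offsets else sample(offsets, 1L)
    chars[start - u] <- context_residue
  } else if (length(window) > 0L) {
    stray <- window[chars[window] == context_residue]
    if (length(stray) > 0L)
      chars[stray] <- sample(pool, length(stray), replace = TRUE)
  }
  seq_set(seq$id[1L], paste(chars, collapse = ""), seq$description[1L])
}

#' Generate an ideal alpha-helix structure model
#'
#' C-alpha trace of an ideal alpha helix — 1.5 Angstrom rise and 100
#' degrees rotation per residue on a 2.3 Angstrom radius — with the C-beta
#' placed 1.53 Angstrom from the C-alpha along the outward radial
#' direction (glycines get no C-beta). Residues listed in `unresolved` are
#' omitted from the model, emulating disordered regions absent from a
#' deposited structure.
#'
#' @param n Number of residues (numbered 1..n).
#' @param unresolved Residue numbers to omit (subset of 1..n).
#' @param seed Integer seed (used to sample residue identities when `aa`
#'   is not given).
#' @param aa Optional vector of one-letter codes, length `n`.
#' @param chain Chain identifier.
#' @param origin Translation applied to all coordinates (length-3).
#' @return A [structure_model()].
#' @export
gen_structure <- function(n, unresolved = integer(0), seed = 1L, aa = NULL,
                          chain = "A", origin = c(0, 0, 0)) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("n must be >= 1", "spec_error")
  unresolved <- as.integer(unresolved)
  if (any(unresolved < 1L | unresolved > n))
    abort("unresolved positions must lie in 1..n", "spec_error")
  if (is.null(aa)) {
    set.seed(seed)
    aa <- sample(AA20, n, replace = TRUE)
  }
  if (length(aa) != n) abort("aa must have length n", "spec_error")
  rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3; cb_len <- 1.53
  i <- seq_len(n)
  ang <- (i - 1L) * twist
  ca <- cbind(radius * cos(ang), radius * sin(ang), (i - 1L) * rise)
  radial <- cbind(cos(ang), sin(ang), 0)
  cb <- ca + cb_len * radial
  cb[toupper(aa) == "G", ] <- NA_real_
  ca <- sweep(ca, 2L, origin, `+`)
  cb <- sweep(cb, 2L, origin, `+`)
  keep <- !(i %in% unresolved)
  structure_model(i[keep], aa[keep], ca[keep, , drop = FALSE],
                  cb[keep, , drop = FALSE], chain = chain)
}
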