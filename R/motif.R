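# Literal/wildcard motif patterns with positional context constraints,
# sequence scanning, clade surveys and alignment-column consistency.
#
# The motivating pattern is the separase cysteine motif "CxCxxC" with a
# histidine required 4-6 residues upstream of the first cysteine
# (H442/C448 in C. elegans numbering: offset 448 - 442 = 6).

#' Compile a literal/wildcard motif pattern
#'
#' Pattern strings use uppercase residue letters as literals and lowercase
#' `x` as a one-residue wildcard: `"CxCxxC"` places literal cysteines at
#' offsets 0, 2 and 5 from the start. Context constraints require a residue
#' within an inclusive positional window measured from the first pattern
#' position; `"H:4-6:upstream"` demands a histidine at `start - 6` ..
#' `start - 4`.
#'
#' @param spec Pattern string.
#' @param contexts Character vector of context constraints, each
#'   `"R:min-max:direction"` with direction `upstream` or `downstream`, or
#'   a data frame with columns `residue`, `min`, `max`, `direction`.
#' @return A `motif_pattern` object.
#' @examples
#' compile_pattern("CxCxxC", "H:4-6:upstream")
#' @export
compile_pattern <- function(spec, contexts = character(0)) {
  chars <- strsplit(spec, "")[[1L]]
  if (length(chars) < 1L)
    abort("empty pattern", "pattern_error")
  bad <- which(!(chars %in% AA20 | chars == "x"))
  if (length(bad) > 0L)
    abort(sprintf("illegal pattern character '%s' at position %d",
                  chars[bad[1L]], bad[1L]), "pattern_error")
  ctx <- parse_contexts(contexts)
  structure(list(spec = spec, elements = chars,
                 literal_offsets = which(chars != "x") - 1L,
                 length = length(chars), contexts = ctx),
            class = "motif_pattern")
}

parse_contexts <- function(contexts) {
  empty <- data.frame(residue = character(0), min = integer(0),
                      max = integer(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (is.data.frame(contexts)) {
    if (nrow(contexts) == 0L) return(empty)
    ctx <- contexts
  } else if (length(contexts) == 0L) {
    return(empty)
  } else {
    parts <- strsplit(contexts, ":", fixed = TRUE)
    if (any(lengths(parts) != 3L))
      abort("context must be 'R:min-max:direction'", "pattern_error")
    rng <- strsplit(vapply(parts, `[[`, "", 2L), "-", fixed = TRUE)
    ctx <- data.frame(
      residue = toupper(vapply(parts, `[[`, "", 1L)),
      min = suppressWarnings(as.integer(vapply(rng, `[[`, "", 1L))),
      max = suppressWarnings(as.integer(vapply(rng, function(p) p[[length(p)]], ""))),
      direction = tolower(vapply(parts, `[[`, "", 3L)),
      stringsAsFactors = FALSE)
  }
  if (any(!ctx$residue %in% AA20))
    abort("context residue must be a standard amino-acid letter",
          "pattern_error")
  if (any(is.na(ctx$min) | is.na(ctx$max) | ctx$min < 1L | ctx$min > ctx$max))
    abort("context offsets must satisfy 1 <= min <= max", "pattern_error")
  if (any(!ctx$direction %in% c("upstream", "downstream")))
    abort("context direction must be 'upstream' or 'downstream'",
          "pattern_error")
  ctx
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("Motif pattern %s (%d positions, literals at %s)\n", x$spec,
              x$length, paste(x$literal_offsets + 1L, collapse = ",")))
  if (nrow(x$contexts) > 0L)
    cat(sprintf("  context: %s %d-%d %s\n", x$contexts$residue,
                x$contexts$min, x$contexts$max, x$contexts$direction))
  invisible(x)
}

#' Scan a sequence for motif hits
#'
#' Reports all (possibly overlapping) matches in ascending start order.
#' Literals must match exactly; the unknown residue `X` never matches a
#' literal and never satisfies a context. Each context window is evaluated
#' on the ungapped sequence and truncated at the sequence boundary;
#' `context_ok` is true iff every context has at least one satisfying
#' position.
#'
#' @param residues A residue string, a single-row [seq_set()], or one row
#'   of one.
#' @param pattern A [compile_pattern()] result.
#' @param id Sequence id used in the output (taken from a `seq_set` input).
#' @return Data frame of hits: `id`, `start`, `end` (1-based, inclusive),
#'   `matched`, `context_ok`, `context_positions` (comma-separated residue
#'   indices satisfying the contexts).
#' @export
scan_motif <- function(residues, pattern, id = NA_character_) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (inherits(residues, "seq_set")) {
    if (nrow(residues) != 1L)
      abort("scan_motif takes one sequence; use motif_survey for sets",
            "format_error")
    id <- residues$id[1L]
    residues <- residues$residues[1L]
  }
  s <- toupper(residues)
  n <- nchar(s)
  # literal -> itself, wildcard -> '.', X excluded from matching a literal
  rx <- paste0(ifelse(pattern$elements == "x", ".", pattern$elements),
               collapse = "")
  starts <- integer(0)
  if (n >= pattern$length) {
    m <- gregexpr(sprintf("(?=%s)", rx), s, perl = TRUE)[[1L]]
    if (m[1L] != -1L) starts <- as.integer(m)
  }
  hits <- data.frame(id = rep(id, length(starts)), start = starts,
                     end = starts + pattern$length - 1L,
                     matched = if (length(starts) > 0L)
                       substring(s, starts, starts + pattern$length - 1L)
                     else character(0),
                     context_ok = logical(length(starts)),
                     context_positions = character(length(starts)),
                     stringsAsFactors = FALSE)
  chars <- strsplit(s, "")[[1L]]
  for (i in seq_along(starts)) {
    ev <- eval_contexts(chars, starts[i], pattern$contexts)
    hits$context_ok[i] <- ev$ok
    hits$context_positions[i] <- ev$positions
  }
  hits
}

eval_contexts <- function(chars, start, contexts) {
  if (nrow(contexts) == 0L)
    return(list(ok = TRUE, positions = ""))
  ok <- TRUE
  pos_all <- integer(0)
  for (j in seq_len(nrow(contexts))) {
    win <- if (contexts$direction[j] == "upstream") {
      seq2(start - contexts$max[j], start - contexts$min[j])
    } else {
      seq2(start + contexts$min[j], start + contexts$max[j])
    }
    win <- win[win >= 1L & win <= length(chars)]
    sat <- win[chars[win] == contexts$residue[j]]
    ok <- ok && length(sat) > 0L
    pos_all <- c(pos_all, sat)
  }
  list(ok = ok, positions = paste(pos_all, collapse = ","))
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Survey clades for motif presence and context satisfaction
#'
#' Per clade, counts sequences with at least one hit, with exactly one hit,
#' and whose *first* hit satisfies all context constraints. Two context
#' fractions are reported: `frac_context` uses motif-bearing sequences as
#' the denominator (the default reading of a "fraction of cases with the
#' upstream histidine"), `frac_context_all` uses all surveyed sequences.
#'
#' @param seqs A [seq_set()].
#' @param clades A [group_assignment()] covering all sequences; empty
#'   clades are dropped with a warning.
#' @param pattern A [compile_pattern()] result.
#' @return `motif_survey` data frame: one row per clade with counts
#'   `n_sequences`, `n_with_motif`, `n_with_unique_motif`, `n_context_ok`
#'   and fractions.
#' @export
motif_survey <- function(seqs, clades, pattern) {
  stopifnot(inherits(seqs, "seq_set"), inherits(pattern, "motif_pattern"))
  g <- check_groups(seqs$id, clades, min_n = 1L)
  empty <- setdiff(unique(unname(unclass(clades))), unique(unname(g)))
  if (length(empty) > 0L)
    warning(sprintf("clade(s) with no sequences omitted: %s",
                    paste(empty, collapse = ", ")))
  per_seq <- lapply(seq_len(nrow(seqs)), function(i) {
    h <- scan_motif(seqs$residues[i], pattern, id = seqs$id[i])
    data.frame(id = seqs$id[i], clade = g[i], n_hits = nrow(h),
               first_context_ok = if (nrow(h) > 0L) h$context_ok[1L] else FALSE,
               stringsAsFactors = FALSE)
  })
  per_seq <- do.call(rbind, per_seq)
  out <- do.call(rbind, lapply(split(per_seq, per_seq$clade), function(d) {
    n_motif <- sum(d$n_hits >= 1L)
    data.frame(clade = d$clade[1L],
               n_sequences = nrow(d),
               n_with_motif = n_motif,
               n_with_unique_motif = sum(d$n_hits == 1L),
               n_context_ok = sum(d$first_context_ok),
               frac_motif = n_motif / nrow(d),
               frac_unique = sum(d$n_hits == 1L) / nrow(d),
               frac_context = if (n_motif > 0L) sum(d$first_context_ok) / n_motif
                              else NA_real_,
               frac_context_all = sum(d$first_context_ok) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("motif_survey", "data.frame")
  out
}

#' Phyletic presence/absence matrix
#'
#' Collapses a survey into a per-clade presence/absence table of the kind
#' used to tabulate a motif across major taxonomic lineages:
#' `motif_present` (any sequence with a hit), `context_present` (any
#' sequence whose first hit satisfies the contexts), and
#' `sequence_truncated` (any surveyed sequence shorter than `min_length`,
#' flagging likely gene-calling artifacts; disabled when `min_length` is 0).
#'
#' @param seqs A [seq_set()].
#' @param clades A [group_assignment()].
#' @param pattern A [compile_pattern()] result.
#' @param min_length Sequences shorter than this are flagged truncated.
#' @return Data frame: `clade`, `motif_present`, `context_present`,
#'   `sequence_truncated` (0/1 integers).
#' @export
phyletic_matrix <- function(seqs, clades, pattern, min_length = 0L) {
  survey <- motif_survey(seqs, clades, pattern)
  g <- check_groups(seqs$id, clades, min_n = 1L)
  trunc <- vapply(split(nchar(seqs$residues), g),
                  function(w) any(w < min_length), logical(1L))
  data.frame(clade = survey$clade,
             motif_present = as.integer(survey$n_with_motif > 0L),
             context_present = as.integer(survey$n_context_ok > 0L),
             sequence_truncated = as.integer(trunc[survey$clade]),
             stringsAsFactors = FALSE)
}

#' Check that a motif occupies the same alignment columns in every row
#'
#' For each row's first hit on its ungapped sequence, the pattern's literal
#' positions are mapped to alignment columns; the report states whether all
#' motif-bearing rows share one column set (the behaviour expected of a
#' well-aligned family) and lists rows without a hit.
#'
#' @param aln An [alignment()].
#' @param pattern A [compile_pattern()] result.
#' @return List with `consistent` (logical; `NA` when no row has a hit),
#'   `columns` (data frame `id` x literal columns), `modal_columns`
#'   (most frequent column set), `outliers` (ids deviating from it) and
#'   `missing` (ids without a hit).
#' @export
motif_column_consistency <- function(aln, pattern) {
  stopifnot(inherits(aln, "aln"), inherits(pattern, "motif_pattern"))
  missing <- character(0)
  cols <- list()
  for (i in seq_along(aln$id)) {
    ug <- gsub("-", "", aln$rows[i], fixed = TRUE)
    h <- scan_motif(ug, pattern, id = aln$id[i])
    if (nrow(h) == 0L) {
      missing <- c(missing, aln$id[i])
      next
    }
    lit_res <- h$start[1L] + pattern$literal_offsets
    cols[[aln$id[i]]] <- residue_to_column(aln, aln$id[i], lit_res)
  }
  if (length(cols) == 0L)
    return(list(consistent = NA, columns = NULL, modal_columns = integer(0),
                outliers = character(0), missing = missing))
  mat <- do.call(rbind, cols)
  keys <- apply(mat, 1L, paste, collapse = ",")
  modal_key <- names(sort(table(keys), decreasing = TRUE))[1L]
  outliers <- rownames(mat)[keys != modal_key]
  columns <- data.frame(id = rownames(mat), mat, row.names = NULL,
                        stringsAsFactors = FALSE)
  names(columns)[-1L] <- paste0("literal_col_",
                                seq_along(pattern$literal_offsets))
  list(consistent = length(outliers) == 0L,
       columns = columns,
       modal_columns = as.integer(strsplit(modal_key, ",")[[1L]]),
       outliers = outliers,
       missing = missing)
}
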