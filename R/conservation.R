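# Per-group conservation profiling of alignment columns, universal
# positions, column <-> residue coordinate maps, and variant overlap.

#' Default physicochemical residue classification
#'
#' Six classes plus a remainder, matching the coloring scheme commonly used
#' for per-group identity in alignment figures: negatively charged (D, E),
#' positively charged (K, R, H), aromatic (F, W, Y), aliphatic (I, L, V, M),
#' alcohol (S, T), small (A, G, C, P); N, Q and the unknown residue X fall
#' into `other`. The table is a total function on the alphabet and can be
#' overridden wherever a `class_table` argument is accepted.
#'
#' @return Named character vector mapping residue letters to class names.
#' @examples
#' default_class_table()[["D"]]  # "negative"
#' @export
default_class_table <- function() {
  c(D = "negative", E = "negative",
    K = "positive", R = "positive", H = "positive",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    I = "aliphatic", L = "aliphatic", V = "aliphatic", M = "aliphatic",
    S = "alcohol", T = "alcohol",
    A = "small", G = "small", C = "small", P = "small",
    N = "other", Q = "other", X = "other")
}

check_class_table <- function(table) {
  missing <- setdiff(AA20, names(table))
  if (length(missing) > 0L)
    abort(sprintf("class table misses residue(s): %s",
                  paste(missing, collapse = ", ")), "config_error")
  table
}

#' Classify a residue by physicochemical class
#'
#' @param aa One-letter residue code (or `X`).
#' @param table Class table, see [default_class_table()].
#' @return Class name; `X` and any residue missing from the table map to
#'   `"other"`.
#' @export
classify_residue <- function(aa, table = default_class_table()) {
  aa <- toupper(aa)
  if (any(!aa %in% AA_ALPHABET))
    abort(sprintf("not an amino-acid letter: %s",
                  paste(setdiff(aa, AA_ALPHABET), collapse = ", ")),
          "format_error")
  check_class_table(table)
  out <- unname(table[aa])
  out[is.na(out) | aa == "X"] <- "other"
  out
}

#' Per-group conservation profile of an alignment
#'
#' For every column and every group, the column state is one of:
#' * `gapped` — at least one group member has a gap in the column;
#' * `identical` — all members share the same non-gap residue (`value` is
#'   that residue);
#' * `class_conserved` — residues differ but share a physicochemical class
#'   (`value` is the class); the unknown residue `X` never supports a
#'   conservation call;
#' * `unconserved` — otherwise.
#'
#' A column is *universal* when every group is `identical` with one common
#' residue across groups.
#'
#' @param aln An [alignment()].
#' @param groups A [group_assignment()] covering all rows; every group
#'   needs at least 2 members.
#' @param class_table Residue class table ([default_class_table()]).
#' @return A `conservation_profile`: list with `states` (data frame:
#'   `column`, `group`, `state`, `value`), `universal` (logical per
#'   column), `groups`, and `ncol`.
#' @export
column_conservation <- function(aln, groups,
                                class_table = default_class_table()) {
  stopifnot(inherits(aln, "aln"))
  check_class_table(class_table)
  g <- check_groups(aln$id, groups, min_n = 2L)
  m <- aln_matrix(aln)
  labels <- unique(unname(g))
  states <- vector("list", length(labels))
  ident_res <- matrix(NA_character_, length(labels), aln$ncol)

  for (k in seq_along(labels)) {
    sub <- m[g == labels[k], , drop = FALSE]
    gapped <- colSums(sub == "-") > 0L
    first <- sub[1L, ]
    identical_col <- !gapped & colSums(sub != rep(first, each = nrow(sub))) == 0L &
      first != "X"
    has_x <- colSums(sub == "X") > 0L
    sub_nogap <- sub
    sub_nogap[sub_nogap == "-"] <- "X"   # gapped columns never reach a call
    cls <- matrix(classify_residue(sub_nogap, class_table), nrow(sub))
    cls_first <- cls[1L, ]
    class_same <- colSums(cls != rep(cls_first, each = nrow(cls))) == 0L
    class_conserved <- !gapped & !identical_col & !has_x & class_same
    state <- ifelse(gapped, "gapped",
             ifelse(identical_col, "identical",
             ifelse(class_conserved, "class_conserved", "unconserved")))
    value <- ifelse(identical_col, first,
             ifelse(class_conserved, cls_first, NA_character_))
    ident_res[k, identical_col] <- first[identical_col]
    states[[k]] <- data.frame(column = seq_len(aln$ncol), group = labels[k],
                              state = state, value = value,
                              stringsAsFactors = FALSE)
  }
  universal <- colSums(is.na(ident_res)) == 0L &
    apply(ident_res, 2L, function(r) length(unique(r)) == 1L)
  structure(list(states = do.call(rbind, states),
                 universal = unname(universal),
                 groups = labels, ncol = aln$ncol),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("Conservation profile: %d columns, groups: %s\n",
              x$ncol, paste(x$groups, collapse = ", ")))
  cat(sprintf("  universal columns: %d\n", sum(x$universal)))
  invisible(x)
}

#' Universally conserved alignment columns
#'
#' Columns where every group is identical and the residue is shared across
#' groups.
#'
#' @param profile A `conservation_profile` from [column_conservation()].
#' @return Sorted integer vector of 1-based column indices.
#' @export
universal_positions <- function(profile) {
  stopifnot(inherits(profile, "conservation_profile"))
  which(profile$universal)
}

#' Map an alignment column to a residue index in one row
#'
#' Counts non-gap characters up to and including the column. Returns `NA`
#' when the row has a gap at that column.
#'
#' @param aln An [alignment()].
#' @param id Row identifier.
#' @param column 1-based column index (vectorized).
#' @return Integer vector of 1-based residue indices, `NA` at gaps.
#' @seealso [residue_to_column()], its exact inverse on non-gap positions.
#' @export
column_to_residue <- function(aln, id, column) {
  row <- aln_row(aln, id)
  column <- as.integer(column)
  if (any(column < 1L | column > aln$ncol))
    abort(sprintf("column out of range 1..%d", aln$ncol), "format_error")
  chars <- strsplit(row, "")[[1L]]
  idx <- cumsum(chars != "-")
  out <- idx[column]
  out[chars[column] == "-"] <- NA_integer_
  out
}

#' Map a residue index in one row to its alignment column
#'
#' @param aln An [alignment()].
#' @param id Row identifier.
#' @param residue 1-based index into the ungapped row (vectorized).
#' @return Integer vector of 1-based column indices.
#' @export
residue_to_column <- function(aln, id, residue) {
  row <- aln_row(aln, id)
  residue <- as.integer(residue)
  chars <- strsplit(row, "")[[1L]]
  pos <- which(chars != "-")
  if (any(residue < 1L | residue > length(pos)))
    abort(sprintf("residue index out of range 1..%d for row %s",
                  length(pos), id), "format_error")
  pos[residue]
}

aln_row <- function(aln, id) {
  stopifnot(inherits(aln, "aln"))
  i <- match(id, aln$id)
  if (is.na(i))
    abort(sprintf("no alignment row with id '%s'", id), "key_error")
  aln$rows[i]
}

#' Overlap of conserved positions with a missense-variant table
#'
#' Reports which conserved residue positions carry at least one missense
#' variant. An empty report reproduces the observation that conserved
#' regulatory-domain positions are devoid of population and tumor variants.
#'
#' @param conserved Integer vector of 1-based residue positions (on the
#'   same sequence as the variant table).
#' @param variants Data frame with columns `pos`, `ref`, `alt`, `freq`
#'   (see [read_variants()]).
#' @return Data frame of overlapping variants (columns of `variants` plus
#'   `conserved_pos`); zero rows when conserved positions are variant-free.
#' @export
variant_overlap <- function(conserved, variants) {
  variants <- validate_variants(variants)
  conserved <- sort(unique(as.integer(conserved)))
  hit <- variants[variants$pos %in% conserved, , drop = FALSE]
  hit$conserved_pos <- hit$pos
  rownames(hit) <- NULL
  hit
}

#' Export a conservation profile as a wide TSV table
#'
#' One row per column: `column`, one `<group>_state` / `<group>_value` pair
#' per group, and the `universal` flag.
#'
#' @param profile A `conservation_profile`.
#' @param path Output TSV path.
#' @return The wide data frame, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "conservation_profile"))
  wide <- data.frame(column = seq_len(profile$ncol))
  for (grp in profile$groups) {
    sub <- profile$states[profile$states$group == grp, ]
    sub <- sub[order(sub$column), ]
    wide[[paste0(grp, "_state")]] <- sub$state
    wide[[paste0(grp, "_value")]] <- ifelse(is.na(sub$value), ".", sub$value)
  }
  wide$universal <- profile$universal
  write_tsv(wide, path)
  invisible(wide)
}
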