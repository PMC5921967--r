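# Core domain types (S3) and classed error conditions.
#
# All coordinates in the package are 1-based: residue numbers follow the
# structural-biology convention (C450, H442), and alignment columns are
# numbered 1..length.

#' @importFrom stats setNames runif
#' @importFrom utils head read.delim write.table
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA20, "X")

abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("sepmotif_", class), "sepmotif_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Construct a set of protein sequences
#'
#' A `seq_set` is a plain `data.frame` with columns `id`, `residues` and
#' `description`, one row per sequence. Residues are uppercase letters from
#' the 20-letter amino-acid alphabet plus `X` (unknown residue).
#'
#' @param id Character vector of unique, non-empty sequence identifiers.
#' @param residues Character vector of residue strings (no gaps).
#' @param description Optional character vector of free-text descriptions.
#' @return A `seq_set` data frame.
#' @examples
#' seq_set(c("s1", "s2"), c("MKV", "CCH"))
#' @export
seq_set <- function(id, residues, description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    abort("id and residues must have the same length", "format_error")
  if (any(!nzchar(id)) || anyDuplicated(id))
    abort("sequence ids must be non-empty and unique", "format_error")
  if (any(nchar(residues) < 1L))
    abort(sprintf("zero-length sequence: %s",
                  paste(id[nchar(residues) < 1L], collapse = ", ")),
          "empty_input")
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), residues)
  if (any(bad))
    abort(sprintf("illegal residue character in sequence(s): %s",
                  paste(id[bad], collapse = ", ")), "format_error")
  out <- data.frame(id = id, residues = residues,
                    description = rep_len(as.character(description), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Construct a protein multiple alignment
#'
#' Rows are gapped residue strings of identical length; the only gap
#' character is `-` (`.` is normalized on read). Removing gaps from any row
#' yields a valid sequence.
#'
#' @param id Character vector of unique row identifiers.
#' @param rows Character vector of gapped residue strings, equal lengths.
#' @return An object of class `aln` with elements `id`, `rows` and `ncol`.
#' @export
alignment <- function(id, rows) {
  id <- as.character(id)
  rows <- toupper(gsub(".", "-", as.character(rows), fixed = TRUE))
  if (length(id) != length(rows) || length(id) < 1L)
    abort("alignment needs matching, non-empty id and rows", "format_error")
  if (anyDuplicated(id))
    abort("alignment row ids must be unique", "format_error")
  w <- nchar(rows)
  if (length(unique(w)) != 1L)
    abort(sprintf("ragged alignment rows: %s",
                  paste(id[w != stats::median(w)], collapse = ", ")),
          "alignment_shape_error")
  pat <- sprintf("^[-%s]+$", paste(AA_ALPHABET, collapse = ""))
  bad <- !grepl(pat, rows)
  if (any(bad))
    abort(sprintf("illegal character in alignment row(s): %s",
                  paste(id[bad], collapse = ", ")), "format_error")
  ungapped <- gsub("-", "", rows, fixed = TRUE)
  if (any(nchar(ungapped) < 1L))
    abort(sprintf("all-gap alignment row(s): %s",
                  paste(id[nchar(ungapped) < 1L], collapse = ", ")),
          "empty_input")
  structure(list(id = id, rows = rows, ncol = w[1L]), class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("Protein alignment: %d rows x %d columns\n",
              length(x$id), x$ncol))
  shown <- head(seq_along(x$id), 6L)
  for (i in shown)
    cat(sprintf("  %-20s %s%s\n", x$id[i],
                substr(x$rows[i], 1L, 50L),
                if (x$ncol > 50L) "..." else ""))
  if (length(x$id) > 6L) cat(sprintf("  ... %d more rows\n", length(x$id) - 6L))
  invisible(x)
}

# alignment as a character matrix (rows x columns), rownames = ids
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Ungapped sequences of an alignment
#'
#' @param aln An [alignment()].
#' @return A [seq_set()] with gaps removed from every row.
#' @export
ungap <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  seq_set(aln$id, gsub("-", "", aln$rows, fixed = TRUE))
}

#' Construct a structure model
#'
#' Per-residue C-alpha / C-beta coordinate records for one chain. A residue
#' is *resolved* iff its C-alpha is present; a C-beta without a C-alpha is
#' rejected. Residue numbers are strictly increasing; residues absent from
#' the model (e.g. disordered loops) simply have no row.
#'
#' @param resnum Integer vector of residue numbers, strictly increasing.
#' @param aa One-letter residue codes.
#' @param ca,cb Numeric matrices (n x 3) of coordinates in Angstrom; `NA`
#'   rows mark absent atoms.
#' @param chain Chain identifier.
#' @return A `structure_model` data frame with columns `resnum`, `aa`,
#'   `ca_x..ca_z`, `cb_x..cb_z`, `resolved`.
#' @export
structure_model <- function(resnum, aa, ca, cb, chain = "A") {
  resnum <- as.integer(resnum)
  n <- length(resnum)
  if (n > 0L && any(diff(resnum) <= 0L))
    abort("residue numbers must be strictly increasing", "format_error")
  ca <- matrix(as.numeric(ca), ncol = 3L)
  cb <- matrix(as.numeric(cb), ncol = 3L)
  if (nrow(ca) != n || nrow(cb) != n)
    abort("ca/cb must have one row per residue", "format_error")
  has_ca <- stats::complete.cases(ca)
  has_cb <- stats::complete.cases(cb)
  if (any(has_cb & !has_ca))
    abort("C-beta present without C-alpha", "format_error")
  out <- data.frame(resnum = resnum, aa = toupper(as.character(aa)),
                    ca_x = ca[, 1L], ca_y = ca[, 2L], ca_z = ca[, 3L],
                    cb_x = cb[, 1L], cb_y = cb[, 2L], cb_z = cb[, 3L],
                    resolved = has_ca, stringsAsFactors = FALSE)
  attr(out, "chain") <- chain
  class(out) <- c("structure_model", "data.frame")
  out
}

#' Construct or validate a group assignment
#'
#' Maps sequence ids to taxonomic group labels (clades), e.g. `nematode`,
#' `vertebrate`, `other_metazoa`.
#'
#' @param id Character vector of sequence ids.
#' @param group Character vector of group labels, recycled if length 1.
#' @return A named character vector (names = ids, values = labels) of class
#'   `group_assignment`.
#' @export
group_assignment <- function(id, group) {
  id <- as.character(id)
  group <- rep_len(as.character(group), length(id))
  if (anyDuplicated(id))
    abort("duplicate sequence id in group assignment", "config_error")
  structure(setNames(group, id), class = "group_assignment")
}

# Checks that `groups` covers all of `ids`, and that every group used has
# at least `min_n` members among `ids`.
check_groups <- function(ids, groups, min_n = 2L) {
  missing <- setdiff(ids, names(groups))
  if (length(missing) > 0L)
    abort(sprintf("sequences without group assignment: %s",
                  paste(missing, collapse = ", ")), "config_error")
  g <- groups[ids]
  sizes <- table(g)
  if (any(sizes < min_n))
    abort(sprintf("group(s) with fewer than %d members: %s", min_n,
                  paste(names(sizes)[sizes < min_n], collapse = ", ")),
          "config_error")
  unclass(g)
}
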