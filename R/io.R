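# Readers/writers for the formats the pipeline touches: FASTA, aligned
# FASTA, PDB coordinates, and the TSV tables (groups, helices, variants).

#' Read protein sequences from a FASTA file
#'
#' Lowercase input is uppercased and a terminal `*` stop codon is stripped.
#' Residues outside the 20-letter alphabet plus `X` raise a format error
#' naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A [seq_set()].
#' @export
read_fasta <- function(path) {
  recs <- parse_fasta_records(path)
  res <- toupper(sub("\\*$", "", recs$residues))
  empty <- !nzchar(res)
  if (any(empty))
    abort(sprintf("FASTA record(s) with no residues: %s",
                  paste(recs$id[empty], collapse = ", ")), "empty_input")
  check_residue_lines(path, allow_gap = FALSE)
  seq_set(recs$id, res, recs$description)
}

#' Read a protein multiple alignment from aligned FASTA
#'
#' Accepts `-` and `.` as gap characters, normalizing to `-`. Rows of
#' unequal length raise an alignment-shape error listing the offending ids.
#'
#' @param path Path to an aligned FASTA file.
#' @return An [alignment()].
#' @export
read_alignment <- function(path) {
  recs <- parse_fasta_records(path)
  check_residue_lines(path, allow_gap = TRUE)
  rows <- toupper(gsub(".", "-", sub("\\*$", "", recs$residues), fixed = TRUE))
  w <- nchar(rows)
  if (length(unique(w)) != 1L) {
    common <- as.integer(names(sort(table(w), decreasing = TRUE))[1L])
    abort(sprintf("ragged alignment rows (expected width %d): %s",
                  common, paste(recs$id[w != common], collapse = ", ")),
          "alignment_shape_error")
  }
  alignment(recs$id, rows)
}

# Shared low-level FASTA parsing through Biostrings; returns id, residues,
# description without any residue-alphabet policy.
parse_fasta_records <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "format_error")
  if (file.size(path) == 0L)
    abort(sprintf("empty file: %s", path), "empty_input")
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(sprintf("cannot parse FASTA %s: %s",
                                      path, conditionMessage(e)),
                              "format_error")
  )
  if (length(set) == 0L)
    abort(sprintf("no FASTA records in %s", path), "empty_input")
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  list(id = id, residues = as.character(set), description = desc)
}

# Scan the raw file for illegal residue characters so errors can name the
# line; Biostrings accepts a wider alphabet than this pipeline does.
check_residue_lines <- function(path, allow_gap) {
  lines <- readLines(path, warn = FALSE)
  seq_lines <- which(!startsWith(lines, ">") & nzchar(trimws(lines)))
  ok <- sprintf("^[%sXx*%s]*$",
                paste0(AA20, tolower(AA20), collapse = ""),
                if (allow_gap) ".-" else "")   # '-' last: not a range
  bad <- seq_lines[!grepl(ok, trimws(lines[seq_lines]))]
  if (length(bad) > 0L)
    abort(sprintf("illegal residue character in %s at line %d: %s",
                  path, bad[1L], trimws(lines[bad[1L]])), "format_error")
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' @param x A [seq_set()].
#' @param path Output path.
#' @param width Line-wrap width (0 = single line per record).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "seq_set"))
  hdr <- ifelse(nzchar(x$description),
                paste(x$id, x$description), x$id)
  out <- character(0)
  for (i in seq_len(nrow(x))) {
    body <- if (width > 0L) {
      s <- x$residues[i]
      substring(s, seq(1L, nchar(s), width),
                pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    } else x$residues[i]
    out <- c(out, paste0(">", hdr[i]), body)
  }
  writeLines(out, path)
  invisible(path)
}

#' Write an alignment to aligned FASTA
#'
#' @param aln An [alignment()].
#' @param path Output path.
#' @param width Line-wrap width (0 = single line per record).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  stopifnot(inherits(aln, "aln"))
  out <- character(0)
  for (i in seq_along(aln$id)) {
    body <- if (width > 0L) {
      s <- aln$rows[i]
      substring(s, seq(1L, nchar(s), width),
                pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    } else aln$rows[i]
    out <- c(out, paste0(">", aln$id[i]), body)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read C-alpha / C-beta coordinates from a PDB file
#'
#' Reads the first MODEL only and ATOM records only (HETATM ignored). For
#' each residue of the requested chain the CA and CB atoms are extracted;
#' alternate locations are resolved by highest occupancy, then first seen.
#' Residues lacking a CA do not appear in the model (they are *unresolved*;
#' see [unresolved_positions()]). Insertion codes are rejected.
#'
#' @param path Path to a PDB-format coordinate file.
#' @param chain Chain identifier (default `"A"`).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, chain = "A") {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "format_error")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     rm.insert = FALSE, verbose = FALSE)),
    error = function(e) abort(sprintf("cannot parse PDB %s: %s",
                                      path, conditionMessage(e)),
                              "format_error")
  )
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L)
    abort(sprintf("no ATOM records in %s", path), "format_error")
  if (!chain %in% atoms$chain)
    abort(sprintf("chain '%s' not found in %s (chains: %s)", chain, path,
                  paste(sort(unique(atoms$chain)), collapse = ", ")),
          "chain_not_found")
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  ins <- atoms$insert
  if (any(!is.na(ins) & nzchar(ins)))
    abort(sprintf("insertion codes are not supported (chain %s)", chain),
          "format_error")
  atoms <- atoms[atoms$elety %in% c("CA", "CB"), , drop = FALSE]
  # altloc: keep highest occupancy, ties broken by file order
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  ord <- order(atoms$resno, atoms$elety, -occ, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(atoms[, c("resno", "elety")]), , drop = FALSE]

  resno <- sort(unique(atoms$resno))
  get_xyz <- function(elety) {
    m <- matrix(NA_real_, length(resno), 3L)
    sel <- atoms[atoms$elety == elety, , drop = FALSE]
    idx <- match(sel$resno, resno)
    m[idx, ] <- cbind(sel$x, sel$y, sel$z)
    m
  }
  ca <- get_xyz("CA")
  cb <- get_xyz("CB")
  aa3 <- atoms$resid[match(resno, atoms$resno)]
  aa1 <- suppressWarnings(bio3d::aa321(aa3))
  aa1[is.na(aa1) | aa1 == ""] <- "X"
  keep <- stats::complete.cases(ca)   # CB without CA cannot enter the model
  cb[!keep, ] <- NA_real_
  structure_model(resno[keep], aa1[keep],
                  ca[keep, , drop = FALSE], cb[keep, , drop = FALSE],
                  chain = chain)
}

#' Write a structure model as PDB ATOM records
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  chain <- attr(model, "chain") %||% "A"
  lines <- character(0)
  serial <- 0L
  aa123 <- function(a) {
    out <- suppressWarnings(bio3d::aa123(a))
    out[is.na(out)] <- "UNK"
    out
  }
  for (i in seq_len(nrow(model))) {
    res3 <- aa123(model$aa[i])
    if (model$resolved[i]) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, res3, chain, model$resnum[i],
        model$ca_x[i], model$ca_y[i], model$ca_z[i], 1, 0))
    }
    if (!is.na(model$cb_x[i])) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CB  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, res3, chain, model$resnum[i],
        model$cb_x[i], model$cb_y[i], model$cb_z[i], 1, 0))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a group-assignment table
#'
#' Two-column TSV (`id`, `group`), with or without a header line.
#'
#' @param path Path to the TSV file.
#' @return A [group_assignment()].
#' @export
read_groups <- function(path) {
  tab <- read_tsv_flex(path, c("id", "group"))
  group_assignment(tab$id, tab$group)
}

#' Read helix-range annotations
#'
#' Three-column TSV (`label`, `start`, `end`), residue-number ranges with
#' inclusive ends; ranges must not overlap and labels must be unique.
#'
#' @param path Path to the TSV file.
#' @return A `helix_annotation` data frame.
#' @export
read_helices <- function(path) {
  tab <- read_tsv_flex(path, c("label", "start", "end"))
  helix_annotation(tab$label, as.integer(tab$start), as.integer(tab$end))
}

#' Read a missense-variant table
#'
#' TSV with columns `pos`, `ref`, `alt`, `freq` (header optional). Positions
#' are 1-based residue indices on the same sequence as the conserved
#' positions they will be compared against.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `pos` (integer), `ref`, `alt`
#'   (one-letter codes) and `freq` (numeric).
#' @export
read_variants <- function(path) {
  tab <- read_tsv_flex(path, c("pos", "ref", "alt", "freq"))
  validate_variants(data.frame(pos = suppressWarnings(as.integer(tab$pos)),
                               ref = toupper(tab$ref), alt = toupper(tab$alt),
                               freq = suppressWarnings(as.numeric(tab$freq)),
                               stringsAsFactors = FALSE))
}

validate_variants <- function(v) {
  need <- c("pos", "ref", "alt", "freq")
  if (!is.data.frame(v) || !all(need %in% names(v)))
    abort("variant table needs columns pos, ref, alt, freq", "format_error")
  pos <- suppressWarnings(as.integer(v$pos))
  if (any(is.na(pos)) || any(pos < 1L))
    abort("variant positions must be positive integers", "format_error")
  bad <- !(toupper(v$ref) %in% AA_ALPHABET) | !(toupper(v$alt) %in% AA_ALPHABET)
  if (any(bad))
    abort(sprintf("malformed variant row(s): %s",
                  paste(which(bad), collapse = ", ")), "format_error")
  v$pos <- pos
  v
}

# Tolerant TSV reader: uses the header when present (detected by matching
# the expected first column name), otherwise assigns `cols` positionally.
read_tsv_flex <- function(path, cols) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "format_error")
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- identical(tolower(strsplit(first, "\t")[[1L]][1L]), cols[1L])
  tab <- if (has_header) {
    out <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    names(out) <- tolower(names(out))
    out
  } else {
    read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  }
  if (ncol(tab) < length(cols))
    abort(sprintf("%s: expected %d columns (%s)", path, length(cols),
                  paste(cols, collapse = ", ")), "format_error")
  names(tab)[seq_along(cols)] <- cols
  tab
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
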