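# End-to-end orchestration: conservation -> motif survey -> structure
# contacts -> variant overlap, with a JSON summary. Stages are independent:
# a stage whose inputs are absent is skipped with a logged notice.

#' Build a pipeline configuration
#'
#' @param alignment,sequences,structure,groups,helices,variants Input file
#'   paths (aligned FASTA, FASTA, PDB, TSVs); `NULL` entries skip the
#'   stages that need them. When `sequences` is `NULL` the ungapped
#'   alignment rows are used for motif scanning.
#' @param pattern Motif pattern string (default `"CxCxxC"`).
#' @param contexts Context constraints (default `"H:4-6:upstream"`).
#' @param reference_id Alignment row used to report universal positions in
#'   residue coordinates (default: first row).
#' @param class_table Optional named vector overriding
#'   [default_class_table()].
#' @param threshold Cbeta contact threshold in Angstrom (default 6, strict).
#' @param chain Structure chain identifier.
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed recorded in the summary (the pipeline stages
#'   themselves are deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alignment = NULL, sequences = NULL,
                            structure = NULL, groups = NULL,
                            helices = NULL, variants = NULL,
                            pattern = "CxCxxC",
                            contexts = "H:4-6:upstream",
                            reference_id = NULL,
                            class_table = NULL,
                            threshold = 6.0, chain = "A",
                            outdir = "sepmotif_out", seed = 1L) {
  if (!is.numeric(threshold) || threshold <= 0)
    abort("contact threshold must be > 0", "config_error")
  cfg <- list(alignment = alignment, sequences = sequences,
              structure = structure, groups = groups, helices = helices,
              variants = variants, pattern = pattern, contexts = contexts,
              reference_id = reference_id, class_table = class_table,
              threshold = threshold, chain = chain, outdir = outdir,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a key-value file
#'
#' One `key = value` (or `key: value`) pair per line; `#` starts a
#' comment. Recognized keys match the arguments of [pipeline_config()];
#' `contexts` may hold several comma-separated constraints.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path), "config_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- lines[lengths(kv) != 3L]
  if (length(bad) > 0L)
    abort(sprintf("cannot parse config line: %s", bad[1L]), "config_error")
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L)
    abort(sprintf("unknown config key(s): %s",
                  paste(unknown, collapse = ", ")), "config_error")
  args <- as.list(stats::setNames(vals, keys))
  if (!is.null(args$threshold)) args$threshold <- as.numeric(args$threshold)
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  if (!is.null(args$contexts))
    args$contexts <- trimws(strsplit(args$contexts, ",")[[1L]])
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the stages whose inputs are configured:
#' * **conserve** (alignment + groups): per-group conservation profile
#'   (`profile.tsv`), universal positions with reference-row residue
#'   coordinates (`universal.tsv`);
#' * **motif** (sequences, or ungapped alignment rows, + groups): clade
#'   survey (`survey.tsv`), phyletic presence/absence matrix
#'   (`phyletic.tsv`), and — when an alignment is present — motif
#'   column-consistency (`motif_columns.tsv`);
#' * **contacts** (structure): unresolved check and Cbeta contact pairs
#'   among the universal positions mapped to reference-row residue numbers
#'   (`contacts.tsv`), helix-annotated when helices are supplied;
#' * **variants** (variants + conserve): overlap of conserved reference
#'   positions with the missense-variant table (`variant_overlap.tsv`).
#'
#' A `summary.json` records the headline counts; notices go to
#' `pipeline.log`. Re-running with identical config and inputs reproduces
#' the outputs byte for byte.
#'
#' @param config A [pipeline_config()] or path to a config file.
#' @return Invisibly, a list with the in-memory results and the summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  # fail on contradictions before any computation
  for (key in c("alignment", "sequences", "structure", "groups", "helices",
                "variants")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      abort(sprintf("configured %s file does not exist: %s", key, p),
            "config_error")
  }
  if (is.null(config$alignment) && is.null(config$sequences))
    abort("need an alignment or a sequence file", "config_error")
  if (!is.null(config$alignment) && is.null(config$groups))
    abort("conservation stage needs a group-assignment file", "config_error")

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "pipeline.log")
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  class_table <- config$class_table %||% default_class_table()
  pattern <- compile_pattern(config$pattern, config$contexts)
  groups <- if (!is.null(config$groups)) read_groups(config$groups)
  res <- list(config = config)

  # --- conserve ---------------------------------------------------------
  profile <- NULL; universal_tab <- NULL; ref_positions <- integer(0)
  if (!is.null(config$alignment)) {
    aln <- read_alignment(config$alignment)
    profile <- column_conservation(aln, groups, class_table)
    write_profile(profile, file.path(config$outdir, "profile.tsv"))
    ucols <- universal_positions(profile)
    ref <- config$reference_id %||% aln$id[1L]
    ref_res <- if (length(ucols) > 0L) column_to_residue(aln, ref, ucols)
               else integer(0)
    ref_aa <- if (length(ucols) > 0L)
      substring(gsub("-", "", aln_row(aln, ref), fixed = TRUE),
                ref_res, ref_res) else character(0)
    universal_tab <- data.frame(column = ucols,
                                reference_id = rep(ref, length(ucols)),
                                reference_residue = ref_res,
                                reference_aa = ref_aa,
                                stringsAsFactors = FALSE)
    write_tsv(universal_tab, file.path(config$outdir, "universal.tsv"))
    ref_positions <- ref_res[!is.na(ref_res)]
    note("conserve: %d universal positions (reference %s)",
         length(ucols), ref)
    res$aln <- aln; res$profile <- profile; res$universal <- universal_tab
  } else {
    note("conserve: skipped (no alignment)")
  }

  # --- motif ------------------------------------------------------------
  survey <- NULL
  if (!is.null(groups)) {
    seqs <- if (!is.null(config$sequences)) read_fasta(config$sequences)
            else ungap(res$aln)
    survey <- motif_survey(seqs, groups, pattern)
    write_tsv(survey, file.path(config$outdir, "survey.tsv"))
    write_tsv(phyletic_matrix(seqs, groups, pattern),
              file.path(config$outdir, "phyletic.tsv"))
    if (!is.null(res$aln)) {
      cons <- motif_column_consistency(res$aln, pattern)
      if (!is.null(cons$columns))
        write_tsv(cons$columns, file.path(config$outdir, "motif_columns.tsv"))
      note("motif: columns %s across rows (%d rows without hit)",
           if (isTRUE(cons$consistent)) "consistent" else "NOT consistent",
           length(cons$missing))
      res$motif_columns <- cons
    }
    note("motif: %d/%d clades carry the motif",
         sum(survey$n_with_motif > 0L), nrow(survey))
    res$survey <- survey
  } else {
    note("motif: skipped (no group assignment)")
  }

  # --- contacts ---------------------------------------------------------
  contacts <- NULL; unresolved <- integer(0)
  if (!is.null(config$structure)) {
    model <- read_structure(config$structure, config$chain)
    helices <- if (!is.null(config$helices)) read_helices(config$helices)
    query <- if (length(ref_positions) > 0L) ref_positions
             else model$resnum
    unresolved <- unresolved_positions(query, model)
    if (length(unresolved) > 0L)
      note("contacts: %d queried position(s) unresolved: %s",
           length(unresolved), paste(unresolved, collapse = ", "))
    contacts <- suppressWarnings(
      contact_pairs(model, query, config$threshold, helices))
    write_tsv(contacts, file.path(config$outdir, "contacts.tsv"))
    note("contacts: %d pair(s) under %.1f Angstrom",
         nrow(contacts), config$threshold)
    res$model <- model; res$contacts <- contacts
    res$unresolved <- unresolved
  } else {
    note("contacts: skipped (no structure)")
  }

  # --- variants ---------------------------------------------------------
  overlap <- NULL
  if (!is.null(config$variants)) {
    if (length(ref_positions) == 0L) {
      note("variants: skipped (no conserved reference positions)")
    } else {
      overlap <- variant_overlap(ref_positions, read_variants(config$variants))
      write_tsv(overlap, file.path(config$outdir, "variant_overlap.tsv"))
      note("variants: %d conserved position(s) with missense variants",
           nrow(overlap))
      res$variant_overlap <- overlap
    }
  } else {
    note("variants: skipped (no variant table)")
  }

  summary <- list(
    n_universal = if (is.null(universal_tab)) 0L else nrow(universal_tab),
    n_motif_clades = if (is.null(survey)) 0L
                     else sum(survey$n_with_motif > 0L),
    n_context_ok = if (is.null(survey)) 0L else sum(survey$n_context_ok),
    n_contacts = if (is.null(contacts)) 0L else nrow(contacts),
    n_unresolved = length(unresolved),
    n_variant_overlap = if (is.null(overlap)) 0L else nrow(overlap),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, log_path)
  res$summary <- summary
  invisible(res)
}
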