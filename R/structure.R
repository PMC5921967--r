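# Mapping conserved residues onto structure coordinates: unresolved
# residues, beta-carbon contact pairs under a distance threshold, and
# helix-membership annotation.

#' Construct a helix annotation
#'
#' Labeled, non-overlapping residue-number ranges with inclusive ends, as
#' used for the 25 helices (H1-H25) of an alpha-solenoid domain.
#'
#' @param label Unique helix labels.
#' @param start,end Integer residue-number bounds, `start <= end`.
#' @return A `helix_annotation` data frame.
#' @export
helix_annotation <- function(label, start, end) {
  label <- as.character(label)
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyDuplicated(label))
    abort("helix labels must be unique", "config_error")
  if (any(is.na(start) | is.na(end) | start > end))
    abort("helix ranges need start <= end", "config_error")
  ord <- order(start)
  if (any(start[ord][-1L] <= end[ord][-length(ord)]))
    abort("helix ranges must not overlap", "config_error")
  out <- data.frame(label = label, start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("helix_annotation", "data.frame")
  out
}

#' Helix membership of a residue
#'
#' @param pos Residue number(s).
#' @param helices A [helix_annotation()].
#' @return Character vector of helix labels; `NA` for positions outside
#'   every range. Range ends are inclusive.
#' @export
annotate_helix <- function(pos, helices) {
  stopifnot(inherits(helices, "helix_annotation"))
  vapply(as.integer(pos), function(p) {
    i <- which(helices$start <= p & p <= helices$end)
    if (length(i) == 1L) helices$label[i] else NA_character_
  }, character(1L))
}

#' Queried positions that are unresolved in a structure model
#'
#' A position is unresolved when it is absent from the model or lacks a
#' C-alpha atom — e.g. residues in disordered loops that were not built in
#' the deposited model.
#'
#' @param positions Integer vector of residue numbers to query.
#' @param model A [structure_model()].
#' @return Sorted integer vector, the unresolved subset of `positions`.
#' @export
unresolved_positions <- function(positions, model) {
  stopifnot(inherits(model, "structure_model"))
  positions <- sort(unique(as.integer(positions)))
  resolved <- model$resnum[model$resolved]
  positions[!positions %in% resolved]
}

#' Beta-carbon coordinate of a residue
#'
#' Falls back to the C-alpha when the C-beta is absent (glycine, or a
#' truncated side chain); the fallback is reported via a message.
#'
#' @param model A [structure_model()].
#' @param pos Residue number.
#' @return Numeric length-3 coordinate vector (Angstrom), with attribute
#'   `fallback = TRUE` when the C-alpha was used.
#' @export
cb_coordinate <- function(model, pos) {
  stopifnot(inherits(model, "structure_model"))
  i <- match(as.integer(pos), model$resnum)
  if (is.na(i) || !model$resolved[i])
    abort(sprintf("residue %d is not resolved in the model", pos),
          "unresolved_residue")
  if (!is.na(model$cb_x[i]))
    return(c(model$cb_x[i], model$cb_y[i], model$cb_z[i]))
  message(sprintf("residue %d (%s): no C-beta, using C-alpha",
                  model$resnum[i], model$aa[i]))
  structure(c(model$ca_x[i], model$ca_y[i], model$ca_z[i]), fallback = TRUE)
}

# cb coordinates (with silent CA fallback) for a set of resolved positions
cb_matrix <- function(model, positions) {
  idx <- match(positions, model$resnum)
  cb <- cbind(model$cb_x[idx], model$cb_y[idx], model$cb_z[idx])
  fb <- is.na(cb[, 1L])
  cb[fb, ] <- cbind(model$ca_x[idx], model$ca_y[idx], model$ca_z[idx])[fb, ,
                                                                       drop = FALSE]
  cb
}

#' Beta-carbon contact pairs among queried residues
#'
#' All unordered pairs of resolved queried positions whose C-beta atoms lie
#' strictly closer than `threshold` Angstrom (glycines fall back to the
#' C-alpha). Unresolved positions are skipped and listed in the
#' `skipped` attribute. When a helix annotation is supplied, each pair is
#' flagged `same_helix` and carries both helix labels.
#'
#' @param model A [structure_model()].
#' @param positions Integer vector of residue numbers.
#' @param threshold Contact distance threshold in Angstrom (default 6.0,
#'   strict `<`).
#' @param helices Optional [helix_annotation()].
#' @return Data frame with columns `pos_i`, `pos_j` (`pos_i < pos_j`),
#'   `distance`, `same_helix`, `helix_i`, `helix_j`; attribute `skipped`
#'   holds unresolved queried positions.
#' @export
contact_pairs <- function(model, positions, threshold = 6.0, helices = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.numeric(threshold) || threshold <= 0)
    abort("threshold must be a positive distance in Angstrom", "config_error")
  positions <- sort(unique(as.integer(positions)))
  skipped <- unresolved_positions(positions, model)
  pos <- setdiff(positions, skipped)
  empty <- data.frame(pos_i = integer(0), pos_j = integer(0),
                      distance = numeric(0), same_helix = logical(0),
                      helix_i = character(0), helix_j = character(0),
                      stringsAsFactors = FALSE)
  if (length(pos) < 2L) {
    if (length(positions) >= 2L)
      warning("fewer than 2 resolved positions; no pairs computed")
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  xyz <- cb_matrix(model, pos)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d < threshold, arr.ind = TRUE)
  out <- if (nrow(idx) == 0L) empty else {
    data.frame(pos_i = pos[idx[, 1L]], pos_j = pos[idx[, 2L]],
               distance = d[idx],
               same_helix = NA, helix_i = NA_character_,
               helix_j = NA_character_, stringsAsFactors = FALSE)
  }
  if (nrow(out) > 0L) {
    if (!is.null(helices)) {
      out$helix_i <- annotate_helix(out$pos_i, helices)
      out$helix_j <- annotate_helix(out$pos_j, helices)
      out$same_helix <- !is.na(out$helix_i) & out$helix_i == out$helix_j
    }
    out <- out[order(out$pos_i, out$pos_j), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}
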