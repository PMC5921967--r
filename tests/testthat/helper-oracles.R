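# Independent brute-force oracles and random-instance builders. These
# deliberately recompute everything residue by residue, pair by pair, so
# the vectorized implementations are checked against a second route.

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# per-column, per-group conservation by naive iteration
naive_profile <- function(aln, groups, table = default_class_table()) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  g <- unname(unclass(groups)[aln$id])
  labels <- unique(g)
  states <- list()
  ident <- matrix(NA_character_, length(labels), ncol(m))
  for (k in seq_along(labels)) {
    for (col in seq_len(ncol(m))) {
      res <- m[g == labels[k], col]
      if (any(res == "-")) {
        st <- "gapped"; val <- NA_character_
      } else if (length(unique(res)) == 1L && res[1L] != "X") {
        st <- "identical"; val <- res[1L]
        ident[k, col] <- res[1L]
      } else if (!any(res == "X") &&
                 length(unique(unname(table[res]))) == 1L) {
        st <- "class_conserved"; val <- unname(table[res[1L]])
      } else {
        st <- "unconserved"; val <- NA_character_
      }
      states[[length(states) + 1L]] <-
        data.frame(column = col, group = labels[k], state = st, value = val,
                   stringsAsFactors = FALSE)
    }
  }
  universal <- logical(ncol(m))
  for (col in seq_len(ncol(m))) {
    universal[col] <- !any(is.na(ident[, col])) &&
      length(unique(ident[, col])) == 1L
  }
  list(states = do.call(rbind, states), universal = universal)
}

# brute-force sliding-window motif matcher with context windows
naive_scan <- function(s, pattern) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  L <- pattern$length
  hits <- list()
  for (start in seq_len(max(n - L + 1L, 0L))) {
    ok <- TRUE
    for (k in seq_len(L)) {
      e <- pattern$elements[k]
      if (e != "x" && chars[start + k - 1L] != e) { ok <- FALSE; break }
    }
    if (!ok) next
    ctx_ok <- TRUE
    if (nrow(pattern$contexts) > 0L) {
      for (j in seq_len(nrow(pattern$contexts))) {
        cc <- pattern$contexts[j, ]
        win <- if (cc$direction == "upstream")
          (start - cc$max):(start - cc$min) else (start + cc$min):(start + cc$max)
        win <- win[win >= 1L & win <= n]
        if (!any(chars[win] == cc$residue)) { ctx_ok <- FALSE; break }
      }
    }
    hits[[length(hits) + 1L]] <- data.frame(
      start = start, matched = paste(chars[start:(start + L - 1L)],
                                     collapse = ""),
      context_ok = ctx_ok, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(0), matched = character(0),
                      context_ok = logical(0)))
  do.call(rbind, hits)
}

# all-pairs O(n^2) contact filter with Cbeta -> Calpha fallback
naive_contacts <- function(model, positions, threshold) {
  positions <- sort(unique(as.integer(positions)))
  resolved <- positions[positions %in% model$resnum[model$resolved]]
  out <- list()
  coord <- function(p) {
    i <- match(p, model$resnum)
    if (!is.na(model$cb_x[i])) c(model$cb_x[i], model$cb_y[i], model$cb_z[i])
    else c(model$ca_x[i], model$ca_y[i], model$ca_z[i])
  }
  for (a in seq_along(resolved)) {
    for (b in seq_along(resolved)) {
      if (a >= b) next
      d <- sqrt(sum((coord(resolved[a]) - coord(resolved[b]))^2))
      if (d < threshold)
        out[[length(out) + 1L]] <- data.frame(pos_i = resolved[a],
                                              pos_j = resolved[b],
                                              distance = d)
    }
  }
  if (length(out) == 0L)
    return(data.frame(pos_i = integer(0), pos_j = integer(0),
                      distance = numeric(0)))
  do.call(rbind, out)
}

# random gapped alignment + a 2-3 group assignment covering all rows
random_alignment <- function(n_rows, n_cols, gap_p = 0.08, x_p = 0.02) {
  pool <- c(AA20_T, "X", "-")
  prob <- c(rep((1 - gap_p - x_p) / 20, 20), x_p, gap_p)
  repeat {
    m <- matrix(sample(pool, n_rows * n_cols, TRUE, prob), n_rows)
    rows <- apply(m, 1L, paste, collapse = "")
    if (all(grepl("[^-]", rows))) break   # no all-gap rows
  }
  alignment(paste0("r", seq_len(n_rows)), rows)
}

random_groups <- function(ids, n_groups = 2L) {
  n <- length(ids)
  n_groups <- min(n_groups, n %/% 2L)   # every group needs >= 2 members
  lab <- paste0("g", seq_len(n_groups))
  assign <- rep(lab, length.out = n)   # every group gets >= 2 members
  group_assignment(ids, sample(assign))
}

random_sequence <- function(len, letters = AA20_T) {
  paste(sample(letters, len, TRUE), collapse = "")
}

aln_row_for_test <- function(aln, id) aln$rows[match(id, aln$id)]

digest_file <- function(f) unname(tools::md5sum(f))

# structure model from explicit coordinates (Cbeta = Calpha + offset)
toy_model <- function(coords, aa = NULL, cb_offset = c(0, 0, 0.5)) {
  n <- nrow(coords)
  if (is.null(aa)) aa <- rep("A", n)
  cb <- sweep(coords, 2L, cb_offset, `+`)
  cb[aa == "G", ] <- NA_real_
  structure_model(seq_len(n), aa, coords, cb)
}
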