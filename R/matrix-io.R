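# Reading, writing and editing matrices in the TNT (xread) and NEXUS dialects.
#
# Both '?' and '-' are treated as fully missing: discrete morphological
# matrices carry no gap semantics. Character indices in all user-facing
# reports and edits are 1-based; the TNT ccode command itself numbers
# characters from 0 (the TNT convention) and the translation happens here.

#' Parse a morphological character matrix
#'
#' Reads a TNT `xread` block or a NEXUS `DATA`/`CHARACTERS` block into a
#' [char_matrix()]. Ordering declarations (TNT `ccode +`, NEXUS `TYPESET`
#' with an `ord:` part) populate the per-character additive flags; if no
#' declaration is present every character is left unordered and a warning is
#' emitted.
#'
#' @param text Matrix file content: a single string or a character vector of
#'   lines.
#' @param dialect `"tnt"`, `"nexus"` or `"auto"` (detect from content).
#' @return A [char_matrix()].
#' @seealso [read_matrix()] to read from a file path, [write_matrix()].
#' @export
parse_matrix <- function(text, dialect = c("auto", "tnt", "nexus")) {
  dialect <- match.arg(dialect)
  txt <- paste(text, collapse = "\n")
  if (dialect == "auto") {
    dialect <- if (grepl("#NEXUS", txt, ignore.case = TRUE)) "nexus"
    else if (grepl("\\bxread\\b", txt, ignore.case = TRUE)) "tnt"
    else stop("cannot detect dialect: no '#NEXUS' header or 'xread' keyword")
  }
  if (dialect == "tnt") parse_tnt(txt) else parse_nexus(txt)
}

#' Read a matrix file from disk
#' @param path File path.
#' @inheritParams parse_matrix
#' @export
read_matrix <- function(path, dialect = c("auto", "tnt", "nexus")) {
  parse_matrix(readLines(path, warn = FALSE), dialect)
}

# --- TNT ---------------------------------------------------------------

parse_tnt <- function(txt) {
  m <- regexpr("\\bxread\\b", txt, ignore.case = TRUE)
  if (m < 0) stop("not a TNT matrix: no 'xread' keyword")
  rest <- substr(txt, m + attr(m, "match.length"), nchar(txt))
  # optional quoted title (may span lines)
  rest <- sub("^[[:space:]]*'[^']*'", "", rest)
  hdr <- regmatches(rest, regexec("^[[:space:]]*([0-9]+)[[:space:]]+([0-9]+)", rest))[[1]]
  if (length(hdr) != 3L) stop("malformed xread header: expected 'nchar ntax'")
  nchr <- as.integer(hdr[2]); ntax <- as.integer(hdr[3])
  rest <- substr(rest, nchar(hdr[1]) + 1L, nchar(rest))
  semi <- regexpr(";", rest, fixed = TRUE)
  if (semi < 0) stop("unterminated xread block: missing ';'")
  body <- substr(rest, 1L, semi - 1L)
  tail_cmds <- substr(rest, semi + 1L, nchar(rest))

  rows <- parse_matrix_rows(body, dialect = "tnt")
  cm <- assemble_matrix(rows, ntax, nchr)

  ord <- tnt_ccode_flags(tail_cmds, nchr)
  if (is.null(ord)) {
    warning("no ccode ordering declaration found: all characters left unordered",
            call. = FALSE)
    ord <- rep(FALSE, nchr)
  }
  new_char_matrix(cm$cells, cm$labels, ord)
}

# ccode: only '+' (additive) and '-' (non-additive) modes are honored;
# indices are 0-based, ranges written a.b, '.' means all characters.
tnt_ccode_flags <- function(txt, nchr) {
  cmds <- regmatches(txt, gregexpr("\\bcc(ode)?\\b[^;]*;", txt, ignore.case = TRUE))[[1]]
  if (length(cmds) == 0L) return(NULL)
  ord <- rep(FALSE, nchr)
  for (cmd in cmds) {
    body <- sub(";$", "", sub("^[[:space:]]*cc(ode)?\\b", "", cmd, ignore.case = TRUE))
    mode <- NA
    for (tok in strsplit(trimws(body), "[[:space:]]+")[[1]]) {
      if (tok == "") next
      if (tok %in% c("+", "-")) { mode <- tok; next }
      if (grepl("^[+-]", tok)) { mode <- substr(tok, 1, 1); tok <- substr(tok, 2, nchar(tok)) }
      if (tok == "") next
      if (is.na(mode)) next  # weight or unknown mode tokens are ignored
      idx <- if (tok == ".") seq_len(nchr) - 1L
      else if (grepl("^[0-9]+\\.[0-9]+$", tok)) {
        ab <- as.integer(strsplit(tok, ".", fixed = TRUE)[[1]]); ab[1]:ab[2]
      } else if (grepl("^[0-9]+$", tok)) as.integer(tok)
      else next
      if (any(idx < 0L | idx >= nchr)) {
        stop("ccode character index out of range (0-based): ", tok, call. = FALSE)
      }
      ord[idx + 1L] <- mode == "+"
    }
  }
  ord
}

# --- NEXUS -------------------------------------------------------------

parse_nexus <- function(txt) {
  txt <- gsub("\\[[^]]*\\]", " ", txt)  # NEXUS square brackets are comments
  up <- toupper(txt)
  ntax <- nexus_number(txt, "NTAX")
  nchr <- nexus_number(txt, "NCHAR")
  if (is.na(ntax) || is.na(nchr)) stop("NEXUS DIMENSIONS with NTAX and NCHAR required")
  sym <- regmatches(txt, regexec("SYMBOLS[[:space:]]*=[[:space:]]*\"([^\"]*)\"",
                                 txt, ignore.case = TRUE))[[1]]
  if (length(sym) == 2L && grepl("[^0-9[:space:]~-]", sym[2])) {
    stop("unsupported SYMBOLS (only integer states 0-9 are handled): ", sym[2])
  }
  mstart <- regexpr("\\bMATRIX\\b", up)
  if (mstart < 0) stop("no MATRIX keyword in NEXUS data block")
  rest <- substr(txt, mstart + 6L, nchar(txt))
  semi <- regexpr(";", rest, fixed = TRUE)
  if (semi < 0) stop("unterminated MATRIX: missing ';'")
  body <- substr(rest, 1L, semi - 1L)
  rows <- parse_matrix_rows(body, dialect = "nexus")
  cm <- assemble_matrix(rows, ntax, nchr)

  ord <- nexus_typeset_flags(substr(rest, semi + 1L, nchar(rest)), nchr)
  if (is.null(ord)) {
    warning("no TYPESET ordering declaration found: all characters left unordered",
            call. = FALSE)
    ord <- rep(FALSE, nchr)
  }
  new_char_matrix(cm$cells, cm$labels, ord)
}

nexus_number <- function(txt, key) {
  m <- regmatches(txt, regexec(paste0("\\b", key, "[[:space:]]*=[[:space:]]*([0-9]+)"),
                               txt, ignore.case = TRUE))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NA_integer_
}

# TYPESET * name = ord: 2 5-8, unord: 1 3-4;   (1-based, '-' ranges)
nexus_typeset_flags <- function(txt, nchr) {
  cmds <- regmatches(txt, gregexpr("\\bTYPESET\\b[^;]*;", txt, ignore.case = TRUE))[[1]]
  if (length(cmds) == 0L) return(NULL)
  ord <- rep(FALSE, nchr)
  for (cmd in cmds) {
    body <- sub(".*=", "", sub(";$", "", cmd))
    for (part in strsplit(body, ",", fixed = TRUE)[[1]]) {
      kv <- strsplit(part, ":", fixed = TRUE)[[1]]
      if (length(kv) != 2L) next
      type <- tolower(trimws(kv[1]))
      is_ord <- type %in% c("ord", "o", "ordered")
      if (!is_ord && !type %in% c("unord", "u", "unordered")) next
      for (tok in strsplit(trimws(kv[2]), "[[:space:]]+")[[1]]) {
        if (tok == "") next
        idx <- if (grepl("^[0-9]+-[0-9]+$", tok)) {
          ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]]); ab[1]:ab[2]
        } else if (grepl("^[0-9]+$", tok)) as.integer(tok)
        else stop("malformed TYPESET entry: ", tok, call. = FALSE)
        if (any(idx < 1L | idx > nchr)) {
          stop("TYPESET character index out of range (1-based): ", tok, call. = FALSE)
        }
        ord[idx] <- is_ord
      }
    }
  }
  ord
}

# --- shared row machinery ----------------------------------------------

# Rows are 'label states'; interleaved blocks repeat labels and are
# concatenated in first-seen order.
parse_matrix_rows <- function(body, dialect) {
  poly_open <- if (dialect == "tnt") "[{(" else "{("
  poly_close <- if (dialect == "tnt") "]})" else "})"
  labels <- character(0)
  cells <- list()
  for (line in strsplit(body, "\n", fixed = TRUE)[[1]]) {
    line <- trimws(line)
    if (line == "" || line == "&") next
    if (grepl("^'", line)) {  # quoted label
      m <- regexec("^'([^']*)'[[:space:]]*(.*)$", line)[[1]]
      lab <- regmatches(line, list(m))[[1]][2]
      states <- regmatches(line, list(m))[[1]][3]
    } else {
      sp <- regexpr("[[:space:]]", line)
      if (sp < 0) stop("malformed matrix row (no states): ", line, call. = FALSE)
      lab <- substr(line, 1L, sp - 1L)
      states <- substr(line, sp + 1L, nchar(line))
    }
    parsed <- parse_states_string(states, poly_open, poly_close)
    if (!is.na(parsed$bad)) {
      stop(sprintf("illegal state symbol in row '%s' at position %d: '%s'",
                   lab, parsed$bad, substr(states, parsed$bad, parsed$bad)),
           call. = FALSE)
    }
    key <- norm_label(lab)
    at <- match(key, norm_label(labels))
    if (is.na(at)) {
      labels <- c(labels, lab)
      cells[[length(labels)]] <- parsed$masks
    } else {
      cells[[at]] <- c(cells[[at]], parsed$masks)  # interleaved continuation
    }
  }
  list(labels = labels, cells = cells)
}

assemble_matrix <- function(rows, ntax, nchr) {
  if (length(rows$labels) != ntax) {
    stop(sprintf("declared %d taxa but found %d matrix rows", ntax, length(rows$labels)),
         call. = FALSE)
  }
  bad <- which(lengths(rows$cells) != nchr)
  if (length(bad) > 0L) {
    stop(sprintf("row '%s' has %d characters, expected %d",
                 rows$labels[bad[1]], lengths(rows$cells)[bad[1]], nchr),
         call. = FALSE)
  }
  list(labels = rows$labels, cells = do.call(rbind, rows$cells))
}

# --- writing -----------------------------------------------------------

#' Write a character matrix as TNT or NEXUS text
#'
#' The output re-parses to an equal matrix (same cells and ordered flags;
#' labels are equal under the package's whitespace/underscore-insensitive
#' label equivalence, since TNT labels cannot contain spaces). An ordering
#' declaration (`ccode`/`TYPESET`) is written only when at least one
#' character is flagged additive.
#'
#' @param cm A [char_matrix()].
#' @param dialect `"tnt"` or `"nexus"`.
#' @param path Optional file path; when `NULL` the text is returned.
#' @return The matrix text, invisibly when written to `path`.
#' @export
write_matrix <- function(cm, dialect = c("tnt", "nexus"), path = NULL) {
  dialect <- match.arg(dialect)
  labs <- gsub("[[:space:]]+", "_", cm$labels)
  wid <- max(nchar(labs)) + 2L
  rows <- vapply(seq_len(n_taxa(cm)), function(i) {
    sprintf("%-*s%s", wid, labs[i], cells_to_string(cm$cells[i, ], dialect))
  }, character(1))
  if (dialect == "tnt") {
    out <- c("xread", "'written by mpsearch'",
             sprintf("%d %d", n_chars(cm), n_taxa(cm)), rows, ";")
    if (any(cm$ordered)) {
      out <- c(out, paste0("ccode + ", paste(which(cm$ordered) - 1L, collapse = " "), ";"))
    }
    out <- c(out, "proc /;")
  } else {
    out <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(cm), n_chars(cm)),
             "  FORMAT SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
             "  MATRIX", paste0("    ", rows), "  ;", "END;")
    if (any(cm$ordered)) {
      out <- c(out, "BEGIN ASSUMPTIONS;",
               sprintf("  TYPESET * default = ord: %s;",
                       paste(which(cm$ordered), collapse = " ")),
               "END;")
    }
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# --- OTU merge ----------------------------------------------------------

#' Merge two OTUs into one row
#'
#' Combines the scorings of `source` into `target` and drops the source row.
#' Per cell: the known cell wins when exactly one side is missing; when both
#' are known the intersection is used if non-empty; disjoint known cells are
#' a conflict — under `"union"` policy the union is kept and the conflict is
#' logged (returned in the `"conflicts"` attribute and reported via
#' [message()]), under `"error"` the merge fails.
#'
#' @param cm A [char_matrix()].
#' @param source,target Taxon labels (whitespace/underscore-insensitive).
#' @param conflict `"union"` or `"error"`.
#' @return A `char_matrix` with one fewer taxon, target row merged.
#' @export
merge_otus <- function(cm, source, target, conflict = c("union", "error")) {
  conflict <- match.arg(conflict)
  si <- match_label(cm$labels, source)
  ti <- match_label(cm$labels, target)
  if (si == ti) stop("source and target are the same taxon")
  a <- cm$cells[si, ]; b <- cm$cells[ti, ]
  inter <- bitwAnd(a, b)
  merged <- ifelse(a == 0L, b, ifelse(b == 0L, a, ifelse(inter != 0L, inter, bitwOr(a, b))))
  clash <- which(a != 0L & b != 0L & inter == 0L)
  if (length(clash) > 0L) {
    if (conflict == "error") {
      stop(sprintf("conflicting states at character(s) %s between '%s' and '%s'",
                   paste(clash, collapse = ", "), source, target), call. = FALSE)
    }
    message(sprintf("merge_otus: %d conflicting cell(s) resolved by union (characters %s)",
                    length(clash), paste(clash, collapse = ", ")))
  }
  cells <- cm$cells
  cells[ti, ] <- as.integer(merged)
  cells <- cells[-si, , drop = FALSE]
  out <- new_char_matrix(cells, cm$labels[-si], cm$ordered)
  attr(out, "conflicts") <- if (length(clash) > 0L) {
    data.frame(char = clash,
               source_states = vapply(a[clash], function(m) paste(states_of(m), collapse = "/"), character(1)),
               target_states = vapply(b[clash], function(m) paste(states_of(m), collapse = "/"), character(1)))
  } else NULL
  out
}

# --- scoring edits ------------------------------------------------------

#' Apply character re-scorings to a matrix
#'
#' Edits follow the printed `character:state` convention: indices are 1-based
#' and the new state may be `NA` (or `"?"`) for missing. When an edit carries
#' an `old` assertion that does not match the current cell, the mismatch is
#' reported (one warning listing all mismatches) before the edit is applied.
#'
#' @param cm A [char_matrix()].
#' @param edits Data frame with columns `taxon`, `char`, `new` and optionally
#'   `old`. `new`/`old` may be integers, state strings such as `"01"`, `"?"`,
#'   or `NA` for missing.
#' @return The edited `char_matrix`.
#' @examples
#' cm <- char_matrix(c(A = "010", B = "120"))
#' edited <- apply_scoring_edits(cm, data.frame(taxon = "A", char = 2, new = 1))
#' matrix_cell(edited, "A", 2)
#' @export
apply_scoring_edits <- function(cm, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(cm)
  stopifnot(all(c("taxon", "char", "new") %in% names(edits)))
  cells <- cm$cells
  mism <- character(0)
  for (k in seq_len(nrow(edits))) {
    i <- match_label(cm$labels, edits$taxon[k])
    j <- as.integer(edits$char[k])
    if (j < 1L || j > n_chars(cm)) {
      stop(sprintf("edit %d: character index %d out of range 1..%d", k, j, n_chars(cm)),
           call. = FALSE)
    }
    new_mask <- edit_state_mask(edits$new[k])
    if ("old" %in% names(edits)) {
      old_mask <- edit_state_mask(edits$old[k], assert = TRUE)
      if (!is.null(old_mask) && old_mask != cells[i, j]) {
        mism <- c(mism, sprintf("%s %d: expected '%s', found '%s'",
                                cm$labels[i], j,
                                cells_to_string(old_mask, "tnt"),
                                cells_to_string(cells[i, j], "tnt")))
      }
    }
    cells[i, j] <- new_mask
  }
  if (length(mism) > 0L) {
    warning("old-state assertions did not match current cells:\n  ",
            paste(mism, collapse = "\n  "), call. = FALSE)
  }
  new_char_matrix(cells, cm$labels, cm$ordered)
}

# state spec -> mask; NA/"?"/"" mean missing; assert=TRUE returns NULL for
# an absent assertion (NA old field)
edit_state_mask <- function(x, assert = FALSE) {
  if (is.na(x) || identical(x, "?") || identical(x, "")) {
    return(if (assert) NULL else 0L)
  }
  if (is.numeric(x)) return(mask_of(as.integer(x)))
  p <- parse_states_string(as.character(x))
  if (!is.na(p$bad) || length(p$masks) != 1L) stop("malformed state spec: ", x, call. = FALSE)
  p$masks
}
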