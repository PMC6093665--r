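# Discrete morphological character matrices.
#
# A cell is a *state set*: a subset of the integer alphabet {0..9}. Cells are
# stored as integer bitmasks (bit i set <=> state i present); the empty mask 0
# encodes a fully missing cell ('?' or '-'), which behaves as the whole
# alphabet of its character in every scoring operation.

MAX_STATE <- 9L

#' Convert a vector of states to a bitmask
#' @noRd
mask_of <- function(states) {
  states <- unique(as.integer(states))
  if (length(states) == 0L || anyNA(states)) return(0L)
  stopifnot(all(states >= 0L & states <= MAX_STATE))
  sum(bitwShiftL(1L, states))
}

#' Convert a bitmask back to the sorted vector of states (integer(0) = missing)
#' @noRd
states_of <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:MAX_STATE)) != 0L) - 1L
}

# label matching is whitespace/underscore-insensitive (TNT labels use
# underscores where display names use spaces)
norm_label <- function(x) tolower(gsub("[_[:space:]]+", " ", trimws(x)))

match_label <- function(labels, x, what = "taxon") {
  i <- match(norm_label(x), norm_label(labels))
  if (anyNA(i)) {
    stop(sprintf("unknown %s label(s): %s", what,
                 paste(x[is.na(i)], collapse = ", ")), call. = FALSE)
  }
  i
}

#' Build a character matrix from state strings
#'
#' Constructs the central data object of the package: a taxa x characters grid
#' of state sets with per-character ordered (additive) flags. Each row string
#' uses the TNT cell alphabet: digits `0`-`9` for single states, `?` or `-`
#' for missing, and `[..]`, `{..}` or `(..)` for polymorphic cells.
#'
#' @param rows Named character vector, one state string per taxon, or a list
#'   of integer state vectors / lists of state vectors.
#' @param ordered Logical vector flagging additive characters (recycled;
#'   default all unordered).
#' @param labels Taxon labels; defaults to `names(rows)`.
#' @return An object of class `char_matrix` with fields `labels`, `cells`
#'   (bitmask matrix), `ordered` and `alphabet` (maximum observed state per
#'   character, `-1` for characters with no observed state).
#' @examples
#' cm <- char_matrix(c(A = "0101", B = "01?2", C = "1[01]00", D = "110-"))
#' dim(cm)
#' @export
char_matrix <- function(rows, ordered = NULL, labels = NULL) {
  if (is.character(rows)) {
    labels <- labels %||% names(rows)
    if (is.null(labels)) stop("taxon labels are required")
    cells <- lapply(rows, function(s) parse_states_string(s)$masks)
  } else if (is.list(rows)) {
    labels <- labels %||% names(rows)
    if (is.null(labels)) stop("taxon labels are required")
    cells <- lapply(rows, function(r) {
      if (is.list(r)) vapply(r, mask_of, integer(1)) else vapply(as.list(r), mask_of, integer(1))
    })
  } else {
    stop("`rows` must be a character vector or a list")
  }
  nch <- unique(lengths(cells))
  if (length(nch) != 1L) {
    stop("all rows must have the same number of characters")
  }
  m <- do.call(rbind, cells)
  rownames(m) <- NULL
  new_char_matrix(m, as.character(labels), ordered)
}

new_char_matrix <- function(cells, labels, ordered = NULL) {
  storage.mode(cells) <- "integer"
  ntax <- nrow(cells); nchr <- ncol(cells)
  if (length(labels) != ntax) stop("label / row count mismatch")
  if (anyDuplicated(norm_label(labels))) {
    stop("duplicate taxon labels: ",
         paste(labels[duplicated(norm_label(labels))], collapse = ", "))
  }
  ordered <- if (is.null(ordered)) rep(FALSE, nchr) else rep_len(as.logical(ordered), nchr)
  alphabet <- vapply(seq_len(nchr), function(j) {
    s <- states_of(Reduce(bitwOr, cells[, j], 0L))
    if (length(s) == 0L) -1L else max(s)
  }, integer(1))
  structure(list(labels = labels, cells = cells,
                 ordered = ordered, alphabet = alphabet),
            class = "char_matrix")
}

#' @export
dim.char_matrix <- function(x) c(length(x$labels), ncol(x$cells))

n_taxa <- function(cm) length(cm$labels)
n_chars <- function(cm) ncol(cm$cells)

#' Read one cell as a vector of states
#'
#' @param cm A `char_matrix`.
#' @param taxon Taxon label (whitespace/underscore-insensitive) or row index.
#' @param char 1-based character index.
#' @return Sorted integer vector of states; `integer(0)` for a missing cell.
#' @export
matrix_cell <- function(cm, taxon, char) {
  i <- if (is.character(taxon)) match_label(cm$labels, taxon) else as.integer(taxon)
  j <- as.integer(char)
  if (j < 1L || j > n_chars(cm)) stop("character index out of range: ", char)
  states_of(cm$cells[i, j])
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters (%d ordered, %d unordered)\n",
              n_taxa(x), n_chars(x), sum(x$ordered), sum(!x$ordered)))
  miss <- mean(x$cells == 0L)
  poly <- mean(vapply(x$cells, function(m) length(states_of(m)) > 1L, logical(1)))
  cat(sprintf("  missing cells: %.1f%%; polymorphic cells: %.1f%%\n",
              100 * miss, 100 * poly))
  show <- utils::head(x$labels, 5L)
  for (lb in show) {
    i <- match(lb, x$labels)
    cat(sprintf("  %-20s %s\n", lb,
                cells_to_string(x$cells[i, seq_len(min(40L, n_chars(x)))], "tnt")))
  }
  if (n_taxa(x) > 5L) cat(sprintf("  ... and %d more taxa\n", n_taxa(x) - 5L))
  invisible(x)
}

# equality under the package's label equivalence; used by round-trip tests
cm_equal <- function(a, b) {
  identical(dim(a), dim(b)) &&
    identical(norm_label(a$labels), norm_label(b$labels)) &&
    identical(unname(a$cells), unname(b$cells)) &&
    identical(a$ordered, b$ordered)
}

cm_drop_taxa <- function(cm, taxa) {
  i <- match_label(cm$labels, taxa)
  keep <- setdiff(seq_len(n_taxa(cm)), i)
  if (length(keep) < 1L) stop("cannot drop all taxa")
  new_char_matrix(cm$cells[keep, , drop = FALSE], cm$labels[keep], cm$ordered)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- cell string scanning -----------------------------------------------

# Scan a TNT/NEXUS state string into bitmasks. Returns list(masks, bad)
# where bad is the 1-based position of the first illegal symbol (NA if none).
parse_states_string <- function(s, poly_open = "[{(", poly_close = "]})") {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  masks <- integer(0)
  i <- 1L; n <- length(chars)
  opens <- strsplit(poly_open, "")[[1]]
  closes <- strsplit(poly_close, "")[[1]]
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else if (ch >= "0" && ch <= "9") {
      masks <- c(masks, bitwShiftL(1L, as.integer(ch)))
      i <- i + 1L
    } else if (ch == "?" || ch == "-") {
      masks <- c(masks, 0L)
      i <- i + 1L
    } else if (ch %in% opens) {
      close_ch <- closes[match(ch, opens)]
      j <- i + 1L; acc <- 0L
      while (j <= n && chars[j] != close_ch) {
        if (chars[j] >= "0" && chars[j] <= "9") {
          acc <- bitwOr(acc, bitwShiftL(1L, as.integer(chars[j])))
        } else if (!grepl("[[:space:]]", chars[j])) {
          return(list(masks = masks, bad = j))
        }
        j <- j + 1L
      }
      if (j > n) return(list(masks = masks, bad = i))  # unclosed bracket
      if (acc == 0L) return(list(masks = masks, bad = i))  # empty set
      masks <- c(masks, acc)
      i <- j + 1L
    } else {
      return(list(masks = masks, bad = i))
    }
  }
  list(masks = masks, bad = NA_integer_)
}

# Render a row of masks as a cell string
cells_to_string <- function(masks, dialect = c("tnt", "nexus")) {
  dialect <- match.arg(dialect)
  open <- if (dialect == "tnt") "[" else "{"
  close <- if (dialect == "tnt") "]" else "}"
  paste(vapply(masks, function(m) {
    s <- states_of(m)
    if (length(s) == 0L) "?"
    else if (length(s) == 1L) as.character(s)
    else paste0(open, paste(s, collapse = ""), close)
  }, character(1)), collapse = "")
}
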