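# Equally weighted parsimony scoring.
#
# Unordered characters are optimized by the Fitch set pass (exact on binary
# trees, including ambiguous and polymorphic leaf sets); ordered (additive)
# characters by the Farris interval pass, where a polymorphic cell enters as
# the smallest enclosing interval of its states and a missing cell as the
# whole state line of its character. Trees with polytomies are scored by a
# generalized Sankoff dynamic program (unit cost for unordered characters,
# |i-j| for ordered), which agrees with the fast passes on binary trees.

BIG_COST <- 1e7

# lookup tables: lowest/highest set bit for masks 0..1023
.mask_lo <- vapply(0:1023, function(m) {
  s <- which(bitwAnd(m, bitwShiftL(1L, 0:9)) != 0L)
  if (length(s) == 0L) NA_integer_ else s[1] - 1L
}, integer(1))
.mask_hi <- vapply(0:1023, function(m) {
  s <- which(bitwAnd(m, bitwShiftL(1L, 0:9)) != 0L)
  if (length(s) == 0L) NA_integer_ else s[length(s)] - 1L
}, integer(1))

# Precompute scoring arrays for a matrix. Missing cells are expanded to the
# full alphabet of their character; characters with no observed state get a
# one-state alphabet and never contribute cost.
mp_prep <- function(cm) {
  smax <- pmax(cm$alphabet, 0L)
  full <- bitwShiftL(1L, smax + 1L) - 1L
  mask <- cm$cells
  for (j in seq_len(ncol(mask))) {
    mj <- mask[, j]
    mj[mj == 0L] <- full[j]
    mask[, j] <- mj
  }
  lo <- matrix(.mask_lo[mask + 1L], nrow(mask), ncol(mask))
  hi <- matrix(.mask_hi[mask + 1L], nrow(mask), ncol(mask))
  list(labels = cm$labels, nchar = ncol(mask), mask = mask,
       lo = lo, hi = hi, smax = smax, ordered = cm$ordered)
}

prep_rows <- function(ut, prep) {
  i <- match(norm_label(ut$labels), norm_label(prep$labels))
  if (anyNA(i)) {
    stop("tree leaf without a matrix row: ",
         paste(ut$labels[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}

# --- fast passes (binary trees rooted at tip 1) --------------------------

fitch_farris_steps <- function(ut, prep, rows) {
  n <- ut$ntip
  tr <- ut_traverse(ut, root = 1L)
  nn <- ut_nnode(ut)
  steps <- integer(prep$nchar)

  uo <- which(!prep$ordered)
  if (length(uo) > 0L) {
    S <- matrix(0L, nn, length(uo))
    cnt <- integer(length(uo))
    for (v in tr$post) {
      if (v == 1L) next
      if (v <= n) {
        S[v, ] <- prep$mask[rows[v], uo]
      } else {
        ch <- tr$children[[v]]
        A <- S[ch[1], ]; B <- S[ch[2], ]
        I <- bitwAnd(A, B)
        z <- I == 0L
        cnt <- cnt + z
        if (any(z)) I[z] <- bitwOr(A[z], B[z])
        S[v, ] <- I
      }
    }
    A <- prep$mask[rows[1L], uo]
    B <- S[tr$children[[1L]][1], ]
    cnt <- cnt + (bitwAnd(A, B) == 0L)
    steps[uo] <- cnt
  }

  od <- which(prep$ordered)
  if (length(od) > 0L) {
    LO <- matrix(0L, nn, length(od)); HI <- matrix(0L, nn, length(od))
    cnt <- integer(length(od))
    for (v in tr$post) {
      if (v == 1L) next
      if (v <= n) {
        LO[v, ] <- prep$lo[rows[v], od]; HI[v, ] <- prep$hi[rows[v], od]
      } else {
        ch <- tr$children[[v]]
        ol <- pmax(LO[ch[1], ], LO[ch[2], ])
        oh <- pmin(HI[ch[1], ], HI[ch[2], ])
        cnt <- cnt + pmax(0L, ol - oh)
        LO[v, ] <- pmin(ol, oh); HI[v, ] <- pmax(ol, oh)
      }
    }
    c1 <- tr$children[[1L]][1]
    ol <- pmax(prep$lo[rows[1L], od], LO[c1, ])
    oh <- pmin(prep$hi[rows[1L], od], HI[c1, ])
    cnt <- cnt + pmax(0L, ol - oh)
    steps[od] <- cnt
  }
  steps
}

# --- generalized Sankoff pass -------------------------------------------

# leaf cost matrix (smax_g+1 states x chars) for a taxon row and char subset
snk_leafcost <- function(prep, row, chars, s) {
  k <- length(chars)
  C <- matrix(BIG_COST, s, k)
  unordered <- !prep$ordered[chars]
  for (jj in seq_len(k)) {
    j <- chars[jj]
    if (unordered[jj]) {
      st <- states_of(prep$mask[row, j])
    } else {
      st <- prep$lo[row, j]:prep$hi[row, j]
    }
    C[st + 1L, jj] <- 0
  }
  C
}

col_mins <- function(C) {
  m <- C[1, ]
  if (nrow(C) > 1L) for (i in 2:nrow(C)) m <- pmin(m, C[i, ])
  m
}

# child cost vector -> contribution at the parent, unit cost
contrib_unit <- function(C, pad) {
  m <- col_mins(C) + 1
  out <- pmin(C, matrix(m, nrow(C), ncol(C), byrow = TRUE))
  out[pad] <- BIG_COST
  out
}

# child cost vector -> contribution at the parent, |i-j| cost
contrib_linear <- function(C, pad) {
  s <- nrow(C)
  out <- C
  if (s > 1L) {
    for (i in 2:s) out[i, ] <- pmin(out[i, ], out[i - 1L, ] + 1)
    for (i in (s - 1L):1L) out[i, ] <- pmin(out[i, ], out[i + 1L, ] + 1)
  }
  out[pad] <- BIG_COST
  out
}

# pad matrix: TRUE where the state is outside the character's own alphabet
snk_pad <- function(prep, chars, s) {
  outer(seq_len(s) - 1L, prep$smax[chars], ">")
}

# down-pass cost vectors for one character group; root is tip 1
snk_down <- function(ut, prep, rows, chars, tr, contrib, pad, s) {
  nn <- ut_nnode(ut)
  D <- vector("list", nn)
  for (v in tr$post) {
    if (v == tr$root) next
    if (v <= ut$ntip) {
      D[[v]] <- snk_leafcost(prep, rows[v], chars, s)
    } else {
      acc <- matrix(0, s, length(chars))
      for (u in tr$children[[v]]) acc <- acc + contrib(D[[u]], pad)
      D[[v]] <- acc
    }
  }
  D
}

snk_group_steps <- function(ut, prep, rows, chars, ordered_group) {
  if (length(chars) == 0L) return(numeric(0))
  s <- max(prep$smax[chars]) + 1L
  contrib <- if (ordered_group) contrib_linear else contrib_unit
  pad <- snk_pad(prep, chars, s)
  tr <- ut_traverse(ut, root = 1L)
  D <- snk_down(ut, prep, rows, chars, tr, contrib, pad, s)
  R <- snk_leafcost(prep, rows[1L], chars, s)
  for (u in tr$children[[1L]]) R <- R + contrib(D[[u]], pad)
  col_mins(R)
}

sankoff_steps <- function(ut, prep, rows) {
  steps <- numeric(prep$nchar)
  uo <- which(!prep$ordered); od <- which(prep$ordered)
  steps[uo] <- snk_group_steps(ut, prep, rows, uo, FALSE)
  steps[od] <- snk_group_steps(ut, prep, rows, od, TRUE)
  as.integer(round(steps))
}

# total length; fast path on binary trees, Sankoff otherwise
ut_steps <- function(ut, prep, rows = NULL) {
  rows <- rows %||% prep_rows(ut, prep)
  if (ut$ntip < 3L) {
    if (ut$ntip == 1L) return(integer(prep$nchar))
    a <- prep$mask[rows[1], ]; b <- prep$mask[rows[2], ]
    uo_steps <- as.integer(bitwAnd(a, b) == 0L)
    gap <- pmax(0L, pmax(prep$lo[rows[1], ], prep$lo[rows[2], ]) -
                     pmin(prep$hi[rows[1], ], prep$hi[rows[2], ]))
    return(ifelse(prep$ordered, gap, uo_steps))
  }
  if (ut_is_binary(ut)) fitch_farris_steps(ut, prep, rows)
  else sankoff_steps(ut, prep, rows)
}

ut_length <- function(ut, prep, rows = NULL) sum(ut_steps(ut, prep, rows))

# --- minimum branch lengths ---------------------------------------------

# Per-edge minimum number of changes over all most-parsimonious
# reconstructions, per character group, via down-pass (D) and up-pass (U)
# Sankoff vectors. Returns a vector over ut$edge rows (NA on terminal edges).
ut_branch_minlens <- function(ut, prep, rows = NULL) {
  rows <- rows %||% prep_rows(ut, prep)
  ne <- nrow(ut$edge)
  internal <- ut$edge[, 1] < 0L & ut$edge[, 2] < 0L
  out <- rep(NA_integer_, ne)
  if (!any(internal)) return(out)
  out[internal] <- 0L
  tr <- ut_traverse(ut, root = 1L)

  for (grp in list(FALSE, TRUE)) {
    chars <- which(prep$ordered == grp)
    if (length(chars) == 0L) next
    s <- max(prep$smax[chars]) + 1L
    contrib <- if (grp) contrib_linear else contrib_unit
    pad <- snk_pad(prep, chars, s)
    D <- snk_down(ut, prep, rows, chars, tr, contrib, pad, s)

    # per-character optimum for this group
    R <- snk_leafcost(prep, rows[1L], chars, s)
    for (u in tr$children[[1L]]) R <- R + contrib(D[[u]], pad)
    L <- col_mins(R)

    # up-pass: U[[v]] = cost vector (at parent(v)) of the tree minus subtree(v)
    nn <- ut_nnode(ut)
    U <- vector("list", nn)
    for (v in tr$pre) {
      ch <- tr$children[[v]]
      if (length(ch) == 0L) next
      base <- if (v == tr$root) {
        snk_leafcost(prep, rows[v], chars, s)
      } else {
        contrib(U[[v]], pad)
      }
      cc <- lapply(ch, function(u) contrib(D[[u]], pad))
      for (i in seq_along(ch)) {
        acc <- base
        for (j in seq_along(ch)) if (j != i) acc <- acc + cc[[j]]
        U[[ch[i]]] <- acc
      }
    }

    for (k in which(internal)) {
      a <- ut_index(ut$edge[k, 1], ut$ntip)
      b <- ut_index(ut$edge[k, 2], ut$ntip)
      child <- if (tr$parent[a] == b) a else b
      X <- U[[child]]; Y <- D[[child]]
      if (grp) {
        # ordered: smallest |i-j| among optimal endpoint pairs
        best_d <- rep(NA_real_, length(chars))
        minlen <- rep(NA_integer_, length(chars))
        for (d in 0:(s - 1L)) {
          vals <- rep(BIG_COST, length(chars))
          for (i in seq_len(s - d)) {
            vals <- pmin(vals, X[i, ] + Y[i + d, ])
            if (d > 0L) vals <- pmin(vals, X[i + d, ] + Y[i, ])
          }
          hit <- is.na(minlen) & abs(vals + d - L) < 0.5
          minlen[hit] <- d
        }
        out[k] <- out[k] + sum(minlen)
      } else {
        # unit cost: an edge needs 0 or 1 change per character
        same <- col_mins(X + Y)
        out[k] <- out[k] + sum(abs(same - L) > 0.5)
      }
    }
  }
  out
}

# --- public wrappers -----------------------------------------------------

#' Parsimony length of a tree on a matrix
#'
#' Sums per-character minimum change counts over all characters, honoring
#' the per-character ordered flags. The length is invariant under the choice
#' of display root; polytomies are allowed.
#'
#' @param tree An ape `phylo` tree whose tip labels match the matrix taxa.
#' @param cm A [char_matrix()].
#' @return A `length_breakdown`: list with `total` (integer) and `steps`
#'   (integer vector, one entry per character).
#' @examples
#' cm <- char_matrix(c(A = "00", B = "00", C = "11", D = "10"))
#' tree <- ape::read.tree(text = "((A,B),(C,D));")
#' tree_length(tree, cm)$total
#' @export
tree_length <- function(tree, cm) {
  ut <- as_ut(tree)
  if (!setequal(norm_label(ut$labels), norm_label(cm$labels))) {
    stop("tree leaf set and matrix taxon set differ")
  }
  prep <- mp_prep(cm)
  steps <- ut_steps(ut, prep)
  structure(list(total = as.integer(sum(steps)), steps = as.integer(steps)),
            class = "length_breakdown")
}

#' @export
print.length_breakdown <- function(x, ...) {
  cat(sprintf("tree length: %d steps over %d characters\n", x$total, length(x$steps)))
  invisible(x)
}

#' Minimum change count of a single character on a tree
#'
#' @param tree An ape `phylo` tree.
#' @param column State sets per taxon: a list of integer state vectors (or a
#'   plain integer vector), named by taxon or ordered as `tree$tip.label`.
#'   `NA`, `NULL` or empty entries are missing cells.
#' @param ordered Score as additive (`|i-j|` step cost) instead of unordered.
#' @return Integer number of steps.
#' @export
character_length <- function(tree, column, ordered = FALSE) {
  ut <- as_ut(tree)
  if (!is.list(column)) column <- as.list(column)
  labs <- names(column) %||% ut$labels
  cells <- vapply(column, function(x) {
    if (is.null(x) || all(is.na(x))) 0L else mask_of(x[!is.na(x)])
  }, integer(1))
  cm <- new_char_matrix(matrix(cells, ncol = 1L), labs, ordered)
  tree_length(ut, cm)$total
}

#' Minimum branch lengths over most-parsimonious reconstructions
#'
#' For each internal edge, the smallest number of changes assigned to that
#' edge by any most-parsimonious reconstruction, computed per character from
#' the Sankoff down-pass and up-pass state vectors and summed. This is the
#' quantity used by rule-1 collapsing ([collapse_zero_length()]).
#'
#' @param tree An ape `phylo` tree (binary or multifurcating).
#' @param cm A [char_matrix()].
#' @param edge Optional row index into the unrooted tree's edge matrix (the
#'   tree is unrooted first when needed). Terminal edges are an error — they
#'   are never candidates for collapsing.
#' @return With `edge`, an integer; otherwise a data frame with one row per
#'   edge of the unrooted tree (`min_length` is `NA` on terminal edges).
#' @export
min_branch_length <- function(tree, cm, edge = NULL) {
  ut <- as_ut(tree)
  prep <- mp_prep(cm)
  ml <- ut_branch_minlens(ut, prep)
  if (is.null(edge)) {
    return(data.frame(edge = seq_along(ml),
                      internal = ut$edge[, 1] < 0L & ut$edge[, 2] < 0L,
                      min_length = ml))
  }
  edge <- as.integer(edge)
  if (edge < 1L || edge > length(ml)) stop("edge index out of range")
  if (is.na(ml[edge])) stop("edge ", edge, " is terminal: terminal branches are never collapsed")
  ml[edge]
}
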