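# Internal unrooted-tree representation.
#
# A `ut` is list(ntip, nint, edge, labels): `edge` is an undirected 2-column
# integer matrix whose entries are tip ids 1..ntip (matching `labels`) or
# internal ids -1..-nint. Negative internal ids survive tip insertion without
# renumbering, which keeps Wagner addition and TBR surgery cheap. The public
# tree type is ape's `phylo`; conversion happens at the package boundary.

ut_new <- function(edge, labels, renumber = TRUE) {
  storage.mode(edge) <- "integer"
  if (renumber) {
    neg <- edge < 0L
    ints <- sort(unique(edge[neg]), decreasing = TRUE)  # -1, -2, ...
    if (length(ints) > 0L && !identical(ints, -seq_along(ints))) {
      edge[neg] <- -match(edge[neg], ints)
    }
    nint <- length(ints)
  } else {
    nint <- if (any(edge < 0L)) -min(edge) else 0L
  }
  list(ntip = length(labels), nint = nint, edge = edge, labels = labels)
}

ut_index <- function(id, ntip) ifelse(id > 0L, id, ntip - id)

ut_nnode <- function(ut) ut$ntip + ut$nint

# adjacency list over node indices (tips first, then internals)
ut_adj <- function(ut) {
  nn <- ut_nnode(ut)
  a <- ut_index(ut$edge[, 1], ut$ntip)
  b <- ut_index(ut$edge[, 2], ut$ntip)
  adj <- rep(list(integer(0)), nn)
  got <- split(c(b, a), factor(c(a, b), levels = seq_len(nn)))
  nonempty <- which(lengths(got) > 0L)
  adj[nonempty] <- got[nonempty]
  adj
}

# DFS from a root node index: returns preorder, parent pointers and children
ut_traverse <- function(ut, root = 1L, adj = NULL) {
  adj <- adj %||% ut_adj(ut)
  nn <- ut_nnode(ut)
  parent <- integer(nn)
  pre <- integer(nn)
  seen <- logical(nn)
  stack <- integer(nn); stack[1] <- root; sp <- 1L; np <- 0L
  seen[root] <- TRUE
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    np <- np + 1L; pre[np] <- v
    for (u in adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        parent[u] <- v
        sp <- sp + 1L; stack[sp] <- u
      }
    }
  }
  if (np != nn) stop("tree is not connected")
  children <- vector("list", nn)
  for (v in pre[-1]) children[[parent[v]]] <- c(children[[parent[v]]], v)
  list(pre = pre[seq_len(np)], post = rev(pre[seq_len(np)]),
       parent = parent, children = children, root = root)
}

ut_is_binary <- function(ut) {
  if (ut$ntip < 3L) return(TRUE)
  deg <- tabulate(c(ut_index(ut$edge[, 1], ut$ntip), ut_index(ut$edge[, 2], ut$ntip)),
                  nbins = ut_nnode(ut))
  all(deg[seq_len(ut$ntip)] == 1L) && all(deg[-seq_len(ut$ntip)] == 3L)
}

# --- splits -------------------------------------------------------------

# Non-trivial splits as canonical keys: membership over tips taken in sorted
# label order, flipped so the first sorted label reads "0". Returns a
# character vector (possibly empty) with attribute "sides" (list of logical
# membership vectors in sorted label order).
ut_splits <- function(ut, keep_sides = FALSE) {
  n <- ut$ntip
  if (n < 4L || nrow(ut$edge) == 0L) {
    out <- character(0)
    if (keep_sides) attr(out, "sides") <- list()
    return(out)
  }
  tr <- ut_traverse(ut, root = 1L)
  nn <- ut_nnode(ut)
  below <- matrix(FALSE, nn, n)  # tip membership of the subtree below node
  for (v in tr$post) {
    if (v <= n) below[v, v] <- TRUE
    for (u in tr$children[[v]]) below[v, ] <- below[v, ] | below[u, ]
  }
  perm <- order(norm_label(ut$labels))
  internal_edge <- ut$edge[, 1] < 0L & ut$edge[, 2] < 0L
  keys <- character(0); sides <- list()
  for (k in which(internal_edge)) {
    a <- ut_index(ut$edge[k, 1], n); b <- ut_index(ut$edge[k, 2], n)
    child <- if (tr$parent[a] == b) a else b
    side <- below[child, perm]
    if (side[1]) side <- !side
    sz <- sum(side)
    if (sz < 2L || sz > n - 2L) next  # trivial
    keys <- c(keys, paste(as.integer(side), collapse = ""))
    if (keep_sides) sides[[length(keys)]] <- side
  }
  if (keep_sides) attr(keys, "sides") <- sides
  keys
}

# topology identity = sorted non-trivial split set over the sorted label set
ut_topokey <- function(ut) {
  paste(c(paste(sort(norm_label(ut$labels)), collapse = ","),
          sort(ut_splits(ut))), collapse = "|")
}

# --- surgery ------------------------------------------------------------

# subdivide edge k with a fresh internal node and attach a new tip
ut_attach <- function(ut, k, label) {
  w <- -(ut$nint + 1L)
  tip <- ut$ntip + 1L
  e <- ut$edge
  u <- e[k, 1]; v <- e[k, 2]
  e[k, ] <- c(u, w)
  e <- rbind(e, c(w, v), c(w, tip))
  list(ntip = tip, nint = ut$nint + 1L, edge = e, labels = c(ut$labels, label))
}

# drop tips by label, suppressing degree-2 internal nodes
ut_prune <- function(ut, drop) {
  di <- match_label(ut$labels, drop)
  keep <- setdiff(seq_len(ut$ntip), di)
  if (length(keep) < 2L) stop("pruning would leave fewer than 2 taxa")
  e <- ut$edge
  # iteratively delete dropped tips and resulting degree-1 internals
  gone <- di
  repeat {
    drop_rows <- e[, 1] %in% gone | e[, 2] %in% gone
    e <- e[!drop_rows, , drop = FALSE]
    ids <- c(e[, 1], e[, 2])
    deg <- table(ids)
    dead <- as.integer(names(deg)[deg == 1L])
    dead <- dead[dead < 0L]
    if (length(dead) == 0L) break
    gone <- dead
  }
  # contract degree-2 internals
  repeat {
    ids <- c(e[, 1], e[, 2])
    deg <- table(ids)
    two <- as.integer(names(deg)[deg == 2L])
    two <- two[two < 0L]
    if (length(two) == 0L) break
    v <- two[1]
    rows <- which(e[, 1] == v | e[, 2] == v)
    nb <- c(e[rows, 1], e[rows, 2])
    nb <- nb[nb != v]
    e <- e[-rows, , drop = FALSE]
    e <- rbind(e, nb)
  }
  # renumber tips to 1..length(keep) preserving label order
  new_tip <- integer(ut$ntip)
  new_tip[keep] <- seq_along(keep)
  e[e > 0L] <- new_tip[e[e > 0L]]
  ut_new(e, ut$labels[keep])
}

# contract the internal edges listed in `rows` (indices into ut$edge)
ut_contract <- function(ut, rows) {
  if (length(rows) == 0L) return(ut)
  e <- ut$edge
  # union-find over internal ids
  reps <- new.env(parent = emptyenv())
  find <- function(x) {
    key <- as.character(x)
    r <- reps[[key]]
    if (is.null(r) || r == x) x else {
      top <- find(r)
      assign(key, top, envir = reps)
      top
    }
  }
  for (k in rows) {
    a <- find(e[k, 1]); b <- find(e[k, 2])
    stopifnot(a < 0L, b < 0L)
    if (a != b) assign(as.character(b), a, envir = reps)
  }
  relabel <- function(col) vapply(col, function(x) if (x < 0L) find(x) else x, integer(1))
  e[, 1] <- relabel(e[, 1]); e[, 2] <- relabel(e[, 2])
  e <- e[-rows, , drop = FALSE]
  ut_new(e, ut$labels)
}

# permute tip ids so that the label vector equals `labels` (needed before
# trees from different replicates share one label->matrix-row mapping)
ut_relabel <- function(ut, labels) {
  if (identical(ut$labels, labels)) return(ut)
  perm <- match(norm_label(ut$labels), norm_label(labels))
  stopifnot(!anyNA(perm))
  e <- ut$edge
  tips <- e > 0L
  e[tips] <- perm[e[tips]]
  list(ntip = ut$ntip, nint = ut$nint, edge = e, labels = labels)
}

# --- random and enumerated topologies -----------------------------------

# Uniform random unrooted binary topology: sequential attachment to an edge
# chosen uniformly at random (every topology arises from exactly one choice
# sequence, so the distribution is uniform over the (2n-5)!! topologies).
ut_random <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  ut <- ut_new(rbind(c(1L, -1L), c(2L, -1L), c(3L, -1L)), labels[1:3])
  for (i in seq_len(n - 3L) + 3L) {
    k <- sample.int(nrow(ut$edge), 1L)
    ut <- ut_attach(ut, k, labels[i])
  }
  ut$labels <- labels
  ut
}

# All unrooted binary topologies over the labels (recursive edge insertion).
# (2n-5)!! trees: 3 -> 1, 4 -> 3, 5 -> 15, 6 -> 105, 7 -> 945, 8 -> 10395.
ut_enumerate <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  if (n > 9L) stop("refusing to enumerate topologies for more than 9 taxa (",
                   n, " requested)")
  acc <- list()
  grow <- function(ut, i) {
    if (i > n) {
      acc[[length(acc) + 1L]] <<- ut
      return(invisible())
    }
    for (k in seq_len(nrow(ut$edge))) grow(ut_attach(ut, k, labels[i]), i + 1L)
  }
  grow(ut_new(rbind(c(1L, -1L), c(2L, -1L), c(3L, -1L)), labels[1:3]), 4L)
  acc
}

# --- Newick / phylo conversion ------------------------------------------

nwk_quote <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.|-]", x), paste0("'", gsub("'", "''", x), "'"), x)
}

ut_to_newick <- function(ut) {
  n <- ut$ntip
  if (n == 1L) return(paste0(nwk_quote(ut$labels), ";"))
  if (n == 2L) return(sprintf("(%s,%s);", nwk_quote(ut$labels[1]), nwk_quote(ut$labels[2])))
  adj <- ut_adj(ut)
  root <- adj[[1L]][1]  # internal node adjacent to tip 1
  tr <- ut_traverse(ut, root = root, adj = adj)
  lab <- nwk_quote(ut$labels)
  build <- function(v) {
    if (v <= n) return(lab[v])
    paste0("(", paste(vapply(tr$children[[v]], build, character(1)), collapse = ","), ")")
  }
  paste0(build(root), ";")
}

ut_to_phylo <- function(ut) {
  ape::read.tree(text = ut_to_newick(ut))
}

phylo_to_ut <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected an ape 'phylo' tree")
  phy <- ape::collapse.singles(phy)
  if (ape::is.rooted(phy) && phy$Nnode > 1L) phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  e <- phy$edge
  conv <- function(x) ifelse(x <= n, x, -(x - n))
  ut_new(cbind(conv(e[, 1]), conv(e[, 2])), phy$tip.label)
}

as_ut <- function(tree) {
  if (inherits(tree, "phylo")) phylo_to_ut(tree)
  else if (is.list(tree) && !is.null(tree$edge) && !is.null(tree$ntip)) tree
  else stop("expected an ape 'phylo' tree")
}

#' Number of resolved (internal) nodes of an unrooted tree
#'
#' Counts the non-trivial bipartitions, i.e. the internal edges; a fully
#' resolved unrooted binary tree over n tips has n - 3.
#' @param tree An ape `phylo` tree (unrooted; polytomies allowed).
#' @return Integer count.
#' @export
n_resolved <- function(tree) {
  length(ut_splits(as_ut(tree)))
}
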