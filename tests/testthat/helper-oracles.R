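# Independent oracles and fixture generators, kept deliberately naive.

# Brute-force parsimony score of one character: enumerate every assignment
# of states to internal nodes AND every resolution of ambiguous leaves,
# summing per-edge costs directly. Exponential; use only for <= 6 tips.
brute_char_steps <- function(tree, cm, char) {
  ut <- mpsearch:::as_ut(tree)
  prep <- mpsearch:::mp_prep(cm)
  rows <- mpsearch:::prep_rows(ut, prep)
  s <- prep$smax[char] + 1L
  ordered <- prep$ordered[char]
  nn <- mpsearch:::ut_nnode(ut)
  ntip <- ut$ntip
  internals <- setdiff(seq_len(nn), seq_len(ntip))
  allowed <- lapply(seq_len(ntip), function(i) {
    if (ordered) prep$lo[rows[i], char]:prep$hi[rows[i], char]
    else mpsearch:::states_of(prep$mask[rows[i], char])
  })
  cost <- function(x, y) if (ordered) abs(x - y) else as.integer(x != y)
  grid <- as.matrix(do.call(expand.grid, rep(list(0:(s - 1L)), length(internals))))
  leafgrid <- as.matrix(do.call(expand.grid, allowed))
  ia <- mpsearch:::ut_index(ut$edge[, 1], ntip)
  ib <- mpsearch:::ut_index(ut$edge[, 2], ntip)
  best <- Inf
  st <- integer(nn)
  for (g in seq_len(nrow(grid))) {
    st[internals] <- grid[g, ]
    for (lg in seq_len(nrow(leafgrid))) {
      st[seq_len(ntip)] <- leafgrid[lg, ]
      tot <- sum(mapply(function(a, b) cost(st[a], st[b]), ia, ib))
      if (tot < best) best <- tot
    }
  }
  as.integer(best)
}

# random test matrix with missing, polymorphic and mixed ordered characters
rand_cm <- function(n, m, smax = 3, p_missing = 0.15, p_poly = 0.1, p_ord = 0.4,
                    labels = paste0("x", seq_len(n))) {
  cells <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      r <- stats::runif(1)
      cells[i, j] <- if (r < p_missing) 0L
      else if (r < p_missing + p_poly) mpsearch:::mask_of(sample(0:smax, 2))
      else mpsearch:::mask_of(sample(0:smax, 1))
    }
  }
  mpsearch:::new_char_matrix(cells, labels, stats::runif(m) < p_ord)
}

rand_ut <- function(labels) mpsearch:::ut_random(labels)

topo_key <- function(tree) mpsearch:::ut_topokey(mpsearch:::as_ut(tree))

treeset_keys <- function(ts) sort(vapply(ts$trees, mpsearch:::ut_topokey, character(1)))

# TBR-distance-1 oracle: T2 is one TBR rearrangement from T1 iff deleting
# one branch from each yields the same pair of leaf-labeled fragments.
# Fragments are compared by leaf set plus split set -- a characterization
# independent of the package's move enumerator.
tbr_reachable <- function(ut1, ut2) {
  k1 <- vapply(seq_len(nrow(ut1$edge)), function(k) bisection_key(ut1, k), character(1))
  k2 <- vapply(seq_len(nrow(ut2$edge)), function(k) bisection_key(ut2, k), character(1))
  length(intersect(k1, k2)) > 0L
}

bisection_key <- function(ut, k) {
  adj <- mpsearch:::ut_adj(ut)
  sides <- character(2)
  for (s in 1:2) {
    f <- mpsearch:::tbr_fragment(ut, k, ut$edge[k, s], adj)
    if (!is.null(f$node)) {
      sides[s] <- paste0("leaf:", ut$labels[f$node])
      next
    }
    tips <- sort(unique(f$edge[f$edge > 0L]))
    e <- f$edge
    e[f$edge > 0L] <- match(f$edge[f$edge > 0L], tips)
    u <- mpsearch:::ut_new(e, ut$labels[tips])
    sides[s] <- paste0(paste(sort(ut$labels[tips]), collapse = ","), "#",
                       mpsearch:::ut_topokey(u))
  }
  paste(sort(sides), collapse = " || ")
}

# exhaustive Bremer oracle: per consensus clade, min length over all
# topologies lacking it minus the best length
brute_bremer <- function(cm, keys) {
  all_trees <- mpsearch:::ut_enumerate(cm$labels)
  prep <- mpsearch:::mp_prep(cm)
  lens <- vapply(all_trees, mpsearch:::ut_length, numeric(1), prep = prep)
  best <- min(lens)
  vapply(keys, function(key) {
    lacking <- vapply(all_trees, function(u) !(key %in% mpsearch:::ut_splits(u)),
                      logical(1))
    as.integer(min(lens[lacking]) - best)
  }, integer(1))
}

cm_equal_public <- function(a, b) mpsearch:::cm_equal(a, b)

cm_empty_edits <- function() {
  data.frame(taxon = character(0), char = integer(0), new = integer(0))
}
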