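# Heuristic maximum-parsimony search: random-addition Wagner starting trees,
# TBR branch swapping holding a fixed number of trees per replicate, a final
# unbounded (capped) TBR round over the pooled buffer, rule-1 collapsing and
# topology deduplication. Tie-breaking everywhere is driven by the run RNG,
# so a seeded run is bit-reproducible.

#' Search configuration
#'
#' Defaults encode the traditional-search protocol used throughout
#' TNT-based morphological studies: 100 random-addition replicates, TBR
#' swapping holding 10 trees per replicate, rule-1 collapsing of zero-length
#' branches, plus a final TBR round over the pooled replicate buffer with the
#' hold limit lifted (up to `max_trees`).
#'
#' @param n_replicates Number of random-addition Wagner + TBR replicates.
#' @param hold Trees held per replicate during swapping.
#' @param max_trees Global tree-buffer cap for the final pooled round.
#' @param seed Integer seed recorded in all outputs; `NULL` leaves the RNG
#'   state untouched.
#' @param collapse Zero-length-branch collapse rule; only `"rule1"`
#'   (minimum branch length zero) is implemented.
#' @param final_round Run the pooled TBR round after the replicates.
#' @return A `search_config` list.
#' @export
search_config <- function(n_replicates = 100L, hold = 10L, max_trees = 10000L,
                          seed = NULL, collapse = "rule1", final_round = TRUE) {
  stopifnot(n_replicates >= 1L, hold >= 1L, max_trees >= 1L)
  collapse <- match.arg(collapse, "rule1")
  structure(list(n_replicates = as.integer(n_replicates), hold = as.integer(hold),
                 max_trees = as.integer(max_trees), seed = seed,
                 collapse = collapse, final_round = isTRUE(final_round)),
            class = "search_config")
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# --- Wagner stepwise addition -------------------------------------------

#' Build a Wagner starting tree by stepwise addition
#'
#' Starts from the unique unrooted tree on the first three taxa of
#' `addition_order` and inserts each remaining taxon on the branch that
#' minimizes the total length increase, breaking ties at random.
#'
#' @param cm A [char_matrix()].
#' @param addition_order Taxon labels or indices (default: matrix order).
#'   Randomize it for a random-addition-sequence replicate.
#' @param seed Optional seed for tie-breaking.
#' @return An ape `phylo` binary tree.
#' @export
wagner_addition <- function(cm, addition_order = NULL, seed = NULL) {
  with_local_seed(seed, {
    ord <- if (is.null(addition_order)) seq_len(n_taxa(cm))
    else if (is.character(addition_order)) match_label(cm$labels, addition_order)
    else as.integer(addition_order)
    stopifnot(length(ord) == n_taxa(cm), !anyDuplicated(ord))
    prep <- mp_prep(cm)
    ut_to_phylo(wagner_ut(prep, cm$labels, ord))
  })
}

wagner_ut <- function(prep, labels, ord) {
  n <- length(ord)
  if (n < 3L) stop("Wagner addition needs at least 3 taxa")
  ut <- ut_new(rbind(c(1L, -1L), c(2L, -1L), c(3L, -1L)), labels[ord[1:3]])
  rows <- prep_rows(ut, prep)
  for (i in seq_len(n - 3L) + 3L) {
    rows_i <- c(rows, match(norm_label(labels[ord[i]]), norm_label(prep$labels)))
    lens <- vapply(seq_len(nrow(ut$edge)), function(k) {
      ut_length(ut_attach(ut, k, labels[ord[i]]), prep, rows_i)
    }, numeric(1))
    best <- which(lens == min(lens))
    k <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    ut <- ut_attach(ut, k, labels[ord[i]])
    rows <- rows_i
  }
  ut
}

# --- TBR ----------------------------------------------------------------

# All TBR reconnections of an unrooted binary tree: cut each edge; suppress
# the cut endpoints; reattach every edge (or the sole node) of one fragment
# to every edge of the other. The reconnection reproducing the original tree
# is skipped. Returns a list of ut trees (with duplicate topologies, as
# produced by the enumeration).
tbr_moves_ut <- function(ut) {
  out <- vector("list", 0L)
  n <- ut$ntip
  e <- ut$edge
  adj <- ut_adj(ut)
  for (k in seq_len(nrow(e))) {
    u <- e[k, 1]; v <- e[k, 2]
    f1 <- tbr_fragment(ut, k, u, adj)
    f2 <- tbr_fragment(ut, k, v, adj)
    for (a in seq_len(max(1L, nrow(f1$edge)))) {
      for (b in seq_len(max(1L, nrow(f2$edge)))) {
        if (a == f1$orig && b == f2$orig) next
        out[[length(out) + 1L]] <- tbr_join(ut, f1, f2, a, b)
      }
    }
  }
  out
}

# fragment on `side`'s side after deleting edge k; suppresses the cut
# endpoint and remembers which (possibly merged) edge restores the original
tbr_fragment <- function(ut, k, side, adj) {
  n <- ut$ntip
  # collect nodes of the component by DFS avoiding edge k
  seen <- logical(ut_nnode(ut))
  stack <- ut_index(side, n); seen[stack] <- TRUE
  nodes <- integer(0)
  banned <- c(ut_index(ut$edge[k, 1], n), ut_index(ut$edge[k, 2], n))
  while (length(stack) > 0L) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    nodes <- c(nodes, x)
    for (y in adj[[x]]) {
      if (!seen[y] && !(x %in% banned && y %in% banned)) {
        seen[y] <- TRUE; stack <- c(stack, y)
      }
    }
  }
  id_of <- function(idx) ifelse(idx <= n, idx, -(idx - n))
  node_ids <- id_of(nodes)
  if (length(nodes) == 1L) {
    return(list(edge = matrix(integer(0), 0L, 2L), node = side, orig = 1L))
  }
  rows <- which((ut$edge[, 1] %in% node_ids) & (ut$edge[, 2] %in% node_ids))
  e <- ut$edge[rows, , drop = FALSE]
  orig <- NA_integer_
  if (side < 0L) {
    # cut endpoint now has degree 2: contract it into a single merged edge
    at <- which(e[, 1] == side | e[, 2] == side)
    nb <- c(e[at, 1], e[at, 2]); nb <- nb[nb != side]
    if (length(at) == 2L) {
      e <- e[-at, , drop = FALSE]
      e <- rbind(e, nb)
      orig <- nrow(e)
    } else {
      # degenerate: fragment is a single edge pair? keep as is
      orig <- at[1]
    }
  } else {
    orig <- 1L
  }
  list(edge = e, node = NULL, orig = orig)
}

# join two fragments: subdivide chosen edges with the freed internal ids
tbr_join <- function(ut, f1, f2, a, b) {
  freed <- setdiff(-seq_len(ut$nint + 2L),
                   c(f1$edge[f1$edge < 0L], f2$edge[f2$edge < 0L]))
  build_side <- function(f, pick, w) {
    if (is.null(f$node)) {
      e <- f$edge
      x <- e[pick, 1]; y <- e[pick, 2]
      e[pick, ] <- c(x, w)
      rbind(e, c(w, y))
    } else {
      NULL
    }
  }
  if (is.null(f1$node) && is.null(f2$node)) {
    w1 <- freed[1]; w2 <- freed[2]
    e <- rbind(build_side(f1, a, w1), build_side(f2, b, w2), c(w1, w2))
  } else if (is.null(f2$node)) {
    w2 <- freed[1]
    e <- rbind(build_side(f2, b, w2), c(f1$node, w2))
  } else if (is.null(f1$node)) {
    w1 <- freed[1]
    e <- rbind(build_side(f1, a, w1), c(f2$node, w1))
  } else {
    stop("cannot TBR a two-taxon tree")
  }
  ut_new(e, ut$labels)
}

#' Distinct TBR neighbors of a binary tree
#'
#' Enumerates all tree-bisection-reconnection rearrangements and returns the
#' distinct neighbor topologies (the original topology is excluded). On a
#' 4-leaf tree this is the NNI neighborhood: the other two topologies.
#'
#' @param tree An ape `phylo` unrooted binary tree.
#' @return A list of `phylo` trees.
#' @export
tbr_neighbors <- function(tree) {
  ut <- as_ut(tree)
  if (!ut_is_binary(ut)) stop("TBR swapping requires a binary tree")
  self <- ut_topokey(ut)
  seen <- new.env(parent = emptyenv())
  assign(self, TRUE, envir = seen)
  out <- list()
  for (nb in tbr_moves_ut(ut)) {
    key <- ut_topokey(nb)
    if (is.null(seen[[key]])) {
      assign(key, TRUE, envir = seen)
      out[[length(out) + 1L]] <- ut_to_phylo(nb)
    }
  }
  out
}

#' One round of TBR swapping against an incumbent length
#'
#' Enumerates the TBR neighborhood of `tree` and returns the accepted
#' neighbors: all strictly better trees and, up to `hold`, distinct
#' equal-length trees. This is the acceptance rule used inside
#' [heuristic_search()] replicates.
#'
#' @param tree An ape `phylo` binary tree.
#' @param cm A [char_matrix()].
#' @param incumbent_length Current best length; defaults to the length of
#'   `tree`.
#' @param hold Cap on accepted equal-length trees.
#' @return List with `improved` (logical), `length` (best length seen) and
#'   `trees` (list of accepted `phylo` trees).
#' @export
tbr_swap <- function(tree, cm, incumbent_length = NULL, hold = 10L) {
  ut <- as_ut(tree)
  prep <- mp_prep(cm)
  incumbent <- incumbent_length %||% ut_length(ut, prep)
  best <- incumbent
  equal <- list(); keys <- character(0)
  better <- NULL
  for (nb in tbr_moves_ut(ut)) {
    l <- ut_length(nb, prep)
    if (l < best) { best <- l; better <- nb }
    else if (l == incumbent && is.null(better) && length(equal) < hold) {
      key <- ut_topokey(nb)
      if (!key %in% keys) { keys <- c(keys, key); equal[[length(equal) + 1L]] <- nb }
    }
  }
  if (!is.null(better)) {
    list(improved = TRUE, length = best, trees = list(ut_to_phylo(better)))
  } else {
    list(improved = FALSE, length = best, trees = lapply(equal, ut_to_phylo))
  }
}

# swap a starting tree to a local optimum, keeping up to `hold` equal-length
# trees; strictly better neighbors restart the sweep immediately
swap_to_optimum <- function(start, prep, hold, max_trees = hold) {
  rows <- prep_rows(start, prep)  # TBR surgery never reorders labels
  best <- ut_length(start, prep, rows)
  S <- list(start)
  keys <- ut_topokey(start)
  i <- 1L
  while (i <= length(S)) {
    restart <- FALSE
    for (nb in tbr_moves_ut(S[[i]])) {
      l <- ut_length(nb, prep, rows)
      if (l < best) {
        best <- l
        S <- list(nb)
        keys <- ut_topokey(nb)
        i <- 1L
        restart <- TRUE
        break
      }
      if (l == best && length(S) < min(hold, max_trees)) {
        key <- ut_topokey(nb)
        if (!key %in% keys) {
          keys <- c(keys, key)
          S[[length(S) + 1L]] <- nb
        }
      }
    }
    if (!restart) i <- i + 1L
  }
  list(length = best, trees = S, keys = keys)
}

# --- rule-1 collapsing ---------------------------------------------------

# One zero-minimum edge is contracted at a time and the minimum branch
# lengths are recomputed: contracting several jointly can raise the length
# when no single reconstruction puts zero changes on all of them at once,
# whereas sequential re-evaluated contraction provably preserves it.
ut_collapse_rule1 <- function(ut, prep) {
  repeat {
    ml <- ut_branch_minlens(ut, prep)
    zero <- which(!is.na(ml) & ml == 0L)
    if (length(zero) == 0L) return(ut)
    ut <- ut_contract(ut, zero[1])
  }
}

#' Collapse zero-minimum-length branches (rule 1)
#'
#' Deletes every internal branch whose minimum length over all
#' most-parsimonious reconstructions is zero, producing polytomies where
#' support is absent. The total tree length is unchanged. Collapsing is
#' idempotent: the pass is iterated until no zero-minimum branch remains.
#'
#' @param tree An ape `phylo` tree.
#' @param cm A [char_matrix()].
#' @return A `phylo` tree, possibly multifurcating.
#' @export
collapse_zero_length <- function(tree, cm) {
  ut <- as_ut(tree)
  ut_to_phylo(ut_collapse_rule1(ut, mp_prep(cm)))
}

# --- tree sets -----------------------------------------------------------

new_treeset <- function(trees, length, labels, config = NULL, extra = list()) {
  structure(c(list(trees = trees, length = as.integer(length),
                   labels = labels, config = config), extra),
            class = "mp_treeset")
}

#' @export
print.mp_treeset <- function(x, ...) {
  cat(sprintf("mp_treeset: %d most parsimonious tree(s) of length %d over %d taxa\n",
              length(x$trees), x$length, length(x$labels)))
  if (!is.null(x$config$seed)) cat("  seed:", x$config$seed, "\n")
  if (!is.null(x$replicate_lengths)) {
    cat(sprintf("  replicates: %d (best length hit by %d)\n",
                length(x$replicate_lengths), sum(x$replicate_lengths == x$length)))
  }
  invisible(x)
}

#' Extract the trees of a tree set
#' @param ts An `mp_treeset`.
#' @return An ape `multiPhylo` object.
#' @export
treeset_trees <- function(ts) {
  out <- lapply(ts$trees, ut_to_phylo)
  class(out) <- "multiPhylo"
  out
}

#' Number of trees in a tree set
#' @param ts An `mp_treeset`.
#' @export
n_trees <- function(ts) length(ts$trees)

# --- heuristic and exhaustive search ------------------------------------

#' Heuristic search for most-parsimonious trees
#'
#' Runs `n_replicates` independent random-addition Wagner + TBR replicates
#' (each holding up to `hold` equal-length trees), pools the replicate
#' results at the overall best length, optionally performs a final TBR round
#' over the pooled buffer with the hold limit lifted (up to `max_trees`),
#' collapses every tree by rule 1 and deduplicates topologies.
#'
#' @param cm A [char_matrix()].
#' @param config A [search_config()].
#' @return An `mp_treeset` with fields `trees`, `length`, `labels`,
#'   `config`, `replicate_lengths`, and `complete` (FALSE when the tree
#'   buffer overflowed).
#' @export
heuristic_search <- function(cm, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  prep <- mp_prep(cm)
  with_local_seed(config$seed, {
    best <- Inf
    pool <- list(); pool_keys <- character(0)
    rep_lengths <- integer(config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      ord <- sample.int(n_taxa(cm))
      start <- wagner_ut(prep, cm$labels, ord)
      res <- swap_to_optimum(start, prep, config$hold, config$max_trees)
      rep_lengths[r] <- res$length
      canon <- lapply(res$trees, ut_relabel, labels = cm$labels)
      if (res$length < best) {
        best <- res$length
        pool <- canon
        pool_keys <- res$keys
      } else if (res$length == best) {
        fresh <- !res$keys %in% pool_keys
        pool <- c(pool, canon[fresh])
        pool_keys <- c(pool_keys, res$keys[fresh])
      }
    }
    complete <- TRUE
    if (config$final_round) {
      final <- swap_pool(pool, pool_keys, best, prep, config$max_trees)
      best <- final$length
      pool <- final$trees
      complete <- final$complete
    }
    # rule-1 collapse, then deduplicate collapsed topologies
    collapsed <- lapply(pool, ut_collapse_rule1, prep = prep)
    keys <- vapply(collapsed, ut_topokey, character(1))
    keep <- !duplicated(keys)
    if (!complete) {
      warning("tree buffer overflowed (max_trees = ", config$max_trees,
              "): result flagged incomplete", call. = FALSE)
    }
    new_treeset(collapsed[keep], best, cm$labels, config,
                list(replicate_lengths = rep_lengths, complete = complete))
  })
}

# final pooled TBR round: swap every pooled tree, hold limit lifted
swap_pool <- function(pool, keys, best, prep, max_trees) {
  S <- pool; K <- keys
  rows <- prep_rows(S[[1]], prep)
  i <- 1L
  complete <- TRUE
  while (i <= length(S)) {
    restart <- FALSE
    for (nb in tbr_moves_ut(S[[i]])) {
      l <- ut_length(nb, prep, rows)
      if (l < best) {
        best <- l
        S <- list(nb); K <- ut_topokey(nb)
        i <- 1L; restart <- TRUE
        break
      }
      if (l == best) {
        if (length(S) >= max_trees) { complete <- FALSE; next }
        key <- ut_topokey(nb)
        if (!key %in% K) {
          K <- c(K, key)
          S[[length(S) + 1L]] <- nb
        }
      }
    }
    if (!restart) i <- i + 1L
  }
  list(length = best, trees = S, keys = K, complete = complete)
}

#' Exhaustive search over all unrooted binary topologies
#'
#' Enumerates all (2n-5)!! topologies (n <= 9) and returns every topology
#' attaining the minimum length, collapsed by rule 1 and deduplicated — the
#' exact optimum set used as the oracle for the heuristic search.
#'
#' @param cm A [char_matrix()] with at most 9 taxa.
#' @param collapse Apply rule-1 collapsing to the optimum set (default TRUE).
#' @return An `mp_treeset`. The attribute `"n_evaluated"` records how many
#'   topologies were scored.
#' @export
exhaustive_search <- function(cm, collapse = TRUE) {
  if (n_taxa(cm) > 9L) {
    stop("exhaustive search supports at most 9 taxa (", n_taxa(cm), " given); ",
         "use heuristic_search()")
  }
  prep <- mp_prep(cm)
  all_trees <- ut_enumerate(cm$labels)
  lens <- vapply(all_trees, ut_length, numeric(1), prep = prep)
  best <- min(lens)
  opt <- all_trees[lens == best]
  if (collapse) opt <- lapply(opt, ut_collapse_rule1, prep = prep)
  keys <- vapply(opt, ut_topokey, character(1))
  out <- new_treeset(opt[!duplicated(keys)], best, cm$labels, NULL,
                     list(complete = TRUE))
  attr(out, "n_evaluated") <- length(all_trees)
  out
}
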