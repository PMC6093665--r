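# Post-search pipeline: strict (Nelsen) consensus, Bremer supports from
# suboptimal tree pools, positional-instability (wildcard) detection and
# reduced consensus after pruning.

# build a ut from a set of pairwise-compatible non-trivial splits
ut_from_splits <- function(sides, labels) {
  n <- length(labels)
  perm <- order(norm_label(labels))           # sides are in sorted-label order
  anchor <- perm[1]                           # tip that reads "0" in every key
  clusters <- lapply(sides, function(s) perm[s])  # tip indices, anchor excluded
  ord <- order(-lengths(clusters))
  clusters <- clusters[ord]
  k <- length(clusters)
  # parent of each cluster: smallest strictly containing cluster, else root
  cl_parent <- rep(0L, k)                     # 0 = root internal node
  if (k > 1L) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (j == i) next
        if (length(clusters[[j]]) > length(clusters[[i]]) &&
            all(clusters[[i]] %in% clusters[[j]])) {
          if (cl_parent[i] == 0L ||
              length(clusters[[j]]) < length(clusters[[cl_parent[i]]])) {
            cl_parent[i] <- j
          }
        }
      }
    }
  }
  # internal node ids: root = -1, cluster i = -(i+1)
  edges <- matrix(integer(0), 0L, 2L)
  node_of <- function(ci) if (ci == 0L) -1L else -(ci + 1L)
  for (i in seq_len(k)) edges <- rbind(edges, c(node_of(cl_parent[i]), node_of(i)))
  for (t in seq_len(n)) {
    if (t == anchor) { edges <- rbind(edges, c(-1L, t)); next }
    containing <- which(vapply(clusters, function(cl) t %in% cl, logical(1)))
    p <- if (length(containing) == 0L) 0L
    else containing[which.min(lengths(clusters)[containing])]
    edges <- rbind(edges, c(node_of(p), t))
  }
  ut_new(edges, labels)
}

#' Strict (Nelsen) consensus of a set of trees
#'
#' The consensus contains exactly the non-trivial bipartitions common to all
#' input trees.
#'
#' @param trees An `mp_treeset`, an ape `multiPhylo`, or a list of `phylo`
#'   trees over identical leaf sets.
#' @return An ape `phylo` tree (with polytomies where the inputs disagree).
#' @export
strict_consensus <- function(trees) {
  uts <- as_ut_list(trees)
  if (length(uts) == 0L) stop("no trees given")
  labs <- uts[[1]]$labels
  for (u in uts[-1]) {
    if (!setequal(norm_label(labs), norm_label(u$labels))) {
      stop("trees have mismatched leaf sets")
    }
  }
  sp <- ut_splits(uts[[1]], keep_sides = TRUE)
  common <- as.character(sp)
  sides <- attr(sp, "sides")
  names(sides) <- common
  for (u in uts[-1]) {
    common <- intersect(common, ut_splits(u))
    if (length(common) == 0L) break
  }
  ut_to_phylo(ut_from_splits(sides[common], labs))
}

as_ut_list <- function(trees) {
  if (inherits(trees, "mp_treeset")) trees$trees
  else if (inherits(trees, "phylo")) list(as_ut(trees))
  else lapply(trees, as_ut)
}

# --- Bremer supports -----------------------------------------------------

#' Bremer (decay) supports for the clades of the strict consensus
#'
#' Grows pools of suboptimal trees by TBR swapping from the MPT set,
#' retaining every distinct topology within `k_max` extra steps of the best
#' length. A clade's Bremer value is the smallest k such that some tree of
#' length best + k lacks the clade; clades that survive the whole pool are
#' reported as `NA` (i.e. > `k_max`).
#'
#' @param cm A [char_matrix()].
#' @param treeset The MPT set for `cm` (an `mp_treeset`); an error is raised
#'   if its stored length does not match its trees' lengths on `cm`.
#' @param k_max Maximum extra steps explored (default 6).
#' @param max_trees Cap on the suboptimal pool size.
#' @return A `support_report` data frame with one row per consensus clade:
#'   the clade's smaller side (label list) and its Bremer value.
#' @export
bremer_supports <- function(cm, treeset, k_max = 6L, max_trees = 20000L) {
  stopifnot(inherits(treeset, "mp_treeset"))
  prep <- mp_prep(cm)
  lens <- vapply(treeset$trees, ut_length, numeric(1), prep = prep)
  if (any(lens != treeset$length)) {
    stop("treeset is not an optimal set for this matrix: stored length ",
         treeset$length, ", observed ", paste(unique(lens), collapse = "/"))
  }
  best <- treeset$length
  cons <- as_ut(strict_consensus(treeset))
  sp <- ut_splits(cons, keep_sides = TRUE)
  keys <- as.character(sp)
  if (length(keys) == 0L) {
    return(empty_support_report())
  }

  pool <- suboptimal_pool(treeset, prep, k_max, max_trees)
  bremer <- rep(NA_integer_, length(keys))
  for (i in seq_along(pool$trees)) {
    excess <- pool$lengths[i] - best
    if (excess == 0L) next
    absent <- !(keys %in% ut_splits_any(pool$trees[[i]]))
    upd <- absent & (is.na(bremer) | bremer > excess)
    bremer[upd] <- excess
  }
  labs <- sort(norm_label(cons$labels))
  disp <- cons$labels[order(norm_label(cons$labels))]
  clade <- vapply(attr(sp, "sides"), function(side) {
    small <- if (sum(side) <= sum(!side)) side else !side
    paste(disp[small], collapse = ", ")
  }, character(1))
  structure(data.frame(clade = clade, split = keys, bremer = bremer,
                       stringsAsFactors = FALSE),
            class = c("support_report", "data.frame"),
            best_length = best, k_max = k_max,
            pool_size = length(pool$trees), saturated = pool$complete)
}

empty_support_report <- function() {
  structure(data.frame(clade = character(0), split = character(0),
                       bremer = integer(0), stringsAsFactors = FALSE),
            class = c("support_report", "data.frame"))
}

# splits including on collapsed (possibly polytomous) trees
ut_splits_any <- function(ut) ut_splits(ut)

# breadth-first TBR closure over all distinct topologies within best + k_max
suboptimal_pool <- function(treeset, prep, k_max, max_trees) {
  best <- treeset$length
  bound <- best + k_max
  # start from binary resolutions: the stored MPTs may be collapsed and TBR
  # needs binary trees; a resolution may score worse than best, which is
  # harmless — every pool tree carries its own length
  frontier <- lapply(treeset$trees, function(u) {
    ut_relabel(ut_resolve_binary(u), treeset$labels)
  })
  rows <- prep_rows(frontier[[1]], prep)
  seen <- new.env(parent = emptyenv())
  trees <- list(); lengths <- integer(0)
  push <- function(u, l) {
    trees[[length(trees) + 1L]] <<- u
    lengths[length(lengths) + 1L] <<- l
  }
  for (u in frontier) {
    key <- ut_topokey(u)
    if (is.null(seen[[key]])) { assign(key, TRUE, envir = seen); push(u, ut_length(u, prep, rows)) }
  }
  complete <- TRUE
  i <- 1L
  while (i <= length(trees)) {
    if (length(trees) >= max_trees) { complete <- FALSE; break }
    for (nb in tbr_moves_ut(trees[[i]])) {
      l <- ut_length(nb, prep, rows)
      if (l > bound) next
      key <- ut_topokey(nb)
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        push(nb, l)
        if (length(trees) >= max_trees) { complete <- FALSE; break }
      }
    }
    i <- i + 1L
  }
  list(trees = trees, lengths = lengths, complete = complete)
}

# arbitrary binary resolution of a (possibly polytomous) ut
ut_resolve_binary <- function(ut) {
  if (ut_is_binary(ut)) return(ut)
  e <- ut$edge
  nint <- ut$nint
  repeat {
    ids <- c(e[, 1], e[, 2])
    deg <- table(ids[ids < 0L])
    bad <- as.integer(names(deg)[deg > 3L])
    if (length(bad) == 0L) break
    v <- bad[1]
    rows <- which(e[, 1] == v | e[, 2] == v)
    # split off two of v's incidences onto a fresh internal node
    w <- -(nint + 1L); nint <- nint + 1L
    r2 <- rows[1:2]
    for (r in r2) {
      if (e[r, 1] == v) e[r, 1] <- w else e[r, 2] <- w
    }
    e <- rbind(e, c(v, w))
  }
  ut_new(e, ut$labels)
}

#' @export
print.support_report <- function(x, ...) {
  cat(sprintf("Bremer supports (best length %s, pool of %s trees%s):\n",
              attr(x, "best_length") %||% "?", attr(x, "pool_size") %||% "?",
              if (isTRUE(attr(x, "saturated"))) "" else ", pool capped"))
  if (nrow(x) == 0L) { cat("  (consensus has no resolved clades)\n"); return(invisible(x)) }
  for (i in seq_len(nrow(x))) {
    b <- if (is.na(x$bremer[i])) paste0(">", attr(x, "k_max")) else x$bremer[i]
    cat(sprintf("  %s  {%s}\n", format(b, width = 4), x$clade[i]))
  }
  invisible(x)
}

# --- positional instability (PCR-style wildcard detection) ---------------

# position of a taxon in one tree: the partition of the remaining leaves
# induced by its attachment node (for a binary attachment this is the
# bipartition of the merged edge; at a polytomy, the full partition)
taxon_position_key <- function(ut, tip_label) {
  t <- match_label(ut$labels, tip_label)
  adj <- ut_adj(ut)
  v_idx <- adj[[t]][1]
  # components of remaining leaves around the attachment node
  nn <- ut_nnode(ut)
  comp_leaves <- function(start) {
    seen <- logical(nn); seen[v_idx] <- TRUE; seen[t] <- TRUE
    stack <- start; seen[start] <- TRUE
    leaves <- character(0)
    while (length(stack) > 0L) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (x <= ut$ntip) leaves <- c(leaves, norm_label(ut$labels[x]))
      for (y in adj[[x]]) if (!seen[y]) { seen[y] <- TRUE; stack <- c(stack, y) }
    }
    paste(sort(leaves), collapse = ",")
  }
  parts <- sort(vapply(setdiff(adj[[v_idx]], t), comp_leaves, character(1)))
  paste(parts, collapse = " | ")
}

#' Positional instability of taxa across a set of MPTs
#'
#' For each taxon, counts the distinct attachment positions it occupies
#' across the tree set (two positions are equal when the trees restricted to
#' the remaining taxa place the attachment on the same edge), and measures
#' the consensus-resolution gain from pruning it: resolved nodes of the
#' reduced strict consensus (taxon pruned from every tree, then consensus)
#' minus resolved nodes of the full strict consensus with the taxon pruned.
#' Taxa are ranked by gain, then by position count. `greedy_prune()` iterates
#' this ranking, re-evaluating after each pruning.
#'
#' @param treeset An `mp_treeset` (or list of `phylo` trees).
#' @return An `instability_report` data frame with columns `taxon`,
#'   `n_positions` and `gain`, sorted by the ranking; the attribute
#'   `"ranking"` lists the unstable taxa (position count > 1) in rank order.
#' @export
positional_instability <- function(treeset) {
  uts <- as_ut_list(treeset)
  labs <- uts[[1]]$labels
  n_pos <- integer(length(labs)); gain <- integer(length(labs))
  if (length(uts) < 2L) {
    rep <- data.frame(taxon = labs, n_positions = rep(1L, length(labs)),
                      gain = rep(0L, length(labs)), stringsAsFactors = FALSE)
    return(structure(rep, class = c("instability_report", "data.frame"),
                     ranking = character(0)))
  }
  full_cons <- as_ut(strict_consensus(uts))
  for (i in seq_along(labs)) {
    keys <- vapply(uts, taxon_position_key, character(1), tip_label = labs[i])
    n_pos[i] <- length(unique(keys))
    reduced <- lapply(uts, ut_prune, drop = labs[i])
    rkeys <- vapply(reduced, ut_topokey, character(1))
    red_cons <- strict_consensus(reduced[!duplicated(rkeys)])
    proj_cons <- ut_prune(full_cons, labs[i])
    gain[i] <- n_resolved(red_cons) - length(ut_splits(proj_cons))
  }
  ord <- order(-gain, -n_pos, norm_label(labs))
  rep <- data.frame(taxon = labs, n_positions = n_pos, gain = gain,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(rep) <- NULL
  unstable <- rep$taxon[rep$n_positions > 1L]
  structure(rep, class = c("instability_report", "data.frame"),
            ranking = unstable)
}

#' @export
print.instability_report <- function(x, ...) {
  cat("positional instability (ranked by consensus-resolution gain):\n")
  print.data.frame(x)
  invisible(x)
}

#' Greedy iterated wildcard pruning
#'
#' Repeatedly prunes the taxon whose removal gains the most consensus
#' resolution (ties broken by position count, then label), re-evaluating the
#' instability report after each pruning, until no taxon yields a positive
#' gain.
#'
#' @param treeset An `mp_treeset`.
#' @param max_prune Safety cap on the number of pruned taxa.
#' @return Character vector of pruned taxa, in pruning order, with the final
#'   pruned `mp_treeset` as attribute `"treeset"`.
#' @export
greedy_prune <- function(treeset, max_prune = Inf) {
  pruned <- character(0)
  ts <- treeset
  while (length(pruned) < max_prune) {
    rep <- positional_instability(ts)
    cand <- rep[rep$gain > 0L & rep$n_positions > 1L, , drop = FALSE]
    if (nrow(cand) == 0L) break
    pick <- cand$taxon[1]
    ts <- prune_taxa(ts, pick)
    pruned <- c(pruned, pick)
  }
  attr(pruned, "treeset") <- ts
  pruned
}

# --- pruning -------------------------------------------------------------

#' Prune taxa from a matrix (a priori) or a tree set (a posteriori)
#'
#' A priori exclusion removes matrix rows — the search must then be re-run.
#' A posteriori pruning removes the leaves from every tree of an MPT set,
#' suppresses the resulting degree-2 nodes and deduplicates the topologies
#' (pruning is many-to-one, so the number of distinct trees never grows).
#'
#' @param x A [char_matrix()] or an `mp_treeset`.
#' @param taxa Labels to remove.
#' @param mode `"a_priori"` (matrix) or `"a_posteriori"` (tree set);
#'   defaults to the mode implied by the class of `x`.
#' @return An object of the same kind as `x`.
#' @export
prune_taxa <- function(x, taxa, mode = NULL) {
  if (length(taxa) == 0L) return(x)
  if (inherits(x, "char_matrix")) {
    if (!is.null(mode) && mode != "a_priori") {
      stop("a matrix can only be pruned a priori (rows removed, search re-run)")
    }
    cm_drop_taxa(x, taxa)
  } else if (inherits(x, "mp_treeset")) {
    if (!is.null(mode) && mode != "a_posteriori") {
      stop("a tree set can only be pruned a posteriori")
    }
    trees <- lapply(x$trees, ut_prune, drop = taxa)
    keys <- vapply(trees, ut_topokey, character(1))
    new_treeset(trees[!duplicated(keys)], x$length,
                x$labels[-match_label(x$labels, taxa)], x$config,
                list(complete = x$complete, pruned = c(x$pruned, taxa)))
  } else {
    stop("prune_taxa() expects a char_matrix or an mp_treeset")
  }
}
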