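# Synthetic morphological matrices with known generating trees.
#
# Characters evolve by placing a fixed number of state-change events on
# random branches of the generating tree (an event-count scheme rather than
# continuous-time Mk rates: it gives direct, testable control over the
# amount of homoplasy, which is the quantity parsimony inference responds
# to). Ordered characters step +/-1 along the state line (reflecting at the
# ends); unordered characters jump uniformly to another state. Missing and
# polymorphic masks are applied afterwards.

#' Simulation configuration
#'
#' The defaults emulate the structure of a fossil-grade aetosaur-style
#' matrix: 28 OTUs by 83 characters, a small fraction of ordered
#' (additive) characters (7/83), mostly binary characters with some 3- and
#' 4-state ones, around two change events per character (moderate
#' homoplasy), roughly 30% missing cells as typical for fossil taxa, and a
#' token rate of polymorphic cells.
#'
#' @param n_taxa,n_characters Matrix dimensions.
#' @param state_counts Possible per-character state counts.
#' @param state_probs Sampling weights for `state_counts`.
#' @param ordered_prob Probability that a character is additive.
#' @param events_per_char Change events placed per character (the homoplasy
#'   knob; 1 = homoplasy-free).
#' @param missing_frac Fraction of cells replaced by '?'.
#' @param poly_frac Fraction of cells made polymorphic (one extra state).
#' @param seed Optional seed recorded in the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 28L, n_characters = 83L,
                       state_counts = c(2L, 3L, 4L),
                       state_probs = c(0.7, 0.2, 0.1),
                       ordered_prob = 7 / 83,
                       events_per_char = 2L,
                       missing_frac = 0.3,
                       poly_frac = 0.02,
                       seed = NULL) {
  stopifnot(n_taxa >= 3L, n_characters >= 1L, events_per_char >= 0L,
            missing_frac >= 0, missing_frac <= 1,
            poly_frac >= 0, poly_frac <= 1,
            ordered_prob >= 0, ordered_prob <= 1,
            all(state_counts >= 2L), length(state_probs) == length(state_counts))
  structure(list(n_taxa = as.integer(n_taxa), n_characters = as.integer(n_characters),
                 state_counts = as.integer(state_counts), state_probs = state_probs,
                 ordered_prob = ordered_prob, events_per_char = as.integer(events_per_char),
                 missing_frac = missing_frac, poly_frac = poly_frac, seed = seed),
            class = "sim_config")
}

#' Simulate a uniform random unrooted binary topology
#'
#' Leaves are attached sequentially to a branch chosen uniformly at random;
#' every topology corresponds to exactly one choice sequence, so the
#' distribution is uniform over the (2n-5)!! unrooted binary topologies.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param labels Leaf labels (default `t1..tn`).
#' @param seed Optional seed.
#' @return An ape `phylo` tree.
#' @export
simulate_tree <- function(n_taxa, labels = NULL, seed = NULL) {
  stopifnot(n_taxa >= 3L)
  labels <- labels %||% paste0("t", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  with_local_seed(seed, ut_to_phylo(ut_random(labels)))
}

#' Simulate a character matrix on a generating tree
#'
#' @param tree Generating tree (ape `phylo`, treated as unrooted).
#' @param config A [sim_config()]; its `n_taxa` is ignored in favor of the
#'   tree's leaf count.
#' @param seed Optional seed (overrides `config$seed`).
#' @return A list of class `mp_simulation`: `matrix` (a [char_matrix()]),
#'   and `truth` with the generating tree, per-character event counts,
#'   state counts and ordered flags.
#' @export
simulate_matrix <- function(tree, config = sim_config(), seed = NULL) {
  ut <- as_ut(tree)
  seed <- seed %||% config$seed
  with_local_seed(seed, {
    n <- ut$ntip
    m <- config$n_characters
    tr <- ut_traverse(ut, root = 1L)
    nn <- ut_nnode(ut)
    ne <- nrow(ut$edge)
    n_states <- sample(config$state_counts, m, replace = TRUE, prob = config$state_probs)
    ordered <- stats::runif(m) < config$ordered_prob
    cells <- matrix(0L, n, m)
    events <- integer(m)
    for (j in seq_len(m)) {
      s <- n_states[j]
      # events on edges, identified by their child node in the traversal
      ev <- tabulate(sample.int(ne, config$events_per_char, replace = TRUE), nbins = ne)
      # map edge row -> child node index
      state <- integer(nn)
      root_state <- sample.int(s, 1L) - 1L
      state[tr$root] <- root_state
      child_of_edge <- integer(ne)
      for (k in seq_len(ne)) {
        a <- ut_index(ut$edge[k, 1], n); b <- ut_index(ut$edge[k, 2], n)
        child_of_edge[k] <- if (tr$parent[a] == b) a else b
      }
      pick <- function(v) v[sample.int(length(v), 1L)]
      for (v in tr$pre[-1]) {
        k <- which(child_of_edge == v)
        x <- state[tr$parent[v]]
        n_ev <- ev[k]
        if (n_ev > 0L) {
          for (dummy in seq_len(n_ev)) {
            x <- if (ordered[j]) {
              if (x == 0L) 1L
              else if (x == s - 1L) x - 1L
              else x + pick(c(-1L, 1L))
            } else {
              pick(setdiff(0:(s - 1L), x))
            }
          }
        }
        state[v] <- x
      }
      events[j] <- config$events_per_char
      cells[, j] <- bitwShiftL(1L, state[seq_len(n)])
    }
    # polymorphic mask: add one extra state to a known cell
    if (config$poly_frac > 0) {
      hit <- which(stats::runif(n * m) < config$poly_frac)
      for (ix in hit) {
        i <- ((ix - 1L) %% n) + 1L; j <- ((ix - 1L) %/% n) + 1L
        s <- n_states[j]
        cur <- states_of(cells[i, j])
        extra <- setdiff(0:(s - 1L), cur)
        if (length(extra) > 0L) {
          cells[i, j] <- bitwOr(cells[i, j], bitwShiftL(1L, extra[sample.int(length(extra), 1L)]))
        }
      }
    }
    if (config$missing_frac > 0) {
      cells[stats::runif(n * m) < config$missing_frac] <- 0L
    }
    cm <- new_char_matrix(cells, ut$labels, ordered)
    structure(list(matrix = cm,
                   truth = list(tree = ut_to_phylo(ut), events = events,
                                n_states = n_states, ordered = ordered,
                                seed = seed)),
              class = "mp_simulation")
  })
}

#' @export
print.mp_simulation <- function(x, ...) {
  cat("mp_simulation:\n")
  print(x$matrix)
  cat(sprintf("  truth: %d events/character on a %d-leaf generating tree\n",
              x$truth$events[1], length(x$truth$tree$tip.label)))
  invisible(x)
}
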