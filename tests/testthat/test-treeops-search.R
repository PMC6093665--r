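test_that("random topologies are valid, sized right, and roughly uniform", {
  expect_error(simulate_tree(2), "")
  t3 <- simulate_tree(3, seed = 1)
  expect_identical(sort(t3$tip.label), c("t1", "t2", "t3"))
  expect_identical(length(simulate_tree(9, seed = 2)$tip.label), 9L)
  # n=4: three topologies, uniform over many draws
  counts <- table(vapply(1:300, function(i) topo_key(simulate_tree(4, seed = i)),
                         character(1)))
  expect_identical(length(counts), 3L)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("topology enumeration hits the double-factorial counts", {
  expect_identical(length(mpsearch:::ut_enumerate(paste0("a", 1:4))), 3L)
  expect_identical(length(mpsearch:::ut_enumerate(paste0("a", 1:6))), 105L)
  cm <- rand_cm(4, 2)
  expect_identical(attr(exhaustive_search(cm), "n_evaluated"), 3L)
  big <- rand_cm(10, 2)
  expect_error(exhaustive_search(big), "at most 9 taxa")
})

test_that("Wagner addition is exact on 3 taxa and free for duplicate rows", {
  cm <- char_matrix(c(A = "01", B = "10", C = "11"))
  w <- wagner_addition(cm)
  expect_identical(topo_key(w), topo_key(ape::read.tree(text = "(A,B,C);")))
  # a taxon duplicating an existing row never adds length
  set.seed(301)
  base <- rand_cm(5, 8, p_missing = 0)
  cells <- rbind(base$cells, base$cells[3, ])
  cm2 <- mpsearch:::new_char_matrix(cells, c(base$labels, "dup"), base$ordered)
  w5 <- wagner_addition(base, seed = 1)
  w6 <- wagner_addition(cm2, addition_order = c(base$labels, "dup"), seed = 1)
  expect_identical(tree_length(w6, cm2)$total, tree_length(w5, base)$total)
})

test_that("Wagner trees never beat the exhaustive optimum", {
  set.seed(302)
  hits <- 0L
  for (trial in 1:6) {
    cm <- rand_cm(6, 10)
    opt <- exhaustive_search(cm)$length
    wl <- tree_length(wagner_addition(cm, sample(cm$labels)), cm)$total
    expect_gte(wl, opt)
    if (wl == opt) hits <- hits + 1L
  }
  expect_gte(hits, 1L)  # stepwise addition should reach the optimum sometimes
})

test_that("the 4-leaf TBR neighborhood is the other two topologies", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  nb <- tbr_neighbors(tr)
  expect_identical(length(nb), 2L)
  keys <- sort(vapply(nb, topo_key, character(1)))
  others <- c("((A,C),(B,D));", "((A,D),(B,C));")
  expect_identical(keys, sort(vapply(others, function(s) {
    topo_key(ape::read.tree(text = s))
  }, character(1), USE.NAMES = FALSE)))
})

test_that("TBR neighbor sets match the fragment-matching oracle", {
  set.seed(303)
  labs <- paste0("x", 1:6)
  all6 <- mpsearch:::ut_enumerate(labs)
  for (trial in 1:2) {
    ut <- rand_ut(labs)
    mine <- sort(vapply(tbr_neighbors(mpsearch:::ut_to_phylo(ut)), topo_key,
                        character(1)))
    self <- mpsearch:::ut_topokey(ut)
    oracle <- sort(vapply(Filter(function(u2) {
      mpsearch:::ut_topokey(u2) != self && tbr_reachable(ut, u2)
    }, all6), mpsearch:::ut_topokey, character(1)))
    expect_identical(mine, oracle)
  }
})

test_that("TBR swapping from a random start recovers a clean matrix's optimum", {
  tr <- simulate_tree(8, seed = 304)
  sim <- simulate_matrix(tr, sim_config(n_characters = 30, events_per_char = 1,
                                        missing_frac = 0, poly_frac = 0),
                         seed = 305)
  truth_len <- tree_length(tr, sim$matrix)$total
  start <- wagner_addition(sim$matrix, sample(sim$matrix$labels), seed = 306)
  prep <- mpsearch:::mp_prep(sim$matrix)
  res <- mpsearch:::swap_to_optimum(mpsearch:::as_ut(start), prep, hold = 5)
  expect_identical(as.integer(res$length), truth_len)
})

test_that("tbr_swap accepts improvements first, then equal trees up to hold", {
  set.seed(307)
  cm <- rand_cm(6, 8)
  bad <- mpsearch:::ut_to_phylo(rand_ut(cm$labels))
  out <- tbr_swap(bad, cm, hold = 3)
  if (out$improved) {
    expect_identical(length(out$trees), 1L)
    expect_lt(out$length, tree_length(bad, cm)$total)
  } else {
    expect_lte(length(out$trees), 3L)
  }
  for (tr2 in out$trees) {
    expect_lte(tree_length(tr2, cm)$total, tree_length(bad, cm)$total)
  }
})

test_that("rule-1 collapsing preserves length, is idempotent, stars identical rows", {
  # identical rows: every branch collapses
  cm_same <- char_matrix(c(A = "010", B = "010", C = "010", D = "010", E = "010"))
  star <- collapse_zero_length(ape::read.tree(text = "((A,B),(C,D),E);"), cm_same)
  expect_identical(n_resolved(star), 0L)
  # a supported quartet edge survives
  cm1 <- char_matrix(c(A = "0", B = "0", C = "1", D = "1"))
  kept <- collapse_zero_length(ape::read.tree(text = "((A,B),(C,D));"), cm1)
  expect_identical(n_resolved(kept), 1L)
  # random cases: length preserved and second pass is a no-op
  set.seed(308)
  for (trial in 1:6) {
    cm <- rand_cm(7, 5)
    phy <- mpsearch:::ut_to_phylo(rand_ut(cm$labels))
    c1 <- collapse_zero_length(phy, cm)
    expect_identical(tree_length(c1, cm)$total, tree_length(phy, cm)$total)
    c2 <- collapse_zero_length(c1, cm)
    expect_identical(topo_key(c1), topo_key(c2))
  }
})

test_that("heuristic search matches the exhaustive oracle on small matrices", {
  set.seed(309)
  for (trial in 1:5) {
    n <- sample(5:7, 1)
    cm <- rand_cm(n, 12)
    ex <- exhaustive_search(cm)
    hs <- heuristic_search(cm, search_config(n_replicates = 3, seed = trial))
    expect_identical(hs$length, ex$length)
    expect_identical(treeset_keys(hs), treeset_keys(ex))
  }
})

test_that("searches are seed-reproducible and free of duplicate topologies", {
  tr <- simulate_tree(8, seed = 310)
  sim <- simulate_matrix(tr, sim_config(n_characters = 20, events_per_char = 2,
                                        missing_frac = 0.2), seed = 311)
  a <- heuristic_search(sim$matrix, search_config(n_replicates = 3, seed = 42))
  b <- heuristic_search(sim$matrix, search_config(n_replicates = 3, seed = 42))
  expect_identical(treeset_keys(a), treeset_keys(b))
  expect_identical(a$replicate_lengths, b$replicate_lengths)
  expect_false(anyDuplicated(treeset_keys(a)) > 0L)
  # every returned tree re-scores to the reported best length
  for (u in a$trees) {
    expect_identical(tree_length(mpsearch:::ut_to_phylo(u), sim$matrix)$total,
                     a$length)
  }
  # identical rows collapse to a star of length 0
  cm_flat <- char_matrix(c(A = "01", B = "01", C = "01", D = "01", E = "01"))
  hs0 <- heuristic_search(cm_flat, search_config(n_replicates = 2, seed = 1))
  expect_identical(hs0$length, 0L)
  expect_identical(n_trees(hs0), 1L)
  expect_identical(n_resolved(treeset_trees(hs0)[[1]]), 0L)
})
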