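test_that("strict consensus reduces to the obvious cases", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_identical(topo_key(strict_consensus(list(tr))), topo_key(tr))
  # all three quartet topologies -> star
  quartets <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
                     function(s) ape::read.tree(text = s))
  expect_identical(n_resolved(strict_consensus(quartets)), 0L)
  expect_error(strict_consensus(list(tr, ape::read.tree(text = "((A,B),(C,X));"))),
               "leaf sets")
})

test_that("strict consensus agrees with ape and is contained in every input", {
  set.seed(401)
  for (trial in 1:6) {
    n <- sample(5:8, 1)
    trees <- lapply(1:3, function(i) mpsearch:::ut_to_phylo(rand_ut(paste0("x", 1:n))))
    cons <- strict_consensus(trees)
    keys <- mpsearch:::ut_splits(mpsearch:::as_ut(cons))
    for (tr in trees) {
      expect_true(all(keys %in% mpsearch:::ut_splits(mpsearch:::as_ut(tr))))
    }
    ref <- ape::consensus(trees, p = 1)
    expect_identical(topo_key(cons), topo_key(ref))
  }
})

test_that("Bremer values equal the exhaustive-oracle definition on small matrices", {
  set.seed(402)
  done <- 0L
  for (trial in 1:8) {
    cm <- rand_cm(6, 10, p_missing = 0.1)
    ts <- exhaustive_search(cm)
    br <- bremer_supports(cm, ts, k_max = 6L, max_trees = 5000)
    if (nrow(br) == 0L) next
    done <- done + 1L
    oracle <- brute_bremer(cm, br$split)
    capped <- oracle > 6L  # values beyond k_max are reported as NA
    expect_identical(is.na(br$bremer), unname(capped))
    expect_identical(br$bremer[!capped], unname(oracle[!capped]))
    # complete MPT set: every consensus clade has support >= 1
    expect_true(all(br$bremer[!is.na(br$bremer)] >= 1L))
    if (done >= 3L) break
  }
  expect_gte(done, 2L)
})

test_that("Bremer supports are positive on homoplasy-free true clades", {
  tr <- simulate_tree(7, seed = 403)
  sim <- simulate_matrix(tr, sim_config(n_characters = 25, events_per_char = 1,
                                        missing_frac = 0, poly_frac = 0),
                         seed = 404)
  ts <- exhaustive_search(sim$matrix)
  br <- bremer_supports(sim$matrix, ts, k_max = 4L, max_trees = 5000)
  expect_gt(nrow(br), 0L)
  expect_true(all(is.na(br$bremer) | br$bremer >= 1L))
  # rejects a non-optimal tree set
  worse <- ts
  worse$length <- ts$length + 1L
  expect_error(bremer_supports(sim$matrix, worse), "not an optimal set")
})

test_that("identical trees are fully stable; a hopping taxon is flagged", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  same <- mpsearch:::new_treeset(list(mpsearch:::as_ut(tr), mpsearch:::as_ut(tr)),
                                 0L, tr$tip.label)
  rep0 <- positional_instability(same)
  expect_true(all(rep0$n_positions == 1L))
  expect_true(all(rep0$gain == 0L))
  # W hops across the backbone; everything else is fixed
  hop <- lapply(c("(((A,W),B),(C,(D,E)));",
                  "((A,B),(C,((D,W),E)));",
                  "((A,B),((C,W),(D,E)));"),
                function(s) ape::read.tree(text = s))
  ts <- mpsearch:::new_treeset(lapply(hop, mpsearch:::as_ut), 0L, hop[[1]]$tip.label)
  rep1 <- positional_instability(ts)
  # W has the most positions and the whole resolution gain; the other taxa
  # also count >1 positions (their attachment bipartitions involve the
  # moving W) but pruning them gains nothing
  expect_identical(rep1$taxon[1], "W")
  expect_identical(rep1$n_positions[match("W", rep1$taxon)], 3L)
  expect_gt(rep1$gain[match("W", rep1$taxon)], 0L)
  expect_true(all(rep1$gain[rep1$taxon != "W"] <=
                    rep1$gain[match("W", rep1$taxon)]))
  expect_identical(attr(rep1, "ranking")[1], "W")
  # greedy pruning removes exactly the wildcard and restores full resolution
  pruned <- greedy_prune(ts)
  expect_identical(as.character(pruned), "W")
  after <- attr(pruned, "treeset")
  expect_identical(n_trees(after), 1L)
  expect_identical(n_resolved(strict_consensus(after)), 2L)
})

test_that("reduced consensus is at least as resolved as the projected consensus", {
  set.seed(405)
  for (trial in 1:5) {
    cm <- rand_cm(7, 8)
    ts <- exhaustive_search(cm)
    if (n_trees(ts) < 2L) next
    rep <- positional_instability(ts)
    expect_true(all(rep$gain >= 0L))
  }
})

test_that("pruning behaves on matrices and on tree sets", {
  cm <- rand_cm(6, 5)
  expect_identical(dim(prune_taxa(cm, cm$labels[c(2, 5)])), c(4L, 5L))
  expect_identical(prune_taxa(cm, character(0)), cm)
  expect_error(prune_taxa(cm, "nope"), "unknown taxon")
  expect_error(prune_taxa(cm, cm$labels[1], mode = "a_posteriori"), "a priori")

  set.seed(406)
  trees <- lapply(1:4, function(i) rand_ut(paste0("x", 1:7)))
  ts <- mpsearch:::new_treeset(trees, 0L, paste0("x", 1:7))
  ps <- prune_taxa(ts, c("x3", "x5"))
  expect_lte(n_trees(ps), n_trees(ts))
  for (u in ps$trees) expect_identical(sort(u$labels), sort(setdiff(paste0("x", 1:7), c("x3", "x5"))))
  expect_error(prune_taxa(ts, "x1", mode = "a_priori"), "a posteriori")
})
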