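test_that("degenerate simulation settings give the expected matrices", {
  tr <- simulate_tree(6, seed = 501)
  # zero events: all characters constant, any tree scores 0
  s0 <- simulate_matrix(tr, sim_config(n_characters = 12, events_per_char = 0,
                                       missing_frac = 0, poly_frac = 0), seed = 1)
  expect_identical(tree_length(simulate_tree(6, seed = 9), s0$matrix)$total, 0L)
  # fully missing: every tree scores 0
  s1 <- simulate_matrix(tr, sim_config(n_characters = 12, events_per_char = 2,
                                       missing_frac = 1), seed = 2)
  expect_true(all(s1$matrix$cells == 0L))
  expect_identical(tree_length(tr, s1$matrix)$total, 0L)
})

test_that("one event per character makes the generating tree an optimum", {
  for (seed in 502:504) {
    tr <- simulate_tree(6, seed = seed)
    sim <- simulate_matrix(tr, sim_config(n_characters = 20, events_per_char = 1,
                                          missing_frac = 0, poly_frac = 0),
                           seed = seed + 10)
    expect_identical(tree_length(tr, sim$matrix)$total, 20L)
    expect_identical(exhaustive_search(sim$matrix)$length, 20L)
  }
})

test_that("the generating tree never scores above the simulated event total", {
  set.seed(505)
  for (trial in 1:5) {
    tr <- simulate_tree(sample(5:9, 1), seed = trial)
    ev <- sample(1:4, 1)
    sim <- simulate_matrix(tr, sim_config(n_characters = 15, events_per_char = ev,
                                          missing_frac = 0.2, poly_frac = 0.05),
                           seed = trial + 100)
    expect_lte(tree_length(tr, sim$matrix)$total, sum(sim$truth$events))
  }
})

test_that("simulation is seed-deterministic end to end", {
  tr <- simulate_tree(7, seed = 506)
  a <- simulate_matrix(tr, sim_config(n_characters = 10), seed = 7)
  b <- simulate_matrix(tr, sim_config(n_characters = 10), seed = 7)
  expect_identical(a$matrix$cells, b$matrix$cells)
  expect_identical(a$matrix$ordered, b$matrix$ordered)
  expect_identical(topo_key(simulate_tree(7, seed = 506)), topo_key(tr))
})
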