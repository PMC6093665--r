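quartet <- ape::read.tree(text = "((A,B),(C,D));")

test_that("quartet character lengths match hand-derived values", {
  # one forced change
  expect_identical(character_length(quartet, c(A = 0, B = 0, C = 1, D = 1)), 1L)
  # ordered vs unordered with two missing leaves
  col <- list(A = 0L, B = 2L, C = NA, D = NA)
  expect_identical(character_length(quartet, col, ordered = TRUE), 2L)
  expect_identical(character_length(quartet, col, ordered = FALSE), 1L)
  # an all-missing column costs nothing
  expect_identical(character_length(quartet, list(A = NA, B = NA, C = NA, D = NA)), 0L)
  # leaf without a cell errors
  expect_error(character_length(quartet, list(A = 0, B = 1, C = 0)), "")
})

test_that("scoring agrees with the brute-force enumeration oracle", {
  set.seed(202)
  for (trial in 1:25) {
    n <- sample(4:6, 1)
    cm <- rand_cm(n, 2)
    ut <- rand_ut(cm$labels)
    phy <- mpsearch:::ut_to_phylo(ut)
    got <- tree_length(phy, cm)$steps
    for (j in 1:2) {
      expect_identical(got[j], brute_char_steps(phy, cm, j),
                       info = sprintf("trial %d char %d (ordered=%s)",
                                      trial, j, cm$ordered[j]))
    }
  }
})

test_that("polytomous trees score identically to the brute-force oracle", {
  set.seed(203)
  for (trial in 1:8) {
    cm <- rand_cm(6, 2)
    ut <- rand_ut(cm$labels)
    # contract a random internal edge to force a polytomy
    internal <- which(ut$edge[, 1] < 0L & ut$edge[, 2] < 0L)
    poly <- mpsearch:::ut_contract(ut, internal[sample.int(length(internal), 1)])
    phy <- mpsearch:::ut_to_phylo(poly)
    got <- tree_length(phy, cm)$steps
    for (j in 1:2) {
      expect_identical(got[j], brute_char_steps(phy, cm, j))
    }
  }
})

test_that("length is invariant under display rooting and leaf order", {
  set.seed(204)
  cm <- rand_cm(7, 10)
  ut <- rand_ut(cm$labels)
  phy <- mpsearch:::ut_to_phylo(ut)
  ref <- tree_length(phy, cm)$total
  for (og in cm$labels[1:4]) {
    rooted <- ape::root(phy, outgroup = og, resolve.root = TRUE)
    expect_identical(tree_length(rooted, cm)$total, ref)
  }
  shuffled <- mpsearch:::new_char_matrix(cm$cells[7:1, ], cm$labels[7:1], cm$ordered)
  expect_identical(tree_length(phy, shuffled)$total, ref)
})

test_that("ordered scoring never undercuts unordered scoring", {
  # holds for single-state and missing cells; polymorphic cells are exempt
  # because ordered scoring widens them to their enclosing interval
  set.seed(205)
  for (trial in 1:20) {
    n <- sample(4:8, 1)
    cm <- rand_cm(n, 6, p_ord = 0, p_poly = 0)
    ut <- rand_ut(cm$labels)
    phy <- mpsearch:::ut_to_phylo(ut)
    uo <- tree_length(phy, cm)$steps
    cm$ordered[] <- TRUE
    od <- tree_length(phy, cm)$steps
    expect_true(all(od >= uo))
  }
})

test_that("scoring is additive over matrix concatenation", {
  set.seed(206)
  labs <- paste0("x", 1:6)
  a <- rand_cm(6, 5, labels = labs)
  b <- rand_cm(6, 7, labels = labs)
  both <- mpsearch:::new_char_matrix(cbind(a$cells, b$cells), labs,
                                     c(a$ordered, b$ordered))
  phy <- mpsearch:::ut_to_phylo(rand_ut(labs))
  expect_identical(tree_length(phy, both)$total,
                   tree_length(phy, a)$total + tree_length(phy, b)$total)
  bd <- tree_length(phy, both)
  expect_identical(bd$total, sum(bd$steps))
})

test_that("unordered binary-tree lengths agree with phangorn's Fitch", {
  set.seed(207)
  for (trial in 1:6) {
    cm <- rand_cm(8, 12, smax = 2, p_poly = 0, p_ord = 0)
    phy <- mpsearch:::ut_to_phylo(rand_ut(cm$labels))
    chr <- lapply(seq_len(8), function(i) {
      vapply(cm$cells[i, ], function(m) {
        s <- mpsearch:::states_of(m)
        if (length(s) == 1L) as.character(s) else "?"
      }, character(1))
    })
    dat <- phangorn::phyDat(do.call(rbind, stats::setNames(chr, cm$labels)),
                            type = "USER", levels = c("0", "1", "2"),
                            ambiguity = "?")
    expect_equal(tree_length(phy, cm)$total,
                 as.integer(phangorn::parsimony(phy, dat, method = "fitch")))
  }
})

test_that("minimum branch lengths match small-case expectations", {
  # identical-row leaf pairs that agree wherever both sides are scored:
  # no character can force a change onto the internal edge
  cm0 <- char_matrix(c(A = "01?1", B = "01?1", C = "01??", D = "01??"))
  ml <- min_branch_length(quartet, cm0)
  k <- which(ml$internal)
  expect_identical(ml$min_length[k], 0L)
  # ... but characters differing *between* the pairs do force it
  cm0b <- char_matrix(c(A = "0101", B = "0101", C = "1100", D = "1100"))
  expect_identical(min_branch_length(quartet, cm0b, edge = k), 2L)
  # one supporting character forces one change on the internal edge
  cm1 <- char_matrix(c(A = "0", B = "0", C = "1", D = "1"))
  expect_identical(min_branch_length(quartet, cm1, edge = k), 1L)
  expect_error(min_branch_length(quartet, cm1, edge = which(!ml$internal)[1]),
               "terminal")
  # summed minimum branch lengths never exceed the tree length
  set.seed(208)
  for (trial in 1:8) {
    cm <- rand_cm(7, 6)
    phy <- mpsearch:::ut_to_phylo(rand_ut(cm$labels))
    ml <- min_branch_length(phy, cm)$min_length
    expect_lte(sum(ml, na.rm = TRUE), tree_length(phy, cm)$total)
  }
})
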