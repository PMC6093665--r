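test_that("TNT parsing handles the smallest legal matrix and missing cells", {
  txt <- "xread\n'tiny'\n1 1\nTaxonA ?\n;\n"
  expect_warning(cm <- parse_matrix(txt, "tnt"), "unordered")
  expect_identical(dim(cm), c(1L, 1L))
  expect_identical(matrix_cell(cm, "TaxonA", 1), integer(0))
})

test_that("TNT ccode (0-based) and NEXUS TYPESET (1-based) set ordered flags", {
  txt <- "xread\n4 3\nA 0120\nB 1111\nC 0000\n;\ncc + 0 2;\nproc /;"
  cm <- parse_matrix(txt, "tnt")
  expect_identical(cm$ordered, c(TRUE, FALSE, TRUE, FALSE))

  nx <- paste0("#NEXUS\nBEGIN DATA;\nDIMENSIONS NTAX=3 NCHAR=4;\n",
               "FORMAT SYMBOLS=\"0123\" MISSING=? GAP=-;\nMATRIX\nA 0120\nB 1111\nC 0000\n;\nEND;\n",
               "BEGIN ASSUMPTIONS;\nTYPESET * default = ord: 1 3, unord: 2 4;\nEND;\n")
  cm2 <- parse_matrix(nx, "auto")
  expect_identical(cm2$ordered, c(TRUE, FALSE, TRUE, FALSE))
  expect_true(cm_equal_public(cm, cm2))
})

test_that("polymorphic cells parse to state sets and survive write/parse", {
  txt <- "xread\n3 4\nA 0[01]2\nB 111\nC {02}00\nD (12)2?\n;\ncc + 1;\n"
  cm <- parse_matrix(txt, "tnt")
  expect_identical(matrix_cell(cm, "A", 2), c(0L, 1L))
  expect_identical(matrix_cell(cm, "C", 1), c(0L, 2L))
  expect_identical(matrix_cell(cm, "D", 1), c(1L, 2L))
  for (d in c("tnt", "nexus")) {
    expect_true(cm_equal_public(cm, parse_matrix(write_matrix(cm, d), d)))
  }
})

test_that("parse/write identity holds on random matrices in both dialects", {
  set.seed(101)
  for (trial in 1:12) {
    cm <- rand_cm(sample(3:9, 1), sample(1:15, 1))
    for (d in c("tnt", "nexus")) {
      # a draw without ordered characters writes no declaration and warns
      back <- suppressWarnings(parse_matrix(write_matrix(cm, d), d))
      expect_true(cm_equal_public(cm, back),
                  info = sprintf("trial %d dialect %s", trial, d))
    }
  }
  # a matrix without ordered characters writes no ccode/TYPESET block
  cm0 <- rand_cm(4, 5, p_ord = 0)
  expect_false(grepl("ccode", write_matrix(cm0, "tnt")))
  expect_false(grepl("TYPESET", write_matrix(cm0, "nexus")))
  expect_warning(parse_matrix(write_matrix(cm0, "tnt"), "tnt"), "unordered")
  # missing cells are written back as ?
  cmq <- char_matrix(c(A = "?0", B = "1-"))
  expect_match(write_matrix(cmq, "tnt"), "A +\\?0")
})

test_that("parse errors name the offending row or symbol position", {
  expect_error(parse_matrix("xread\n3 2\nA 010\nB 01\n;", "tnt"), "row 'B'")
  expect_error(parse_matrix("xread\n3 2\nA 010\n;", "tnt"), "declared 2 taxa")
  expect_error(parse_matrix("xread\n3 2\nA 0x0\nB 000\n;", "tnt"),
               "position 2.*'x'")
})

test_that("merge_otus follows the cell-combination rule on all 2-state pairs", {
  # enumerate pairs over {missing, {0}, {1}, {0,1}}
  cells <- list(integer(0), 0L, 1L, c(0L, 1L))
  for (a in cells) {
    for (b in cells) {
      cm <- char_matrix(list(S = list(a), T = list(b), U = list(0L)))
      both_known <- length(a) > 0L && length(b) > 0L
      inter <- intersect(a, b)
      expected <- if (!both_known) union(a, b)        # known beats unknown
      else if (length(inter) > 0L) inter              # overlapping: intersection
      else union(a, b)                                # disjoint: union + conflict
      conflict <- both_known && length(inter) == 0L
      if (conflict) {
        expect_error(merge_otus(cm, "S", "T", conflict = "error"), "conflict")
        expect_message(out <- merge_otus(cm, "S", "T", conflict = "union"),
                       "conflict")
        expect_identical(nrow(attr(out, "conflicts")), 1L)
      } else {
        out <- merge_otus(cm, "S", "T", conflict = "union")
        expect_null(attr(out, "conflicts"))
      }
      expect_identical(dim(out), c(2L, 1L))
      expect_identical(matrix_cell(out, "T", 1), sort(as.integer(expected)))
    }
  }
})

test_that("merging an identical row is idempotent and matching ignores underscores", {
  cm <- char_matrix(c("Taxon one" = "01?", "Taxon_two" = "01?", Other = "120"))
  out <- merge_otus(cm, "Taxon_one", "Taxon two")
  expect_identical(dim(out), c(2L, 3L))
  expect_identical(matrix_cell(out, "Taxon two", 1), 0L)
  expect_identical(matrix_cell(out, "Taxon two", 3), integer(0))
  expect_error(merge_otus(cm, "nope", "Other"), "unknown taxon")
})

test_that("scoring edits change exactly the addressed cells, 1-based", {
  cm <- char_matrix(c(H = "01010", X = "11111"))
  edits <- data.frame(taxon = c("H", "H", "H", "H"),
                      char = c(1L, 2L, 4L, 5L),
                      old = c("0", "1", "1", "0"),
                      new = c("1", "0", "1", NA))
  out <- apply_scoring_edits(cm, edits)
  expect_identical(matrix_cell(out, "H", 1), 1L)
  expect_identical(matrix_cell(out, "H", 2), 0L)
  expect_identical(matrix_cell(out, "H", 4), 1L)
  expect_identical(matrix_cell(out, "H", 5), integer(0))  # -> missing
  expect_identical(matrix_cell(out, "H", 3), 0L)          # untouched
  expect_identical(out$cells[2, ], cm$cells[2, ])          # other taxon untouched

  expect_identical(apply_scoring_edits(cm, cm_empty_edits()), cm)
  expect_warning(
    apply_scoring_edits(cm, data.frame(taxon = "H", char = 1, old = "1", new = "0")),
    "did not match")
  expect_error(apply_scoring_edits(cm, data.frame(taxon = "H", char = 9, new = 0)),
               "out of range")
  expect_error(apply_scoring_edits(cm, data.frame(taxon = "Z", char = 1, new = 0)),
               "unknown taxon")
})

test_that("merge never widens a cell except under the disjoint-union branch", {
  set.seed(7)
  for (trial in 1:10) {
    cm <- rand_cm(4, 8)
    suppressMessages(out <- merge_otus(cm, cm$labels[1], cm$labels[2]))
    conflicts <- attr(out, "conflicts")
    widened <- integer(0)
    for (j in 1:8) {
      a <- matrix_cell(cm, 1, j); b <- matrix_cell(cm, 2, j)
      m <- matrix_cell(out, 1, j)
      known <- length(a) > 0L && length(b) > 0L
      if (known && length(m) > max(length(a), length(b))) widened <- c(widened, j)
    }
    expect_true(all(widened %in% conflicts$char))
  }
})
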