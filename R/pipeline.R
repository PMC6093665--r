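# Two-stage analysis pipeline: search on the full matrix, consensus and
# wildcard detection, a priori exclusion of the unstable taxa and re-search,
# then a posteriori pruning of any remaining wildcard and reduced consensus
# with Bremer supports. All randomness flows from the single run seed.

#' Run the full two-stage parsimony pipeline on a matrix
#'
#' Executes: optional OTU merge and scoring edits; heuristic search on the
#' full matrix; strict consensus and positional-instability ranking; greedy
#' a priori exclusion of the most unstable taxa; re-search on the reduced
#' matrix with the same configuration; a posteriori pruning of remaining
#' wildcards from the reduced MPT set; reduced strict consensus and Bremer
#' supports. Every number in the returned report is re-derivable from the
#' stored trees and the matrix (see [verify_report()]).
#'
#' @param cm A [char_matrix()].
#' @param config A [search_config()]; its seed drives all randomness.
#' @param merge Optional list(source=, target=) OTU merge applied first.
#' @param edits Optional scoring-edit data frame (see
#'   [apply_scoring_edits()]).
#' @param outgroup Optional outgroup label: used only to root the trees for
#'   display in the written report — parsimony length is root-invariant and
#'   the search itself is unrooted.
#' @param exclude Taxa to exclude a priori before stage 2. Default `NULL`
#'   excludes the taxa chosen by greedy instability pruning on the stage-1
#'   MPT set.
#' @param k_max Bremer depth for the final supports.
#' @param require_ordering Refuse to run if the matrix carries no ordered
#'   (additive) characters — protection for replication runs whose source
#'   matrix is known to have an ordering declaration that a parsing step may
#'   have dropped. Default FALSE.
#' @return A `run_report` list; see Details.
#' @details The report fields: `matrix_digest`, `config`, `stage1` (best
#'   length, MPT count, consensus Newick, instability table, excluded taxa),
#'   `stage2` (best length, MPT count, consensus Newick, wildcard positions,
#'   a posteriori pruned taxa, reduced consensus Newick, Bremer table).
#' @export
run_mp_pipeline <- function(cm, config = search_config(), merge = NULL,
                            edits = NULL, outgroup = NULL, exclude = NULL,
                            k_max = 6L, require_ordering = FALSE) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  if (require_ordering && !any(cm$ordered)) {
    stop("[matrix] replication mode requires an ordering declaration ",
         "(no character is flagged additive)")
  }
  if (!is.null(merge)) {
    cm <- stage("merge", merge_otus(cm, merge$source, merge$target))
  }
  if (!is.null(edits)) {
    cm <- stage("edits", apply_scoring_edits(cm, edits))
  }
  if (!is.null(outgroup)) stage("outgroup", match_label(cm$labels, outgroup))

  ts1 <- stage("search-1", heuristic_search(cm, config))
  cons1 <- stage("consensus-1", strict_consensus(ts1))
  inst1 <- stage("pcr-1", positional_instability(ts1))
  excluded <- if (is.null(exclude)) {
    as.character(stage("pcr-1", greedy_prune(ts1)))
  } else as.character(exclude)

  if (length(excluded) > 0L) {
    cm2 <- stage("exclude", prune_taxa(cm, excluded, mode = "a_priori"))
    ts2 <- stage("search-2", heuristic_search(cm2, config))
  } else {
    cm2 <- cm
    ts2 <- ts1
  }
  cons2 <- stage("consensus-2", strict_consensus(ts2))
  inst2 <- stage("pcr-2", positional_instability(ts2))
  wildcards <- as.character(stage("pcr-2", greedy_prune(ts2)))
  ts_final <- if (length(wildcards) > 0L) {
    stage("prune", prune_taxa(ts2, wildcards, mode = "a_posteriori"))
  } else ts2
  cons_final <- stage("consensus-final", strict_consensus(ts_final))
  cm_final <- cm2_drop(cm2, wildcards)
  bremer <- stage("bremer",
                  bremer_supports(cm_final, rescore_treeset(ts_final, cm_final),
                                  k_max = k_max))

  report <- list(
    matrix_digest = matrix_digest(cm),
    config = unclass(config),
    outgroup = outgroup,
    stage1 = list(
      n_taxa = n_taxa(cm), n_characters = n_chars(cm),
      best_length = ts1$length, n_mpts = n_trees(ts1),
      consensus = write_display(cons1, outgroup),
      instability = as.data.frame(inst1),
      excluded = excluded
    ),
    stage2 = list(
      n_taxa = n_taxa(cm2), n_characters = n_chars(cm2),
      best_length = ts2$length, n_mpts = n_trees(ts2),
      consensus = write_display(cons2, outgroup),
      instability = as.data.frame(inst2),
      wildcards = wildcards,
      wildcard_positions = wildcard_positions(ts2, wildcards),
      n_mpts_pruned = n_trees(ts_final),
      reduced_consensus = write_display(cons_final, outgroup),
      bremer = as.data.frame(bremer)
    ),
    treesets = list(stage1 = ts1, stage2 = ts2, final = ts_final)
  )
  class(report) <- "run_report"
  report
}

cm2_drop <- function(cm, taxa) if (length(taxa) == 0L) cm else cm_drop_taxa(cm, taxa)

# After a posteriori pruning the trees are scored on the pruned matrix,
# where their lengths differ from the stored stage-2 best; Bremer on the
# reduced system is computed from the pruned trees attaining the minimum
# pruned length.
rescore_treeset <- function(ts, cm) {
  prep <- mp_prep(cm)
  lens <- vapply(ts$trees, function(u) sum(ut_steps(u, prep)), numeric(1))
  best <- min(lens)
  new_treeset(ts$trees[lens == best], best, cm$labels, ts$config,
              list(complete = ts$complete))
}

# distinct attachment positions of each wildcard across the stage-2 MPT set
wildcard_positions <- function(ts, wildcards) {
  if (length(wildcards) == 0L) return(integer(0))
  stats::setNames(vapply(wildcards, function(w) {
    length(unique(vapply(ts$trees, taxon_position_key, character(1), tip_label = w)))
  }, integer(1)), wildcards)
}

write_display <- function(tree, outgroup = NULL) {
  phy <- if (inherits(tree, "phylo")) tree else ut_to_phylo(as_ut(tree))
  if (!is.null(outgroup)) {
    og <- phy$tip.label[match(norm_label(outgroup), norm_label(phy$tip.label))]
    if (!is.na(og)) phy <- ape::root(phy, outgroup = og, resolve.root = FALSE)
  }
  ape::write.tree(phy)
}

matrix_digest <- function(cm) {
  f <- tempfile(fileext = ".tnt")
  on.exit(unlink(f))
  write_matrix(cm, "tnt", path = f)
  unname(tools::md5sum(f))
}

#' @export
print.run_report <- function(x, ...) {
  cat("Two-stage parsimony run\n")
  cat(sprintf("  matrix: %d taxa x %d characters (md5 %s)\n",
              x$stage1$n_taxa, x$stage1$n_characters, substr(x$matrix_digest, 1, 8)))
  cat(sprintf("  stage 1: best length %d, %d MPT(s)\n",
              x$stage1$best_length, x$stage1$n_mpts))
  if (length(x$stage1$excluded) > 0L) {
    cat("  excluded a priori:", paste(x$stage1$excluded, collapse = ", "), "\n")
  }
  cat(sprintf("  stage 2: best length %d, %d MPT(s)\n",
              x$stage2$best_length, x$stage2$n_mpts))
  if (length(x$stage2$wildcards) > 0L) {
    cat("  pruned a posteriori:", paste(x$stage2$wildcards, collapse = ", "), "\n")
  }
  cat("  reduced consensus:", x$stage2$reduced_consensus, "\n")
  invisible(x)
}

#' Re-derive the numbers of a run report from its stored trees
#'
#' Confirms that every reported best length re-scores from the stored trees
#' on the (re-derived) matrices, that MPT counts match the stored sets and
#' that the consensus strings re-parse to trees whose splits are contained
#' in every stored MPT.
#'
#' @param report A `run_report`.
#' @param cm The matrix passed to [run_mp_pipeline()] (after any merge /
#'   edits, i.e. the matrix of stage 1).
#' @return TRUE (invisibly) or an error describing the inconsistency.
#' @export
verify_report <- function(report, cm) {
  ts1 <- report$treesets$stage1
  for (u in ts1$trees) {
    if (sum(ut_steps(u, mp_prep(cm))) != report$stage1$best_length) {
      stop("stage-1 tree does not re-score to the reported best length")
    }
  }
  cm2 <- cm2_drop(cm, report$stage1$excluded)
  for (u in report$treesets$stage2$trees) {
    if (sum(ut_steps(u, mp_prep(cm2))) != report$stage2$best_length) {
      stop("stage-2 tree does not re-score to the reported best length")
    }
  }
  if (n_trees(ts1) != report$stage1$n_mpts ||
      n_trees(report$treesets$stage2) != report$stage2$n_mpts) {
    stop("MPT counts do not match stored tree sets")
  }
  for (nm in c("stage1", "stage2")) {
    cons <- ape::read.tree(text = report[[nm]]$consensus)
    keys <- ut_splits(as_ut(cons))
    for (u in report$treesets[[if (nm == "stage1") "stage1" else "stage2"]]$trees) {
      if (!all(keys %in% ut_splits(u))) {
        stop(nm, " consensus contains a split absent from a stored MPT")
      }
    }
  }
  invisible(TRUE)
}

#' Write a run report to a directory
#'
#' Emits `report.json` (jsonlite), `mpts_stage1.nwk`, `mpts_stage2.nwk`,
#' `mpts_final.nwk` (one Newick per line) and `report.md` (human-readable
#' summary).
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("stage1", "stage2", "final")) {
    writeLines(vapply(report$treesets[[nm]]$trees, ut_to_newick, character(1)),
               file.path(dir, paste0("mpts_", nm, ".nwk")))
  }
  json <- report[setdiff(names(report), "treesets")]
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# Parsimony run report", "",
          sprintf("- matrix: %d taxa x %d characters (md5 `%s`)",
                  report$stage1$n_taxa, report$stage1$n_characters, report$matrix_digest),
          sprintf("- seed: %s", report$config$seed %||% "none"),
          sprintf("- stage 1: best length %d, %d MPTs", report$stage1$best_length,
                  report$stage1$n_mpts),
          sprintf("- excluded a priori: %s",
                  if (length(report$stage1$excluded)) paste(report$stage1$excluded, collapse = ", ") else "none"),
          sprintf("- stage 2: best length %d, %d MPTs", report$stage2$best_length,
                  report$stage2$n_mpts),
          sprintf("- pruned a posteriori: %s",
                  if (length(report$stage2$wildcards)) paste(report$stage2$wildcards, collapse = ", ") else "none"),
          "", "## Reduced strict consensus", "",
          paste0("    ", report$stage2$reduced_consensus))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
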