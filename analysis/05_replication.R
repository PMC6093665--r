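#!/usr/bin/env Rscript
# Replication driver for the published aetosaur analysis.
#
# The deposited character/taxon matrix (83 characters x 28 taxa, built from
# Parker's aetosaur matrix with the SMNS 19003 scorings merged into
# Paratypothorax andressorum and the UFSM 11505 / holotype re-scorings
# applied) is not redistributable here. Drop it at data-raw/s1_matrix.txt
# (TNT or NEXUS dialect) and this script runs the published protocol:
#
#   1. traditional search, 100 random-addition replicates, TBR, hold 10,
#      rule-1 collapsing            -> expect 34 MPTs at 205 steps
#   2. PCR instability ranking      -> expect Aetobarbakinoides
#      brasiliensis, Stenomyti huangae, Polesinesuchus aurelioi on top
#   3. a priori exclusion of those three, same search on 25 taxa
#                                   -> expect 6 MPTs at 193 steps
#   4. a posteriori pruning of Coahomasuchus kahleorum (2 positions) and
#      reduced strict consensus with Bremer supports
#
# Replication mode refuses to run unless the matrix carries an ordering
# declaration for its seven additive characters (ccode/TYPESET): their
# identity comes from the source matrix publication, and silently treating
# them as unordered would not be a replication.

library(mpsearch)

path <- "data-raw/s1_matrix.txt"
if (!file.exists(path)) {
  message("data-raw/s1_matrix.txt not found.\n",
          "Obtain the study's S1 character/taxon matrix and place it there; ",
          "see the file header for the expected protocol and results.")
  quit(status = 0)
}

cm <- read_matrix(path)
stopifnot(dim(cm) == c(28L, 83L))

protocol <- jsonlite::read_json(system.file("extdata", "study_protocol.json",
                                            package = "mpsearch"))
cfg <- search_config(n_replicates = protocol$n_replicates,
                     hold = protocol$hold, seed = 1L)

rep <- run_mp_pipeline(
  cm, cfg,
  outgroup = protocol$outgroup,
  exclude = unlist(protocol$expected_unstable),
  k_max = 6L,
  require_ordering = TRUE
)
print(rep)
verify_report(rep, cm)
write_report(rep, "results/replication_report")

message(sprintf("stage 1: %d MPTs at %d steps (published: 34 at 205)",
                rep$stage1$n_mpts, rep$stage1$best_length))
message(sprintf("stage 2: %d MPTs at %d steps (published: 6 at 193)",
                rep$stage2$n_mpts, rep$stage2$best_length))
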