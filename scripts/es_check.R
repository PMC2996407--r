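#!/usr/bin/env Rscript
# Optional external spot-check (requires two locally downloaded PDB files):
# builds a table for enolase 1EBH, matches the five-residue enolase-
# superfamily motif defined on mandelate racemase 2MNR
# (164 K/H, 195 D, 221 E, 247 E/D/N, 297 H/K), and reports the number of
# enumerated complete matches in 1EBH plus the best match under the
# side-chain-centroid criterion.
#
# Usage: Rscript scripts/es_check.R <path/to/2mnr.pdb> <path/to/1ebh.pdb>

suppressPackageStartupMessages(library(motifhash))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 2L)
  stop("usage: Rscript scripts/es_check.R <2mnr.pdb> <1ebh.pdb>")

src <- read_pdb_file(args[1L], chain_selection = "merged", id = "2MNR")[[1L]]
mo <- parse_motif_spec("2MNR A164 KH; A195 D; A221 E; A247 EDN; A297 HK", src)
print(mo)

targets <- read_pdb_file(args[2L], chain_selection = "all-separate",
                         id = "1EBH")
targets <- lapply(targets, compute_depth)
tab <- build_table(targets, geometric_params(), tempfile("es_table_"), r = 7)

res <- match_motif(mo, tab,
                   options = match_options(keep_multiple_per_target = TRUE))
df <- matches_data_frame(res)
df <- df[df$complete, , drop = FALSE]
cat("complete matches enumerated:", nrow(df), "\n")
best <- select_best_per_target(res, "sidechain_centroid_rmsd")
print(summary(best))
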