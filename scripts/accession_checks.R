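#!/usr/bin/env Rscript
# Optional crystal-structure checks that need locally downloaded PDB
# files (no downloads are performed here). Computes apo-vs-holo CA RMSD
# over the common resolved residue set for the classic hinge benchmark
# pairs and prints a table.
#
# Usage:
#   Rscript scripts/accession_checks.R <pdb_dir>
# where <pdb_dir> contains e.g. 4ake.pdb/1ake.pdb, 2lao.pdb/1lst.pdb,
# 1dpe.pdb/1dpp.pdb, 1cll.pdb/1wrz.pdb (lower-case accession names).

suppressPackageStartupMessages(library(enmexplore))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 1) stop("usage: accession_checks.R <pdb_dir>")
pdb_dir <- args[1]

pairs <- list(
  AK  = c(apo = "4ake", holo = "1ake", chains = "A"),
  LAO = c(apo = "2lao", holo = "1lst", chains = NA),
  DBP = c(apo = "1dpe", holo = "1dpp", chains = NA),
  CAM = c(apo = "1cll", holo = "1wrz", chains = "A")
)

for (nm in names(pairs)) {
  p <- pairs[[nm]]
  fa <- file.path(pdb_dir, paste0(p[["apo"]], ".pdb"))
  fh <- file.path(pdb_dir, paste0(p[["holo"]], ".pdb"))
  if (!file.exists(fa) || !file.exists(fh)) {
    cat(sprintf("%-4s skipped (missing %s or %s)\n", nm, fa, fh))
    next
  }
  apo <- read_pdb(fa)
  holo <- read_pdb(fh)
  ch <- if (is.na(p[["chains"]])) NULL else p[["chains"]]
  r <- rmsd_ca(apo, holo, chains = ch)
  n <- length(intersect(
    paste(apo$atoms$chain, apo$atoms$resno)[apo$atoms$elety == "CA"],
    paste(holo$atoms$chain, holo$atoms$resno)[holo$atoms$elety == "CA"]))
  cat(sprintf("%-4s apo %s vs holo %s: CA RMSD %.2f A over %d residues\n",
              nm, p[["apo"]], p[["holo"]], r, n))
}
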