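#' Evaluate a lineage tree against a bound reference structure
#'
#' Per-conformer report of RG, CA RMSD to the holo reference, energy and
#' the close-to-bound flag. Evaluation never feeds back into the search;
#' it is computed after the fact from the recorded tree. For multimers a
#' per-chain RMSD (superposing on that chain alone) is appended per
#' chain as `rmsd_chain_<id>` columns.
#'
#' @param tree enx_lineage
#' @param holo enx_structure sharing a common residue set with the tree's
#'   topology
#' @param close_threshold RMSD below which a conformer counts as close
#'   to the bound structure (reporting constant, default 3 Angstrom)
#' @param apo_rg reference RG for the `in_rg_filter` flag (default: the
#'   tree root's RG)
#' @return data.frame of class `enx_eval` with one row per conformer and
#'   attribute `summary` (list: n_conformers, n_after_rg_filter,
#'   n_below_threshold, min_rmsd, min_rmsd_id)
#' @export
evaluate_tree <- function(tree, holo, close_threshold = 3.0,
                          apo_rg = NULL) {
  stopifnot(inherits(tree, "enx_lineage"), inherits(holo, "enx_structure"))
  nodes <- tree$nodes
  if (is.null(apo_rg)) apo_rg <- nodes[[tree$root_id]]$rg
  chains <- unique(holo$residues$chain)
  rows <- lapply(nodes, function(c) {
    r <- rmsd_ca(c$structure, holo)
    row <- data.frame(
      conformer_id = c$id, generation = c$generation,
      rg = c$rg, rmsd_to_holo = r, energy = c$energy,
      below_threshold = r < close_threshold,
      in_rg_filter = c$rg <= apo_rg,
      stringsAsFactors = FALSE
    )
    if (length(chains) > 1) {
      for (ch in chains)
        row[[paste0("rmsd_chain_", ch)]] <-
          tryCatch(rmsd_ca(c$structure, holo, chains = ch),
                   error = function(e) NA_real_)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_conformers = nrow(out),
    n_after_rg_filter = sum(out$in_rg_filter),
    n_below_threshold = sum(out$below_threshold),
    min_rmsd = min(out$rmsd_to_holo),
    min_rmsd_id = out$conformer_id[which.min(out$rmsd_to_holo)]
  )
  class(out) <- c("enx_eval", "data.frame")
  out
}

#' RG-versus-RMSD table
#'
#' Tabulates (generation, rg, rmsd_to_holo) per conformer for external
#' plotting of the compaction-versus-approach trend, with the apo and
#' holo reference RGs as header comment lines. Columns and headers are
#' fixed: `generation`, `rg`, `rmsd_to_holo`, tab-separated.
#'
#' @param rows enx_eval from [evaluate_tree()]
#' @param apo_rg,holo_rg reference RG values written as comment lines
#' @param path optional output file; if NULL the lines are returned
#' @return character vector of TSV lines (invisibly when written)
#' @export
rg_rmsd_table <- function(rows, apo_rg, holo_rg, path = NULL) {
  if (nrow(rows) == 0) stop("empty evaluation table")
  lines <- c(
    sprintf("# apo_rg\t%.4f", apo_rg),
    sprintf("# holo_rg\t%.4f", holo_rg),
    "generation\trg\trmsd_to_holo",
    sprintf("%d\t%.4f\t%.4f", rows$generation, rows$rg, rows$rmsd_to_holo)
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Per-generation summary of a tree (optionally against a reference)
#'
#' @param tree enx_lineage
#' @param holo optional enx_structure reference
#' @param close_threshold RMSD threshold for the close-conformer count
#' @return data.frame: generation, n_conformers, and (with a reference)
#'   n_below_threshold, min_rmsd
#' @export
generation_summary <- function(tree, holo = NULL, close_threshold = 3.0) {
  gens <- seq_along(tree$generations) - 1L
  base <- data.frame(
    generation = gens,
    n_conformers = vapply(tree$generations, length, integer(1))
  )
  if (is.null(holo)) return(base)
  ev <- evaluate_tree(tree, holo, close_threshold)
  base$n_below_threshold <- vapply(gens, function(g)
    sum(ev$below_threshold[ev$generation == g]), integer(1))
  base$min_rmsd <- vapply(gens, function(g)
    min(ev$rmsd_to_holo[ev$generation == g]), numeric(1))
  base
}
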