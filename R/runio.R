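#' Write a run directory
#'
#' Persists a lineage tree as plain-text artifacts: one PDB per
#' conformer under `conformers/`, the lineage graph (nodes with energy,
#' RG, generation, parentage) as `lineage.json`, and a per-generation
#' `summary.tsv`.
#'
#' @param tree enx_lineage
#' @param dir output directory (created if absent)
#' @param holo optional reference structure for the summary columns
#' @export
write_run <- function(tree, dir, holo = NULL) {
  dir.create(file.path(dir, "conformers"), recursive = TRUE,
             showWarnings = FALSE)
  for (c in tree$nodes)
    write_pdb(c$structure,
              file.path(dir, "conformers", paste0(c$id, ".pdb")))
  nodes <- lapply(tree$nodes, function(c) Filter(Negate(is.null), list(
    id = c$id, generation = c$generation,
    parent_id = if (is.na(c$parent_id)) NULL else c$parent_id,
    energy = c$energy, rg = c$rg, rg_chain = as.list(c$rg_chain),
    coefficients = c$coefficients,
    rmsd_to_reference =
      if (is.na(c$rmsd_to_reference)) NULL else c$rmsd_to_reference
  )))
  jsonlite::write_json(
    list(root_id = tree$root_id,
         reference_energy = tree$reference_energy,
         stop_reason = tree$stop_reason,
         mode = tree$config$mode, df = tree$config$df,
         n_modes = tree$config$n_modes,
         generations = tree$generations,
         nodes = unname(nodes)),
    file.path(dir, "lineage.json"), auto_unbox = TRUE, digits = NA
  )
  s <- generation_summary(tree, holo)
  utils::write.table(s, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Load a run directory
#'
#' Reconstructs an enx_lineage written by [write_run()]. The stored
#' run configuration is partial (mode, df, n_modes); fields that only
#' matter during generation are restored as defaults.
#'
#' @param dir run directory
#' @return enx_lineage
#' @export
load_run <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "lineage.json"))
  nodes <- list()
  for (nd in meta$nodes) {
    st <- read_pdb(file.path(dir, "conformers", paste0(nd$id, ".pdb")))
    rec <- list(
      id = nd$id, structure = st, energy = nd$energy,
      rg = nd$rg, rg_chain = unlist(nd$rg_chain),
      generation = as.integer(nd$generation),
      parent_id = if (length(nd$parent_id) == 0) NA_character_
                  else nd$parent_id,
      coefficients = if (length(nd$coefficients) == 0) NULL
                     else as.numeric(unlist(nd$coefficients)),
      rmsd_to_reference = if (length(nd$rmsd_to_reference) == 0) NA_real_
                          else nd$rmsd_to_reference
    )
    class(rec) <- "enx_conformer"
    nodes[[nd$id]] <- rec
  }
  structure(list(
    nodes = nodes,
    generations = lapply(meta$generations,
                         function(g) as.character(unlist(g))),
    root_id = meta$root_id,
    reference_energy = meta$reference_energy,
    config = explore_config(mode = meta$mode, df = meta$df,
                            n_modes = meta$n_modes),
    stop_reason = meta$stop_reason
  ), class = "enx_lineage")
}

#' Write a docking-chain ensemble PDB
#'
#' Multi-MODEL PDB of the lineage chain (root first), the ensemble of
#' progressively closing states handed to docking.
#'
#' @param chain list of enx_conformer from [docking_chain()]
#' @param path output PDB path
#' @export
write_chain_ensemble <- function(chain, path) {
  write_pdb(lapply(chain, function(c) c$structure), path)
}

#' Read an exploration configuration from YAML
#'
#' Loads a flat YAML file whose keys mirror [explore_config()]
#' (`mode`, `df`, `n_modes`, `max_generations`, `enm_cutoff`,
#' `cluster_seed`, `rg_filter_scope`, `ancestor_scope`,
#' `ligand_chains`) plus an optional `relax:` block with
#' [relax_config()] keys. Missing keys take the package defaults.
#'
#' @param path YAML file path
#' @return enx_explore_config
#' @export
read_explore_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  relax_args <- y$relax %||% list()
  y$relax <- NULL
  args <- y
  args$relax <- do.call(relax_config, relax_args)
  do.call(explore_config, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
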