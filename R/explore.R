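#' Exploration configuration
#'
#' Settings for the iterative generation engine. `blind` mode iterates
#' until `max_generations` with no information about any bound state;
#' `energy_based` mode additionally requires a conformer to have energy
#' below the minimized starting structure to parent the next generation,
#' and stops early when no such conformer exists.
#'
#' @param mode "blind" or "energy_based"
#' @param df deformation RMSD in Angstrom (default 2; 3 is the scale
#'   used for very large transitions)
#' @param n_modes number of slow modes combined (default 3)
#' @param max_generations generation cap (mandatory stop in blind mode)
#' @param enm_cutoff elastic-network contact cutoff in Angstrom
#'   (default 10)
#' @param relax enx_relax_config for the minimization stage
#' @param cluster_seed optional integer seed for the clustering
#'   assignment order
#' @param rg_filter_scope "global" or "per_chain" (how [rg_filter()] is
#'   applied downstream for multimers)
#' @param ancestor_scope "all" pools every recorded conformer into each
#'   generation's clustering; "previous" pools only the current parents
#' @param ligand_chains chain ids treated as a bound ligand: their
#'   residues are network nodes and deform with the receptor, while
#'   receptor-only metrics are reported separately
#' @return enx_explore_config
#' @export
explore_config <- function(mode = c("blind", "energy_based"),
                           df = 2.0, n_modes = 3, max_generations = 7,
                           enm_cutoff = 10, relax = relax_config(),
                           cluster_seed = NULL,
                           rg_filter_scope = c("global", "per_chain"),
                           ancestor_scope = c("all", "previous"),
                           ligand_chains = NULL) {
  mode <- match.arg(mode)
  rg_filter_scope <- match.arg(rg_filter_scope)
  ancestor_scope <- match.arg(ancestor_scope)
  stopifnot(df > 0, n_modes >= 1, max_generations >= 1, enm_cutoff > 0,
            inherits(relax, "enx_relax_config"))
  structure(list(mode = mode, df = df, n_modes = n_modes,
                 max_generations = as.integer(max_generations),
                 enm_cutoff = enm_cutoff, relax = relax,
                 cluster_seed = cluster_seed,
                 rg_filter_scope = rg_filter_scope,
                 ancestor_scope = ancestor_scope,
                 ligand_chains = ligand_chains),
            class = "enx_explore_config")
}

.receptor_chains <- function(structure, config) {
  ch <- unique(structure$residues$chain)
  if (is.null(config$ligand_chains)) return(ch)
  setdiff(ch, config$ligand_chains)
}

.make_conformer <- function(id, structure, energy, generation, parent_id,
                            config, reference = NULL, coefficients = NULL) {
  rec_ch <- .receptor_chains(structure, config)
  rec <- list(
    id = id, structure = structure, energy = energy,
    rg = radius_of_gyration(structure, chains = rec_ch),
    rg_chain = rg_by_chain(structure),
    generation = generation, parent_id = parent_id,
    coefficients = coefficients,
    rmsd_to_reference =
      if (is.null(reference)) NA_real_
      else rmsd_ca(structure, reference, chains = rec_ch)
  )
  class(rec) <- "enx_conformer"
  rec
}

#' Run the iterative conformer generation
#'
#' Generation 0 is the relaxed input structure. Each generation then,
#' for every eligible parent: recomputes the elastic network and its
#' slow modes on that parent, enumerates all mode-combination
#' deformations at fixed RMSD `df`, relaxes every deformed child
#' (discarding non-convergent ones), pools the children with the
#' ancestor conformers, clusters the pool at radius `df`, and promotes
#' the representative of every parent-free cluster to the next
#' generation. The run stops at `max_generations`, when no
#' representative remains, or (energy-based mode) when no representative
#' has energy below the generation-0 reference.
#'
#' @param apo enx_structure of the unbound starting state (or a
#'   ligand-bound complex when re-seeding; see [reseed_with_ligand()])
#' @param config enx_explore_config
#' @param reference optional enx_structure of a bound state, used only
#'   to annotate conformers with `rmsd_to_reference` for evaluation;
#'   it never influences the search
#' @param verbose print one line per generation
#' @return An `enx_lineage`: list with `nodes` (named list of
#'   `enx_conformer`), `generations` (list of id vectors, element 1 =
#'   generation 0), `root_id`, `reference_energy`, `config`,
#'   `stop_reason`.
#' @export
run_exploration <- function(apo, config = explore_config(),
                            reference = NULL, verbose = FALSE) {
  stopifnot(inherits(apo, "enx_structure"),
            inherits(config, "enx_explore_config"))
  r0 <- relax_minimize(apo, config$relax)
  if (!r0$converged)
    stop("relaxation of the starting structure did not converge")
  root_id <- "g0.c01"
  nodes <- list()
  nodes[[root_id]] <- .make_conformer(root_id, r0$structure, r0$energy,
                                      0L, NA_character_, config, reference)
  generations <- list(root_id)
  parents <- root_id
  ancestors <- root_id
  spec <- deform_spec(df = config$df, n_modes = config$n_modes)
  stop_reason <- "max_generations"

  for (gen in seq_len(config$max_generations)) {
    children <- list()
    child_meta <- list()
    for (pid in parents) {
      ps <- nodes[[pid]]$structure
      cg <- coarse_grain(ps)
      net <- build_network(cg, ps, cutoff = config$enm_cutoff)
      modes <- slow_modes(enm_hessian(net), n_modes = config$n_modes)
      dirs <- enumerate_directions(modes, spec)
      for (d in seq_along(dirs)) {
        child <- apply_deformation(ps, cg, dirs[[d]])
        rr <- relax_minimize(child, config$relax, reference = ps)
        if (!rr$converged) next
        tmp <- sprintf("tmp.%s.d%02d", pid, d)
        children[[tmp]] <- rr$structure
        child_meta[[tmp]] <- list(parent = pid, energy = rr$energy,
                                  coefficients = dirs[[d]]$coefficients)
      }
    }
    if (length(children) == 0) { stop_reason <- "no_viable_children"; break }

    pool <- c(lapply(nodes[if (config$ancestor_scope == "all") ancestors
                           else parents],
                     function(x) x$structure),
              children)
    clusters <- kcluster(pool, cluster_config(radius = config$df,
                                              seed = config$cluster_seed))
    rep_ids <- select_representatives(clusters, parent_ids = ancestors)
    if (length(rep_ids) == 0) { stop_reason <- "no_new_clusters"; break }
    rep_ids <- rep_ids[order(match(rep_ids, names(pool)))]

    gen_ids <- character(0)
    for (k in seq_along(rep_ids)) {
      meta <- child_meta[[rep_ids[k]]]
      id <- sprintf("g%d.c%02d", gen, k)
      nodes[[id]] <- .make_conformer(
        id, children[[rep_ids[k]]], meta$energy, gen, meta$parent,
        config, reference, meta$coefficients)
      gen_ids <- c(gen_ids, id)
    }
    generations[[gen + 1]] <- gen_ids
    if (verbose)
      message(sprintf(
        "generation %d: %d children, %d clusters, %d representatives",
        gen, length(children), length(clusters), length(gen_ids)))

    ancestors <- c(ancestors, gen_ids)
    if (config$mode == "energy_based") {
      ref_e <- nodes[[root_id]]$energy
      parents <- gen_ids[vapply(gen_ids,
                                function(i) nodes[[i]]$energy < ref_e,
                                logical(1))]
      if (length(parents) == 0) { stop_reason <- "no_lower_energy"; break }
    } else {
      parents <- gen_ids
    }
  }

  structure(list(nodes = nodes, generations = generations,
                 root_id = root_id,
                 reference_energy = nodes[[root_id]]$energy,
                 config = config, stop_reason = stop_reason),
            class = "enx_lineage")
}

#' @export
print.enx_lineage <- function(x, ...) {
  cat(sprintf(
    "enx_lineage: %d conformers over %d generation(s) (stop: %s)\n",
    length(x$nodes), length(x$generations) - 1, x$stop_reason))
  invisible(x)
}

#' All conformers of a lineage tree
#' @param tree enx_lineage
#' @param include_root include the generation-0 conformer (default TRUE)
#' @return named list of enx_conformer
#' @export
tree_conformers <- function(tree, include_root = TRUE) {
  out <- tree$nodes
  if (!include_root) out[[tree$root_id]] <- NULL
  out
}

#' Energy-based selection filter
#'
#' Keeps conformers with energy strictly below the reference (the
#' minimized starting structure in the pipeline).
#'
#' @param candidates list of enx_conformer
#' @param reference_energy numeric reference
#' @return filtered list
#' @export
energy_filter <- function(candidates, reference_energy) {
  candidates[vapply(candidates,
                    function(c) c$energy < reference_energy, logical(1))]
}

#' Radius-of-gyration post-filter
#'
#' Discards conformers more expanded than the starting structure:
#' conformers with RG less than or equal to the reference are kept (the
#' boundary is inclusive since only strictly higher RGs are discarded).
#' With `scope = "per_chain"` each chain's RG is compared to that
#' chain's reference RG; `per_chain_rule` selects whether one chain
#' (`"any"`, the default) or every chain (`"all"`) must satisfy the
#' criterion.
#'
#' @param conformers list of enx_conformer
#' @param apo_rg numeric reference RG (global scope) or named per-chain
#'   vector (per_chain scope)
#' @param scope "global" or "per_chain"
#' @param per_chain_rule "any" or "all"
#' @return filtered list
#' @export
rg_filter <- function(conformers, apo_rg,
                      scope = c("global", "per_chain"),
                      per_chain_rule = c("any", "all")) {
  scope <- match.arg(scope)
  per_chain_rule <- match.arg(per_chain_rule)
  keep <- vapply(conformers, function(c) {
    if (scope == "global") {
      c$rg <= apo_rg
    } else {
      ch <- intersect(names(apo_rg), names(c$rg_chain))
      if (length(ch) == 0)
        stop("per-chain reference RG does not match conformer chains")
      ok <- c$rg_chain[ch] <= apo_rg[ch]
      if (per_chain_rule == "any") any(ok) else all(ok)
    }
  }, logical(1))
  conformers[keep]
}

#' Extract the docking lineage chain
#'
#' Selects the lowest-RG conformer among a filtered set (ties broken by
#' lowest conformer id) and walks its parent pointers back to the root,
#' returning the chain root-to-leaf: the ensemble of progressively
#' closing states used for docking.
#'
#' @param tree enx_lineage
#' @param filtered non-empty list of enx_conformer (normally the output
#'   of [rg_filter()])
#' @return list of enx_conformer ordered root first
#' @export
docking_chain <- function(tree, filtered) {
  if (length(filtered) == 0) stop("filtered conformer set is empty")
  rgs <- vapply(filtered, function(c) c$rg, numeric(1))
  ids <- vapply(filtered, function(c) c$id, character(1))
  leaf <- ids[order(rgs, ids)][1]
  chain <- character(0)
  cur <- leaf
  while (!is.na(cur)) {
    chain <- c(cur, chain)
    cur <- tree$nodes[[cur]]$parent_id
  }
  lapply(chain, function(i) tree$nodes[[i]])
}

#' Re-seed the generation engine from a ligand-bound complex
#'
#' Identical engine run in which the ligand chains' residues are elastic
#' network nodes and move with the deformations, while the reference
#' energy is that of the minimized complex and receptor-only RMSD/RG are
#' reported separately from whole-complex metrics. This is the second
#' stage of the two-stage procedure for transitions that only complete
#' with the ligand bound.
#'
#' @param complex_structure enx_structure of receptor plus bound ligand
#' @param config enx_explore_config with `ligand_chains` set (may be
#'   empty, in which case the run degenerates to a plain receptor run)
#' @param reference,verbose passed to [run_exploration()]
#' @return enx_lineage
#' @export
reseed_with_ligand <- function(complex_structure, config,
                               reference = NULL, verbose = FALSE) {
  if (!is.null(config$ligand_chains)) {
    have <- unique(complex_structure$residues$chain)
    missing <- setdiff(config$ligand_chains, have)
    if (length(missing) > 0)
      stop("ligand chain(s) not found in complex: ",
           paste(missing, collapse = ", "))
  }
  run_exploration(complex_structure, config, reference = reference,
                  verbose = verbose)
}
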