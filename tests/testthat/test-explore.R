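test_that("a single blind generation respects the combinatorial bound", {
  hf <- get_hinge(2)
  cfg <- explore_config(mode = "blind", df = 1.0, max_generations = 1,
                        cluster_seed = 2)
  tree <- run_exploration(hf$open, cfg)
  gen1 <- tree$generations[[2]]
  expect_gte(length(gen1), 0)
  expect_lte(length(gen1), 26)            # 3^3 - 1 deformations, 1 parent
  for (id in gen1) {
    c <- tree$nodes[[id]]
    expect_equal(c$parent_id, tree$root_id)
    expect_equal(c$generation, 1L)
    expect_length(c$coefficients, 3)
    expect_gt(c$rg, 0)
  }
})

test_that("the lineage tree is a single-rooted arborescence with unique ids", {
  tree <- get_run(1)
  ids <- names(tree$nodes)
  expect_equal(anyDuplicated(ids), 0)
  expect_equal(unlist(tree$generations), ids, ignore_attr = TRUE)
  expect_true(is.na(tree$nodes[[tree$root_id]]$parent_id))
  for (id in setdiff(ids, tree$root_id)) {
    p <- tree$nodes[[id]]$parent_id
    expect_true(p %in% ids)
    expect_equal(tree$nodes[[p]]$generation,
                 tree$nodes[[id]]$generation - 1L)
  }
  # per-generation counts bounded by parents x 26
  for (g in 2:length(tree$generations)) {
    n_parents <- length(tree$generations[[g - 1]])
    expect_lte(length(tree$generations[[g]]), n_parents * 26)
  }
})

test_that("energy filter equals the brute-force strict filter", {
  mk <- function(e, id) {
    structure(list(id = id, energy = e), class = "enx_conformer")
  }
  cands <- list(mk(-5, "a"), mk(0, "b"), mk(3, "c"))
  kept <- energy_filter(cands, 0)
  expect_equal(vapply(kept, function(c) c$id, ""), "a")
  expect_length(energy_filter(cands, -100), 0)

  es <- enmexplore:::.with_seed(7, stats::rnorm(100))
  cands2 <- lapply(seq_along(es), function(i) mk(es[i], paste0("x", i)))
  ref <- 0.2
  kept2 <- energy_filter(cands2, ref)
  expect_equal(vapply(kept2, function(c) c$energy, numeric(1)),
               es[es < ref])
})

test_that("RG filter keeps compact conformers with an inclusive boundary", {
  mk <- function(rg, id, rg_chain = c(A = rg)) {
    structure(list(id = id, rg = rg, rg_chain = rg_chain),
              class = "enx_conformer")
  }
  cands <- list(mk(9.8, "a"), mk(10.0, "b"), mk(10.2, "c"))
  kept <- rg_filter(cands, 10.0)
  expect_equal(vapply(kept, function(c) c$id, ""), c("a", "b"))
  expect_length(rg_filter(cands, 9.0), 0)

  # per-chain scope: "any" vs "all"
  dimer <- list(
    mk(9, "d1", c(A = 9.5, B = 10.5)),
    mk(9, "d2", c(A = 10.5, B = 10.5)),
    mk(9, "d3", c(A = 9.5, B = 9.5)))
  apo <- c(A = 10, B = 10)
  expect_equal(vapply(rg_filter(dimer, apo, scope = "per_chain"),
                      function(c) c$id, ""), c("d1", "d3"))
  expect_equal(vapply(rg_filter(dimer, apo, scope = "per_chain",
                                per_chain_rule = "all"),
                      function(c) c$id, ""), "d3")
})

test_that("docking chain walks parent edges from the lowest-RG conformer", {
  tree <- get_run(1)
  confs <- tree_conformers(tree, include_root = FALSE)
  filtered <- rg_filter(confs, tree$nodes[[tree$root_id]]$rg)
  expect_gt(length(filtered), 0)
  chain <- docking_chain(tree, filtered)

  # starts at the root, ends at the lowest-RG filtered conformer
  expect_equal(chain[[1]]$id, tree$root_id)
  rgs <- vapply(filtered, function(c) c$rg, numeric(1))
  ids <- vapply(filtered, function(c) c$id, "")
  expect_equal(chain[[length(chain)]]$id,
               unname(ids[order(rgs, ids)][1]))
  # every consecutive pair is a parent-child edge (independent check)
  for (k in 2:length(chain))
    expect_equal(chain[[k]]$parent_id, chain[[k - 1]]$id)

  # tie in RG resolves to the lowest conformer id
  a <- structure(list(id = "g1.c02", rg = 5), class = "enx_conformer")
  b <- structure(list(id = "g1.c01", rg = 5), class = "enx_conformer")
  t2 <- list(nodes = list(
    "g0.c01" = structure(list(id = "g0.c01", rg = 6,
                              parent_id = NA_character_),
                         class = "enx_conformer"),
    "g1.c01" = structure(list(id = "g1.c01", rg = 5,
                              parent_id = "g0.c01"),
                         class = "enx_conformer"),
    "g1.c02" = structure(list(id = "g1.c02", rg = 5,
                              parent_id = "g0.c01"),
                         class = "enx_conformer")),
    root_id = "g0.c01")
  class(t2) <- "enx_lineage"
  ch2 <- docking_chain(t2, list(a, b))
  expect_equal(ch2[[2]]$id, "g1.c01")
  expect_error(docking_chain(t2, list()), "empty")
})

test_that("energy-based mode stops when nothing beats the reference energy", {
  hf <- get_hinge(3)
  cfg <- explore_config(mode = "energy_based", df = 1.0,
                        max_generations = 4, cluster_seed = 3)
  tree <- run_exploration(hf$open, cfg)
  # the relaxed apo sits at the surrogate minimum, so no child can go
  # strictly below it: the run must end after one generation
  expect_equal(tree$stop_reason, "no_lower_energy")
  expect_lte(length(tree$generations), 2)
  e0 <- tree$reference_energy
  for (id in tree$generations[[2]])
    expect_gte(tree$nodes[[id]]$energy, e0)
})

test_that("identical config and seed reproduce the run exactly", {
  hf <- get_hinge(1)
  cfg <- explore_config(mode = "blind", df = 1.0, max_generations = 2,
                        cluster_seed = 1)
  t1 <- run_exploration(hf$open, cfg)
  t2 <- run_exploration(hf$open, cfg)
  expect_identical(names(t1$nodes), names(t2$nodes))
  expect_identical(t1$generations, t2$generations)
  for (id in names(t1$nodes)) {
    expect_identical(coords(t1$nodes[[id]]$structure),
                     coords(t2$nodes[[id]]$structure))
    expect_identical(t1$nodes[[id]]$energy, t2$nodes[[id]]$energy)
    expect_identical(t1$nodes[[id]]$parent_id, t2$nodes[[id]]$parent_id)
  }
})

test_that("re-seeding with a bound ligand extends the network and reports receptor metrics", {
  hf <- get_hinge(1)
  open <- hf$open
  ca <- ca_coords(open)
  pivot <- ca[30, ]
  pep_ca <- rbind(pivot + c(-3.8, 0, -7), pivot + c(0, 0, -8),
                  pivot + c(3.8, 0, -7))
  pep <- enmexplore:::.atoms_from_ca(pep_ca, chain = "B")
  pep$eleno <- pep$eleno + nrow(open$atoms)
  cplx <- enx_structure(rbind(open$atoms[, names(pep)], pep))
  expect_equal(n_residues(cplx), n_residues(open) + 3)

  cfg <- explore_config(mode = "blind", df = 1.0, max_generations = 1,
                        cluster_seed = 1, ligand_chains = "B")
  expect_error(
    reseed_with_ligand(cplx, explore_config(ligand_chains = "Z")),
    "not found")
  tree <- reseed_with_ligand(cplx, cfg, reference = hf$closed)

  # ligand residues are network nodes and deform with the receptor
  for (id in tree$generations[[2]]) {
    c <- tree$nodes[[id]]
    expect_equal(n_residues(c$structure), 63)
    # receptor-only RG excludes the ligand chain
    expect_equal(c$rg, radius_of_gyration(c$structure, chains = "A"),
                 tolerance = 1e-10)
    expect_true(all(c("A", "B") %in% names(c$rg_chain)))
  }

  # ligand-free reseed degenerates to the plain receptor run
  cfg0 <- explore_config(mode = "blind", df = 1.0, max_generations = 1,
                         cluster_seed = 1)
  ta <- reseed_with_ligand(open, cfg0)
  tb <- run_exploration(open, cfg0)
  expect_identical(names(ta$nodes), names(tb$nodes))
  expect_identical(lapply(ta$nodes, function(c) coords(c$structure)),
                   lapply(tb$nodes, function(c) coords(c$structure)))
})

test_that("run directories round-trip through write_run/load_run", {
  tree <- get_run(1)
  dir <- file.path(tempdir(), "runio_test")
  write_run(tree, dir, holo = get_hinge(1)$closed)
  expect_true(file.exists(file.path(dir, "lineage.json")))
  expect_true(file.exists(file.path(dir, "summary.tsv")))
  back <- load_run(dir)
  expect_identical(names(back$nodes), names(tree$nodes))
  expect_identical(back$generations, tree$generations)
  for (id in names(tree$nodes)) {
    expect_equal(coords(back$nodes[[id]]$structure),
                 coords(tree$nodes[[id]]$structure), tolerance = 1e-3)
    expect_equal(back$nodes[[id]]$energy, tree$nodes[[id]]$energy,
                 tolerance = 1e-12)
    expect_identical(back$nodes[[id]]$parent_id,
                     tree$nodes[[id]]$parent_id)
  }
  # parent walking works on the reloaded tree
  confs_back <- tree_conformers(back, include_root = FALSE)
  ch <- docking_chain(back, confs_back)
  expect_equal(ch[[1]]$id, back$root_id)
  # chain ensemble is a multi-model PDB
  confs <- tree_conformers(tree, include_root = FALSE)
  chain <- docking_chain(tree, confs)
  p <- file.path(dir, "chain.pdb")
  write_chain_ensemble(chain, p)
  expect_equal(sum(grepl("^MODEL", readLines(p))), length(chain))
})
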