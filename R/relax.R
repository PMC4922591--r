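.enx_backends <- new.env(parent = emptyenv())

#' Relaxation configuration
#'
#' Parameters of the energy-minimization stage. The `implicit_solvent`
#' backend follows the generalized-Born protocol contract (steepest
#' descent for `sd_steps` cycles, then conjugate gradient to
#' `gradient_tolerance`, nonbonded cutoff and Debye-Hueckel salt
#' screening as configured) and must be bound to a molecular-mechanics
#' engine via [register_relax_backend()]. The `fallback` backend
#' minimizes the package's surrogate potential -- harmonic pseudo-bonds
#' between sequential CA atoms at their reference distances plus
#' quadratic soft-sphere repulsion between heavy atoms of
#' non-adjacent residues -- which is sufficient for clash relief and
#' keeps the whole pipeline dependency-free. `none` evaluates the
#' surrogate energy without moving atoms.
#'
#' @param backend "fallback", "implicit_solvent" or "none"
#' @param sd_steps steepest-descent cycles before conjugate gradient
#'   (implicit-solvent protocol parameter; default 500)
#' @param gradient_tolerance convergence threshold on the energy
#'   gradient, kcal/mol/A scale (default 0.01)
#' @param nonbonded_cutoff nonbonded cutoff in Angstrom (default 16)
#' @param salt_concentration monovalent counter-ion concentration in M
#'   (default 0.1)
#' @param max_steps iteration cap for the gradient minimizer
#'   (default 10000)
#' @param k_bond pseudo-bond force constant, energy/A^2 (default 10)
#' @param k_rep soft-sphere repulsion constant, energy/A^2 (default 10)
#' @param sigma soft-sphere diameter in Angstrom (default 3.0)
#' @return enx_relax_config
#' @export
relax_config <- function(backend = c("fallback", "implicit_solvent", "none"),
                         sd_steps = 500L, gradient_tolerance = 0.01,
                         nonbonded_cutoff = 16, salt_concentration = 0.1,
                         max_steps = 10000L,
                         k_bond = 10, k_rep = 10, sigma = 3.0) {
  backend <- match.arg(backend)
  stopifnot(gradient_tolerance > 0, nonbonded_cutoff > 0, sigma > 0,
            k_bond >= 0, k_rep >= 0, max_steps >= 1)
  structure(list(backend = backend, sd_steps = as.integer(sd_steps),
                 gradient_tolerance = gradient_tolerance,
                 nonbonded_cutoff = nonbonded_cutoff,
                 salt_concentration = salt_concentration,
                 max_steps = as.integer(max_steps),
                 k_bond = k_bond, k_rep = k_rep, sigma = sigma),
            class = "enx_relax_config")
}

#' Register an external relaxation backend
#'
#' Binds an engine adapter: a function `(structure, config, reference)`
#' returning a list with `structure`, `energy` and `converged`. Used to
#' attach an implicit-solvent molecular-mechanics engine; the engine
#' preparation specifics live entirely inside the adapter.
#'
#' @param name backend identifier (e.g. "implicit_solvent")
#' @param fn adapter function
#' @export
register_relax_backend <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .enx_backends)
  invisible(NULL)
}

# Precompute the surrogate's index structures for one topology.
# Reference CA-CA distances come from `reference` (the parent
# conformer in the pipeline; the structure itself by default).
.surrogate_terms <- function(structure, reference, config) {
  at <- structure$atoms
  ca_rows <- which(at$elety == "CA")
  ca_chain <- at$chain[ca_rows]
  ca_i <- ca_rows[-length(ca_rows)]; ca_j <- ca_rows[-1]
  same <- ca_chain[-length(ca_chain)] == ca_chain[-1]
  ca_i <- ca_i[same]; ca_j <- ca_j[same]
  rxyz <- coords(reference)
  r0 <- sqrt(rowSums((rxyz[ca_j, , drop = FALSE] -
                      rxyz[ca_i, , drop = FALSE])^2))
  hv <- which(at$is_heavy)
  list(ca_i = as.integer(ca_i - 1L), ca_j = as.integer(ca_j - 1L), r0 = r0,
       heavy = as.integer(hv - 1L),
       res = as.integer(at$res_index[hv]),
       chain = as.integer(factor(at$chain[hv])))
}

.surrogate_energy <- function(xyz_flat, terms, config, grad = FALSE) {
  surrogate_eval(xyz_flat, terms$ca_i, terms$ca_j, terms$r0,
                 terms$heavy, terms$res, terms$chain,
                 config$k_bond, config$k_rep, config$sigma, grad)
}

#' Energy-minimize a conformer
#'
#' Relaxes a deformed structure to repair distortions and assigns it an
#' energy. Energies are comparable only within one backend; the
#' generation engine enforces a single backend per run.
#'
#' @param structure enx_structure to relax
#' @param config enx_relax_config
#' @param reference structure supplying the pseudo-bond reference
#'   distances for the surrogate potential (default: the input itself;
#'   the engine passes the parent conformer)
#' @return `enx_relax_result`: list with `structure` (minimized),
#'   `energy`, `converged` and `backend_used`. Non-convergence is
#'   reported, not raised; the engine discards such conformers.
#' @export
relax_minimize <- function(structure, config = relax_config(),
                           reference = structure) {
  stopifnot(inherits(structure, "enx_structure"),
            inherits(config, "enx_relax_config"))
  if (config$backend == "implicit_solvent") {
    fn <- .enx_backends[["implicit_solvent"]]
    if (is.null(fn))
      stop("backend 'implicit_solvent' requires a registered ",
           "molecular-mechanics adapter; none is registered ",
           "(see register_relax_backend)")
    r <- fn(structure, config, reference)
    return(structure(list(structure = r$structure, energy = r$energy,
                          converged = isTRUE(r$converged),
                          backend_used = "implicit_solvent"),
                     class = "enx_relax_result"))
  }
  terms <- .surrogate_terms(structure, reference, config)
  x0 <- as.numeric(t(coords(structure)))
  if (config$backend == "none") {
    e <- .surrogate_energy(x0, terms, config)$energy
    return(structure(list(structure = structure, energy = e,
                          converged = TRUE, backend_used = "none"),
                     class = "enx_relax_result"))
  }
  # verlet-style neighbor list for the repulsion term: rebuilt when any
  # coordinate drifts far enough that an unlisted pair could come
  # within range
  margin <- 2.0
  ev <- local({
    pairs <- NULL; x_build <- NULL; cache_p <- NULL; cache <- NULL
    function(p) {
      if (is.null(pairs) ||
          max(abs(p - x_build)) > margin / (2 * sqrt(3))) {
        pairs <<- surrogate_pairs(p, terms$heavy, terms$res, terms$chain,
                                  config$sigma, margin)
        x_build <<- p
      }
      if (is.null(cache_p) || !identical(p, cache_p)) {
        cache <<- surrogate_eval_pairs(p, terms$ca_i, terms$ca_j, terms$r0,
                                       pairs$i, pairs$j, config$k_bond,
                                       config$k_rep, config$sigma, TRUE)
        cache_p <<- p
      }
      cache
    }
  })
  fn <- function(p) ev(p)$energy
  gr <- function(p) ev(p)$gradient
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$max_steps,
                                     pgtol = config$gradient_tolerance,
                                     factr = 0))
  gmax <- max(abs(.surrogate_energy(opt$par, terms, config,
                                    grad = TRUE)$gradient))
  ok <- is.finite(opt$value) && gmax <= config$gradient_tolerance
  out <- set_coords(structure, matrix(opt$par, ncol = 3, byrow = TRUE))
  structure(list(structure = out, energy = opt$value, converged = ok,
                 backend_used = "fallback"),
            class = "enx_relax_result")
}

#' Single-point energy
#'
#' Potential energy of a structure without moving atoms, on the same
#' scale as [relax_minimize()] for the same backend.
#'
#' @inheritParams relax_minimize
#' @return numeric energy
#' @export
energy_of <- function(structure, config = relax_config(),
                      reference = structure) {
  stopifnot(inherits(structure, "enx_structure"))
  if (config$backend == "implicit_solvent") {
    fn <- .enx_backends[["implicit_solvent_energy"]]
    if (is.null(fn))
      stop("backend 'implicit_solvent' requires a registered ",
           "molecular-mechanics adapter; none is registered ",
           "(see register_relax_backend)")
    return(fn(structure, config, reference))
  }
  terms <- .surrogate_terms(structure, reference, config)
  .surrogate_energy(as.numeric(t(coords(structure))), terms, config)$energy
}
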