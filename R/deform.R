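#' Deformation specification
#'
#' Controls how slow modes are combined into deformation directions:
#' each direction is a tuple of coefficients (one per mode, drawn from
#' `alphabet`, the all-zero tuple excluded), each mode weighted by
#' 1/sqrt(eigenvalue) so softer modes contribute larger amplitude, and
#' the combined vector rescaled so the per-node displacement RMS equals
#' the deformation RMSD `df`.
#'
#' @param df deformation RMSD in Angstrom (default 2; 3 is the usual
#'   choice for very large transitions)
#' @param n_modes number of slow modes combined (default 3)
#' @param alphabet allowed coefficient values (default -1, 0, +1)
#' @return enx_deform_spec
#' @export
deform_spec <- function(df = 2.0, n_modes = 3, alphabet = c(-1, 0, 1)) {
  stopifnot(df > 0, n_modes >= 1, length(alphabet) >= 2)
  structure(list(df = df, n_modes = n_modes, alphabet = alphabet),
            class = "enx_deform_spec")
}

#' Enumerate all mode-combination deformation directions
#'
#' One direction per coefficient tuple in `alphabet^n_modes` minus the
#' all-zero tuple: with the default three modes and coefficients
#' \{-1, 0, +1\} that is 26 directions. Each raw vector is
#' `sum_j a_j u_j / sqrt(lambda_j)`, rescaled to norm `df * sqrt(N)` so
#' that the RMS displacement per node is exactly `df`.
#'
#' @param modes enx_modes from [slow_modes()]
#' @param spec enx_deform_spec
#' @return list of `enx_direction` objects, each with `coefficients`,
#'   `raw` and `scaled` (3N vectors); enumeration order is
#'   lexicographic over tuples with the first mode varying fastest
#' @export
enumerate_directions <- function(modes, spec = deform_spec()) {
  stopifnot(inherits(modes, "enx_modes"), inherits(spec, "enx_deform_spec"))
  m <- spec$n_modes
  if (modes$n_modes_kept < m)
    stop("spec asks for ", m, " modes but only ",
         modes$n_modes_kept, " kept")
  if (any(modes$eigenvalues[seq_len(m)] <= 0))
    stop("non-positive eigenvalue among combined modes")
  tuples <- as.matrix(expand.grid(rep(list(spec$alphabet), m)))
  tuples <- tuples[rowSums(tuples != 0) > 0, , drop = FALSE]
  scaled_u <- sweep(modes$eigenvectors[, seq_len(m), drop = FALSE], 2,
                    sqrt(modes$eigenvalues[seq_len(m)]), "/")
  target <- spec$df * sqrt(modes$n_nodes)
  lapply(seq_len(nrow(tuples)), function(k) {
    a <- as.numeric(tuples[k, ])
    raw <- as.numeric(scaled_u %*% a)
    structure(list(coefficients = a, raw = raw,
                   scaled = raw * (target / sqrt(sum(raw^2)))),
              class = "enx_direction")
  })
}

#' Apply a deformation direction to an all-atom structure
#'
#' The per-node displacement computed at residue centroids is applied as
#' a rigid translation to every atom of that residue, so local geometry
#' is preserved and the CA displacement RMSD from the parent (without
#' re-superposition) equals the deformation RMSD exactly.
#'
#' @param parent enx_structure
#' @param coarse enx_coarse built from `parent`
#' @param direction enx_direction from [enumerate_directions()]
#' @return deformed enx_structure
#' @export
apply_deformation <- function(parent, coarse, direction) {
  stopifnot(inherits(parent, "enx_structure"),
            inherits(coarse, "enx_coarse"),
            inherits(direction, "enx_direction"))
  n <- coarse$n_nodes
  if (length(direction$scaled) != 3 * n)
    stop("direction length ", length(direction$scaled),
         " does not match 3 x ", n, " nodes")
  disp <- matrix(direction$scaled, ncol = 3, byrow = TRUE)
  xyz <- coords(parent)
  xyz <- xyz + disp[parent$atoms$res_index, , drop = FALSE]
  set_coords(parent, xyz)
}

#' Raw per-CA displacement RMSD between two conformers of one topology
#'
#' Root-mean-square of the per-CA displacement without superposition;
#' verifies the fixed-magnitude deformation contract (a freshly deformed
#' child is exactly `df` from its parent by this measure).
#'
#' @param parent,child enx_structure objects with identical CA sets
#' @return RMSD in Angstrom
#' @export
deformation_rmsd <- function(parent, child) {
  a <- ca_coords(parent); b <- ca_coords(child)
  if (nrow(a) != nrow(b)) stop("CA count mismatch")
  sqrt(mean(rowSums((b - a)^2)))
}
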