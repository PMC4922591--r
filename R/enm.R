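#' Build the contact-weighted elastic network
#'
#' Residue-level anisotropic network in which the spring constant of a
#' residue pair is proportional to the number of their heavy-atom pairs
#' within the cutoff. This weighting lets well-packed interfaces resist
#' deformation more than loose contacts, unlike the uniform-spring
#' classical model.
#'
#' @param coarse enx_coarse from [coarse_grain()]
#' @param structure the enx_structure the coarse model was derived from
#'   (supplies the heavy-atom coordinates for contact counting)
#' @param cutoff contact cutoff in Angstrom (default 10)
#' @return An `enx_network`: list with `coarse`, `cutoff`, `weights`
#'   (data.frame `i`, `j`, `count`, i < j, counts >= 1) and `connected`
#'   (logical; FALSE triggers a warning, the caller decides how to
#'   proceed since a disconnected network has more than six zero modes).
#' @export
build_network <- function(coarse, structure, cutoff = 10) {
  stopifnot(inherits(coarse, "enx_coarse"),
            inherits(structure, "enx_structure"), cutoff > 0)
  at <- structure$atoms
  hv <- at$is_heavy
  trip <- contact_counts(cbind(at$x[hv], at$y[hv], at$z[hv]),
                         as.integer(at$res_index[hv]), cutoff)
  weights <- data.frame(i = trip$i, j = trip$j, count = trip$count)
  connected <- .network_connected(coarse$n_nodes, weights)
  if (!connected)
    warning("elastic network is disconnected at cutoff ", cutoff,
            " A; expect more than six zero modes")
  structure(list(coarse = coarse, cutoff = cutoff, weights = weights,
                 connected = connected),
            class = "enx_network")
}

# union-find connectivity over the weighted edges
.network_connected <- function(n, weights) {
  if (n == 1) return(TRUE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(weights))) {
    a <- find(weights$i[k]); b <- find(weights$j[k])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1
}

#' Assemble the anisotropic network Hessian
#'
#' Standard 3x3 super-element construction: for a connected pair (i, j)
#' with separation vector d, the off-diagonal block is
#' `-k_ij (d d^T) / |d|^2` and diagonal blocks accumulate the negated sum
#' of the off-diagonals of their row. `k_ij` is the contact count times a
#' uniform base force constant of 1 (only relative spring strengths
#' matter; deformation amplitudes are renormalised downstream).
#'
#' @param network enx_network
#' @return dense symmetric 3N x 3N matrix
#' @export
enm_hessian <- function(network) {
  stopifnot(inherits(network, "enx_network"))
  cent <- network$coarse$centroids
  n <- network$coarse$n_nodes
  H <- matrix(0, 3 * n, 3 * n)
  w <- network$weights
  for (k in seq_len(nrow(w))) {
    i <- w$i[k]; j <- w$j[k]
    d <- cent[j, ] - cent[i, ]
    dd <- sum(d * d)
    if (dd < 1e-12)
      stop("coincident centroids for connected residues ", i, " and ", j)
    blk <- -(w$count[k] / dd) * tcrossprod(d)
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    H[ri, rj] <- H[ri, rj] + blk
    H[rj, ri] <- H[rj, ri] + blk
    H[ri, ri] <- H[ri, ri] - blk
    H[rj, rj] <- H[rj, rj] - blk
  }
  H
}

#' Slowest nontrivial normal modes
#'
#' Eigendecomposition of the Hessian; the six near-zero rigid-body
#' eigenvalues are removed by a relative threshold and the next
#' `n_modes` eigenpairs are returned in ascending eigenvalue order.
#' For reproducibility each eigenvector's sign is fixed so its first
#' component of magnitude above 1e-8 is positive.
#'
#' @param hessian symmetric 3N x 3N matrix
#' @param n_modes number of slow modes to keep (default 3)
#' @param zero_tol relative threshold below which an eigenvalue counts as
#'   rigid-body (default 1e-8 of the largest eigenvalue)
#' @return An `enx_modes`: list with `eigenvalues` (length M, ascending,
#'   positive), `eigenvectors` (3N x M, orthonormal columns),
#'   `n_modes_kept`, `n_nodes`.
#' @export
slow_modes <- function(hessian, n_modes = 3, zero_tol = 1e-8) {
  stopifnot(n_modes >= 1)
  if (max(abs(hessian - t(hessian))) > 1e-8 * max(abs(hessian)))
    stop("hessian is not symmetric")
  e <- eigen(hessian, symmetric = TRUE)
  lam <- rev(e$values)            # ascending
  vec <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  thr <- zero_tol * max(abs(lam))
  n_zero <- sum(abs(lam) < thr)
  if (n_zero > 6)
    stop("network appears disconnected: ", n_zero,
         " near-zero modes (expected 6)")
  if (n_zero < 6)
    stop("fewer than six rigid-body modes (", n_zero,
         "); input is not a free-standing 3-D network")
  avail <- length(lam) - 6
  if (n_modes > avail)
    stop("requested ", n_modes, " modes but only ", avail, " available")
  keep <- (6 + 1):(6 + n_modes)
  vecs <- vec[, keep, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    v <- vecs[, k]
    lead <- which(abs(v) > 1e-8)[1]
    if (!is.na(lead) && v[lead] < 0) vecs[, k] <- -v
    vecs[, k] <- vecs[, k] / sqrt(sum(vecs[, k]^2))
  }
  structure(list(eigenvalues = lam[keep], eigenvectors = vecs,
                 n_modes_kept = n_modes, n_nodes = nrow(hessian) / 3),
            class = "enx_modes")
}

#' Overlap of a mode with a displacement
#'
#' Normalised inner product between a mode eigenvector and a 3N
#' displacement vector (e.g. the apo-to-holo transition over residue
#' nodes), in \[-1, 1\]. Both vectors must be expressed in the same frame;
#' superpose the end states first.
#'
#' @param mode numeric 3N vector
#' @param displacement numeric 3N vector
#' @return scalar overlap
#' @export
mode_overlap <- function(mode, displacement) {
  if (length(mode) != length(displacement))
    stop("length mismatch: ", length(mode), " vs ", length(displacement))
  nm <- sqrt(sum(mode^2)); nd <- sqrt(sum(displacement^2))
  if (nm < 1e-12 || nd < 1e-12) stop("zero-norm vector")
  sum(mode * displacement) / (nm * nd)
}
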