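# Synthetic all-atom fixtures: reduced poly-alanine-like residues
# (N, CA, C, O, CB) around a generated CA trace. Enough atoms for
# contact-count weighting and per-residue rigid shifts to be
# nontrivial, small enough for instant tests.

# Build backbone + CB atoms from a CA trace using a local frame per
# residue (tangent t, normal u, binormal v). Bond lengths approximate
# ideal values; chemical realism is not the goal.
.atoms_from_ca <- function(ca, chain = "A", resno = NULL) {
  n <- nrow(ca)
  if (is.null(resno)) resno <- seq_len(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p_prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - (ca[i + 1, ] - ca[i, ])
    p_next <- if (i < n) ca[i + 1, ] else ca[i, ] + (ca[i, ] - ca[i - 1, ])
    t <- p_next - p_prev; t <- t / sqrt(sum(t^2))
    w <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- w - sum(w * t) * t; u <- u / sqrt(sum(u^2))
    v <- c(t[2] * u[3] - t[3] * u[2],
           t[3] * u[1] - t[1] * u[3],
           t[1] * u[2] - t[2] * u[1])
    pos <- rbind(
      N  = ca[i, ] - 0.70 * t + 1.25 * u,
      CA = ca[i, ],
      C  = ca[i, ] + 0.70 * t + 1.35 * u,
      O  = ca[i, ] + 0.70 * t + 1.35 * u + 1.23 * v,
      CB = ca[i, ] - 1.32 * u + 0.77 * v
    )
    rows[[i]] <- data.frame(
      eleno = 0L, elety = rownames(pos),
      elesy = c("N", "C", "C", "O", "C"),
      resid = "ALA", chain = chain, resno = resno[i], insert = "",
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      stringsAsFactors = FALSE
    )
  }
  at <- do.call(rbind, rows)
  at$eleno <- seq_len(nrow(at))
  rownames(at) <- NULL
  at
}

#' Generate a synthetic poly-alanine-like chain
#'
#' Five atoms per residue (N, CA, C, O, CB) around an ideal helical or
#' extended CA trace, with a small seeded jitter so distinct seeds give
#' distinct but equivalent structures. Deterministic for a fixed seed.
#'
#' @param n_residues chain length (>= 2)
#' @param geometry "helix" (alpha-helical trace) or "extended"
#'   (zigzag strand)
#' @param seed integer RNG seed for the jitter
#' @return enx_structure with consecutive CA distances of about 3.8 A
#' @export
make_chain <- function(n_residues, geometry = c("helix", "extended"),
                       seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_residues < 2) stop("n_residues must be >= 2")
  i <- seq_len(n_residues)
  ca <- if (geometry == "helix") {
    ang <- (i - 1) * 100 * pi / 180
    cbind(2.3 * cos(ang), 2.3 * sin(ang), (i - 1) * 1.5)
  } else {
    cbind((i - 1) * 3.68, rep(c(0, 0.95), length.out = n_residues), 0)
  }
  ca <- ca + .with_seed(seed, matrix(stats::rnorm(3 * n_residues, 0, 0.02),
                                     ncol = 3))
  enx_structure(.atoms_from_ca(ca))
}

# CA positions along a spherical spiral of a (possibly z-flattened)
# sphere, sampled at fixed arc spacing, running pole to pole along the
# x axis. `from_pole` = -1 starts near the -x pole. The polar caps are
# trimmed (theta_min) because arc-length sampling through the pole
# produces sharp turns and steric collisions.
.domain_spiral <- function(n, radius, center, from_pole = -1L,
                           spacing = 3.8, turn_gap = 6.5, flatten_z = 1,
                           theta_min = 0.25) {
  a <- 2 * pi * radius / turn_gap      # total twist over the theta range
  th <- seq(theta_min, pi - theta_min, length.out = 20000)
  pts <- cbind(from_pole * radius * cos(th),
               radius * sin(th) * cos(a * th),
               flatten_z * radius * sin(th) * sin(a * th))
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  want <- (seq_len(n) - 1) * spacing
  if (max(want) > max(s))
    stop("domain radius too small for ", n, " residues")
  idx <- vapply(want, function(w) which.min(abs(s - w)), integer(1))
  sweep(pts[idx, , drop = FALSE], 2, center, "+")
}

#' Generate a two-domain hinge fixture
#'
#' Two compact globular domains (spherical-spiral CA traces, flattened
#' along z to split the two bending directions) joined by a 4-residue
#' linker bowed out of the bending plane, emulating the hinge-bending
#' closure of two-domain receptor proteins. The closed reference state
#' is a rigid rotation of the second domain (and the distal linker)
#' about the hinge axis -- perpendicular to the inter-domain axis,
#' through the linker -- with the angle solved numerically so the
#' superposed CA RMSD between open and closed states hits
#' `target_rmsd` to 0.1%. The geometry keeps non-adjacent heavy atoms
#' beyond the soft-sphere diameter, so both states sit at surrogate
#' energy zero.
#'
#' @param n_per_domain residues per domain (>= 10); total residue count
#'   is `2 * n_per_domain + 4`
#' @param target_rmsd open-to-closed CA RMSD in Angstrom
#' @param seed integer seed for the CA jitter
#' @return An `enx_hinge_fixture`: list with `open`, `closed`
#'   (enx_structure), `hinge_residues` (linker indices), `angle`
#'   (radians), `target_rmsd`, `seed`.
#' @export
make_hinge <- function(n_per_domain = 28, target_rmsd = 5.0, seed = 1L) {
  if (n_per_domain < 10) stop("n_per_domain must be >= 10")
  if (target_rmsd <= 0) stop("target_rmsd must be > 0")
  n <- n_per_domain
  turn_gap <- 6.5
  stretch_x <- 1.9
  radius <- sqrt(n * 3.8 * turn_gap / (4 * pi)) + 0.5
  gap <- 7.5                               # pole-to-pole separation
  c1 <- c(0, 0, 0)
  c2 <- c(2 * radius * stretch_x + gap, 0, 0)

  # domain 1 ends at its +x pole, domain 2 starts at its -x pole; the
  # short gap puts the facing caps in direct contact range, which
  # stiffens inter-domain twist so that hinge bending is the softest
  # motion; z-flattening splits the two bending directions; the
  # x-elongation lengthens the bending lever so the closing rotation
  # angle stays moderate for a given RMSD
  spiral <- function(from_pole, center) {
    pts <- .domain_spiral(n, radius, c(0, 0, 0), from_pole,
                          turn_gap = turn_gap, flatten_z = 0.70)
    pts[, 1] <- pts[, 1] * stretch_x
    sweep(pts, 2, center, "+")
  }
  d1 <- spiral(+1L, c1)
  d1 <- d1[rev(seq_len(n)), , drop = FALSE]
  d2 <- spiral(-1L, c2)
  p_end <- d1[n, ]; p_start <- d2[1, ]
  # linker bowed in +y so consecutive CA spacing stays near 3.8 A and
  # its nodes remain in contact range of both domains
  frac <- seq(0, 1, length.out = 6)
  linker_pts <- function(h) {
    cbind(p_end[1] + frac * (p_start[1] - p_end[1]),
          p_end[2] + frac * (p_start[2] - p_end[2]) + h * sin(pi * frac),
          p_end[3] + frac * (p_start[3] - p_end[3]))
  }
  seglen <- function(h) sum(sqrt(rowSums(diff(linker_pts(h))^2)))
  h <- stats::uniroot(function(h) seglen(h) - 5 * 3.8, c(0, 15))$root
  linker <- linker_pts(h)[2:5, , drop = FALSE]
  ca <- rbind(d1, linker, d2)
  ca <- ca + .with_seed(seed, matrix(stats::rnorm(3 * nrow(ca), 0, 0.05),
                                     ncol = 3))
  raw <- enx_structure(.atoms_from_ca(ca))
  # polish residual junction contacts down to surrogate energy zero
  open <- relax_minimize(raw, relax_config("fallback"))$structure

  hinge_idx <- n + 2L                     # second linker residue
  pivot <- ca_coords(open)[hinge_idx, ]
  rotate_closed <- function(angle) {
    # hinge axis: y, through the linker, perpendicular to the
    # inter-domain axis; the distal part swings in the xz plane
    Ry <- matrix(c(cos(angle), 0, -sin(angle),
                   0, 1, 0,
                   sin(angle), 0, cos(angle)), 3, 3)
    xyz <- coords(open)
    moving <- open$atoms$res_index > hinge_idx
    xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, pivot) %*%
                             Ry, 2, pivot, "+")
    set_coords(open, xyz)
  }
  relaxed_closed <- function(angle)
    relax_minimize(rotate_closed(angle), relax_config("fallback"),
                   reference = open)$structure
  f <- function(a) rmsd_ca(open, rotate_closed(a)) - target_rmsd
  upper <- 170 * pi / 180
  if (f(upper) < 0)
    stop("target_rmsd ", target_rmsd, " unreachable (angle > 170 deg)")
  angle <- stats::uniroot(f, c(0, upper), tol = 1e-6)$root
  closed <- relaxed_closed(angle)
  # clash polishing can nudge the RMSD; re-solve on the relaxed states
  # if it drifted outside half the stated 5% tolerance
  if (abs(rmsd_ca(open, closed) - target_rmsd) > 0.025 * target_rmsd) {
    f2 <- function(a) rmsd_ca(open, relaxed_closed(a)) - target_rmsd
    angle <- stats::uniroot(f2, c(0.5 * angle, min(upper, 1.5 * angle)),
                            tol = 1e-4)$root
    closed <- relaxed_closed(angle)
  }

  structure(list(open = open, closed = closed,
                 hinge_residues = (n + 1L):(n + 4L),
                 angle = angle, target_rmsd = target_rmsd, seed = seed),
            class = "enx_hinge_fixture")
}

#' Randomly perturb a structure
#'
#' Adds a seeded Gaussian rigid displacement per residue (all atoms of
#' a residue shifted together) with per-CA RMS approximately equal to
#' `magnitude`. Used to build controlled near-duplicate conformers in
#' clustering tests.
#'
#' @param structure enx_structure
#' @param magnitude target per-CA RMS displacement in Angstrom (>= 0)
#' @param seed integer seed
#' @return perturbed enx_structure
#' @export
perturb <- function(structure, magnitude, seed = 1L) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(structure)
  n <- n_residues(structure)
  disp <- .with_seed(seed,
                     matrix(stats::rnorm(3 * n, 0, magnitude / sqrt(3)),
                            ncol = 3))
  set_coords(structure,
             coords(structure) + disp[structure$atoms$res_index, ,
                                      drop = FALSE])
}
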