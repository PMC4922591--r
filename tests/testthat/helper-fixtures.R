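# Shared fixtures, memoised for the session so expensive objects
# (hinge fixtures, pipeline runs) are built once across test files.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

get_hinge <- function(seed = 1L, n = 28L, target = 5.0) {
  cached(sprintf("hinge_%d_%d_%g", seed, n, target),
         make_hinge(n, target, seed))
}

# a small blind hinge run shared by explore/eval tests
get_run <- function(seed = 1L, gens = 3L) {
  cached(sprintf("run_%d_%d", seed, gens), {
    hf <- get_hinge(seed)
    cfg <- explore_config(mode = "blind", df = 1.0, n_modes = 3,
                          max_generations = gens, cluster_seed = seed)
    run_exploration(hf$open, cfg, reference = hf$closed)
  })
}

# random rigid transform applied to a structure
random_rigid <- function(s, seed) {
  .with_seed <- enmexplore:::.with_seed
  q <- .with_seed(seed, stats::rnorm(4)); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    q[1]^2+q[2]^2-q[3]^2-q[4]^2, 2*(q[2]*q[3]-q[1]*q[4]), 2*(q[2]*q[4]+q[1]*q[3]),
    2*(q[2]*q[3]+q[1]*q[4]), q[1]^2-q[2]^2+q[3]^2-q[4]^2, 2*(q[3]*q[4]-q[1]*q[2]),
    2*(q[2]*q[4]-q[1]*q[3]), 2*(q[3]*q[4]+q[1]*q[2]), q[1]^2-q[2]^2-q[3]^2+q[4]^2
  ), 3, 3, byrow = TRUE)
  t <- .with_seed(seed + 1000L, stats::rnorm(3, 0, 10))
  set_coords(s, sweep(coords(s) %*% t(R), 2, t, "+"))
}

# brute-force minimum RMSD over rotations: multistart Nelder-Mead over
# Euler angles on centred point sets; independent of the analytic
# superposition used by the package
brute_force_rmsd <- function(a, b, n_starts = 40L) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1,0,0, 0,cx,sx, 0,-sx,cx), 3, 3)
    Ry <- matrix(c(cy,0,-sy, 0,1,0, sy,0,cy), 3, 3)
    Rz <- matrix(c(cz,sz,0, -sz,cz,0, 0,0,1), 3, 3)
    Rx %*% Ry %*% Rz
  }
  obj <- function(ang) sqrt(mean(rowSums((a %*% rot(ang) - b)^2)))
  starts <- enmexplore:::.with_seed(99L,
    matrix(stats::runif(3 * n_starts, -pi, pi), ncol = 3))
  best <- Inf
  for (i in seq_len(n_starts)) {
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  best
}

# tiny hand-written PDB text fixtures
write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}
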