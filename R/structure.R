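#' @useDynLib enmexplore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Elements heavier than hydrogen. Element symbols are normalised to
# upper case; "H" and "D" count as hydrogen.
.is_heavy_element <- function(elesy) {
  e <- toupper(trimws(elesy))
  !(e %in% c("H", "D", ""))
}

#' All-atom structure container
#'
#' An `enx_structure` holds an ordered atom table together with per-residue
#' bookkeeping. Residues are indexed by a contiguous internal index
#' (1..N, unique across chains); the author residue numbering of the source
#' PDB is preserved for I/O only.
#'
#' @param atoms data.frame with columns `eleno`, `elety` (atom name),
#'   `elesy` (element symbol), `resid` (residue name), `chain`, `resno`
#'   (author residue number), `insert`, `x`, `y`, `z`.
#' @return An object of class `enx_structure`: a list with `atoms`
#'   (the atom table plus `res_index` and `is_heavy` columns) and
#'   `residues` (one row per residue: `res_index`, `chain`, `resno`,
#'   `insert`, `resid`).
#' @export
enx_structure <- function(atoms) {
  need <- c("eleno", "elety", "elesy", "resid", "chain", "resno",
            "insert", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty atom table")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinates")
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "
  # residue key in order of first appearance; contiguous internal index
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  atoms$res_index <- match(key, unique(key))
  atoms$is_heavy <- .is_heavy_element(atoms$elesy)
  first <- !duplicated(atoms$res_index)
  residues <- data.frame(
    res_index = atoms$res_index[first],
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    insert = atoms$insert[first],
    resid = atoms$resid[first],
    stringsAsFactors = FALSE
  )
  n_heavy <- tapply(atoms$is_heavy, atoms$res_index, sum)
  if (any(n_heavy == 0))
    stop("residue(s) without heavy atoms: internal index ",
         paste(which(n_heavy == 0), collapse = ", "))
  structure(list(atoms = atoms, residues = residues),
            class = "enx_structure")
}

#' @export
print.enx_structure <- function(x, ...) {
  cat(sprintf("enx_structure: %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$residues$chain)),
              paste(unique(x$residues$chain), collapse = ",")))
  invisible(x)
}

#' Number of residues of a structure
#' @param x enx_structure
#' @return integer count
#' @export
n_residues <- function(x) nrow(x$residues)

#' Atom coordinates as an n x 3 matrix
#' @param x enx_structure
#' @return numeric matrix, one row per atom, in Angstrom
#' @export
coords <- function(x) {
  m <- cbind(x$atoms$x, x$atoms$y, x$atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace atom coordinates
#' @param x enx_structure
#' @param xyz n x 3 matrix matching the atom count
#' @return the structure with updated coordinates
#' @export
set_coords <- function(x, xyz) {
  stopifnot(nrow(xyz) == nrow(x$atoms), ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

#' Alpha-carbon coordinates
#'
#' One row per residue that has a CA atom, in residue order.
#'
#' @param x enx_structure
#' @param chains optional character vector restricting to these chain ids
#' @return matrix with rows named by internal residue index
#' @export
ca_coords <- function(x, chains = NULL) {
  sel <- x$atoms$elety == "CA"
  if (!is.null(chains)) sel <- sel & x$atoms$chain %in% chains
  if (!any(sel)) stop("no CA atoms in selection")
  m <- cbind(x$atoms$x[sel], x$atoms$y[sel], x$atoms$z[sel])
  rownames(m) <- x$atoms$res_index[sel]
  m
}

#' Read a PDB file
#'
#' Parses a PDB file via bio3d, resolving alternate locations to the
#' highest-occupancy copy (ties broken by altLoc label order) and dropping
#' non-standard HETATM records unless `keep_hetatm = TRUE`. Hydrogens are
#' retained but flagged (`is_heavy = FALSE`).
#'
#' @param path file path
#' @param model_index which MODEL to take from a multi-model file (1-based)
#' @param keep_hetatm keep HETATM records (waters are always dropped)
#' @return enx_structure
#' @export
read_pdb <- function(path, model_index = 1L, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unparseable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  nmod <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > nmod)
    stop("model_index ", model_index, " out of range (file has ",
         nmod, " model(s))")
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms after filtering in '", path, "'")
  # altLoc: keep highest occupancy per (chain,resno,insert,atom name),
  # ties by label order
  alt <- at$alt; alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o; occ[is.na(occ)] <- 1
    akey <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                  at$elety, sep = "|")
    ord <- order(akey, -occ, alt)
    keep_first <- !duplicated(akey[ord])
    at <- at[sort(ord[keep_first]), , drop = FALSE]
  }
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy) | trimws(elesy) == ""))
    elesy <- bio3d::atom2ele(at$elety)
  enx_structure(data.frame(
    eleno = at$eleno, elety = trimws(at$elety), elesy = trimws(elesy),
    resid = at$resid, chain = at$chain, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  ))
}

#' Write one or more structures to a PDB file
#'
#' Author residue numbering, chain ids and atom names are written as read.
#' A list of structures sharing one topology is written as a multi-MODEL
#' ensemble.
#'
#' @param x enx_structure, or a list of them with identical atom tables
#' @param path output file path
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "enx_structure")) x <- list(x)
  stopifnot(length(x) >= 1, all(vapply(x, inherits, TRUE, "enx_structure")))
  ref <- x[[1]]$atoms
  xyz <- do.call(rbind, lapply(x, function(s) as.vector(t(coords(s)))))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    eleno = ref$eleno, elety = ref$elety, resid = ref$resid,
    chain = ref$chain, resno = ref$resno,
    insert = ifelse(ref$insert == "", NA, ref$insert),
    elesy = ref$elesy, verbose = FALSE
  )
  invisible(NULL)
}

#' Coarse-grain a structure to residue centroids
#'
#' One node per residue at the arithmetic mean of its heavy-atom positions
#' (hydrogens excluded so that centroids do not depend on whether a model
#' was protonated).
#'
#' @param x enx_structure
#' @return An `enx_coarse` object: list with `centroids` (N x 3 matrix),
#'   `membership` (list mapping residue index -> atom row indices) and
#'   `n_nodes`.
#' @export
coarse_grain <- function(x) {
  stopifnot(inherits(x, "enx_structure"))
  at <- x$atoms
  n <- n_residues(x)
  hv <- at$is_heavy
  cx <- tapply(at$x[hv], at$res_index[hv], mean)
  cy <- tapply(at$y[hv], at$res_index[hv], mean)
  cz <- tapply(at$z[hv], at$res_index[hv], mean)
  idx <- as.integer(names(cx))
  cent <- matrix(NA_real_, n, 3)
  cent[idx, ] <- cbind(cx, cy, cz)
  if (any(is.na(cent))) stop("residue(s) without heavy atoms")
  membership <- split(seq_len(nrow(at)), at$res_index)
  structure(list(centroids = cent, membership = membership, n_nodes = n),
            class = "enx_coarse")
}

# Least-squares superposition of two point sets (rows paired).
# Returns rotation R and translation t such that  mobile %*% R + t  best
# fits reference, plus the residual RMSD. Hot path: the quaternion
# formulation compiled in src/.
.kabsch <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference), nrow(mobile) >= 3)
  kabsch_fit(mobile, reference)
}

# Reference implementation via base svd(); retained as an independent
# cross-check of the compiled quaternion path.
.kabsch_svd <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference), nrow(mobile) >= 3)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- A %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

#' Optimal rigid-body superposition
#'
#' Least-squares (Kabsch) fit of `mobile` onto `reference` over a selected
#' atom subset. The returned transform applies to coordinate rows as
#' `xyz %*% rotation + translation`.
#'
#' @param mobile,reference enx_structure objects
#' @param selection `"calpha"` (default) or `"heavy"`; both structures must
#'   yield the same number of selected atoms, paired by order
#' @return An `enx_superposition`: list with `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (Angstrom) and `selection`.
#' @export
superpose <- function(mobile, reference, selection = c("calpha", "heavy")) {
  selection <- match.arg(selection)
  pick <- function(s) {
    if (selection == "calpha") ca_coords(s)
    else coords(s)[s$atoms$is_heavy, , drop = FALSE]
  }
  m <- pick(mobile); r <- pick(reference)
  if (nrow(m) != nrow(r))
    stop("selection sizes differ: ", nrow(m), " vs ", nrow(r))
  if (nrow(m) < 3) stop("need at least 3 points to superpose")
  k <- .kabsch(m, r)
  structure(list(rotation = k$rotation, translation = k$translation,
                 rmsd = k$rmsd, selection = selection),
            class = "enx_superposition")
}

#' Apply a superposition transform to a structure
#' @param x enx_structure
#' @param sp enx_superposition
#' @return transformed structure
#' @export
apply_superposition <- function(x, sp) {
  set_coords(x, sweep(coords(x) %*% sp$rotation, 2, sp$translation, "+"))
}

# Pair two structures on their common author-numbered residue set and
# return the paired CA coordinate matrices. No sequence alignment: the
# intended use is crystal pairs / conformers of one sequence.
.paired_ca <- function(a, b, chains = NULL) {
  keyed <- function(s) {
    sel <- s$atoms$elety == "CA"
    if (!is.null(chains)) sel <- sel & s$atoms$chain %in% chains
    at <- s$atoms[sel, , drop = FALSE]
    list(key = paste(at$chain, at$resno, at$insert, sep = "|"),
         xyz = cbind(at$x, at$y, at$z))
  }
  ka <- keyed(a); kb <- keyed(b)
  common <- intersect(ka$key, kb$key)
  if (length(common) == 0) stop("no common CA residues between structures")
  list(a = ka$xyz[match(common, ka$key), , drop = FALSE],
       b = kb$xyz[match(common, kb$key), , drop = FALSE],
       n = length(common))
}

#' Alpha-carbon RMSD after optimal superposition
#'
#' Structures are paired on their common author-numbered residue set
#' (chain + residue number + insertion code); the minimum RMSD over rigid
#' transforms is returned. With `strict = TRUE` (used inside the engine,
#' where all conformers share one topology) differing CA counts are an
#' error rather than silently reduced.
#'
#' @param a,b enx_structure objects
#' @param chains optional chain subset (applied to both structures)
#' @param strict error if the structures do not share all CA residues
#' @return RMSD in Angstrom
#' @export
rmsd_ca <- function(a, b, chains = NULL, strict = FALSE) {
  p <- .paired_ca(a, b, chains)
  if (strict) {
    na <- sum(a$atoms$elety == "CA"); nb <- sum(b$atoms$elety == "CA")
    if (p$n != na || p$n != nb)
      stop("CA sets differ: ", na, " vs ", nb, " (", p$n, " common)")
  }
  if (p$n < 3) stop("fewer than 3 common CA residues")
  .kabsch(p$a, p$b)$rmsd
}

#' Radius of gyration over alpha carbons
#'
#' Mass-unweighted root-mean-square distance of CA atoms from their
#' centroid, the chain-compactness measure used for post-filtering.
#'
#' @param x enx_structure
#' @param chains optional chain subset
#' @return RG in Angstrom
#' @export
radius_of_gyration <- function(x, chains = NULL) {
  m <- ca_coords(x, chains)
  sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
}

#' Per-chain radius of gyration
#' @param x enx_structure
#' @return named numeric vector, one RG per chain
#' @export
rg_by_chain <- function(x) {
  ch <- unique(x$residues$chain)
  vapply(ch, function(c) radius_of_gyration(x, chains = c), numeric(1))
}
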