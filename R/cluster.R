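#' Pairwise CA RMSD matrix
#'
#' Symmetric matrix of superposed alpha-carbon RMSDs over a conformer
#' list sharing one topology.
#'
#' @param structures list of enx_structure
#' @return symmetric numeric matrix (Angstrom), zero diagonal
#' @export
pairwise_rmsd <- function(structures) {
  stopifnot(length(structures) >= 1)
  cas <- lapply(structures, ca_coords)
  n <- length(cas)
  nr <- vapply(cas, nrow, integer(1))
  if (length(unique(nr)) != 1) stop("conformers do not share topology")
  m <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- kabsch_rmsd(cas[[i]], cas[[j]])
  }
  dimnames(m) <- list(names(structures), names(structures))
  m
}

#' Clustering configuration
#'
#' @param radius cluster RMSD radius in Angstrom (the pipeline sets this
#'   to the deformation RMSD)
#' @param max_iterations reassignment-pass cap (default 100)
#' @param seed optional integer; if given, the initial assignment order
#'   is a seeded shuffle of the input order (default: input order)
#' @return enx_cluster_config
#' @export
cluster_config <- function(radius, max_iterations = 100L, seed = NULL) {
  stopifnot(radius > 0, max_iterations >= 1)
  structure(list(radius = radius,
                 max_iterations = as.integer(max_iterations), seed = seed),
            class = "enx_cluster_config")
}

# superpose each member's CA set onto the representative's, then average
.cluster_centroid <- function(cas, members, rep_idx) {
  ref <- cas[[rep_idx]]
  acc <- matrix(0, nrow(ref), 3)
  for (m in members) {
    k <- .kabsch(cas[[m]], ref)
    acc <- acc + sweep(cas[[m]] %*% k$rotation, 2, k$translation, "+")
  }
  acc / length(members)
}

#' Fixed-radius k-means clustering of conformers
#'
#' Radius-based variant of k-means on mutual CA RMSD: each conformer is
#' assigned to the nearest existing centroid if within `radius`,
#' otherwise it spawns a new cluster; centroids (mean CA coordinates of
#' the members after superposition onto the cluster representative) are
#' recomputed and assignment repeated until stable or `max_iterations`.
#' Deterministic for a fixed seed and input order. The averaged centroid
#' is used only for distances, never emitted as a conformer; the
#' representative is always a real member.
#'
#' @param structures list of enx_structure sharing one topology; names,
#'   if present, are used as conformer ids (default: "s1", "s2", ...)
#' @param config enx_cluster_config
#' @return list of `enx_cluster` objects (`member_ids`, `centroid`,
#'   `representative_id`, `rmsd_to_centroid` named per member), ordered
#'   by each cluster's first member in input order, with attribute
#'   `converged` (FALSE means the iteration cap was hit; a warning is
#'   raised and the last assignment returned)
#' @export
kcluster <- function(structures, config) {
  stopifnot(inherits(config, "enx_cluster_config"), length(structures) >= 1)
  ids <- names(structures)
  if (is.null(ids)) ids <- paste0("s", seq_along(structures))
  cas <- lapply(structures, ca_coords)
  if (length(unique(vapply(cas, nrow, integer(1)))) != 1)
    stop("conformers do not share topology")
  n <- length(cas)
  ord <- seq_len(n)
  if (!is.null(config$seed)) ord <- .with_seed(config$seed, sample(n))

  dist_to <- function(i, centroid) kabsch_rmsd(cas[[i]], centroid)

  # initial sequential assignment with spawn-on-overflow
  centroids <- list(); assign_vec <- integer(n)
  for (i in ord) {
    if (length(centroids) > 0) {
      d <- vapply(centroids, function(c) dist_to(i, c), numeric(1))
      k <- which.min(d)
    } else d <- Inf
    if (length(centroids) > 0 && d[k] <= config$radius) {
      assign_vec[i] <- k
    } else {
      centroids[[length(centroids) + 1]] <- cas[[i]]
      assign_vec[i] <- length(centroids)
    }
  }

  converged <- FALSE
  for (pass in seq_len(config$max_iterations)) {
    # recompute centroids from current membership
    for (k in seq_along(centroids)) {
      members <- which(assign_vec == k)
      if (length(members) == 0) next
      d <- vapply(members, function(i) dist_to(i, centroids[[k]]),
                  numeric(1))
      rep_idx <- members[which.min(d)]
      centroids[[k]] <- .cluster_centroid(cas, members, rep_idx)
    }
    new_assign <- assign_vec
    for (i in ord) {
      d <- vapply(centroids, function(c) dist_to(i, c), numeric(1))
      k <- which.min(d)
      if (d[k] <= config$radius) new_assign[i] <- k
      else {
        centroids[[length(centroids) + 1]] <- cas[[i]]
        new_assign[i] <- length(centroids)
      }
    }
    if (identical(new_assign, assign_vec)) { converged <- TRUE; break }
    assign_vec <- new_assign
  }
  if (!converged)
    warning("kcluster hit max_iterations without a stable assignment")

  # drop empty clusters, order by first member in input order
  occupied <- sort(unique(assign_vec))
  first_member <- vapply(occupied, function(k) min(which(assign_vec == k)),
                         integer(1))
  occupied <- occupied[order(first_member)]
  out <- lapply(occupied, function(k) {
    members <- which(assign_vec == k)
    d <- vapply(members, function(i) dist_to(i, centroids[[k]]),
                numeric(1))
    # representative: min RMSD to centroid, ties by lowest conformer id
    best <- members[order(d, ids[members])][1]
    names(d) <- ids[members]
    structure(list(member_ids = ids[members], centroid = centroids[[k]],
                   representative_id = ids[best], rmsd_to_centroid = d),
              class = "enx_cluster")
  })
  attr(out, "converged") <- converged
  out
}

#' Select next-generation representatives
#'
#' Returns the representative of every cluster that contains no parent
#' structure; clusters holding any parent are excluded so each
#' generation explores genuinely new territory. An empty result is valid
#' and terminates the generation loop upstream.
#'
#' @param clusters list of enx_cluster from [kcluster()]
#' @param parent_ids character vector of parent conformer ids
#' @return character vector of representative ids (possibly empty)
#' @export
select_representatives <- function(clusters, parent_ids) {
  reps <- vapply(clusters, function(cl) {
    if (any(cl$member_ids %in% parent_ids)) NA_character_
    else cl$representative_id
  }, character(1))
  reps[!is.na(reps)]
}

#' Cluster membership table
#'
#' Flat per-conformer view of a clustering for export.
#'
#' @param clusters list of enx_cluster
#' @return data.frame: conformer_id, cluster, rmsd_to_centroid,
#'   is_representative
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    data.frame(conformer_id = cl$member_ids, cluster = k,
               rmsd_to_centroid = as.numeric(cl$rmsd_to_centroid),
               is_representative = cl$member_ids == cl$representative_id,
               stringsAsFactors = FALSE)
  }))
}
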