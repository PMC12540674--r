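#' Daura-style greedy conformational clustering
#'
#' Two snapshots are neighbours when their pairwise RMSD is at or below the
#' threshold (the membership indicator is 1 for dRMSD <= threshold, 0
#' otherwise; the comparison is inclusive). The greedy procedure repeatedly
#' takes the unassigned snapshot with the most unassigned neighbours, forms
#' a cluster of it plus those neighbours, removes them, and repeats until
#' every snapshot is assigned. Neighbour-count ties are broken by the lowest
#' snapshot index, making the procedure deterministic.
#'
#' The default 1.7 Angstrom cutoff is the value commonly used to separate
#' functionally distinct states of a folded protein on C-alpha RMSD.
#'
#' @param m symmetric RMSD matrix (Angstrom, zero diagonal), e.g. from
#'   [rmsd_matrix()].
#' @param threshold neighbour cutoff in Angstrom (> 0), default 1.7.
#' @return An object of class `ClusterResult`: list with `threshold`,
#'   `clusters` (list of integer snapshot-index vectors, decreasing size),
#'   `centers` (the greedy seed snapshot of each cluster), `occupancy`
#'   (fractions summing to 1) and `membership` (per-snapshot cluster id).
#' @export
daura_cluster <- function(m, threshold = 1.7) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number (Angstrom)", call. = FALSE)
  m <- .check_rmsd_matrix(m)
  n <- nrow(m)
  adj <- m <= threshold          # inclusive indicator; diagonal TRUE
  unassigned <- rep(TRUE, n)
  clusters <- list()
  centers <- integer()
  while (any(unassigned)) {
    idx <- which(unassigned)
    counts <- colSums(adj[idx, idx, drop = FALSE])
    center <- idx[which.max(counts)]         # which.max: lowest index on ties
    members <- idx[adj[center, idx]]
    clusters[[length(clusters) + 1L]] <- members
    centers <- c(centers, center)
    unassigned[members] <- FALSE
  }
  ord <- order(-vapply(clusters, length, 1L))
  clusters <- clusters[ord]
  centers <- centers[ord]
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  out <- list(threshold = threshold, clusters = clusters, centers = centers,
              occupancy = vapply(clusters, length, 1L) / n,
              membership = membership)
  class(out) <- "ClusterResult"
  out
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult:", length(x$clusters), "cluster(s) at",
      x$threshold, "Angstrom; occupancies:",
      paste(sprintf("%.3f", x$occupancy), collapse = ", "), "\n")
  invisible(x)
}

#' Representative snapshot of a cluster
#'
#' The member with the lowest potential energy is designated the
#' representative conformation; energy ties are broken by the lowest
#' snapshot index.
#'
#' @param cluster integer vector of snapshot indices (non-empty).
#' @param energy per-snapshot potential energies (kcal/mol), either a
#'   vector indexed by snapshot number or a named vector/list.
#' @return the representative snapshot index.
#' @export
cluster_representative <- function(cluster, energy) {
  cluster <- as.integer(cluster)
  if (!length(cluster)) stop("empty cluster", call. = FALSE)
  e <- if (!is.null(names(energy))) {
    unlist(energy)[as.character(cluster)]
  } else {
    if (any(cluster > length(energy))) rep(NA_real_, length(cluster))
    else as.numeric(energy)[cluster]
  }
  if (any(is.na(e)))
    stop("energy missing for snapshot(s): ",
         paste(cluster[is.na(e)], collapse = ", "), call. = FALSE)
  cand <- cluster[e == min(e)]
  min(cand)
}

#' Representatives for every cluster of a ClusterResult
#'
#' @param cr a `ClusterResult`.
#' @param energy per-snapshot potential energies (kcal/mol).
#' @return integer vector, one representative snapshot per cluster.
#' @export
cluster_representatives <- function(cr, energy) {
  stopifnot(inherits(cr, "ClusterResult"))
  vapply(cr$clusters, cluster_representative, integer(1), energy = energy)
}
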