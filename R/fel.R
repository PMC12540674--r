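#' Principal component analysis of trajectory coordinates
#'
#' Frames are superposed onto their iteratively refined mean structure (so
#' global rotation/translation do not masquerade as internal motion), then
#' the Cartesian covariance of the selected atoms is eigen-decomposed.
#' PC1/PC2 projections serve as reaction coordinates for the free-energy
#' landscape. The covariance is mass-unweighted.
#'
#' @param traj a `Trajectory` with at least 3 frames.
#' @param selection optional override of the stored atom selection.
#' @return An object of class `PCAResult`: list with `mean_coords`
#'   (selection mean structure after fitting), `components` (orthonormal
#'   columns, 3m x n_comp), `variances` (eigenvalues, Angstrom^2,
#'   non-increasing) and `projections` (frames x components score matrix,
#'   centred).
#' @export
pca_project <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  sel <- if (is.null(selection)) traj$selection else as.integer(selection)
  if (length(traj$frames) < 3L)
    stop("need at least 3 frames for PCA", call. = FALSE)
  fitted <- .superpose_to_mean(traj, sel)
  X <- t(vapply(fitted, function(f) as.numeric(t(f)),
                numeric(3L * length(sel))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  if (sum(Xc^2) < 1e-12)
    stop("degenerate covariance: trajectory has zero total variance",
         call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  out <- list(mean_coords = matrix(mu, ncol = 3L, byrow = TRUE),
              components = pc$rotation,
              variances = pc$sdev^2,
              projections = pc$x)
  class(out) <- "PCAResult"
  out
}

#' @export
print.PCAResult <- function(x, ...) {
  v <- x$variances
  cat("PCAResult:", nrow(x$projections), "frames;",
      sprintf("PC1/PC2 variance fractions %.2f/%.2f\n",
              v[1] / sum(v), if (length(v) > 1) v[2] / sum(v) else 0))
  invisible(x)
}

#' Free-energy landscape by Boltzmann inversion of PC projections
#'
#' Bins the first two reaction coordinates into a 2-d histogram, normalises
#' it to a probability P per bin, and inverts through
#' `dG = -kB * T * ln P`, shifting so the lowest occupied bin sits at 0.
#' Empty bins are masked (`NA` free energy, `occupied = FALSE`) rather than
#' being assigned an infinite value.
#'
#' @param projections matrix (or data frame) whose first two columns are the
#'   reaction-coordinate samples, e.g. `pca_project(traj)$projections`;
#'   a single column gives a 1-row grid on the second axis.
#' @param T absolute temperature in K (default 300).
#' @param bins number of bins per axis (default 50), or a length-2 vector.
#' @return An object of class `FELGrid`: list with `xbreaks`, `ybreaks`,
#'   `P`, `dG` (kcal/mol, min occupied = 0), `occupied` (logical mask),
#'   `T`, `kB`.
#' @export
free_energy_landscape <- function(projections, T = 300, bins = 50) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("temperature must be a single positive number (K)", call. = FALSE)
  pr <- as.matrix(projections)
  if (nrow(pr) < 1L) stop("need at least one sample", call. = FALSE)
  if (ncol(pr) == 1L) pr <- cbind(pr, 0)
  bins <- rep(as.integer(bins), length.out = 2L)
  if (any(bins < 1L)) stop("bins must be >= 1 per axis", call. = FALSE)
  xbreaks <- .fel_breaks(pr[, 1L], bins[1L])
  ybreaks <- .fel_breaks(pr[, 2L], bins[2L])
  ix <- .fel_bin(pr[, 1L], xbreaks)
  iy <- .fel_bin(pr[, 2L], ybreaks)
  counts <- matrix(0, bins[1L], bins[2L])
  for (s in seq_len(nrow(pr))) {
    counts[ix[s], iy[s]] <- counts[ix[s], iy[s]] + 1
  }
  P <- counts / sum(counts)
  occupied <- P > 0
  dG <- matrix(NA_real_, bins[1L], bins[2L])
  dG[occupied] <- -kB_kcal * T * log(P[occupied])
  dG <- dG - min(dG, na.rm = TRUE)
  out <- list(xbreaks = xbreaks, ybreaks = ybreaks, P = P, dG = dG,
              occupied = occupied, T = T, kB = kB_kcal)
  class(out) <- "FELGrid"
  out
}

.fel_breaks <- function(v, nb) {
  r <- range(v)
  if (diff(r) == 0) r <- r + c(-0.5, 0.5)
  seq(r[1L], r[2L], length.out = nb + 1L)
}

.fel_bin <- function(v, breaks) {
  i <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(i, 1L), length(breaks) - 1L)
}

#' @export
print.FELGrid <- function(x, ...) {
  cat("FELGrid:", nrow(x$P), "x", ncol(x$P), "bins at", x$T, "K;",
      sum(x$occupied), "occupied; max dG",
      sprintf("%.2f kcal/mol\n", max(x$dG, na.rm = TRUE)))
  invisible(x)
}

#' Extract free-energy basins from an FEL grid
#'
#' A basin minimum is an occupied bin that is no higher than any of its
#' occupied 8-neighbours; every occupied bin is assigned to a basin by
#' steepest descent on the grid (repeatedly stepping to the lowest
#' neighbouring bin). Basins are ranked by the free energy of their
#' minimum; grid-index order breaks exact ties, so flat degenerate grids
#' resolve deterministically. At most `k` basins are returned.
#'
#' @param grid an `FELGrid`.
#' @param k maximum number of basins (>= 1).
#' @return list of basins, each a list with `minimum` (bin index pair),
#'   `min_dG`, `members` (2-column matrix of bin indices) and `depth`
#'   (max member dG - min_dG).
#' @export
find_basins <- function(grid, k = 3L) {
  stopifnot(inherits(grid, "FELGrid"))
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  occ <- which(grid$occupied, arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("grid has no occupied bin", call. = FALSE)
  nr <- nrow(grid$dG); nc <- ncol(grid$dG)
  # steepest-descent target of each occupied bin (itself if local minimum)
  descend1 <- function(i, j) {
    best <- c(i, j); bestv <- grid$dG[i, j]
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
          isTRUE(grid$occupied[ii, jj]) && grid$dG[ii, jj] < bestv) {
        bestv <- grid$dG[ii, jj]; best <- c(ii, jj)
      }
    }
    best
  }
  sink_of <- matrix(NA_integer_, nr, nc)   # linear index of basin minimum
  for (r in seq_len(nrow(occ))) {
    cur <- c(occ[r, 1L], occ[r, 2L])
    for (step in seq_len(nr * nc)) {       # bounded walk
      nxt <- descend1(cur[1L], cur[2L])
      if (all(nxt == cur)) break
      cur <- nxt
    }
    sink_of[occ[r, 1L], occ[r, 2L]] <- (cur[2L] - 1L) * nr + cur[1L]
  }
  sinks <- sort(unique(sink_of[!is.na(sink_of)]))
  min_dG <- grid$dG[sinks]
  ord <- order(min_dG, sinks)              # ties -> lowest linear bin index
  sinks <- sinks[ord][seq_len(min(length(sinks), k))]
  lapply(sinks, function(s) {
    mem <- which(sink_of == s, arr.ind = TRUE)
    list(minimum = c((s - 1L) %% nr + 1L, (s - 1L) %/% nr + 1L),
         min_dG = grid$dG[s],
         members = unname(mem),
         depth = max(grid$dG[(mem[, 2L] - 1L) * nr + mem[, 1L]]) - grid$dG[s])
  })
}
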