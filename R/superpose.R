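#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `R %*% x + t` over atoms of `mobile` against `reference`, via SVD of the
#' 3x3 cross-covariance matrix with the usual determinant correction, so a
#' reflection is never returned.
#'
#' @param mobile,reference numeric n x 3 coordinate matrices (Angstrom) with
#'   the same n >= 3.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) such
#'   that `mobile %*% t(rotation) + translation` is the fitted copy, and
#'   `rmsd` (Angstrom), the least-squares minimum over rigid motions.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("coordinate sets must be n x 3", call. = FALSE)
  if (nrow(mobile) != nrow(reference))
    stop("point counts differ (", nrow(mobile), " vs ", nrow(reference), ")",
         call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for superposition", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
  if (max(abs(P)) < 1e-12 && max(abs(Q)) < 1e-12)
    stop("degenerate input: all points coincide", call. = FALSE)
  H <- crossprod(P, Q)                     # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum((fitted - Q)^2) / n)
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

# rmsd only, skipping list assembly (hot path for matrices); residuals are
# computed explicitly rather than via the trace identity, which cancels
# catastrophically for near-identical frames
.kabsch_rmsd <- function(P, Q) {
  # P, Q already centred
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(sum((P %*% t(R) - Q)^2) / nrow(P))
}

#' All-against-all RMSD matrix of a trajectory
#'
#' Entry (i, j) is the Kabsch-minimised RMSD between frames i and j on the
#' trajectory's atom selection (C-alpha by default). This is the N x N
#' matrix fed to [daura_cluster()].
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param selection optional override of the stored atom selection.
#' @return symmetric numeric matrix (Angstrom), zero diagonal, class
#'   `RMSDMatrix`.
#' @export
rmsd_matrix <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  sel <- if (is.null(selection)) traj$selection else as.integer(selection)
  if (!length(sel)) stop("empty atom selection", call. = FALSE)
  if (any(sel < 1L) || any(sel > nrow(traj$atoms)))
    stop("selection indices out of range", call. = FALSE)
  nf <- length(traj$frames)
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  centred <- lapply(traj$frames, function(f) {
    x <- f[sel, , drop = FALSE]
    sweep(x, 2L, colMeans(x))
  })
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    Pi <- centred[[i]]
    for (j in (i + 1L):nf) {
      m[i, j] <- m[j, i] <- .kabsch_rmsd(Pi, centred[[j]])
    }
  }
  class(m) <- c("RMSDMatrix", class(m))
  m
}

.check_rmsd_matrix <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m)) stop("RMSD matrix must be square", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("RMSD matrix entries must be finite and >= 0", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-9)
    stop("RMSD matrix is not symmetric", call. = FALSE)
  if (max(abs(diag(m))) > 1e-9)
    stop("RMSD matrix diagonal is not zero", call. = FALSE)
  m
}

# superpose every frame onto the iterated mean structure of the selection;
# returns list of fitted selection-coordinate matrices
.superpose_to_mean <- function(traj, sel, iter = 2L) {
  frames <- lapply(traj$frames, function(f) f[sel, , drop = FALSE])
  ref <- frames[[1L]]
  for (k in seq_len(iter)) {
    fitted <- lapply(frames, function(f) {
      fit <- kabsch_superpose(f, ref)
      sweep(f %*% t(fit$rotation), 2L, fit$translation, `+`)
    })
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  lapply(frames, function(f) {
    fit <- kabsch_superpose(f, ref)
    sweep(f %*% t(fit$rotation), 2L, fit$translation, `+`)
  })
}

#' Per-atom root mean square fluctuation
#'
#' Frames are first superposed onto their (iteratively refined) mean
#' structure, removing global translation/rotation; the RMSF of atom i is
#' then the square root of its mean squared deviation from its time-average
#' position, i.e. an isotropic 3-d fluctuation amplitude.
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param selection optional override of the stored atom selection.
#' @param fit superpose frames onto the mean structure first (default TRUE).
#' @return numeric vector of fluctuations (Angstrom), one per selected atom.
#' @export
rmsf <- function(traj, selection = NULL, fit = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  sel <- if (is.null(selection)) traj$selection else as.integer(selection)
  if (!length(sel)) stop("empty atom selection", call. = FALSE)
  if (length(traj$frames) < 2L)
    stop("fluctuation undefined for a single frame", call. = FALSE)
  fitted <- if (fit) .superpose_to_mean(traj, sel)
            else lapply(traj$frames, function(f) f[sel, , drop = FALSE])
  mean_xyz <- Reduce(`+`, fitted) / length(fitted)
  msd <- Reduce(`+`, lapply(fitted, function(f) rowSums((f - mean_xyz)^2))) /
    length(fitted)
  sqrt(msd)
}
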