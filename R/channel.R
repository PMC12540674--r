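#' Pore-radius profile of a channel along an axis
#'
#' At each station (a point on the straight axis between the two
#' endpoints), the pore radius is the radius of the largest sphere that can
#' be centred in the plane perpendicular to the axis without touching any
#' atom, atoms being hard spheres of their van der Waals radius:
#' `radius(c) = min_i ( |c - x_i| - r_i )`, maximised over candidate
#' centres `c` in a search disc around the axis. The optimiser is a coarse
#' grid followed by a refined local grid (planar variant of the classic
#' pore-profiling algorithm; the centre is not allowed to wander along the
#' axis). A station whose best value is negative is flagged blocked.
#'
#' @param s a `Structure` with vdW radii.
#' @param axis 2 x 3 matrix (or list of two 3-vectors): axis endpoints,
#'   Angstrom.
#' @param n_stations number of stations, evenly spaced endpoint to endpoint.
#' @param search coarse grid spacing in the plane, Angstrom (default 0.5).
#' @param refine fine grid spacing for local refinement (default 0.02).
#' @param disc search-disc radius around the axis, Angstrom (default 15).
#' @return An object of class `PoreProfile`: data frame with `station`
#'   (position along the axis from the first endpoint), `radius`, centre
#'   coordinates `cx, cy, cz`, and `blocked`.
#' @export
pore_radius_profile <- function(s, axis, n_stations = 50, search = 0.5,
                                refine = 0.02, disc = 15) {
  stopifnot(inherits(s, "Structure"))
  if (nrow(s$atoms) == 0L) stop("empty structure", call. = FALSE)
  if (is.null(s$vdw)) stop("structure carries no vdW radii", call. = FALSE)
  if (is.list(axis) && !is.matrix(axis)) axis <- do.call(rbind, axis)
  axis <- as.matrix(axis)
  if (!all(dim(axis) == c(2L, 3L)))
    stop("axis must be two 3-d endpoints", call. = FALSE)
  v <- axis[2L, ] - axis[1L, ]
  L <- sqrt(sum(v^2))
  if (L < 1e-9) stop("axis endpoints coincide", call. = FALSE)
  u <- v / L
  # in-plane orthonormal basis
  a <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2L] * e1[3L] - u[3L] * e1[2L],
          u[3L] * e1[1L] - u[1L] * e1[3L],
          u[1L] * e1[2L] - u[2L] * e1[1L])
  stations <- seq(0, L, length.out = n_stations)
  X <- s$coords; r <- s$vdw

  clearance <- function(centres) {
    # centres: m x 3; returns per-centre min_i(|c - x_i| - r_i)
    best <- rep(Inf, nrow(centres))
    for (j in seq_len(nrow(X))) {
      dj <- sqrt((centres[, 1L] - X[j, 1L])^2 + (centres[, 2L] - X[j, 2L])^2 +
                   (centres[, 3L] - X[j, 3L])^2) - r[j]
      best <- pmin(best, dj)
    }
    best
  }
  grid_pts <- function(p0, half, step) {
    g <- seq(-half, half, by = step)
    gg <- expand.grid(a = g, b = g)
    keep <- gg$a^2 + gg$b^2 <= (half + step)^2
    gg <- gg[keep, , drop = FALSE]
    sweep(outer(gg$a, e1) + outer(gg$b, e2), 2L, p0, `+`)
  }

  out <- data.frame(station = stations, radius = NA_real_, cx = NA_real_,
                    cy = NA_real_, cz = NA_real_, blocked = FALSE)
  for (k in seq_len(n_stations)) {
    p0 <- axis[1L, ] + stations[k] * u
    cand <- grid_pts(p0, disc, search)
    f <- clearance(cand)
    best <- cand[which.max(f), ]
    # local refinement around the coarse optimum
    cand2 <- grid_pts(best, search, refine)
    f2 <- clearance(cand2)
    i2 <- which.max(f2)
    out$radius[k] <- f2[i2]
    out[k, c("cx", "cy", "cz")] <- cand2[i2, ]
    out$blocked[k] <- f2[i2] < 0
  }
  class(out) <- c("PoreProfile", class(out))
  out
}
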