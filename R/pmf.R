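#' Specification of a harmonic steered-pulling protocol
#'
#' The guiding potential drags an attachment point along direction `n` at
#' constant speed `v` from `X0`, restrained by a spring of stiffness `k`.
#'
#' @param k spring constant, kcal/mol/A^2 (> 0). The conventional setting
#'   for slow protein-ligand pulling is 2.5.
#' @param v pulling speed, A/ns (conventional setting 1).
#' @param n unit direction 3-vector (|n| must be 1 to 1e-9).
#' @param X0 initial attachment coordinate (3-vector, Angstrom).
#' @return An object of class `PullingSpec`.
#' @export
pulling_spec <- function(k = 2.5, v = 1, n = c(0, 0, 1), X0 = c(0, 0, 0)) {
  if (!is.numeric(k) || k <= 0) stop("spring constant k must be > 0",
                                     call. = FALSE)
  n <- as.numeric(n); X0 <- as.numeric(X0)
  if (length(n) != 3L || abs(sqrt(sum(n^2)) - 1) > 1e-9)
    stop("n must be a unit 3-vector", call. = FALSE)
  out <- list(k = k, v = v, n = n, X0 = X0)
  class(out) <- "PullingSpec"
  out
}

#' Guiding potential energy and spring force during pulling
#'
#' At time `t` the schedule point has advanced `v*t` along `n`; the lag of
#' the pulled coordinate behind schedule is
#' `lag = v*t - (X_t - X0) . n`. Then `U = k/2 * lag^2` and the force on
#' the pulled atom has magnitude `k * |lag|`, directed along `n` toward the
#' schedule point (i.e. `F = k * lag * n`).
#'
#' @param spec a `PullingSpec`.
#' @param t time in ns (>= 0).
#' @param X_t current attachment coordinate (3-vector, Angstrom).
#' @return list with `U` (kcal/mol), `F` (3-vector, kcal/mol/A) and `lag`
#'   (Angstrom).
#' @export
guiding_energy_force <- function(spec, t, X_t) {
  stopifnot(inherits(spec, "PullingSpec"))
  if (!is.numeric(t) || t < 0) stop("t must be >= 0", call. = FALSE)
  X_t <- as.numeric(X_t)
  lag <- spec$v * t - sum((X_t - spec$X0) * spec$n)
  list(U = 0.5 * spec$k * lag^2, F = spec$k * lag * spec$n, lag = lag)
}

#' Ensemble of nonequilibrium work curves over reaction-coordinate segments
#'
#' The reaction coordinate is partitioned into segments
#' `boundaries[1] ... boundaries[N'+1]`; each segment holds one or more
#' trajectories, each an accumulated-work curve starting at 0 at the
#' segment's left boundary.
#'
#' @param boundaries increasing reaction-coordinate values (Angstrom),
#'   length N'+1.
#' @param segments list of length N'; element i is a list with `xi`
#'   (grid from `boundaries[i]` to `boundaries[i+1]`) and `W` (matrix,
#'   trajectories x grid, kcal/mol, first column all 0).
#' @param beta inverse temperature 1/(kB*T), mol/kcal.
#' @return An object of class `WorkEnsemble`.
#' @export
work_ensemble <- function(boundaries, segments, beta) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L || any(diff(boundaries) <= 0))
    stop("boundaries must be increasing with at least one segment",
         call. = FALSE)
  if (length(segments) != length(boundaries) - 1L)
    stop("segment count != length(boundaries) - 1", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    sg$W <- as.matrix(sg$W)
    if (!nrow(sg$W)) stop("segment ", i, " has no trajectory", call. = FALSE)
    if (length(sg$xi) != ncol(sg$W))
      stop("segment ", i, ": xi grid and W columns differ", call. = FALSE)
    if (abs(sg$xi[1L] - boundaries[i]) > 1e-9 ||
        abs(sg$xi[length(sg$xi)] - boundaries[i + 1L]) > 1e-9)
      stop("segment ", i, " grid does not span its boundaries", call. = FALSE)
    if (max(abs(sg$W[, 1L])) > 1e-9)
      stop("segment ", i, ": work curves must start at 0", call. = FALSE)
    segments[[i]] <- sg
  }
  out <- list(boundaries = boundaries, segments = segments, beta = beta)
  class(out) <- "WorkEnsemble"
  out
}

#' Jarzynski free-energy estimate for one segment
#'
#' `dG = -(1/beta) * ln < exp(-beta * W) >` over the segment's final work
#' values, evaluated with a log-sum-exp reduction so large `beta*W` does
#' not underflow the naive average.
#'
#' @param works final accumulated work of each trajectory, kcal/mol.
#' @param beta inverse temperature, mol/kcal.
#' @return segment free-energy change, kcal/mol.
#' @export
jarzynski_segment <- function(works, beta) {
  works <- as.numeric(works)
  if (!length(works)) stop("no work values", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  x <- -beta * works
  m <- max(x)
  -(m + log(mean(exp(x - m)))) / beta
}

#' Stitch a segmented work ensemble into a PMF profile
#'
#' Per segment, the free-energy change is the Jarzynski exponential average
#' of the final works; the total profile accumulates these across segments
#' (adaptive steered-MD contraction). Within a segment the curve follows
#' the seed trajectory — the one whose final work is closest to the
#' segment's Jarzynski estimate (ties to the lowest trajectory index) —
#' shifted to the running total, so the profile is continuous across
#' boundaries by construction and starts at 0.
#'
#' @param e a `WorkEnsemble`.
#' @return An object of class `PMFProfile`: list with `xi`, `dG`,
#'   `segment_dG` and `seed_index` (one per segment).
#' @export
asmd_stitch <- function(e) {
  stopifnot(inherits(e, "WorkEnsemble"))
  xi_all <- numeric(); dG_all <- numeric()
  seg_dG <- numeric(); seeds <- integer()
  offset <- 0
  for (i in seq_along(e$segments)) {
    sg <- e$segments[[i]]
    finals <- sg$W[, ncol(sg$W)]
    dGi <- jarzynski_segment(finals, e$beta)
    seed <- which.min(abs(finals - dGi))    # which.min: lowest index on ties
    # seed curve carries the within-segment shape; a linear ramp absorbs the
    # (small) mismatch between its final work and the Jarzynski estimate so
    # segment endpoints sit exactly on the cumulative JA totals
    u <- (sg$xi - sg$xi[1L]) / (sg$xi[length(sg$xi)] - sg$xi[1L])
    curve <- sg$W[seed, ] + (dGi - finals[seed]) * u + offset
    keep <- if (i == 1L) seq_along(sg$xi) else seq_along(sg$xi)[-1L]
    xi_all <- c(xi_all, sg$xi[keep]); dG_all <- c(dG_all, curve[keep])
    seg_dG <- c(seg_dG, dGi); seeds <- c(seeds, seed)
    offset <- offset + dGi
  }
  out <- list(xi = xi_all, dG = dG_all, segment_dG = seg_dG,
              seed_index = seeds)
  class(out) <- "PMFProfile"
  out
}

#' @export
print.PMFProfile <- function(x, ...) {
  cat("PMFProfile:", length(x$xi), "points,",
      length(x$segment_dG), "segment(s); total dG",
      sprintf("%.3f kcal/mol\n", sum(x$segment_dG)))
  invisible(x)
}

#' One umbrella-sampling window
#'
#' @param centre harmonic bias centre, Angstrom.
#' @param spring bias spring constant, kcal/mol/A^2.
#' @param breaks shared histogram bin edges over the reaction coordinate.
#' @param counts per-bin sample counts (length `length(breaks) - 1`,
#'   non-negative, at least one positive).
#' @return An object of class `UmbrellaWindow`.
#' @export
umbrella_window <- function(centre, spring, breaks, counts) {
  breaks <- as.numeric(breaks); counts <- as.numeric(counts)
  if (length(counts) != length(breaks) - 1L)
    stop("counts length must be length(breaks) - 1", call. = FALSE)
  if (any(counts < 0) || !any(counts > 0))
    stop("histogram needs non-negative counts, at least one positive",
         call. = FALSE)
  out <- list(centre = centre, spring = spring, breaks = breaks,
              counts = counts)
  class(out) <- "UmbrellaWindow"
  out
}

#' 1-d weighted histogram analysis (WHAM)
#'
#' Self-consistent unbiasing of overlapping harmonic-window histograms:
#' iterate the coupled equations for the unbiased bin probabilities and the
#' per-window free energies until the largest window free-energy change
#' drops below `tol`, then return `-kB*T*ln P` shifted to minimum 0.
#' All windows must share one set of bin edges.
#'
#' @param windows list of `UmbrellaWindow` objects (>= 1) with overlapping
#'   coverage.
#' @param T temperature, K.
#' @param tol convergence tolerance on window free energies, kcal/mol.
#' @param max_iter iteration cap.
#' @return a `PMFProfile` over the occupied bins (with `f_window` attached).
#' @export
wham_1d <- function(windows, T = 300, tol = 1e-6, max_iter = 1e5) {
  if (!length(windows)) stop("need at least one window", call. = FALSE)
  lapply(windows, function(w) stopifnot(inherits(w, "UmbrellaWindow")))
  breaks <- windows[[1L]]$breaks
  for (w in windows) if (!isTRUE(all.equal(w$breaks, breaks)))
    stop("all windows must share one set of bin edges", call. = FALSE)
  beta <- beta_from_T(T)
  mid <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  counts <- do.call(rbind, lapply(windows, `[[`, "counts"))  # win x bin
  Nw <- rowSums(counts)
  occupied <- colSums(counts) > 0
  if (length(windows) > 1L) {
    # overlap check: consecutive (by centre) windows must share occupied bins
    ordc <- order(vapply(windows, `[[`, numeric(1), "centre"))
    for (k in seq_len(length(ordc) - 1L)) {
      if (!any(counts[ordc[k], ] > 0 & counts[ordc[k + 1L], ] > 0))
        warning("windows ", ordc[k], " and ", ordc[k + 1L],
                " share no occupied bin; coverage gap", call. = FALSE)
    }
  }
  # bias energy of each window at each bin centre
  U <- t(vapply(windows, function(w) 0.5 * w$spring * (mid - w$centre)^2,
                numeric(length(mid))))
  expU <- exp(-beta * U)
  f <- numeric(length(windows))            # window free energies, kcal/mol
  for (it in seq_len(max_iter)) {
    denom <- colSums(Nw * exp(beta * f) * expU)   # per bin
    P <- ifelse(occupied & denom > 0, colSums(counts) / denom, 0)
    Z <- drop(expU %*% P)
    f_new <- -log(Z) / beta
    f_new <- f_new - f_new[1L]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("WHAM failed to converge in ", max_iter, " iterations", call. = FALSE)
  P <- P / sum(P)
  dG <- rep(NA_real_, length(mid))
  dG[occupied] <- -log(P[occupied]) / beta
  dG <- dG - min(dG, na.rm = TRUE)
  out <- list(xi = mid, dG = dG, segment_dG = NULL, seed_index = NULL,
              f_window = f, iterations = it)
  class(out) <- "PMFProfile"
  out
}

#' Read a work-ensemble CSV
#'
#' Schema: `segment, trajectory, xi, W` (long format). Segment boundaries
#' are taken from the per-segment grid extremes.
#'
#' @param path CSV file path.
#' @param beta inverse temperature, mol/kcal.
#' @return a `WorkEnsemble`.
#' @export
read_work_ensemble <- function(path, beta) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "trajectory", "xi", "W")
  if (!all(need %in% names(df)))
    stop("work table lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  segs <- sort(unique(df$segment))
  segments <- lapply(segs, function(s) {
    sub <- df[df$segment == s, ]
    xi <- sort(unique(sub$xi))
    trajs <- sort(unique(sub$trajectory))
    W <- t(vapply(trajs, function(tr) {
      ss <- sub[sub$trajectory == tr, ]
      ss$W[order(ss$xi)]
    }, numeric(length(xi))))
    list(xi = xi, W = W)
  })
  boundaries <- c(segments[[1L]]$xi[1L],
                  vapply(segments, function(sg) sg$xi[length(sg$xi)],
                         numeric(1)))
  work_ensemble(boundaries, segments, beta)
}
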