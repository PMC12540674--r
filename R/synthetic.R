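# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a multi-basin synthetic trajectory
#'
#' Frames are drawn from isotropic Gaussians centred on a set of planted
#' basin structures, with per-basin occupancies; the generating basin label
#' of every frame is returned so clustering/FEL recovery can be scored
#' against ground truth. Deterministic given the seed.
#'
#' @param centres list of basin centre coordinate matrices (n_atoms x 3,
#'   Angstrom), all the same shape.
#' @param occupancy per-basin sampling probabilities (sum 1).
#' @param sigma per-axis jitter standard deviation, Angstrom.
#' @param frames number of frames.
#' @param seed RNG seed.
#' @return list with `trajectory` (a `Trajectory`, all atoms named CA) and
#'   `labels` (integer basin index per frame).
#' @export
gen_multibasin_trajectory <- function(centres, occupancy, sigma, frames,
                                      seed) {
  if (!is.list(centres) || !length(centres))
    stop("centres must be a non-empty list", call. = FALSE)
  centres <- lapply(centres, as.matrix)
  dims <- vapply(centres, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != 3L))
    stop("all basin centres must share one n_atoms x 3 shape", call. = FALSE)
  occupancy <- as.numeric(occupancy)
  if (length(occupancy) != length(centres) ||
      abs(sum(occupancy) - 1) > 1e-9 || any(occupancy < 0))
    stop("occupancy must be per-basin probabilities summing to 1",
         call. = FALSE)
  if (frames < 1L) stop("frames must be >= 1", call. = FALSE)
  na <- nrow(centres[[1L]])
  .with_seed(seed, {
    labels <- sample.int(length(centres), frames, replace = TRUE,
                         prob = occupancy)
    frame_list <- lapply(labels, function(b)
      centres[[b]] + matrix(stats::rnorm(na * 3L, sd = sigma), na, 3L))
    atoms <- data.frame(serial = seq_len(na), name = "CA", resname = "GLY",
                        chain = "A", resno = seq_len(na), element = "C",
                        stringsAsFactors = FALSE)
    list(trajectory = trajectory_new(atoms, frame_list), labels = labels)
  })
}

#' Generate a segmented Gaussian work ensemble
#'
#' Per segment, final works are Gaussian with standard deviation `sigma`
#' and mean `dG + beta*sigma^2/2` — the dissipation offset that makes the
#' Jarzynski exponential average recover `dG` exactly in expectation — and
#' the within-segment curves ramp linearly (optionally with a dissipative
#' bump `gamma_f*u*(1-u)` and endpoint-vanishing noise of amplitude
#' `sigma_n`, neither of which moves the final work). Deterministic per
#' seed.
#'
#' @param dG planted per-segment free-energy changes, kcal/mol.
#' @param sigma per-segment work fluctuation SD (recycled), kcal/mol.
#' @param n_traj trajectories per segment (default 25).
#' @param beta inverse temperature, mol/kcal.
#' @param seed RNG seed.
#' @param boundaries reaction-coordinate segment boundaries (default
#'   `0:N'` Angstrom).
#' @param points grid points per segment (default 21).
#' @param gamma_f friction-like bump amplitude, kcal/mol (default 0).
#' @param sigma_n mid-segment noise amplitude, kcal/mol (default 0).
#' @return a `WorkEnsemble`.
#' @export
gen_work_ensemble <- function(dG, sigma, n_traj = 25, beta, seed,
                              boundaries = NULL, points = 21,
                              gamma_f = 0, sigma_n = 0) {
  dG <- as.numeric(dG)
  if (!length(dG)) stop("need at least one segment target", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  sigma <- rep(as.numeric(sigma), length.out = length(dG))
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (n_traj < 1L) stop("need at least one trajectory per segment",
                        call. = FALSE)
  if (is.null(boundaries)) boundaries <- seq(0, length(dG))
  .with_seed(seed, {
    segments <- lapply(seq_along(dG), function(i) {
      xi <- seq(boundaries[i], boundaries[i + 1L], length.out = points)
      u <- (xi - xi[1L]) / (xi[length(xi)] - xi[1L])
      finals <- stats::rnorm(n_traj, mean = dG[i] + beta * sigma[i]^2 / 2,
                             sd = sigma[i])
      W <- t(vapply(finals, function(f) {
        z <- stats::rnorm(1)
        f * u + gamma_f * u * (1 - u) + sigma_n * z * sin(pi * u)
      }, numeric(points)))
      list(xi = xi, W = W)
    })
    work_ensemble(boundaries, segments, beta)
  })
}

#' Generate per-snapshot MM/PBSA component tables with a planted delta
#'
#' Per-snapshot receptor and ligand rows fluctuate around fixed baselines;
#' each complex row is the sum of that snapshot's receptor and ligand rows
#' plus the planted delta plus noise, so the aggregated
#' complex - receptor - ligand delta equals the planted delta up to
#' sampling error (exactly, at zero noise). `H` is filled as the
#' four-component sum in every row.
#'
#' @param seed RNG seed.
#' @param n_snapshots rows per system (>= 1).
#' @param delta named numeric: planted Delta values for `ELE_IN`, `VDW_IN`,
#'   `ELE_PB`, `VDW_SA`, `TdS` (kcal/mol).
#' @param sd named numeric of per-component snapshot SDs (recycled;
#'   default 0).
#' @param receptor_base,ligand_base named baselines of the two isolated
#'   systems; defaults are magnitudes typical of a solvated ~250-residue
#'   protein and a coenzyme-sized ligand.
#' @return list of data frames `complex`, `receptor`, `ligand` (columns
#'   `label`, components, `H`, `TdS`).
#' @export
gen_mmpbsa_tables <- function(seed, n_snapshots, delta, sd = 0,
                              receptor_base = c(ELE_IN = -7300, VDW_IN = -960,
                                                ELE_PB = -3040, VDW_SA = 69,
                                                TdS = 2627),
                              ligand_base = c(ELE_IN = -512, VDW_IN = -4.5,
                                              ELE_PB = -108, VDW_SA = 6.4,
                                              TdS = 105)) {
  if (n_snapshots < 1L) stop("n_snapshots must be >= 1", call. = FALSE)
  comps <- c("ELE_IN", "VDW_IN", "ELE_PB", "VDW_SA", "TdS")
  if (!all(comps %in% names(delta)))
    stop("delta must name all of: ", paste(comps, collapse = ", "),
         call. = FALSE)
  sdv <- if (length(sd) == 1L && is.null(names(sd)))
    stats::setNames(rep(sd, 5L), comps) else sd[comps]
  .with_seed(seed, {
    noise <- function() {
      m <- vapply(comps, function(cn)
        stats::rnorm(n_snapshots, 0, sdv[[cn]]), numeric(n_snapshots))
      if (n_snapshots == 1L) m <- matrix(m, nrow = 1L,
                                         dimnames = list(NULL, comps))
      m
    }
    rec <- sweep(noise(), 2L, receptor_base[comps], `+`)
    lig <- sweep(noise(), 2L, ligand_base[comps], `+`)
    cpx <- rec + lig + noise() +
      matrix(unlist(delta[comps]), n_snapshots, 5L, byrow = TRUE)
    as_df <- function(m, label) {
      df <- as.data.frame(m)
      names(df) <- comps
      df$H <- rowSums(df[, c("ELE_IN", "VDW_IN", "ELE_PB", "VDW_SA")])
      cbind(data.frame(label = paste0(label, "_", seq_len(n_snapshots)),
                       stringsAsFactors = FALSE),
            df[, c("ELE_IN", "VDW_IN", "ELE_PB", "VDW_SA", "H", "TdS")])
    }
    list(complex = as_df(cpx, "complex"), receptor = as_df(rec, "receptor"),
         ligand = as_df(lig, "ligand"))
  })
}

#' Generate a ring-stack channel structure with a known radius profile
#'
#' Stacks rings of atoms along the z axis, ring k holding `atoms_per_ring`
#' atoms at radius `ring_radii[k]`; the analytic pore radius at each ring
#' plane is `ring_radius - vdw`. Stations where that is <= 0 are flagged
#' blocked.
#'
#' @param ring_radii per-ring radius, Angstrom (> 0).
#' @param spacing ring spacing along z, Angstrom (default 2).
#' @param atoms_per_ring atoms per ring (default 24).
#' @param vdw van der Waals radius of every atom, Angstrom (default 1.5).
#' @return list with `structure` (a `Structure` with vdW radii), `axis`
#'   (2 x 3 endpoint matrix along z), `stations` (ring z positions,
#'   relative to the first ring), `analytic` (planted pore radii) and
#'   `blocked` (logical).
#' @export
gen_channel_structure <- function(ring_radii, spacing = 2,
                                  atoms_per_ring = 24, vdw = 1.5) {
  ring_radii <- as.numeric(ring_radii)
  if (!length(ring_radii) || any(ring_radii <= 0))
    stop("ring radii must be positive", call. = FALSE)
  analytic <- ring_radii - vdw
  blocked <- analytic <= 0
  if (any(blocked))
    warning("channel blocked at station(s) ",
            paste(which(blocked), collapse = ", "), call. = FALSE)
  ang <- seq(0, 2 * pi, length.out = atoms_per_ring + 1L)[-1L]
  coords <- do.call(rbind, lapply(seq_along(ring_radii), function(k)
    cbind(ring_radii[k] * cos(ang), ring_radii[k] * sin(ang),
          (k - 1L) * spacing)))
  n <- nrow(coords)
  atoms <- data.frame(serial = seq_len(n), name = "C", resname = "RNG",
                      chain = "A", resno = rep(seq_along(ring_radii),
                                               each = atoms_per_ring),
                      element = "C", stringsAsFactors = FALSE)
  s <- structure_new(atoms, coords, vdw = rep(vdw, n))
  zmax <- (length(ring_radii) - 1L) * spacing
  list(structure = s,
       axis = rbind(c(0, 0, 0), c(0, 0, max(zmax, 1e-6))),
       stations = (seq_along(ring_radii) - 1L) * spacing,
       analytic = analytic, blocked = blocked)
}

#' Generate umbrella-sampling windows from a known potential
#'
#' Samples each window's biased Boltzmann density
#' `exp(-beta*(V(x) + spring/2 (x - centre)^2))` by rejection: proposals
#' come from the Gaussian implied by the bias alone and are accepted with
#' probability `exp(-beta*(V(x) - min V))`, the minimum taken over the
#' window's +/- 5 SD range. Deterministic per seed.
#'
#' @param potential function of the reaction coordinate, kcal/mol.
#' @param centres window bias centres, Angstrom.
#' @param spring bias spring constant, kcal/mol/A^2.
#' @param n samples per window (>= 1).
#' @param T temperature, K.
#' @param seed RNG seed.
#' @param breaks shared histogram bin edges (default: 120 bins spanning
#'   all windows' +/- 4 SD ranges).
#' @return list of `UmbrellaWindow` objects.
#' @export
gen_umbrella_samples <- function(potential, centres, spring, n, T, seed,
                                 breaks = NULL) {
  if (n < 1L) stop("need at least one sample per window", call. = FALSE)
  beta <- beta_from_T(T)
  sdw <- sqrt(1 / (beta * spring))
  if (is.null(breaks))
    breaks <- seq(min(centres) - 4 * sdw, max(centres) + 4 * sdw,
                  length.out = 121L)
  gap <- diff(sort(centres))
  if (length(gap) && any(gap > 8 * sdw))
    warning("window centres further apart than 8 bias SDs; coverage gap",
            call. = FALSE)
  .with_seed(seed, {
    lapply(centres, function(cc) {
      grid <- seq(cc - 5 * sdw, cc + 5 * sdw, length.out = 201L)
      vmin <- min(potential(grid))
      acc <- numeric(0)
      while (length(acc) < n) {
        prop <- stats::rnorm(2L * n, cc, sdw)
        p <- exp(-beta * (potential(prop) - vmin))
        keep <- stats::runif(length(prop)) < p
        acc <- c(acc, prop[keep])
      }
      acc <- acc[seq_len(n)]
      h <- graphics::hist(pmin(pmax(acc, breaks[1L]),
                               breaks[length(breaks)]),
                          breaks = breaks, plot = FALSE)
      umbrella_window(cc, spring, breaks, h$counts)
    })
  })
}

#' Generate provider tables for the mutant screen with planted outcomes
#'
#' Builds `ddG_fold` and `dG_bind` provider columns for an enumerated
#' mutant table such that a chosen set of sites passes the stability stage
#' with chosen per-site counts and a chosen mutant per site ends up the
#' affinity finalist. Used to exercise the screen end to end with known
#' truth. Deterministic per seed.
#'
#' @param mutants data frame from [enumerate_mutants()].
#' @param pass_counts named integer vector: stability-passing substitution
#'   count per passing site (names are site labels like "K1"); sites not
#'   named pass none.
#' @param finalists character vector of mutant labels (like "K1L"), one
#'   per passing site, each to be planted as its site's weakest binder.
#' @param wt_dG wild-type binding free energy, kcal/mol.
#' @param fold_cut,bind_cut the screen cutoffs the plant must respect.
#' @param seed RNG seed.
#' @return `mutants` with `ddG_fold` and `dG_bind` columns filled.
#' @export
gen_screen_providers <- function(mutants, pass_counts, finalists,
                                 wt_dG = -10.17, fold_cut = 2, bind_cut = 2,
                                 seed = 1) {
  m <- as.data.frame(mutants)
  fin <- data.frame(site = sub(".$", "", finalists),
                    target = sub(".*(.)$", "\\1", finalists),
                    stringsAsFactors = FALSE)
  if (!all(fin$site %in% names(pass_counts)))
    stop("every finalist's site must appear in pass_counts", call. = FALSE)
  .with_seed(seed, {
    m$ddG_fold <- NA_real_
    m$dG_bind <- NA_real_
    for (s in unique(m$site)) {
      rows <- which(m$site == s & !m$is_wt_ref)
      k <- if (s %in% names(pass_counts)) pass_counts[[s]] else 0L
      if (k > length(rows))
        stop("pass count for ", s, " exceeds 19 substitutions", call. = FALSE)
      ftarget <- fin$target[fin$site == s]
      ord <- rows[order(m$target[rows])]
      passing <- integer(0)
      if (k > 0L) {
        passing <- if (length(ftarget)) {
          frow <- rows[m$target[rows] == ftarget]
          union(frow, setdiff(ord, frow)[seq_len(k - 1L)])
        } else ord[seq_len(k)]
      }
      failing <- setdiff(rows, passing)
      m$ddG_fold[passing] <- stats::runif(length(passing), 0,
                                          fold_cut * 0.9)
      m$ddG_fold[failing] <- stats::runif(length(failing), fold_cut + 0.5,
                                          fold_cut + 4)
      # binding: finalist clearly weakest; other stability passers spread
      # across the cutoff; failing mutants still get provider values so
      # the screen stays well-defined when its cutoffs are loosened
      if (length(passing)) {
        m$dG_bind[passing] <- wt_dG +
          stats::runif(length(passing), bind_cut - 1.5, bind_cut + 1.2)
      }
      if (length(failing)) {
        m$dG_bind[failing] <- wt_dG + stats::runif(length(failing), -1, 1)
      }
      if (length(ftarget)) {
        frow <- rows[m$target[rows] == ftarget]
        m$dG_bind[frow] <- wt_dG + bind_cut + 2.5
      }
      m$ddG_fold[m$site == s & m$is_wt_ref] <- 0
      m$dG_bind[m$site == s & m$is_wt_ref] <- wt_dG
    }
    m
  })
}

#' Generate a per-residue decomposition table with planted totals
#'
#' @param n_res number of residues.
#' @param seed RNG seed.
#' @return data frame with `residue`, the four energy terms and `total`
#'   (their exact sum), kcal/mol.
#' @export
gen_residue_energy_table <- function(n_res, seed) {
  if (n_res < 1L) stop("n_res must be >= 1", call. = FALSE)
  .with_seed(seed, {
    t <- data.frame(
      residue = paste0("R", seq_len(n_res)),
      E_VDW = stats::rnorm(n_res, -1, 1),
      E_ELE = stats::rnorm(n_res, -0.5, 1.5),
      E_GB = stats::rnorm(n_res, 0.5, 1),
      E_GBSUR = stats::rnorm(n_res, -0.1, 0.2),
      stringsAsFactors = FALSE)
    t$total <- rowSums(t[, c("E_VDW", "E_ELE", "E_GB", "E_GBSUR")])
    t
  })
}
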