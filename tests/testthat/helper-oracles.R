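# Independent oracles used by the test suite. Deliberately written with
# different algorithms/styles than the package implementations.

# quaternion-method RMSD: largest eigenvalue of the 4x4 key matrix built
# from the cross-correlation of the centred point sets
quaternion_rmsd <- function(mobile, reference) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ssd <- sum(P^2) + sum(Q^2) - 2 * lambda
  sqrt(max(ssd, 0) / nrow(P))
}

# brute-force reimplementation of the greedy neighbour-count clustering,
# with explicit neighbour sets and scalar loops
brute_daura <- function(m, threshold) {
  n <- nrow(m)
  left <- seq_len(n)
  clusters <- list()
  while (length(left) > 0) {
    best_i <- NA; best_count <- -1
    for (i in left) {
      cnt <- 0
      for (j in left) if (m[i, j] <= threshold) cnt <- cnt + 1
      if (cnt > best_count) { best_count <- cnt; best_i <- i }
    }
    members <- c()
    for (j in left) if (m[best_i, j] <= threshold) members <- c(members, j)
    clusters[[length(clusters) + 1]] <- sort(members)
    left <- setdiff(left, members)
  }
  clusters[order(-sapply(clusters, length))]
}

# partitions-as-sets comparison, ignoring cluster order within equal sizes
same_partition <- function(a, b) {
  norm <- function(cl) {
    cl <- lapply(cl, function(x) sort(as.integer(unname(x))))
    cl <- unname(cl)
    cl[order(sapply(cl, function(x) paste(x, collapse = ",")))]
  }
  identical(norm(a), norm(b))
}

# k well-separated random conformations of the same atom count: genuine
# internal differences, so superposition cannot collapse them
separated_centres <- function(k, n_atoms, seed, spread = 10) {
  set.seed(seed)
  lapply(seq_len(k), function(i)
    matrix(runif(n_atoms * 3, 0, spread), n_atoms, 3))
}

# random C-alpha-like trajectory: n frames of jittered random base coords
random_ca_trajectory <- function(n_frames, n_atoms, jitter = 1, seed = 1) {
  set.seed(seed)
  base <- matrix(runif(n_atoms * 3, 0, 20), n_atoms, 3)
  frames <- lapply(seq_len(n_frames), function(i)
    base + matrix(rnorm(n_atoms * 3, sd = jitter), n_atoms, 3))
  atoms <- data.frame(serial = seq_len(n_atoms), name = "CA",
                      resname = "ALA", chain = "A", resno = seq_len(n_atoms),
                      element = "C", stringsAsFactors = FALSE)
  trajectory_new(atoms, frames)
}

# orthonormal basis of the 6 rigid-body modes (3 translations, 3 rotations)
# of a structure, as vectors in flattened (x1,y1,z1,x2,...) coordinate space
rigid_modes <- function(base) {
  m <- nrow(base)
  cen <- sweep(base, 2, colMeans(base))
  modes <- list()
  for (ax in 1:3) {
    v <- rep(0, 3 * m); v[seq(ax, 3 * m, by = 3)] <- 1
    modes[[length(modes) + 1]] <- v
  }
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 1
    rot <- t(apply(cen, 1, function(x) c(e[2] * x[3] - e[3] * x[2],
                                         e[3] * x[1] - e[1] * x[3],
                                         e[1] * x[2] - e[2] * x[1])))
    modes[[length(modes) + 1]] <- as.numeric(t(rot))
  }
  gram_schmidt(do.call(cbind, modes))
}

gram_schmidt <- function(V) {
  out <- NULL
  for (k in seq_len(ncol(V))) {
    v <- V[, k]
    if (!is.null(out)) v <- v - out %*% crossprod(out, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) out <- cbind(out, v / nv)
  }
  out
}

# a unit direction in flattened coordinate space orthogonal to the rigid
# modes (and to `also`, if given): internal deformation only
internal_mode <- function(base, seed, also = NULL) {
  set.seed(seed)
  m <- nrow(base)
  v <- rnorm(3 * m)
  B <- rigid_modes(base)
  if (!is.null(also)) B <- cbind(B, also)
  v <- v - B %*% crossprod(B, v)
  v / sqrt(sum(v^2))
}

# printed SIE component rows of the six designed mutants (inputs)
sie_printed <- function() {
  data.frame(
    label = c("K1L", "N39G", "I40P", "T42N", "N174D", "D218V"),
    dG_R_bind = c(52.45, 62.87, 50.21, 75.47, 68.49, 52.11),
    E_vdw = c(-54.68, -62.35, -53.26, -69.25, -70.49, -40.36),
    E_c = c(-16.27, -16.10, -30.56, -28.65, -29.81, -20.35),
    dMSA = c(-1043.38, -966.47, -1019.20, -990.20, -903.56, -970.43),
    dG_bind = c(-6.24, -5.83, -6.43, -6.58, -7.44, -5.10),
    stringsAsFactors = FALSE)
}

# printed MM/PBSA system rows (inputs)
mmpbsa_printed <- function() {
  list(
    complex = mmpbsa_row("complex", -7917.25, -1023.19, -3048.89, 68.05,
                         -7914.27, 2705.24),
    receptor = mmpbsa_row("receptor", -7325.69, -964.62, -3044.21, 68.97,
                          -7422.89, 2627.37),
    ligand = mmpbsa_row("ligand", -512.76, -4.52, -107.70, 6.44,
                        -454.19, 104.88))
}

# the ten key binding-site residues (site labels with wild-type identity)
key_sites <- function() {
  data.frame(resno = c(1, 30, 39, 40, 42, 170, 174, 186, 188, 218),
             wt = c("K", "R", "N", "I", "T", "N", "N", "R", "Y", "D"),
             stringsAsFactors = FALSE)
}

# per-site stability-pass counts of the six retained sites (inputs)
stability_counts <- function() {
  c(K1 = 8L, N39 = 9L, I40 = 11L, T42 = 17L, N174 = 9L, D218 = 9L)
}

finalist_labels <- function() {
  c("K1L", "N39G", "I40P", "T42N", "N174D", "D218V")
}

# exhaustive fine-grid search in the station plane, independent of the
# package's two-stage pore optimiser
brute_pore_radius <- function(s, p0, e1, e2, half = 3, step = 0.02) {
  g <- seq(-half, half, by = step)
  best <- -Inf
  for (a in g) {
    cand <- outer(rep(1, length(g)), p0) + a * outer(rep(1, length(g)), e1) +
      outer(g, e2)
    d <- sqrt(outer(rowSums(cand^2), rowSums(s$coords^2), `+`) -
                2 * cand %*% t(s$coords))
    clear <- apply(sweep(d, 2, s$vdw), 1, min)
    best <- max(best, max(clear))
  }
  best
}

# nearest occupied (non-NA) grid value of a PMF profile
pmf_at <- function(p, x0) {
  ok <- which(!is.na(p$dG))
  p$dG[ok[which.min(abs(p$xi[ok] - x0))]]
}
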