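#' One row of MM/PBSA energy components
#'
#' Holds the component energies of one system (complex, receptor, ligand,
#' or a Delta row): internal electrostatics `ELE_IN`, internal van der
#' Waals `VDW_IN`, polar solvation `ELE_PB`, nonpolar solvation `VDW_SA`,
#' total enthalpy `H`, and entropy term `TdS` — all kcal/mol. Any component
#' may be `NA` for partial rows. When all five energy terms are present,
#' `H` must equal the four-component sum to within 0.02 kcal/mol (the slack
#' printed tables carry from rounding).
#'
#' @param label system name.
#' @param ELE_IN,VDW_IN,ELE_PB,VDW_SA,H,TdS component energies in kcal/mol.
#' @param strict when `TRUE`, require `H` to equal the four-component sum
#'   to 0.02 kcal/mol. That identity defines the enthalpy of a *Delta*
#'   row; per-system rows quote a total enthalpy that also contains
#'   internal (bonded) terms cancelling in the difference, so the default
#'   only records consistency in the `"H_consistent"` attribute.
#' @return An object of class `MMPBSARow` (a one-row data frame).
#' @export
mmpbsa_row <- function(label, ELE_IN = NA, VDW_IN = NA, ELE_PB = NA,
                       VDW_SA = NA, H = NA, TdS = NA, strict = FALSE) {
  row <- data.frame(label = as.character(label),
                    ELE_IN = as.numeric(ELE_IN), VDW_IN = as.numeric(VDW_IN),
                    ELE_PB = as.numeric(ELE_PB), VDW_SA = as.numeric(VDW_SA),
                    H = as.numeric(H), TdS = as.numeric(TdS),
                    stringsAsFactors = FALSE)
  comp <- unlist(row[1, .mmpbsa_components])
  consistent <- NA
  if (!any(is.na(comp)) && !is.na(row$H)) {
    consistent <- abs(row$H - sum(comp)) <= 0.02
    if (strict && !consistent)
      stop("H inconsistent with component sum for '", label,
           "' (|diff| > 0.02 kcal/mol)", call. = FALSE)
  }
  attr(row, "H_consistent") <- consistent
  class(row) <- c("MMPBSARow", class(row))
  row
}

.mmpbsa_components <- c("ELE_IN", "VDW_IN", "ELE_PB", "VDW_SA")
.mmpbsa_fields <- c(.mmpbsa_components, "H", "TdS")

#' Component-wise MM/PBSA difference (Delta row)
#'
#' Each present component of the Delta row is
#' `complex - receptor - ligand`; the three rows must expose the same set
#' of present (non-`NA`) fields.
#'
#' @param complex,receptor,ligand `MMPBSARow` objects.
#' @return an `MMPBSARow` labelled `"Delta"`.
#' @export
mmpbsa_delta <- function(complex, receptor, ligand) {
  rows <- list(complex, receptor, ligand)
  pres <- lapply(rows, function(r) .mmpbsa_fields[!is.na(unlist(r[1, .mmpbsa_fields]))])
  if (!identical(pres[[1]], pres[[2]]) || !identical(pres[[1]], pres[[3]]))
    stop("the three rows do not share the same set of present fields",
         call. = FALSE)
  vals <- lapply(.mmpbsa_fields, function(f)
    complex[[f]] - receptor[[f]] - ligand[[f]])
  names(vals) <- .mmpbsa_fields
  do.call(mmpbsa_row, c(list(label = "Delta"), vals, list(strict = TRUE)))
}

#' Binding enthalpy and free energy from a Delta row
#'
#' The enthalpy change is the sum of the four interaction components
#' (internal electrostatic + van der Waals, polar + nonpolar solvation);
#' the binding free energy subtracts the entropy term:
#' `dG = dH - TdS`, with `TdS` stored using the printed sign convention
#' (a negative Delta `TdS` therefore raises `dG` above `dH`... i.e.
#' `dG = dH - TdS` applied literally).
#'
#' @param delta an `MMPBSARow` with all four components and `TdS` present.
#' @return list with `dH` and `dG` (kcal/mol).
#' @export
eq3_binding_energy <- function(delta) {
  comp <- unlist(delta[1, .mmpbsa_components])
  if (any(is.na(comp)) || is.na(delta$TdS))
    stop("Delta row must carry all four components and TdS", call. = FALSE)
  dH <- sum(comp)
  list(dH = dH, dG = dH - delta$TdS)
}

#' Aggregate per-snapshot MM/PBSA rows to mean +/- SD
#'
#' End-point schemes average component energies over a set of snapshots;
#' this reduces a per-snapshot table (one row per snapshot) to the
#' mean row and the per-component standard deviation.
#'
#' @param rows data frame with any subset of the MM/PBSA component columns
#'   (one row per snapshot).
#' @param label label of the aggregated row.
#' @return list with `mean` (an `MMPBSARow`) and `sd` (named numeric).
#' @export
aggregate_mmpbsa <- function(rows, label = "mean") {
  rows <- as.data.frame(rows)
  if (!nrow(rows)) stop("no snapshot rows to aggregate", call. = FALSE)
  fields <- intersect(.mmpbsa_fields, names(rows))
  mu <- vapply(fields, function(f) mean(rows[[f]]), numeric(1))
  sdv <- vapply(fields, function(f)
    if (nrow(rows) > 1L) stats::sd(rows[[f]]) else 0, numeric(1))
  args <- as.list(mu)
  list(mean = do.call(mmpbsa_row, c(list(label = label), args)), sd = sdv)
}

#' Read an MM/PBSA component table
#'
#' CSV schema: `label, ELE_IN, VDW_IN, ELE_PB, VDW_SA[, H][, TdS]`.
#'
#' @param path CSV file path.
#' @return data frame of rows (one `MMPBSARow`-shaped row per line).
#' @export
read_mmpbsa_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df))
    stop("MM/PBSA table needs a 'label' column", call. = FALSE)
  for (f in .mmpbsa_fields) if (!f %in% names(df)) df[[f]] <- NA_real_
  df[, c("label", .mmpbsa_fields)]
}

# SIE ------------------------------------------------------------------------

#' Parameters of the solvated interaction energy function
#'
#' Defaults are the calibrated values of the SIE scoring function:
#' `alpha` — global scale factor absorbing conformational-entropy loss
#' (0.1048); `D_in` — solute internal dielectric constant (2.25);
#' `rho` — linear scaling of van der Waals radii (1.1); `gamma` — surface
#' area coefficient (0.0129 kcal/mol/A^2); `C` — calibration constant
#' (-2.89 kcal/mol).
#'
#' @param alpha,D_in,rho,gamma,C see description.
#' @return An object of class `SIEParams`.
#' @export
sie_params <- function(alpha = 0.1048, D_in = 2.25, rho = 1.1,
                       gamma = 0.0129, C = -2.89) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (D_in < 1) stop("D_in must be >= 1", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  out <- list(alpha = alpha, D_in = D_in, rho = rho, gamma = gamma, C = C)
  class(out) <- "SIEParams"
  out
}

#' One row of SIE components
#'
#' @param label mutant/system name.
#' @param E_c intermolecular Coulomb energy at the internal dielectric,
#'   kcal/mol.
#' @param dG_R_bind reaction-field energy change on binding, kcal/mol
#'   (a solver-provided input).
#' @param E_vdw intermolecular van der Waals energy, kcal/mol.
#' @param dMSA change in molecular surface area on binding, A^2 (scaled by
#'   `gamma` at evaluation).
#' @return An object of class `SIEComponents`.
#' @export
sie_components <- function(label, E_c, dG_R_bind, E_vdw, dMSA) {
  vals <- c(E_c = E_c, dG_R_bind = dG_R_bind, E_vdw = E_vdw, dMSA = dMSA)
  if (any(!is.finite(vals)))
    stop("non-finite SIE component for '", label, "'", call. = FALSE)
  out <- c(list(label = as.character(label)), as.list(vals))
  class(out) <- "SIEComponents"
  out
}

#' Solvated interaction energy score
#'
#' `dG_bind = alpha * (E_c + dG_R_bind + E_vdw + gamma * dMSA) + C`.
#' No rounding is applied; round only for presentation.
#'
#' @param c an `SIEComponents` row.
#' @param p an `SIEParams` set (defaults: [sie_params()]).
#' @return binding free energy estimate, kcal/mol.
#' @export
sie_score <- function(c, p = sie_params()) {
  stopifnot(inherits(p, "SIEParams"))
  vals <- c(c$E_c, c$dG_R_bind, c$E_vdw, c$dMSA)
  if (any(!is.finite(vals)))
    stop("non-finite SIE component", call. = FALSE)
  p$alpha * (c$E_c + c$dG_R_bind + c$E_vdw + p$gamma * c$dMSA) + p$C
}

#' Read an SIE component table
#'
#' CSV schema: `label, E_c, dG_R_bind, E_vdw, dMSA`.
#'
#' @param path CSV file path.
#' @return list of `SIEComponents`, one per row.
#' @export
read_sie_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "E_c", "dG_R_bind", "E_vdw", "dMSA")
  if (!all(need %in% names(df)))
    stop("SIE table lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    sie_components(df$label[i], df$E_c[i], df$dG_R_bind[i], df$E_vdw[i],
                   df$dMSA[i]))
}

# per-residue decomposition ---------------------------------------------------

#' Rank residues by their decomposed binding contribution
#'
#' Rows of a per-residue decomposition table carry vacuum van der Waals
#' (`E_VDW`) and electrostatic (`E_ELE`) energies plus polar (`E_GB`) and
#' nonpolar (`E_GBSUR`) solvation parts; `total` is their sum (checked to
#' 0.02 kcal/mol). Residues are sorted by ascending total, i.e. the most
#' favourable (most negative) contributors first.
#'
#' @param t data frame with columns `residue`, `E_VDW`, `E_ELE`, `E_GB`,
#'   `E_GBSUR` and optionally `total` (recomputed when absent).
#' @param n how many residues to return (clamped to the table size).
#' @return the top-`n` rows, ordered by ascending `total`.
#' @export
rank_residue_contributions <- function(t, n = 10) {
  t <- as.data.frame(t)
  if (!nrow(t)) stop("empty residue table", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  terms <- c("E_VDW", "E_ELE", "E_GB", "E_GBSUR")
  if (!all(terms %in% names(t)))
    stop("residue table lacks column(s): ",
         paste(setdiff(terms, names(t)), collapse = ", "), call. = FALSE)
  sums <- rowSums(t[, terms])
  if ("total" %in% names(t)) {
    if (any(abs(t$total - sums) > 0.02))
      stop("total inconsistent with term sum (|diff| > 0.02 kcal/mol)",
           call. = FALSE)
  } else t$total <- sums
  t <- t[order(t$total), , drop = FALSE]
  utils::head(t, n)
}

# vacuum pairwise energies ----------------------------------------------------

#' Vacuum intermolecular Coulomb and Lennard-Jones energies
#'
#' Sums over all intermolecular atom pairs:
#' `E_ELE = sum 332.0637 * qi * qj / (D * rij)` and
#' `E_VDW = sum eij * ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)` with the usual
#' combination rules (`Rmin_ij` = sum of the two `Rmin/2` values, `eij` =
#' geometric mean). No distance cutoff is applied.
#'
#' @param a,b `Structure` objects (the two molecules).
#' @param charges_a,charges_b per-atom partial charges (e).
#' @param lj_a,lj_b per-atom Lennard-Jones parameters: 2-column matrices or
#'   data frames `(Rmin_half, epsilon)` in Angstrom / kcal/mol.
#' @param dielectric relative dielectric constant D (default 1, vacuum).
#' @return list with `E_ELE` and `E_VDW` in kcal/mol.
#' @export
vacuum_interaction_energy <- function(a, b, charges_a, charges_b,
                                      lj_a, lj_b, dielectric = 1) {
  stopifnot(inherits(a, "Structure"), inherits(b, "Structure"))
  na <- nrow(a$atoms); nb <- nrow(b$atoms)
  charges_a <- as.numeric(charges_a); charges_b <- as.numeric(charges_b)
  lj_a <- as.matrix(lj_a); lj_b <- as.matrix(lj_b)
  if (length(charges_a) != na || nrow(lj_a) != na ||
      length(charges_b) != nb || nrow(lj_b) != nb)
    stop("parameter tables must cover every atom", call. = FALSE)
  # pairwise distances (na x nb)
  d2 <- outer(rowSums(a$coords^2), rowSums(b$coords^2), `+`) -
    2 * a$coords %*% t(b$coords)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 1e-6))
    stop("overlapping atoms (r < 1e-6 Angstrom)", call. = FALSE)
  E_ELE <- sum(coulomb_kcal * outer(charges_a, charges_b) / (dielectric * r))
  rmin <- outer(lj_a[, 1L], lj_b[, 1L], `+`)
  eps <- sqrt(outer(lj_a[, 2L], lj_b[, 2L]))
  s6 <- (rmin / r)^6
  E_VDW <- sum(eps * (s6^2 - 2 * s6))
  list(E_ELE = E_ELE, E_VDW = E_VDW)
}

# solvent-accessible surface area ---------------------------------------------

# deterministic near-uniform unit-sphere points (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point counting: each atom is expanded by the probe radius and
#' covered with a near-uniform point lattice; points falling inside any
#' other expanded sphere are buried. Per-atom areas sum to the total.
#'
#' @param s a `Structure` with `vdw` radii present.
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points lattice points per atom (default 960).
#' @return list with `total` (A^2) and `per_atom` (numeric vector).
#' @export
sasa <- function(s, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "Structure"))
  if (is.null(s$vdw)) stop("structure carries no vdW radii", call. = FALSE)
  n <- nrow(s$atoms)
  pts <- .sphere_points(n_points)
  R <- s$vdw + probe
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2L, s$coords[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((s$coords[i, ] - s$coords[j, ])^2))
      if (dij >= R[i] + R[j]) next
      d2 <- rowSums(sweep(p, 2L, s$coords[j, ])^2)
      exposed <- exposed & d2 > R[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- 4 * pi * R[i]^2 * sum(exposed) / n_points
  }
  list(total = sum(per_atom), per_atom = per_atom)
}
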