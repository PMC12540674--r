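test_that("MM/PBSA delta algebra reproduces the printed component table", {
  rows <- mmpbsa_printed()
  d <- mmpbsa_delta(rows$complex, rows$receptor, rows$ligand)
  expect_equal(d$ELE_IN, -78.80, tolerance = 1e-9)
  expect_equal(d$VDW_IN, -54.05, tolerance = 1e-9)
  expect_equal(d$ELE_PB, 103.03, tolerance = 0.015)  # printed-rounding slack
  expect_equal(d$VDW_SA, -7.36, tolerance = 1e-9)
  expect_equal(d$TdS, -27.01, tolerance = 1e-9)

  e <- eq3_binding_energy(d)
  expect_equal(e$dH, -37.18, tolerance = 0.015)
  expect_equal(e$dG, e$dH - d$TdS)
  expect_equal(e$dG, -10.17, tolerance = 0.025)

  # the printed Delta row itself satisfies the enthalpy identity exactly
  dp <- mmpbsa_row("Delta", -78.8, -54.05, 103.03, -7.36, -37.18, -27.01,
                   strict = TRUE)
  ep <- eq3_binding_energy(dp)
  expect_equal(ep$dH, -37.18, tolerance = 1e-9)
  expect_equal(ep$dG, -10.17, tolerance = 1e-9)

  # zero-delta identity
  z <- mmpbsa_delta(mmpbsa_row("c", 3, 4, 5, 6, 18, 2),
                    mmpbsa_row("r", 1, 2, 2, 4, 9, 1),
                    mmpbsa_row("l", 2, 2, 3, 2, 9, 1))
  expect_equal(unlist(z[1, -1]), c(ELE_IN = 0, VDW_IN = 0, ELE_PB = 0,
                                   VDW_SA = 0, H = 0, TdS = 0))
  ez <- eq3_binding_energy(z)
  expect_equal(c(ez$dH, ez$dG), c(0, 0))

  # schema errors
  partial <- mmpbsa_row("r", ELE_IN = 1, VDW_IN = 2)
  expect_error(mmpbsa_delta(rows$complex, partial, rows$ligand),
               "present fields")
  expect_error(eq3_binding_energy(partial), "TdS")
})

test_that("delta algebra is linear and snapshot aggregation matches mean/SD", {
  r1 <- mmpbsa_row("c", 2, -3, 5, 1)
  r2 <- mmpbsa_row("r", 1, -1, 2, 0.5)
  r3 <- mmpbsa_row("l", 0.5, -0.5, 1, 0.2)
  d <- mmpbsa_delta(r1, r2, r3)
  sc <- function(r, k) mmpbsa_row(r$label, r$ELE_IN * k, r$VDW_IN * k,
                                  r$ELE_PB * k, r$VDW_SA * k)
  d3 <- mmpbsa_delta(sc(r1, 3), sc(r2, 3), sc(r3, 3))
  for (f in c("ELE_IN", "VDW_IN", "ELE_PB", "VDW_SA"))
    expect_equal(d3[[f]], 3 * d[[f]], tolerance = 1e-12)

  snaps <- data.frame(ELE_IN = c(-10, -12, -14), VDW_IN = c(1, 2, 3),
                      ELE_PB = c(0, 0, 0), VDW_SA = c(5, 5, 5),
                      TdS = c(1, 2, 3))
  agg <- aggregate_mmpbsa(snaps)
  expect_equal(agg$mean$ELE_IN, -12)
  expect_equal(unname(agg$sd["ELE_IN"]), 2)
  expect_equal(unname(agg$sd["VDW_SA"]), 0)
  one <- aggregate_mmpbsa(snaps[2, ])
  expect_equal(unname(one$sd["TdS"]), 0)
})

test_that("SIE recombines the printed mutant table and is affine in each component", {
  tab <- sie_printed()
  p <- sie_params()
  consistent <- setdiff(tab$label, "I40P")
  for (lab in consistent) {
    r <- tab[tab$label == lab, ]
    sc <- sie_score(sie_components(lab, r$E_c, r$dG_R_bind, r$E_vdw, r$dMSA),
                    p)
    expect_equal(sc, r$dG_bind, tolerance = 0.01, info = lab)
  }
  # the remaining printed row is internally inconsistent: the components
  # recombine to -7.79, not the printed -6.43
  r <- tab[tab$label == "I40P", ]
  sc <- sie_score(sie_components("I40P", r$E_c, r$dG_R_bind, r$E_vdw,
                                 r$dMSA), p)
  expect_equal(sc, -7.79, tolerance = 0.01)
  expect_gt(abs(sc - r$dG_bind), 1)

  # zero components leave only the calibration constant
  expect_equal(sie_score(sie_components("z", 0, 0, 0, 0), p), p$C)

  # affine slopes alpha, alpha, alpha, alpha*gamma by finite differences
  base <- sie_components("b", -10, 20, -30, -500)
  f0 <- sie_score(base, p)
  bump <- function(field, h = 1) {
    x <- base; x[[field]] <- x[[field]] + h
    (sie_score(x, p) - f0) / h
  }
  expect_equal(bump("E_c"), p$alpha, tolerance = 1e-10)
  expect_equal(bump("dG_R_bind"), p$alpha, tolerance = 1e-10)
  expect_equal(bump("E_vdw"), p$alpha, tolerance = 1e-10)
  expect_equal(bump("dMSA"), p$alpha * p$gamma, tolerance = 1e-10)

  expect_error(sie_components("x", NA, 1, 1, 1), "non-finite")
  expect_error(sie_params(alpha = -1), "alpha")
  expect_error(sie_params(D_in = 0.5), "D_in")
})

test_that("SIE tables round-trip through CSV", {
  tab <- sie_printed()
  f <- tempfile(fileext = ".csv")
  write.csv(tab[, c("label", "E_c", "dG_R_bind", "E_vdw", "dMSA")], f,
            row.names = FALSE)
  rows <- read_sie_table(f)
  expect_length(rows, 6L)
  expect_equal(rows[[1]]$label, "K1L")
  expect_equal(sie_score(rows[[5]]), -7.44, tolerance = 0.01)
})

test_that("residue contribution ranking equals an argsort oracle and clamps n", {
  t1 <- gen_residue_energy_table(20, seed = 8)
  top <- rank_residue_contributions(t1, n = 10)
  oracle <- t1$residue[order(t1$total)][1:10]
  expect_equal(top$residue, oracle)
  expect_true(all(diff(top$total) >= 0))

  single <- gen_residue_energy_table(1, seed = 1)
  expect_equal(rank_residue_contributions(single)$residue, "R1")
  expect_equal(nrow(rank_residue_contributions(t1, n = 100)), 20L)
  expect_error(rank_residue_contributions(t1[0, ]), "empty")
  broken <- t1; broken$total <- broken$total + 1
  expect_error(rank_residue_contributions(broken), "inconsistent")
})

test_that("vacuum pair energies match hand-evaluated Coulomb and LJ forms", {
  atoms1 <- data.frame(serial = 1, name = "O", resname = "LIG", chain = "A",
                       resno = 1, element = "O", stringsAsFactors = FALSE)
  atoms2 <- atoms1; atoms2$serial <- 2
  s_at <- function(p, at = atoms1) structure_new(at, matrix(p, 1, 3))
  lj <- matrix(c(1.7, 0.2), 1, 2)   # Rmin/2, epsilon

  e <- vacuum_interaction_energy(s_at(c(0, 0, 0)), s_at(c(3, 0, 0)),
                                 1, -1, lj, lj)
  expect_equal(e$E_ELE, -332.0637 / 3, tolerance = 1e-3)
  expect_equal(e$E_ELE, -110.688, tolerance = 1e-3)

  # at r = Rmin_ij the LJ well depth is exactly -eps_ij
  e2 <- vacuum_interaction_energy(s_at(c(0, 0, 0)), s_at(c(3.4, 0, 0)),
                                  0, 0, lj, lj)
  expect_equal(e2$E_VDW, -0.2, tolerance = 1e-10)

  # dielectric scales the electrostatic term only
  e4 <- vacuum_interaction_energy(s_at(c(0, 0, 0)), s_at(c(3, 0, 0)),
                                  1, -1, lj, lj, dielectric = 4)
  expect_equal(e4$E_ELE, e$E_ELE / 4, tolerance = 1e-10)

  # decay at 1000 Angstrom: LJ vanishes, Coulomb follows 1/r exactly
  e3 <- vacuum_interaction_energy(s_at(c(0, 0, 0)), s_at(c(1000, 0, 0)),
                                  1, -1, lj, lj)
  expect_equal(e3$E_ELE, -332.0637 / 1000, tolerance = 1e-10)
  expect_lt(abs(e3$E_VDW), 1e-3)

  expect_error(vacuum_interaction_energy(s_at(c(0, 0, 0)), s_at(c(0, 0, 0)),
                                         1, -1, lj, lj), "verlapping")
  expect_error(vacuum_interaction_energy(s_at(c(0, 0, 0)), s_at(c(3, 0, 0)),
                                         c(1, 1), -1, lj, lj), "cover")
})

test_that("Shrake-Rupley SASA matches analytic spheres and converges with the lattice", {
  one <- data.frame(serial = 1, name = "C", resname = "X", chain = "A",
                    resno = 1, element = "C", stringsAsFactors = FALSE)
  s1 <- structure_new(one, matrix(0, 1, 3), vdw = 1.6)
  a1 <- sasa(s1, probe = 1.4)
  expect_equal(a1$total, 4 * pi * 3^2, tolerance = 0.01 * 4 * pi * 9)
  expect_equal(a1$total, 113.10, tolerance = 1.2)

  # two distant atoms: additive
  two <- rbind(one, transform(one, serial = 2, resno = 2))
  s2 <- structure_new(two, rbind(c(0, 0, 0), c(50, 0, 0)), vdw = c(1.6, 1.6))
  expect_equal(sasa(s2)$total, 2 * a1$total, tolerance = 1e-6)

  # partial overlap vs the two-cap closed form
  R <- 1.6 + 1.4; d <- 2.5
  s3 <- structure_new(two, rbind(c(0, 0, 0), c(d, 0, 0)), vdw = c(1.6, 1.6))
  h <- R - d / 2                              # buried cap height, equal radii
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  expect_equal(sasa(s3)$total, analytic, tolerance = 0.02 * analytic)

  # lattice convergence on a 20-atom cluster
  set.seed(5)
  atoms20 <- do.call(rbind, lapply(1:20, function(i)
    transform(one, serial = i, resno = i)))
  s20 <- structure_new(atoms20, matrix(runif(60, 0, 8), 20, 3),
                       vdw = rep(1.7, 20))
  a960 <- sasa(s20, n_points = 960)$total
  a4000 <- sasa(s20, n_points = 4000)$total
  expect_lt(abs(a960 - a4000) / a4000, 0.005)
  # per-atom areas sum to the total
  out <- sasa(s20)
  expect_equal(sum(out$per_atom), out$total, tolerance = 1e-9)

  s_norad <- structure_new(one, matrix(0, 1, 3))
  expect_error(sasa(s_norad), "vdW")
})
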