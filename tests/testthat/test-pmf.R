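test_that("the guiding potential and spring force follow the harmonic schedule", {
  spec <- pulling_spec(k = 2.5, v = 1, n = c(0, 0, 1), X0 = c(0, 0, 0))

  # exactly on schedule: no energy, no force
  on <- guiding_energy_force(spec, t = 2, X_t = c(0, 0, 2))
  expect_equal(on$U, 0)
  expect_equal(on$F, c(0, 0, 0))

  # 1 Angstrom lag at k = 2.5: U = 1.25, |F| = 2.5 toward the schedule point
  lag1 <- guiding_energy_force(spec, t = 1, X_t = c(0, 0, 0))
  expect_equal(lag1$U, 1.25)
  expect_equal(sqrt(sum(lag1$F^2)), 2.5)
  expect_equal(lag1$F, c(0, 0, 2.5))

  # homogeneity: doubling k doubles U and F at fixed lag
  spec2 <- pulling_spec(k = 5, v = 1, n = c(0, 0, 1), X0 = c(0, 0, 0))
  lag2 <- guiding_energy_force(spec2, t = 1, X_t = c(0, 0, 0))
  expect_equal(lag2$U, 2 * lag1$U)
  expect_equal(lag2$F, 2 * lag1$F)

  # displacement off-axis does not change the projected lag
  off <- guiding_energy_force(spec, t = 1, X_t = c(7, -4, 0))
  expect_equal(off$U, 1.25)

  expect_error(pulling_spec(k = -1), "k must be")
  expect_error(pulling_spec(n = c(1, 1, 0)), "unit")
  expect_error(guiding_energy_force(spec, t = -1, X_t = c(0, 0, 0)), ">= 0")
})

test_that("the Jarzynski segment estimator matches closed forms and obeys the Jensen bound", {
  beta300 <- 1 / (kB_kcal * 300)

  # constant work: estimator returns it exactly
  expect_equal(jarzynski_segment(rep(3.7, 10), beta300), 3.7)

  # hand-evaluated two-point average at beta = 1
  expect_equal(jarzynski_segment(c(0, log(2)), 1), -log(0.75),
               tolerance = 1e-12)
  expect_equal(jarzynski_segment(c(0, log(2)), 1), 0.28768,
               tolerance = 1e-5)

  # Gaussian work: dG = mu - beta*sigma^2/2
  set.seed(21)
  w <- rnorm(1e4, mean = 5, sd = 1)
  expect_equal(jarzynski_segment(w, beta300), 5 - beta300 / 2,
               tolerance = 0.1)
  expect_equal(5 - beta300 / 2, 4.161, tolerance = 1e-3)

  # numerically stable far beyond naive exp() underflow
  expect_equal(jarzynski_segment(c(1000, 1001), beta300), 1000,
               tolerance = 0.5)

  # Jensen: estimate <= mean, strict when works vary; permutation invariant
  for (s in 1:20) {
    set.seed(s)
    w <- rnorm(50, mean = runif(1, -2, 6), sd = runif(1, 0.1, 2))
    est <- jarzynski_segment(w, beta300)
    expect_lt(est, mean(w))
    expect_equal(jarzynski_segment(sample(w), beta300), est,
                 tolerance = 1e-12)
  }
  # continuity in beta
  expect_equal(jarzynski_segment(c(1, 2), 1), jarzynski_segment(c(1, 2), 1 + 1e-7),
               tolerance = 1e-5)

  expect_error(jarzynski_segment(numeric(0), 1), "no work")
  expect_error(jarzynski_segment(c(1, 2), 0), "beta")
})

test_that("segment stitching is additive, continuous, and recovers planted segment free energies", {
  beta300 <- 1 / (kB_kcal * 300)

  # one segment, one trajectory: PMF equals the work curve
  xi <- seq(0, 1, length.out = 11)
  W <- matrix(3 * xi, 1, 11, byrow = TRUE)
  e1 <- work_ensemble(c(0, 1), list(list(xi = xi, W = W)), beta300)
  p1 <- asmd_stitch(e1)
  expect_equal(p1$dG, as.numeric(W), tolerance = 1e-12)
  expect_equal(p1$segment_dG, 3)

  # two deterministic segments, works 2 then 3: total 5
  seg <- function(a, b, w) list(xi = seq(a, b, length.out = 6),
                                W = matrix(w * seq(0, 1, length.out = 6),
                                           1, 6, byrow = TRUE))
  e2 <- work_ensemble(c(0, 1, 2), list(seg(0, 1, 2), seg(1, 2, 3)), beta300)
  p2 <- asmd_stitch(e2)
  expect_equal(sum(p2$segment_dG), 5)
  expect_equal(p2$dG[length(p2$dG)], 5, tolerance = 1e-12)
  expect_equal(p2$dG[1], 0)
  # stitched grid is continuous: one point per boundary, no jumps
  expect_equal(p2$xi, seq(0, 2, length.out = 11))

  # planted 5-segment x 25-track Gaussian ensemble; the 25-track protocol
  # carries ~0.2 kcal/mol sampling error on the total, so recovery is
  # asserted on the mean over replicate ensembles rather than one draw
  truth <- c(1, 2, 0, -1, 3)
  seg_err <- total_err <- numeric(15)
  for (s in 1:15) {
    f <- asmd_stitch(gen_work_ensemble(truth, sigma = 0.5, n_traj = 25,
                                       beta = beta300, seed = 400 + s))
    seg_err[s] <- mean(abs(f$segment_dG - truth))
    total_err[s] <- abs(sum(f$segment_dG) - sum(truth))
  }
  expect_lt(mean(seg_err), 0.15)
  expect_lt(mean(total_err), 0.3)

  ens <- gen_work_ensemble(truth, sigma = 0.5, n_traj = 25, beta = beta300,
                           seed = 404)
  fit <- asmd_stitch(ens)
  # total equals the sum of segment estimates by construction
  expect_equal(fit$dG[length(fit$dG)], sum(fit$segment_dG),
               tolerance = 1e-12)
  # seed trajectory is the one closest to the segment estimate
  for (i in seq_along(truth)) {
    finals <- ens$segments[[i]]$W[, ncol(ens$segments[[i]]$W)]
    expect_equal(fit$seed_index[i],
                 which.min(abs(finals - fit$segment_dG[i])))
  }

  # malformed ensembles are rejected
  expect_error(work_ensemble(c(0, 1), list(list(xi = xi, W = W + 1)),
                             beta300), "start at 0")
  expect_error(work_ensemble(c(1, 0), list(list(xi = xi, W = W)), beta300),
               "increasing")
  bad_grid <- list(xi = seq(0.2, 1, length.out = 11), W = W)
  expect_error(work_ensemble(c(0, 1), list(bad_grid), beta300),
               "span its boundaries")
})

test_that("work-ensemble CSV round-trips through the long-format schema", {
  beta300 <- 1 / (kB_kcal * 300)
  ens <- gen_work_ensemble(c(1, -0.5), sigma = 0.3, n_traj = 4,
                           beta = beta300, seed = 9, points = 6)
  rows <- do.call(rbind, lapply(seq_along(ens$segments), function(i) {
    sg <- ens$segments[[i]]
    do.call(rbind, lapply(seq_len(nrow(sg$W)), function(tr)
      data.frame(segment = i, trajectory = tr, xi = sg$xi, W = sg$W[tr, ])))
  }))
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  back <- read_work_ensemble(f, beta300)
  expect_equal(back$boundaries, ens$boundaries)
  for (i in 1:2) expect_equal(back$segments[[i]]$W, unname(ens$segments[[i]]$W),
                              tolerance = 1e-12)
  expect_equal(asmd_stitch(back)$segment_dG, asmd_stitch(ens)$segment_dG,
               tolerance = 1e-12)
})

test_that("WHAM unbiases planted potentials: closed form, flat, and double-well", {
  # single unbiased window: PMF is -kBT ln(counts), shifted to 0
  breaks <- seq(0, 1, length.out = 6)
  counts <- c(10, 20, 40, 20, 10)
  w0 <- umbrella_window(0.5, 0, breaks, counts)
  p0 <- wham_1d(list(w0), T = 300)
  expect_equal(p0$dG, -kB_kcal * 300 * log(counts / sum(counts)) -
                 min(-kB_kcal * 300 * log(counts / sum(counts))),
               tolerance = 1e-9)

  # harmonic windows on a flat potential: recovered PMF flat within 0.1
  flat <- function(x) rep(0, length(x))
  wins <- gen_umbrella_samples(flat, centres = seq(-2, 2, by = 0.5),
                               spring = 4, n = 20000, T = 300, seed = 77,
                               breaks = seq(-3.5, 3.5, length.out = 57))
  pf <- wham_1d(wins, T = 300)
  core <- pf$xi > -2 & pf$xi < 2 & !is.na(pf$dG)
  expect_lt(diff(range(pf$dG[core])), 0.1)

  # planted double-well with a 3 kcal/mol barrier
  dw <- function(x) 3 * (x^2 - 1)^2
  wins2 <- gen_umbrella_samples(dw, centres = seq(-1.6, 1.6, by = 0.2),
                                spring = 30, n = 5000, T = 300, seed = 78)
  p2 <- wham_1d(wins2, T = 300)
  barrier <- pmf_at(p2, 0) - min(pmf_at(p2, -1), pmf_at(p2, 1))
  expect_equal(barrier, 3, tolerance = 0.3)

  expect_error(wham_1d(list()), "at least one")
  w_a <- umbrella_window(0, 10, breaks, c(5, 1, 0, 0, 0))
  w_b <- umbrella_window(1, 10, breaks, c(0, 0, 0, 1, 5))
  expect_warning(wham_1d(list(w_a, w_b), T = 300, max_iter = 500),
                 "coverage gap")
})

test_that("segmented Jarzynski and WHAM agree on the same planted double-well", {
  beta300 <- 1 / (kB_kcal * 300)
  dw <- function(x) 3 * (x^2 - 1)^2
  # WHAM route; windows extend past the compared range so its endpoints
  # are bracketed, not anchored by a one-sided edge window
  wins <- gen_umbrella_samples(dw, centres = seq(-2, 2, by = 0.2),
                               spring = 30, n = 5000, T = 300, seed = 101)
  pw <- wham_1d(wins, T = 300)
  # segmented-work route: per-segment truth from the potential itself
  knots <- seq(-1.6, 1.6, by = 0.4)
  ddg <- diff(dw(knots))
  ens <- gen_work_ensemble(ddg, sigma = 0.3, n_traj = 25, beta = beta300,
                           seed = 102, boundaries = knots)
  pa <- asmd_stitch(ens)
  # compare the two estimators at the segment knots
  wham_prof <- vapply(knots, function(x0) pmf_at(pw, x0), numeric(1))
  wham_prof <- wham_prof - wham_prof[1]
  asmd_prof <- c(0, cumsum(pa$segment_dG))
  asmd_prof <- asmd_prof - asmd_prof[1]
  ref <- dw(knots) - dw(knots)[1]
  expect_lt(max(abs(wham_prof - ref)), 0.3)
  expect_lt(max(abs(asmd_prof - ref)), 0.3)
  expect_lt(max(abs(wham_prof - asmd_prof)), 0.3)
})
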