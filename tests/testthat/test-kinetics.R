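test_that("boundaries are placed by linear interpolation at the threshold", {
  # piecewise-linear rise 0 -> 4 kBT over z = -12 -> -8, mirrored above
  zb <- seq(-17.875, 17.875, 0.25)
  ramp <- function(z) pmin(4, pmax(0, (z + 12) )) # slope 1 per A
  F <- ifelse(zb < 0, ramp(zb), ramp(-zb))
  F[abs(zb) < 8] <- 4
  prof <- free_energy_profile(zb, F)
  b <- find_boundaries(prof, threshold = 2.0)
  expect_equal(b$z_l, -10.0, tolerance = 0.26)
  expect_equal(b$z_u, -b$z_l, tolerance = 1e-9) # symmetric profile

  # threshold 0 on a strictly positive-interior profile: bulk edges
  F0 <- ifelse(abs(zb) < 10, 1, 0)
  b0 <- find_boundaries(free_energy_profile(zb, F0), threshold = 0)
  expect_lt(b0$z_l, -9.5)
  expect_gt(b0$z_u, 9.5)

  # no crossing on one side is an error naming the side
  Fl <- ifelse(zb > 0 & zb < 10, 4, 0)
  expect_error(find_boundaries(free_energy_profile(zb, Fl), 2), "lower")
})

test_that("crossing detection resolves fates on constructed paths", {
  b <- kinetic_boundaries(-5, 5, 0)
  # monotone path z_l -> z_u: one upward crossing, all fates successful
  cs <- detect_crossings(seq(-8, 8, 0.5), b, dt = 0.01)
  expect_equal(cs$n_k_lu, 1)
  expect_equal(cs$p_0u, 1)
  expect_equal(cs$f_0u, 1)
  expect_equal(cs$full_up, 1)

  # crossing z_l upward then immediately returning: one crossing, no success
  z <- c(-8, -6, -4.5, -6, -8)
  cs2 <- detect_crossings(z, b, dt = 0.01)
  expect_equal(cs2$n_k_lu, 1)
  expect_equal(cs2$n_0_down + cs2$n_0_up, 0)
  expect_equal(cs2$full_up + cs2$full_down, 0)

  # the event log records crossings with boundary, direction and fate
  expect_equal(nrow(cs$events), 3) # z_l up, z_0 up, z_u up
  expect_equal(cs$events$boundary, c("z_l", "z_0", "z_u"))
  expect_equal(cs$events$direction, rep("up", 3))
  expect_equal(cs$events$fate[cs$events$boundary == "z_0"], "reached")

  expect_error(detect_crossings(seq(-1, 1, 0.1), b, dt = 0.01), "cover")
  expect_error(detect_crossings(seq(-8, 8, 0.5), b, dt = 1, strict = TRUE),
               "resolution")
  expect_warning(detect_crossings(seq(-8, 8, 0.5), b, dt = 1), "resolution")
})

test_that("the exit fraction matches the gambler's-ruin closed form", {
  # symmetric discrete walk on 5 sites: f(z_0 -> z_u) = 1/2
  ch <- toy_chain(rep(0, 6))
  z <- toy_path(ch, 2e5, seed = 14)
  b <- kinetic_boundaries(-2, 2, 0)
  cs <- detect_crossings(z, b, dt = 0.01)
  expect_gt(cs$n_exits, 100)
  expect_lt(abs(cs$f_0u - 0.5), 3 * cs$f_se)
})

test_that("solute crossing rates follow rho k_w exp(F_w - F)", {
  expect_equal(solute_crossing_rate(10, 1, 2, 2), 10)
  expect_equal(solute_crossing_rate(10, 0.5, 0, 0), 5)
  expect_equal(solute_crossing_rate(10, 1, 1, 0), 10 * exp(1))
  expect_error(solute_crossing_rate(10, 0, 0, 0), "rho")
})

test_that("the assembled rate reduces to v_w k_w when all factors are unity", {
  b <- kinetic_boundaries(-5, 5, 0)
  stats <- structure(list(
    k_lu = 10, k_ul = 10, n_k_lu = 1000, n_k_ul = 1000,
    p_0l = 1, p_0l_se = 0, p_0u = 1, p_0u_se = 0,
    n_0_down = 100, n_0_up = 100,
    f_0u = 1, f_0l = 1, f_se = 0, n_exits = 100,
    full_up = 10, full_down = 10, time_ns = 100, boundaries = b,
    dt = 0.01), class = "crossing_stats")
  flat <- free_energy_profile(seq(-17.875, 17.875, 0.25), 0)
  est <- kinetic_pd(stats, flat, direction = "up")
  expect_equal(est$p_d, water_volume() * 10 * 1e9 / 1e-14, tolerance = 1e-9)
})

test_that("the factorized estimator matches the exact Markov-chain flux", {
  B <- 4
  half <- c(0, rep(B, 2), rep(0, 4))
  ch <- toy_chain(c(half, rev(half)))
  m <- length(ch$sites)
  # exact one-way flux by linear algebra
  flux <- ch$pi[2] * ch$P[2, 3]
  interior <- 3:(m - 2)
  h <- solve(diag(length(interior)) - ch$P[interior, interior],
             ch$P[interior, m - 1])
  r_exact <- flux * h[1] / 0.01 * 1000 # per ns at dt = 0.01 ps

  z <- toy_path(ch, 3e7, seed = 6)
  bnd <- kinetic_boundaries(ch$sites[2], ch$sites[m - 1], 0)
  cs <- detect_crossings(z, bnd, dt = 0.01)
  prof <- free_energy_profile(ch$sites, ch$Fs, se = 0, count = 1e6,
                              bin_width = 1,
                              bulk_region = abs(ch$sites[1]) + c(-0.75, 0.75))
  est <- kinetic_pd(cs, prof)
  r_est <- kinetic_pd_combined(est)$p_d * 1e-14 / water_volume() / 1e9
  expect_equal(r_est, r_exact, tolerance = 0.02)

  # Eq.-1 equivalence: following crossings all the way (full passages)
  # agrees with the factorized form within sampling error
  r_direct <- cs$full_up / cs$time_ns
  expect_equal(r_direct, r_exact, tolerance = 0.1)
})

test_that("upward and downward estimates agree on equilibrium data", {
  m <- build_pore_model("wildtype_like", top_barrier = 3)
  p <- langevin_params(dt = 0.01, out_interval = 0.01, n_steps = 2e7,
                       seed = 21)
  z <- as.vector(simulate_langevin(m, p, raw = TRUE))
  dec <- z[seq(1, length(z), by = 200)]
  tr <- z_traj(dec, dt = 2, species = "solute")
  prof <- density_free_energy_1d(tr, "solute")
  bnd <- find_boundaries(prof, 2.0)
  cs <- detect_crossings(z, bnd, dt = 0.01)
  est <- kinetic_pd(cs, prof)
  expect_equal(nrow(est), 2)
  dz <- abs(diff(est$p_d))
  expect_lt(dz, 2 * sqrt(sum(est$se^2)))

  # coarsening the resolution reduces detected crossings, while the
  # assembled estimate stays within uncertainty
  z5 <- z[seq(1, length(z), by = 5)]
  cs5 <- suppressWarnings(detect_crossings(z5, bnd, dt = 0.05))
  expect_lt(cs5$n_k_lu, cs$n_k_lu)
  est5 <- kinetic_pd(cs5, prof)
  comb <- kinetic_pd_combined(est)
  comb5 <- kinetic_pd_combined(est5)
  expect_lt(abs(comb5$p_d - comb$p_d),
            3 * sqrt(comb$se^2 + comb5$se^2) + 0.2 * comb$p_d)

  # boundary threshold robustness: +/- 0.25 kBT moves p_d by less than
  # the estimate's uncertainty scale
  for (thr in c(1.75, 2.25)) {
    bt <- find_boundaries(prof, thr)
    ct <- detect_crossings(z, bt, dt = 0.01)
    et <- kinetic_pd_combined(kinetic_pd(ct, prof, boundaries = bt))
    expect_lt(abs(et$p_d - comb$p_d), 3 * sqrt(comb$se^2 + et$se^2) +
                0.2 * comb$p_d)
  }
})
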