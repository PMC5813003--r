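test_that("uniform density gives a zero profile and counts are conserved", {
  set.seed(1)
  n <- 20000
  tr <- trajectory_table(tibble::tibble(
    time = 50, id = seq_len(n), species = "water", monomer = 0L,
    z = runif(n, -18, 18), d_xy = runif(n, 0, 2)))
  prof <- density_free_energy_1d(tr, "water", bin_width = 2)
  expect_s3_class(prof, "fe_profile")
  expect_lt(max(abs(prof$F), na.rm = TRUE), 0.2)
  expect_equal(sum(prof$count), n)
})

test_that("the count-ratio identity F = ln(bulk/count) holds exactly", {
  # counts [100, 37, 100] in equal-volume bins; bulk = the outer bins
  pore <- pore_definition(half_length = 1.4, sf_region = c(0.5, 1.2),
                          bulk_region = c(1.5, 4.5))
  mk <- function(zc, k) tibble::tibble(
    time = 50, id = seq_len(k), species = "water", monomer = 0L,
    z = zc, d_xy = 0.1)
  tr <- trajectory_table(dplyr::bind_rows(
    mk(-3, 100), mk(0, 37), mk(3, 100)) |>
      dplyr::mutate(id = dplyr::row_number()))
  prof <- density_free_energy_1d(tr, "water", pore = pore, bin_width = 3,
                                 zlim = c(-4.5, 4.5))
  expect_equal(prof$F, c(0, log(100 / 37), 0), tolerance = 1e-12)
  expect_equal(prof$F[2], 0.9943, tolerance = 1e-4)
})

test_that("profiles recover the generating landscape minima", {
  m <- build_pore_model("wildtype_like")
  p <- langevin_params(dt = 0.01, out_interval = 0.1, n_steps = 2e6,
                       seed = 11)
  tr <- simulate_langevin(m, p)
  prof <- density_free_energy_1d(tr, "water")
  d <- tidy(prof)
  dd <- d[d$z > -9 & d$z < 1.5 & is.finite(d$F), ]
  loc <- dd$z[which(diff(sign(diff(dd$F))) == 2) + 1]
  # the four lower minima appear spaced 2.5 A within one bin width
  expect_gte(length(loc), 4)
  near <- sapply(m$wells[m$wells < 1.5], \(w) min(abs(loc - w)))
  expect_true(all(near <= attr(prof, "bin_width")))
})

test_that("2D maps are volume-normalised and bulk-referenced", {
  set.seed(2)
  n <- 60000
  # uniform 3D density in a cylinder: d_xy ~ r sqrt(u)
  tr <- trajectory_table(tibble::tibble(
    time = 50, id = seq_len(n), species = "water", monomer = 0L,
    z = runif(n, -18, 18), d_xy = 5 * sqrt(runif(n))))
  mp <- density_free_energy_2d(tr, "water", bin_width = c(3, 1))
  inner <- dplyr::filter(tibble::as_tibble(mp), d_xy < 4.5, count > 0)
  expect_lt(max(abs(inner$F)), 0.35)

  # all samples in one bin -> that bin is the unique minimum
  tr1 <- trajectory_table(tibble::tibble(
    time = 50, id = 1:100, species = "water", monomer = 0L,
    z = c(rep(0, 80), runif(20, 12, 18)), d_xy = 0.5))
  mp1 <- density_free_energy_2d(tr1, "water", bin_width = c(2, 1))
  m1 <- tibble::as_tibble(mp1) |> dplyr::filter(is.finite(F))
  expect_equal(m1$z[which.min(m1$F)], 0, tolerance = 1.1)

  # radial confinement shrinking at z = 8 A shows up as a shrunk
  # accessible d_xy range there
  m <- build_pore_model("wildtype_like")
  p <- langevin_params(dt = 0.01, out_interval = 0.1, n_steps = 1e6,
                       seed = 4)
  trs <- simulate_langevin(m, p)
  mp2 <- density_free_energy_2d(trs, "water", bin_width = c(0.5, 0.5))
  amax <- tibble::as_tibble(mp2) |>
    dplyr::filter(count > 0) |>
    dplyr::summarise(dmax = max(d_xy), .by = "z")
  at8 <- amax$dmax[abs(amax$z - 8) < 0.35]
  at5 <- amax$dmax[abs(amax$z - 5) < 0.35]
  expect_length(at8, 2)
  expect_length(at5, 2)
  expect_lt(max(at8), min(at5))
})

test_that("exponential averaging combines aligned profiles correctly", {
  zb <- seq(-0.5, 0.5, 1)
  mk <- function(F) free_energy_profile(zb, F, se = 0.1, count = 100,
                                        bin_width = 1)
  # identical profiles -> unchanged, zero jackknife error
  same <- combine_monomer_profiles(list(mk(c(0, 1)), mk(c(0, 1)),
                                        mk(c(0, 1))))
  expect_equal(same$F - same$F[1], c(0, 1), tolerance = 1e-10)
  expect_equal(same$se, c(0, 0), tolerance = 1e-10)

  # profiles differing by additive constants align to the same shape
  offs <- combine_monomer_profiles(list(mk(c(0, 1)), mk(c(2, 3)),
                                        mk(c(-1, 0))))
  expect_equal(offs$F - offs$F[1], c(0, 1), tolerance = 1e-8)

  # pre-aligned two-bin [0,1] and [0,2]: the second bin is the direct
  # exponential average -ln((e^-1 + e^-2)/2) ~ 1.38
  two <- combine_monomer_profiles(list(mk(c(0, 1)), mk(c(0, 2))),
                                  align = FALSE)
  expect_equal(two$F[2] - two$F[1], -log((exp(-1) + exp(-2)) / 2),
               tolerance = 1e-6)

  # permutation invariance
  perm <- combine_monomer_profiles(list(mk(c(0, 2)), mk(c(0, 1))),
                                   align = FALSE)
  expect_equal(perm$F, two$F, tolerance = 1e-8)

  # combined profile is bounded below by the bin-wise minimum of the
  # aligned inputs
  a <- mk(c(0, 1.2)); b <- mk(c(0, 0.4))
  comb <- combine_monomer_profiles(list(a, b), align = FALSE)
  rel <- comb$F - comb$F[1]
  expect_gte(rel[2], 0.4 - 1e-8)

  expect_error(combine_monomer_profiles(list(mk(c(0, 1)))), "2")
  expect_error(combine_monomer_profiles(list(
    mk(c(0, 1)),
    free_energy_profile(c(0, 1), c(0, 1), bin_width = 1))), "identical")
})

test_that("jackknife errors scale like 1/sqrt(n) for iid monomers", {
  zb <- seq(-4.5, 4.5, 1)
  mk_set <- function(n, seed) {
    set.seed(seed)
    lapply(seq_len(n), \(i) free_energy_profile(
      zb, rnorm(length(zb), 0, 0.3), se = 0.1, count = 100, bin_width = 1))
  }
  se4 <- mean(combine_monomer_profiles(mk_set(4, 5))$se)
  se16 <- mean(combine_monomer_profiles(mk_set(16, 5))$se)
  expect_lt(se16 / se4, 0.8)
  expect_gt(se16 / se4, 0.25)
})

test_that("barrier heights and barrier-model factors behave as closed forms", {
  zb <- seq(-17.875, 17.875, 0.25)
  F <- rep(0, length(zb))
  expect_equal(barrier_height(free_energy_profile(zb, F)), 0)
  F[which.min(abs(zb - 3))] <- 2.3
  expect_equal(barrier_height(free_energy_profile(zb, F)), 2.3)
  masked <- free_energy_profile(zb, ifelse(abs(zb) < 9, NA, 0))
  expect_error(barrier_height(masked), "unmasked")

  expect_equal(barrier_permeability_factor(1, 1), 1)
  expect_equal(barrier_permeability_factor(0, 1), exp(1))
  expect_equal(barrier_permeability_factor(0, log(2)), 2)

  # recovery of the model barrier from a long run
  m <- build_pore_model("wildtype_like")
  p <- langevin_params(dt = 0.01, out_interval = 0.1, n_steps = 2e6,
                       seed = 8)
  prof <- density_free_energy_1d(simulate_langevin(m, p), "water")
  expect_equal(barrier_height(prof), m$f_b, tolerance = 0.25)
})
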