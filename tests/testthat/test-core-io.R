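test_that("trajectory tables roundtrip through the TSV dialect", {
  tr <- tiny_traj()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(as.data.frame(back), as.data.frame(tr))
  expect_equal(attr(back, "dt"), 50)
})

test_that("trajectory validation rejects malformed input", {
  base <- tibble::tibble(time = c(0, 50, 100), id = 1L, species = "water",
                         monomer = 0L, z = 0, d_xy = 0.1)
  # two frames x three molecules -> six records, dt from the time difference
  six <- trajectory_table(tibble::tibble(
    time = rep(c(0, 25), each = 3), id = rep(1:3, 2), species = "water",
    monomer = 0L, z = 0, d_xy = 0))
  expect_equal(nrow(six), 6)
  expect_equal(attr(six, "dt"), 25)

  expect_error(trajectory_table(dplyr::mutate(base, time = c(0, 50, 75))),
               "non-uniform")
  dup <- dplyr::bind_rows(base, base[1, ])
  expect_error(trajectory_table(dup), "duplicate")
  expect_error(trajectory_table(dplyr::mutate(base, d_xy = -1)), "d_xy")
  expect_error(trajectory_table(dplyr::mutate(base, species = "ion")),
               "species")
  # species must be constant per molecule id
  expect_error(trajectory_table(tibble::tibble(
    time = c(0, 50), id = 1L, species = c("water", "solute"),
    monomer = 0L, z = 0, d_xy = 0)), "constant")
})

test_that("decreasing frame times in a file raise a parse error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\tid\tspecies\tmonomer\tz\td_xy",
               "100\t1\twater\t0\t0\t0.1",
               "50\t1\twater\t0\t1\t0.1",
               "0\t1\twater\t0\t2\t0.1"), f)
  expect_error(read_trajectory(f), "non-uniform|duplicate|increasing",
               ignore.case = TRUE)
})

test_that("XYZ frames project into the channel frame correctly", {
  # two reference atoms centred at (1, 1, 2); mobile atom at COM + (3, 4, 5)
  xyz <- c("3", "frame 1 time = 0.0",
           "R1 0 0 0", "R2 2 2 4", "W1 4 5 7",
           "3", "frame 2 time = 50.0 (rigidly translated by (7, -3, 2))",
           "R1 7 -3 2", "R2 9 -1 6", "W1 11 2 9")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(xyz, f)
  map <- tibble::tibble(
    atom = c("R1", "R2", "W1"),
    role = c("reference", "reference", "mobile"),
    monomer = 0L, molecule = c(NA, NA, 1L),
    species = c(NA, NA, "water"))
  tr <- read_trajectory(f, format = "xyz", site_map = map)
  # Pythagoras: axial offset 5, radial sqrt(3^2 + 4^2) = 5
  expect_equal(tr$z, c(5, 5), tolerance = 1e-12)
  expect_equal(tr$d_xy, c(5, 5), tolerance = 1e-12)

  coords <- read_xyz_frames(f)
  # molecule exactly at the reference COM
  at_com <- dplyr::mutate(coords,
    x = ifelse(atom == "W1", ifelse(frame == 0, 1, 8), x),
    y = ifelse(atom == "W1", ifelse(frame == 0, 1, -2), y),
    z = ifelse(atom == "W1", ifelse(frame == 0, 2, 4), z))
  tr0 <- project_to_pore_frame(at_com, map)
  expect_equal(tr0$z, c(0, 0), tolerance = 1e-12)
  expect_equal(tr0$d_xy, c(0, 0), tolerance = 1e-12)
})

test_that("pore projection is invariant under rotation about the axis", {
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pts <- rbind(c(0, 0, 0), c(2, 2, 4), c(4, 5, 7))
  rot <- pts %*% t(R)
  mk <- function(p) tibble::tibble(frame = 0L, time = 0,
                                   atom = c("R1", "R2", "W1"),
                                   x = p[, 1], y = p[, 2], z = p[, 3])
  map <- tibble::tibble(atom = c("R1", "R2", "W1"),
                        role = c("reference", "reference", "mobile"),
                        monomer = 0L, molecule = c(NA, NA, 1L),
                        species = c(NA, NA, "water"))
  a <- project_to_pore_frame(mk(pts), map)
  b <- project_to_pore_frame(mk(rot), map)
  expect_equal(a$z, b$z, tolerance = 1e-12)
  expect_equal(a$d_xy, b$d_xy, tolerance = 1e-12)
  expect_error(project_to_pore_frame(mk(pts), map[map$role == "mobile", ]),
               "reference")
})

test_that("monomer mean/SEM follows sigma/sqrt(n) with n-1 denominator", {
  st <- monomer_mean_sem(c(5, 5, 5, 5))
  expect_equal(st$mean, 5)
  expect_equal(st$sem, 0)

  st <- monomer_mean_sem(c(1, 2, 3, 4))
  expect_equal(st$mean, 2.5)
  expect_equal(st$sem, sd(c(1, 2, 3, 4)) / 2)
  expect_equal(st$sem, 0.6455, tolerance = 1e-4)

  # permutation invariance and linearity
  expect_equal(monomer_mean_sem(c(4, 1, 3, 2)), st)
  st3 <- monomer_mean_sem(3 * c(1, 2, 3, 4))
  expect_equal(st3$mean, 3 * st$mean)
  expect_equal(st3$sem, 3 * st$sem)

  expect_error(monomer_mean_sem(5), "at least 2")
})

test_that("profiles roundtrip through TSV including masked bins", {
  prof <- free_energy_profile(z = seq(-1, 1, 0.5),
                              F = c(0, 0.5, NA, 0.25, 0),
                              se = c(0.1, 0.1, NA, 0.1, 0.1),
                              count = c(10, 6, 0, 8, 10),
                              bulk_region = c(12, 18))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, f)
  expect_match(grep("NA", readLines(f), value = TRUE)[1], "NA")
  back <- read_profile(f)
  expect_equal(back$F, prof$F)
  expect_equal(back$se, prof$se)
  expect_equal(back$count, prof$count)
  expect_equal(attr(back, "bin_width"), attr(prof, "bin_width"))
  expect_equal(attr(back, "bulk_region"), c(12, 18))

  # empty profile -> header-only body
  ep <- free_energy_profile(numeric(), numeric(), bin_width = 0.25)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_profile(ep, f2)
  expect_equal(nrow(read_profile(f2)), 0)

  expect_error(write_profile(free_energy_profile(0:1, c(Inf, 0)), f2),
               "finite")
})

test_that("pore definitions roundtrip through YAML and validate", {
  p <- pore_definition(half_length = 8, radial_cutoff = 6,
                       sf_region = c(5, 8), bulk_region = c(11, 16))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_pore_definition(p, f)
  expect_equal(read_pore_definition(f), p)
  expect_error(pore_definition(bulk_region = c(5, 18)), "disjoint")
})
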