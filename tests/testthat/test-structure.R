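test_that("hydrogen bonds require both the distance and angle criteria", {
  yes <- detect_hbonds(hb_coords(make_hbond_fixture(2.8, 180)), hb_donors,
                       "acceptor")
  expect_equal(nrow(yes), 1)
  expect_equal(yes$distance, 2.8, tolerance = 1e-9)

  too_far <- detect_hbonds(hb_coords(make_hbond_fixture(3.6, 180)),
                           hb_donors, "acceptor")
  expect_equal(nrow(too_far), 0)

  too_bent <- detect_hbonds(hb_coords(make_hbond_fixture(3.0, 140)),
                            hb_donors, "acceptor")
  expect_equal(nrow(too_bent), 0)

  # both cutoffs are inclusive
  boundary <- detect_hbonds(hb_coords(make_hbond_fixture(3.5, 150)),
                            hb_donors, "acceptor")
  expect_equal(nrow(boundary), 1)

  expect_error(detect_hbonds(hb_coords(make_hbond_fixture(2.8, 180))[-2, ],
                             hb_donors, "acceptor"), "topology")
})

test_that("hydrogen-bond detection is invariant under rigid-body motion", {
  p <- make_hbond_fixture(3.2, 165)
  th <- 0.9
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  moved <- p %*% R + matrix(rep(c(5, -3, 11), each = 3), 3, 3)
  rownames(moved) <- rownames(p)
  a <- detect_hbonds(hb_coords(p), hb_donors, "acceptor")
  b <- detect_hbonds(hb_coords(moved), hb_donors, "acceptor")
  expect_equal(nrow(b), 1)
  expect_equal(a$distance, b$distance, tolerance = 1e-9)
  expect_equal(a$angle, b$angle, tolerance = 1e-9)
})

test_that("SF bonding probabilities match a constructed design", {
  # 40 water-frame samples in the SF region per monomer, 2 monomers:
  # P(A) = 0.5, P(B) = 0.25, P(both) = 0.10 by construction
  n <- 40
  design <- tibble::tibble(
    sample = seq_len(n),
    A = sample %in% 1:20, B = sample %in% c(1:4, 21:26))
  # per-sample bond rows
  mk_bonds <- function(mono) {
    dplyr::bind_rows(
      tibble::tibble(time = 50 * design$sample[design$A], id = mono * 100L,
                     site = "A"),
      tibble::tibble(time = 50 * design$sample[design$B], id = mono * 100L,
                     site = "B"))
  }
  bonds <- dplyr::bind_rows(mk_bonds(1), mk_bonds(2))
  traj <- trajectory_table(dplyr::bind_rows(lapply(1:2, \(mono)
    tibble::tibble(time = 50 * seq_len(n), id = mono * 100L,
                   species = "water", monomer = mono, z = 7.5,
                   d_xy = 1))))
  out <- sf_hbond_probability(traj, bonds, sites = c("A", "B"))
  expect_equal(out$probability[out$site == "A"], 50)
  expect_equal(out$probability[out$site == "B"], 25)
  expect_equal(out$probability[out$site == "both"], 10)
  # joint probability cannot exceed either marginal
  expect_lte(out$probability[out$site == "both"],
             min(out$probability[out$site != "both"]))

  # samples outside the SF region (z = 5) are excluded from the statistic
  traj5 <- trajectory_table(dplyr::bind_rows(lapply(1:2, \(mono)
    tibble::tibble(time = 50 * seq_len(n), id = mono * 100L,
                   species = "water", monomer = mono,
                   z = ifelse(seq_len(n) <= 20, 7.5, 5), d_xy = 1))))
  out5 <- sf_hbond_probability(traj5, bonds, sites = c("A", "B"))
  expect_equal(out5$probability[out5$site == "A"], 100)

  expect_error(sf_hbond_probability(
    trajectory_table(tibble::tibble(time = 50, id = 1L, species = "water",
                                    monomer = 0L, z = 0, d_xy = 1)),
    bonds, sites = c("A", "B")), "SF region")
})

test_that("bond counts per molecule average correctly in a z interval", {
  traj <- trajectory_table(tibble::tibble(
    time = 50 * 1:4, id = 1L, species = "water", monomer = 0L,
    z = 5, d_xy = 1))
  bonds <- tibble::tibble(time = c(50, 50, 100), id = 1L,
                          site = c("A", "B", "A"))
  out <- hbond_count_interval(traj, bonds, z_range = c(4, 6.8))
  expect_equal(out$mean_bonds, (2 + 1 + 0 + 0) / 4)
})

test_that("dihedral angles use the signed atan2 convention", {
  expect_equal(dihedral_angle(make_dihedral_fixture(0)), 0,
               tolerance = 1e-9)
  expect_equal(dihedral_angle(make_dihedral_fixture(180)), 180,
               tolerance = 1e-9)
  expect_equal(dihedral_angle(make_dihedral_fixture(-94)), -94,
               tolerance = 1e-6)
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(dihedral_angle(collinear), "collinear")
})

test_that("gate classification applies hysteresis and dwell suppression", {
  # constant open series: one segment, no events
  out <- classify_gate(rep(-94, 50))
  expect_equal(unique(out$states$state), "open")
  expect_equal(nrow(out$events), 0)

  # alternating dwells of 100 frames: every alternation is an event
  ang <- rep(rep(c(-94, -35), 4), each = 100)
  out2 <- classify_gate(ang, gate_spec(min_dwell = 10))
  expect_equal(nrow(out2$events), 7)
  expect_equal(out2$events$from[1], "open")
  expect_equal(out2$events$to[1], "closed")

  # a 3-frame excursion is suppressed below the minimum dwell
  ang3 <- c(rep(-94, 50), rep(-35, 3), rep(-94, 50))
  out3 <- classify_gate(ang3, gate_spec(min_dwell = 10))
  expect_equal(nrow(out3$events), 0)

  # hysteresis: frames outside both windows inherit the previous state
  angh <- c(rep(-94, 20), rep(-60, 15), rep(-35, 20))
  outh <- classify_gate(angh, gate_spec(min_dwell = 5))
  expect_equal(outh$states$state[30], "open")
  expect_equal(outh$states$state[55], "closed")

  expect_error(gate_spec(open_mode = -50, closed_mode = -45), "overlap")
  expect_error(classify_gate(numeric()), "empty")
})

test_that("gate classification is idempotent and reverses with the series", {
  ang <- rep(rep(c(-94, -35), 3), each = 60)
  sp <- gate_spec(min_dwell = 10)
  out <- classify_gate(ang, sp)
  # reclassify the mode-mapped state series: nothing changes
  remap <- ifelse(out$states$state == "open", -94, -35)
  again <- classify_gate(remap, sp)
  expect_equal(again$states$state, out$states$state)
  # reversing the series reverses event directions
  outr <- classify_gate(rev(ang), sp)
  expect_equal(nrow(outr$events), nrow(out$events))
  expect_equal(outr$events$from, rev(out$events$to))
})

test_that("the conserved-contact filter keeps and excludes monomers", {
  rule <- quality_rule()
  mk <- function(mono, frac_ok, pair) tibble::tibble(
    monomer = mono, pair = pair,
    distance = c(rep(3, round(100 * frac_ok)),
                 rep(5, 100 - round(100 * frac_ok))))
  all_pairs <- function(mono, fracs) dplyr::bind_rows(
    Map(\(p, f) mk(mono, f, p), rule$pairs, fracs))

  d <- dplyr::bind_rows(
    all_pairs(0, c(1, 1, 1, 1)),        # always in contact -> keep
    all_pairs(1, c(1, 0.85, 1, 1)),     # one pair below 90% -> exclude
    all_pairs(2, c(0.9, 0.95, 1, 1)))   # exactly 90% -> keep (inclusive)
  out <- npa_quality_filter(d, rule)
  expect_equal(out$keep[out$monomer == 0], TRUE)
  expect_equal(out$keep[out$monomer == 1], FALSE)
  expect_equal(out$keep[out$monomer == 2], TRUE)

  # monotone: lowering the required fraction keeps at least as many
  out80 <- npa_quality_filter(d, quality_rule(min_fraction = 0.8))
  expect_true(all(out$keep <= out80$keep))

  expect_error(npa_quality_filter(d[d$pair != rule$pairs[1], ], rule),
               "missing pair")
})
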