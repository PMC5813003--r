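#' Hydrogen-bond detection criteria
#'
#' A donor-acceptor pair is hydrogen bonded when the donor-acceptor
#' distance is at most `distance_cutoff` and the donor-hydrogen-acceptor
#' angle is at least `angle_cutoff` for at least one hydrogen attached to
#' the donor (180 degrees is linear). Both cutoffs are inclusive.
#'
#' @param distance_cutoff Donor-acceptor distance cutoff, Angstrom.
#'   Default 3.5.
#' @param angle_cutoff Donor-hydrogen-acceptor angle cutoff, degrees in
#'   (0, 180]. Default 150.
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(distance_cutoff = 3.5, angle_cutoff = 150) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0, angle_cutoff <= 180)
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff), class = "hbond_criteria")
}

#' Detect hydrogen bonds in frame coordinates
#'
#' @param coords A data frame of atom coordinates: columns `atom`, `x`,
#'   `y`, `z`, and optionally `frame` (multi-frame input is evaluated per
#'   frame).
#' @param donors A data frame pairing donors with their hydrogens: columns
#'   `donor`, `hydrogen` (atom names; a donor may appear with several
#'   hydrogens). Every hydrogen must have a parent donor present in
#'   `coords`.
#' @param acceptors Character vector of acceptor atom names.
#' @param criteria An [hbond_criteria()].
#' @return A tibble of bonds: `frame` (if present), `donor`, `hydrogen`,
#'   `acceptor`, `distance` (donor-acceptor, Angstrom) and `angle`
#'   (donor-hydrogen-acceptor, degrees).
#' @export
detect_hbonds <- function(coords, donors, acceptors,
                          criteria = hbond_criteria()) {
  coords <- as_tibble(coords)
  donors <- as_tibble(donors)
  stopifnot(all(c("donor", "hydrogen") %in% names(donors)))
  if (!"frame" %in% names(coords)) coords$frame <- 0L
  missing_parent <- setdiff(donors$hydrogen, coords$atom)
  if (length(missing_parent) > 0 ||
      length(setdiff(donors$donor, coords$atom)) > 0)
    abort("donor/hydrogen atoms absent from the coordinates (topology error)")
  if (anyDuplicated(coords[c("frame", "atom")]))
    abort("duplicate atom names within a frame")

  cand <- tidyr::expand_grid(donors, acceptor = acceptors) |>
    filter(.data$acceptor != .data$donor)
  xyz <- function(role) {
    cc <- coords[, c("frame", "atom", "x", "y", "z")]
    names(cc) <- c("frame", role, paste(c("x", "y", "z"), role, sep = "_"))
    cc
  }
  res <- tidyr::expand_grid(frame = unique(coords$frame), cand) |>
    inner_join(xyz("donor"), by = c("frame", "donor")) |>
    inner_join(xyz("hydrogen"), by = c("frame", "hydrogen")) |>
    inner_join(xyz("acceptor"), by = c("frame", "acceptor")) |>
    mutate(
      distance = sqrt((.data$x_donor - .data$x_acceptor)^2 +
                        (.data$y_donor - .data$y_acceptor)^2 +
                        (.data$z_donor - .data$z_acceptor)^2),
      angle = vec_angle_deg(
        .data$x_donor - .data$x_hydrogen,
        .data$y_donor - .data$y_hydrogen,
        .data$z_donor - .data$z_hydrogen,
        .data$x_acceptor - .data$x_hydrogen,
        .data$y_acceptor - .data$y_hydrogen,
        .data$z_acceptor - .data$z_hydrogen)) |>
    filter(.data$distance <= criteria$distance_cutoff,
           .data$angle >= criteria$angle_cutoff) |>
    select("frame", "donor", "hydrogen", "acceptor", "distance", "angle")
  # a donor-acceptor pair bonds through at most one hydrogen: keep the best
  res |>
    group_by(.data$frame, .data$donor, .data$acceptor) |>
    slice_max(.data$angle, n = 1, with_ties = FALSE) |>
    ungroup()
}

vec_angle_deg <- function(ax, ay, az, bx, by, bz) {
  dot <- ax * bx + ay * by + az * bz
  na <- sqrt(ax^2 + ay^2 + az^2)
  nb <- sqrt(bx^2 + by^2 + bz^2)
  acos(pmin(1, pmax(-1, dot / (na * nb)))) * 180 / pi
}

#' Probability of SF-region waters hydrogen bonding to pore sites
#'
#' Every (water, frame) occurrence inside the SF region
#' (`sf_region[1] < z < sf_region[2]`, `d_xy <` radial cutoff) is one
#' sample; for each named site the probability is the fraction of samples
#' bonded to that site, and `both` the fraction bonded to the two first
#' sites simultaneously. Monomer means and SEMs use
#' [monomer_mean_sem()].
#'
#' @param traj A `traj_tbl` of water positions.
#' @param bonds A data frame of bond annotations: columns `time`, `id`
#'   (water molecule), `site` (site label; one row per bonded pair and
#'   frame).
#' @param pore A [pore_definition()].
#' @param sites Character vector of at least two site labels to report.
#' @return A tibble with one row per site (plus `"both"`): `site`,
#'   `probability` (%), `sem` (%), `n_monomers`, `n_samples`.
#' @export
sf_hbond_probability <- function(traj, bonds, pore = pore_definition(),
                                 sites) {
  stopifnot(inherits(traj, "traj_tbl"), length(sites) >= 2)
  bonds <- as_tibble(bonds)
  stopifnot(all(c("time", "id", "site") %in% names(bonds)))
  x <- as_tibble(traj) |>
    filter(.data$species == "water", in_sf(.data$z, .data$d_xy, pore))
  if (nrow(x) == 0) abort("no water samples inside the SF region")

  flags <- x |> select("time", "id", "monomer")
  for (s in sites) {
    b <- bonds |> filter(.data$site == s) |> distinct(.data$time, .data$id) |>
      mutate(!!paste0(".b_", s) := TRUE)
    flags <- left_join(flags, b, by = c("time", "id"))
  }
  flags <- flags |> mutate(across(starts_with(".b_"), \(v) !is.na(v)))
  flags$.b_both <- flags[[paste0(".b_", sites[1])]] &
    flags[[paste0(".b_", sites[2])]]

  per_monomer <- flags |>
    summarise(across(starts_with(".b_"), mean), n = dplyr::n(),
              .by = "monomer")
  labels <- c(sites, "both")
  out <- map(labels, \(s) {
    v <- per_monomer[[paste0(".b_", s)]]
    if (length(v) >= 2) {
      st <- monomer_mean_sem(v)
      tibble(site = s, probability = 100 * st$mean, sem = 100 * st$sem,
             n_monomers = st$n, n_samples = sum(per_monomer$n))
    } else {
      tibble(site = s, probability = 100 * v, sem = NA_real_,
             n_monomers = 1L, n_samples = sum(per_monomer$n))
    }
  }) |> list_rbind()
  out
}

#' Average hydrogen-bond count per molecule in a z interval
#'
#' Generalisation of [sf_hbond_probability()] with counts instead of
#' indicators: the average number of bonds per (water, frame) occurrence in
#' the interval, per monomer and overall.
#'
#' @inheritParams sf_hbond_probability
#' @param z_range Numeric length-2 z interval, Angstrom.
#' @param sites Sites whose bonds are counted (default: all in `bonds`).
#' @return A one-row tibble: `mean_bonds`, `sem`, `n_monomers`,
#'   `n_samples`.
#' @export
hbond_count_interval <- function(traj, bonds, z_range,
                                 pore = pore_definition(), sites = NULL) {
  stopifnot(inherits(traj, "traj_tbl"), length(z_range) == 2)
  bonds <- as_tibble(bonds)
  if (!is.null(sites)) bonds <- filter(bonds, .data$site %in% sites)
  x <- as_tibble(traj) |>
    filter(.data$species == "water", .data$z > z_range[1],
           .data$z < z_range[2], .data$d_xy < pore$radial_cutoff)
  if (nrow(x) == 0) abort("no water samples inside the interval")
  nb <- bonds |> dplyr::count(.data$time, .data$id, name = "bonds")
  per_monomer <- x |>
    left_join(nb, by = c("time", "id")) |>
    mutate(bonds = ifelse(is.na(.data$bonds), 0L, .data$bonds)) |>
    summarise(mean_bonds = mean(.data$bonds), n = dplyr::n(),
              .by = "monomer")
  if (nrow(per_monomer) >= 2) {
    st <- monomer_mean_sem(per_monomer$mean_bonds)
    tibble(mean_bonds = st$mean, sem = st$sem, n_monomers = st$n,
           n_samples = sum(per_monomer$n))
  } else {
    tibble(mean_bonds = per_monomer$mean_bonds[1], sem = NA_real_,
           n_monomers = 1L, n_samples = sum(per_monomer$n))
  }
}

#' Signed dihedral angle of four points
#'
#' Standard atan2 construction on the two plane normals; the result is in
#' (-180, 180] degrees.
#'
#' @param p A 4x3 coordinate matrix (rows = atoms in chain order), e.g.
#'   from [make_dihedral_fixture()].
#' @return Dihedral angle in degrees.
#' @export
#' @examples
#' dihedral_angle(make_dihedral_fixture(-94))
dihedral_angle <- function(p) {
  p <- as.matrix(p)
  stopifnot(nrow(p) == 4, ncol(p) == 3)
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    abort("three consecutive points are collinear")
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Gate-state classification spec
#'
#' @param open_mode Dihedral mode of the open state, degrees. Default -94.
#' @param closed_mode Mode of the closed state, degrees. Default -35.
#' @param half_width Window half width around each mode, degrees.
#'   Default 10.
#' @param min_dwell Minimal dwell in frames for a state change to count.
#'   Default 10.
#' @return A `gate_spec` list.
#' @export
gate_spec <- function(open_mode = -94, closed_mode = -35, half_width = 10,
                      min_dwell = 10) {
  stopifnot(half_width > 0, min_dwell >= 1)
  if (abs(open_mode - closed_mode) <= 2 * half_width)
    abort("open and closed windows overlap")
  structure(list(open_mode = open_mode, closed_mode = closed_mode,
                 half_width = half_width, min_dwell = min_dwell),
            class = "gate_spec")
}

#' Classify a gating-dihedral series into open/closed states
#'
#' Frames within `mode +/- half_width` are assigned that state; frames
#' outside both windows inherit the previous assigned state (hysteresis;
#' leading unassigned frames take the first assigned state). Excursions
#' shorter than `min_dwell` frames are suppressed. Transitions are reported
#' with entry times and dwell times.
#'
#' @param angles Dihedral angle series in degrees (vector), or a data frame
#'   with columns `time` and `angle`.
#' @param spec A [gate_spec()].
#' @return A list with `states` (tibble `time`, `angle`, `state`) and
#'   `events` (tibble `from`, `to`, `time`, `frame`, `dwell_before`).
#' @export
classify_gate <- function(angles, spec = gate_spec()) {
  stopifnot(inherits(spec, "gate_spec"))
  if (is.data.frame(angles)) {
    time <- angles$time
    ang <- angles$angle
  } else {
    ang <- as.numeric(angles)
    time <- seq_along(ang)
  }
  if (length(ang) == 0) abort("empty angle series")
  raw <- rep(NA_character_, length(ang))
  raw[abs(ang - spec$open_mode) <= spec$half_width] <- "open"
  raw[abs(ang - spec$closed_mode) <= spec$half_width] <- "closed"
  if (all(is.na(raw)))
    abort("no frame falls inside either state window")
  # hysteresis fill
  st <- raw
  first <- which(!is.na(st))[1]
  st[seq_len(first - 1)] <- st[first]
  for (i in seq_along(st)[-1]) if (is.na(st[i])) st[i] <- st[i - 1]
  # suppress runs shorter than min_dwell (absorbed into the previous state)
  repeat {
    r <- rle(st)
    short <- which(r$lengths < spec$min_dwell)
    short <- short[short > 1]
    if (length(short) == 0) break
    i <- short[1]
    r$values[i] <- r$values[i - 1]
    st <- inverse.rle(r)
  }
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  events <- if (length(r$values) > 1) {
    tibble(from = r$values[-length(r$values)], to = r$values[-1],
           frame = starts[-1], time = time[starts[-1]],
           dwell_before = r$lengths[-length(r$lengths)])
  } else tibble(from = character(), to = character(),
                frame = integer(), time = numeric(),
                dwell_before = integer())
  list(states = tibble(time = time, angle = ang, state = st),
       events = events)
}

#' Monomer quality rule on conserved-contact distances
#'
#' @param pairs Residue-pair labels that must stay in contact. Default the
#'   four conserved NPA-region pairs
#'   `c("N197-V82", "N83-M196", "N83-A85", "N197-A199")`.
#' @param threshold Contact distance threshold, Angstrom (strict `<`).
#'   Default 4.
#' @param min_fraction Minimal fraction of frames in contact (inclusive
#'   `>=`). Default 0.90.
#' @return A `quality_rule` list.
#' @export
quality_rule <- function(pairs = c("N197-V82", "N83-M196", "N83-A85",
                                   "N197-A199"),
                         threshold = 4, min_fraction = 0.90) {
  stopifnot(threshold > 0, min_fraction > 0, min_fraction <= 1)
  structure(list(pairs = pairs, threshold = threshold,
                 min_fraction = min_fraction), class = "quality_rule")
}

#' Keep or exclude monomers by conserved-contact stability
#'
#' A monomer is kept iff, for every rule pair, the fraction of frames with
#' minimum distance strictly below the threshold is at least
#' `min_fraction`.
#'
#' @param distances Data frame of per-frame minimum distances: columns
#'   `monomer`, `pair`, `distance` (one row per frame; a `time` column is
#'   allowed and ignored).
#' @param rule A [quality_rule()].
#' @return A tibble per monomer: `monomer`, `keep`, `worst_pair`,
#'   `worst_fraction`.
#' @export
npa_quality_filter <- function(distances, rule = quality_rule()) {
  stopifnot(inherits(rule, "quality_rule"))
  distances <- as_tibble(distances)
  stopifnot(all(c("monomer", "pair", "distance") %in% names(distances)))
  for (m in unique(distances$monomer)) {
    have <- unique(distances$pair[distances$monomer == m])
    miss <- setdiff(rule$pairs, have)
    if (length(miss) > 0)
      abort(sprintf("monomer %s is missing pair series: %s", m,
                    paste(miss, collapse = ", ")))
  }
  distances |>
    filter(.data$pair %in% rule$pairs) |>
    summarise(fraction = mean(.data$distance < rule$threshold),
              .by = c("monomer", "pair")) |>
    group_by(.data$monomer) |>
    summarise(keep = all(.data$fraction >= rule$min_fraction),
              worst_pair = .data$pair[which.min(.data$fraction)],
              worst_fraction = min(.data$fraction)) |>
    ungroup()
}
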