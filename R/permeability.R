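#' Cumulative collective permeation coordinate n(t)
#'
#' Per frame pair the axial displacements of all waters that are inside the
#' pore (\eqn{|z| < L/2}, \eqn{d_{xy} \le} cutoff) are summed and divided by
#' the pore length L:
#' \eqn{dn = \sum_i (z_i(t) - z_i(t - \Delta t))/L}; n(t) is the cumulative
#' sum starting from 0. By default a water contributes only when it is
#' in-pore at both frames of the pair (`membership = "both"`), which
#' suppresses entry/exit jump artifacts; `"either"` is the permissive
#' alternative.
#'
#' @param traj A `traj_tbl` (2 or more frames).
#' @param pore A [pore_definition()].
#' @param monomer Optional monomer selection (default: all monomers,
#'   one series each).
#' @param membership `"both"` (default) or `"either"`.
#' @param species Species entering the sum. Default `"water"`.
#' @return A `net_permeation` tibble with columns `monomer`, `time`, `n`;
#'   attributes `dt` (ps) and `L` (Angstrom).
#' @export
net_permeation_series <- function(traj, pore = pore_definition(),
                                  monomer = NULL,
                                  membership = c("both", "either"),
                                  species = "water") {
  stopifnot(inherits(traj, "traj_tbl"))
  membership <- match.arg(membership)
  dt <- traj_dt(traj)
  if (length(unique(traj$time)) < 2)
    abort("need at least 2 frames for a permeation series")
  L <- 2 * pore$half_length
  x <- filter(as_tibble(traj), .data$species == !!species)
  if (!is.null(monomer)) x <- filter(x, .data$monomer %in% !!monomer)
  times <- sort(unique(traj$time))

  x <- x |>
    mutate(inp = in_pore(.data$z, .data$d_xy, pore)) |>
    arrange(.data$monomer, .data$id, .data$time) |>
    group_by(.data$monomer, .data$id) |>
    mutate(dz = .data$z - lag(.data$z),
           keep = if (membership == "both")
             .data$inp & lag(.data$inp) else .data$inp | lag(.data$inp)) |>
    ungroup() |>
    filter(!is.na(.data$dz), .data$keep)

  incr <- x |>
    summarise(dn = sum(.data$dz) / L, .by = c("monomer", "time"))
  grid <- tidyr::expand_grid(monomer = sort(unique(traj$monomer)),
                             time = times)
  out <- grid |>
    left_join(incr, by = c("monomer", "time")) |>
    mutate(dn = ifelse(is.na(.data$dn) | .data$time == times[1], 0, .data$dn)) |>
    arrange(.data$monomer, .data$time) |>
    group_by(.data$monomer) |>
    mutate(n = cumsum(.data$dn)) |>
    ungroup() |>
    select("monomer", "time", "n")
  attr(out, "dt") <- dt
  attr(out, "L") <- L
  attr(out, "pore") <- pore
  class(out) <- c("net_permeation", class(out))
  out
}

#' Construct a collective permeation series from external n(t) values
#'
#' Wraps an already-computed cumulative collective coordinate (for example
#' a constructed hopping process with known rate) so it can be analysed
#' with [osmotic_permeability()].
#'
#' @param n Cumulative collective coordinate, one value per frame
#'   (n\[1\] is shifted to 0).
#' @param dt Frame interval, ps.
#' @param L Pore length, Angstrom. Default 18.
#' @param monomer Monomer label. Default 0.
#' @return A `net_permeation` tibble.
#' @export
net_permeation <- function(n, dt, L = 18, monomer = 0L) {
  stopifnot(length(n) >= 2, dt > 0, all(is.finite(n)))
  out <- tibble(monomer = monomer, time = (seq_along(n) - 1) * dt,
                n = n - n[1])
  attr(out, "dt") <- dt
  attr(out, "L") <- L
  class(out) <- c("net_permeation", class(out))
  out
}

msd_curve <- function(n, dt, fit_max) {
  m_max <- max(1L, floor(fit_max / dt))
  m_max <- min(m_max, length(n) - 1L)
  tibble(tau = seq_len(m_max) * dt,
         msd = vapply(seq_len(m_max),
                      \(m) mean(diff(n, lag = m)^2), numeric(1)))
}

#' Osmotic permeability from the collective diffusion method
#'
#' The series n(t) is split into segments; within each segment the mean
#' square displacement \eqn{\langle \Delta n^2(\tau)\rangle} is computed
#' over all overlapping time pairs for \eqn{0 < \tau \le} `fit_max`, and the
#' collective diffusion coefficient \eqn{D_n} is half the least-squares
#' slope over `fit_min` \eqn{< \tau \le} `fit_max` (the short-time points
#' are excluded). Then \eqn{p_f = v_w D_n}, reported in units of
#' \eqn{10^{-14}} cm\eqn{^3} s\eqn{^{-1}}; segments are averaged and the
#' monomer spread gives the SEM.
#'
#' @param x A `net_permeation` series, or a `traj_tbl` (which is converted
#'   with [net_permeation_series()]).
#' @param segment_ns Segment length in ns. Default 100.
#' @param fit_min,fit_max Fit range bounds in ps (default 50 and 1000;
#'   \eqn{\tau \le} `fit_min` is excluded).
#' @param v_w Water molecular volume in cm^3. Default `water_volume()`.
#' @param gate_mask Optional logical vector, one element per frame
#'   (`TRUE` = pore open); closed frames are excluded and the open
#'   stretches analysed as separate segments.
#' @param ... Passed to [net_permeation_series()] when `x` is a trajectory.
#' @return A `permeability_result` (see [tidy()] / [glance()] methods) with
#'   the `p_f` component filled in.
#' @export
osmotic_permeability <- function(x, segment_ns = 100, fit_min = 50,
                                 fit_max = 1000, v_w = water_volume(),
                                 gate_mask = NULL, ...) {
  if (inherits(x, "traj_tbl")) x <- net_permeation_series(x, ...)
  stopifnot(inherits(x, "net_permeation"))
  dt <- attr(x, "dt")
  seg_frames <- max(2L, round(segment_ns * 1000 / dt))

  per_monomer <- x |>
    group_by(.data$monomer) |>
    group_map(\(d, key) {
      n <- d$n
      if (!is.null(gate_mask)) {
        if (length(gate_mask) != length(n))
          abort("`gate_mask` must have one element per frame")
        blocks <- split(seq_along(n), cumsum(!gate_mask))
        pieces <- map(blocks, \(i) n[gate_mask[i]])
        pieces <- pieces[lengths(pieces) >= 2]
      } else pieces <- list(n)
      # split open stretches into segments
      segs <- list()
      for (p in pieces) {
        k <- max(1L, floor(length(p) / seg_frames))
        if (length(p) < seg_frames) k <- 1L
        idx <- split(seq_along(p), ceiling(seq_along(p) / seg_frames))
        for (i in idx) if (length(i) >= 2) segs[[length(segs) + 1]] <- p[i]
      }
      if (length(segs) == 0) abort("series shorter than one segment")
      dns <- map_dbl(segs, \(s) {
        msd <- msd_curve(s, dt, fit_max)
        fitpts <- filter(msd, .data$tau > fit_min, .data$tau <= fit_max)
        if (nrow(fitpts) < 3) abort("fewer than 3 MSD points in the fit range")
        # least-squares slope with intercept
        stats::cov(fitpts$tau, fitpts$msd) / stats::var(fitpts$tau) / 2
      })
      tibble(monomer = key$monomer, D_n = mean(dns),
             D_n_se = if (length(dns) > 1) sd(dns) / sqrt(length(dns))
                      else NA_real_,
             n_segments = length(dns))
    }) |>
    list_rbind()
  # v_w [cm^3] * D_n [1/ps] = cm^3/ps; report in 1e-14 cm^3/s
  per_monomer$p_f <- per_monomer$D_n * v_w * 1e26

  new_permeability_result(per_monomer, what = "p_f", v_w = v_w,
                          segment_ns = segment_ns)
}

#' Diffusion permeability from permeation-event counting
#'
#' A permeation event is a continuous pore passage: a molecule enters
#' through one face (\eqn{z = \pm L/2}), stays within the radial cutoff, and
#' exits through the opposite face. Radial excursions beyond the cutoff
#' reset the passage. The equilibrium one-way rate \eqn{q_0} is the number
#' of events in one direction per unit time (by default the mean of the two
#' directions; `direction_rule = "sum"` gives the 2x convention), and
#' \eqn{p_d = v_w q_0}.
#'
#' @inheritParams net_permeation_series
#' @param v_w Water molecular volume, cm^3.
#' @param direction_rule `"mean"` (default) or `"sum"`.
#' @param gate_mask Optional per-frame logical (TRUE = open); closed frames
#'   are dropped from both the event count and the elapsed time.
#' @return A `permeability_result` with the `p_d` component filled in.
#' @export
diffusion_permeability <- function(traj, pore = pore_definition(),
                                   monomer = NULL, v_w = water_volume(),
                                   species = "water",
                                   direction_rule = c("mean", "sum"),
                                   gate_mask = NULL) {
  stopifnot(inherits(traj, "traj_tbl"))
  direction_rule <- match.arg(direction_rule)
  dt <- traj_dt(traj)
  x <- filter(as_tibble(traj), .data$species == !!species)
  if (!is.null(monomer)) x <- filter(x, .data$monomer %in% !!monomer)
  times <- sort(unique(traj$time))
  if (!is.null(gate_mask)) {
    if (length(gate_mask) != length(times))
      abort("`gate_mask` must have one element per frame")
    open_times <- times[gate_mask]
    x <- filter(x, .data$time %in% open_times)
    span_ps <- max(0, (sum(gate_mask) - 1)) * dt
  } else {
    span_ps <- (length(times) - 1) * dt
  }

  counts <- x |>
    arrange(.data$monomer, .data$id, .data$time) |>
    group_by(.data$monomer, .data$id) |>
    group_map(\(d, key) {
      ev <- count_events(d$z, d$d_xy, pore)
      tibble(monomer = key$monomer, up = ev[1], down = ev[2])
    }) |>
    list_rbind()

  per_monomer <- counts |>
    summarise(up = sum(.data$up), down = sum(.data$down), .by = "monomer")
  rate <- if (direction_rule == "mean")
    (per_monomer$up + per_monomer$down) / 2 else
      per_monomer$up + per_monomer$down
  q0 <- rate / (span_ps * 1e-12) # events per second
  per_monomer$q0 <- q0
  per_monomer$p_d <- q0 * v_w / 1e-14
  new_permeability_result(per_monomer, what = "p_d", v_w = v_w,
                          span_ns = span_ps / 1000,
                          direction_rule = direction_rule)
}

# upward/downward full-passage counts for one molecule's frame series,
# using first-entry/last-exit bookkeeping with strict radial enforcement
count_events <- function(z, d_xy, pore) {
  L2 <- pore$half_length
  state <- ifelse(z < -L2, 1L,                     # below
           ifelse(z > L2, 3L,                      # above
           ifelse(d_xy <= pore$radial_cutoff, 2L, 4L))) # inside / radial-out
  r <- rle(state)$values
  if (length(r) < 3) return(c(0, 0))
  mid <- r[2:(length(r) - 1)]
  lo <- r[1:(length(r) - 2)]
  hi <- r[3:length(r)]
  up <- sum(mid == 2L & lo == 1L & hi == 3L)
  down <- sum(mid == 2L & lo == 3L & hi == 1L)
  c(up, down)
}

new_permeability_result <- function(per_monomer, what, v_w, ...) {
  stat <- if (nrow(per_monomer) >= 2)
    monomer_mean_sem(per_monomer[[what]]) else
      tibble(mean = per_monomer[[what]][1], sem = NA_real_, sd = NA_real_,
             n = 1L)
  structure(list(per_monomer = per_monomer, what = what,
                 mean = stat$mean, sem = stat$sem, n = stat$n,
                 v_w = v_w, extra = list(...)),
            class = c(paste0(what, "_result"), "permeability_result"))
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("<%s>  %s = %.4g +/- %.2g  [1e-14 cm^3/s]  (n = %d monomers)\n",
              class(x)[1], x$what, x$mean,
              ifelse(is.na(x$sem), 0, x$sem), x$n))
  invisible(x)
}

#' Ratio of osmotic to diffusion permeability
#'
#' \eqn{p_f/p_d} measures the effective number of steps a water molecule
#' takes while permeating a single-file channel (approximately the number of
#' single-file positions). Uncertainty is first-order propagated from the
#' two SEMs.
#'
#' @param pf A `p_f` [osmotic_permeability()] result.
#' @param pd A `p_d` [diffusion_permeability()] result (mean must be > 0).
#' @return A one-row tibble: `ratio`, `se`.
#' @export
permeability_ratio <- function(pf, pd) {
  stopifnot(inherits(pf, "p_f_result"), inherits(pd, "p_d_result"))
  if (!isTRUE(pd$mean > 0)) abort("p_d must be > 0 for a ratio")
  r <- pf$mean / pd$mean
  se <- r * sqrt((pf$sem / pf$mean)^2 + (pd$sem / pd$mean)^2)
  tibble(ratio = r, se = se)
}

#' Selectivity change between two systems from permeability reductions
#'
#' Given the permeability of one species in systems A (reference) and B
#' (perturbed), and likewise for a second species, the change in selectivity
#' for the second species is the ratio of the two reduction factors
#' \eqn{(p_{1,A}/p_{1,B}) / (p_{2,A}/p_{2,B})}.
#'
#' @param p1_A,p1_B Permeability of species 1 in systems A and B.
#' @param p2_A,p2_B Permeability of species 2 in systems A and B.
#' @return A one-row tibble: the two reduction factors and the selectivity
#'   factor for species 2.
#' @export
#' @examples
#' selectivity_change(0.7, 0.18, 1.0, 0.41)
selectivity_change <- function(p1_A, p1_B, p2_A, p2_B) {
  stopifnot(p1_B > 0, p2_B > 0, p2_A > 0)
  f1 <- p1_A / p1_B
  f2 <- p2_A / p2_B
  tibble(reduction_1 = f1, reduction_2 = f2, selectivity_factor = f1 / f2)
}
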