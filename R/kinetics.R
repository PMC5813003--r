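#' Place kinetic boundaries on a free-energy profile
#'
#' The pore is divided at \eqn{z_0 = 0} into a lower and an upper section;
#' the outer boundaries \eqn{z_l} and \eqn{z_u} are placed where the
#' bulk-referenced free energy crosses the threshold (default
#' 2.0 \eqn{k_B T}): \eqn{z_l} at the outermost upward crossing below 0 and
#' \eqn{z_u} at the outermost downward crossing above 0, each located by
#' linear interpolation between bin centres.
#'
#' @param profile A bulk-referenced `fe_profile`.
#' @param threshold Crossing level in \eqn{k_B T}. Default 2.0.
#' @param z0 Dividing point, Angstrom. Default 0.
#' @return A `kinetic_boundaries` list: `z_l`, `z_0`, `z_u`, `threshold`.
#' @export
find_boundaries <- function(profile, threshold = 2.0, z0 = 0) {
  stopifnot(inherits(profile, "fe_profile"))
  z <- profile$z
  F <- profile$F
  ok <- is.finite(F)
  z <- z[ok]; F <- F[ok]
  below <- z < z0
  above <- z > z0

  cross_up <- function(zz, FF) {
    # first upward crossing scanning from the outside in (from <= to >)
    i <- which(FF[-length(FF)] <= threshold & FF[-1] > threshold)
    if (length(i) == 0) return(NA_real_)
    i <- i[1]
    zz[i] + (threshold - FF[i]) / (FF[i + 1] - FF[i]) * (zz[i + 1] - zz[i])
  }
  zl <- cross_up(z[below], F[below])
  if (is.na(zl))
    abort("profile does not cross the threshold below z_0 (lower side)")
  # upper side: mirror so the outermost downward crossing becomes the
  # first upward crossing scanned from the outside
  zu <- cross_up(rev(-z[above]), rev(F[above]))
  if (is.na(zu))
    abort("profile does not cross the threshold above z_0 (upper side)")
  zu <- -zu
  if (!(zl < z0 && z0 < zu)) abort("boundaries must straddle z_0")
  structure(list(z_l = zl, z_0 = z0, z_u = zu, threshold = threshold),
            class = "kinetic_boundaries")
}

#' @rdname find_boundaries
#' @param z_l,z_u Explicit boundary positions, Angstrom (`z_l < z0 < z_u`);
#'   for landscapes where the boundary placement is known by construction.
#' @export
kinetic_boundaries <- function(z_l, z_u, z0 = 0, threshold = NA_real_) {
  stopifnot(z_l < z0, z0 < z_u)
  structure(list(z_l = z_l, z_0 = z0, z_u = z_u, threshold = threshold),
            class = "kinetic_boundaries")
}

#' @export
print.kinetic_boundaries <- function(x, ...) {
  cat(sprintf("<kinetic_boundaries>  z_l = %.3f, z_0 = %.3f, z_u = %.3f A  (F = %.2f kBT)\n",
              x$z_l, x$z_0, x$z_u, x$threshold))
  invisible(x)
}

#' Boundary-crossing statistics from a finely sampled path
#'
#' Counts directional crossings of \eqn{z_l}, \eqn{z_0} and \eqn{z_u}
#' (a crossing at \eqn{z_l} toward \eqn{z_u} is a sign change of
#' \eqn{z - z_l} with positive displacement), follows every \eqn{z_0}
#' crossing to its fate (reach the outer boundary before returning), and
#' classifies completed pore exits. Crossing rates are per ns; splitting
#' probabilities carry binomial standard errors.
#'
#' @param z Position series at fine time resolution, Angstrom (a numeric
#'   vector or a single-molecule `traj_tbl`).
#' @param boundaries A [find_boundaries()] object.
#' @param dt Sampling interval in ps (taken from the trajectory when `z` is
#'   a `traj_tbl`).
#' @param resolution Requested time resolution in ps (default 0.01).
#'   Sampling coarser than 10x this raises an error in strict mode, a
#'   warning otherwise.
#' @param strict Escalate the resolution warning to an error.
#' @param log_events Maximal number of boundary-crossing events kept in
#'   the event log (time, boundary, direction, fate). Default 10000.
#' @return A `crossing_stats` list; see Details.
#' @details The returned list contains `k_lu` and `k_ul` (crossings per ns
#'   at \eqn{z_l} toward \eqn{z_u} and at \eqn{z_u} toward \eqn{z_l}),
#'   `p_0l` and `p_0u` (probabilities of a \eqn{z_0} crossing reaching the
#'   boundary before returning, with `p_0l_se`/`p_0u_se`), `f_0u` and
#'   `f_0l` (exit fractions, `f_0u + f_0l = 1` over completed exits),
#'   `full_up`/`full_down` full-passage counts, and `time_ns`.
#' @export
detect_crossings <- function(z, boundaries, dt = NULL, resolution = 0.01,
                             strict = FALSE, log_events = 10000) {
  stopifnot(inherits(boundaries, "kinetic_boundaries"))
  if (inherits(z, "traj_tbl")) {
    if (dplyr::n_distinct(z$id) != 1)
      abort("crossing detection expects a single-molecule series")
    dt <- traj_dt(z)
    z <- arrange(as_tibble(z), .data$time)$z
  }
  if (is.null(dt)) abort("`dt` is required for a bare numeric series")
  if (dt > 10 * resolution) {
    msg <- sprintf("sampling interval (%g ps) exceeds 10x the requested resolution (%g ps)",
                   dt, resolution)
    if (strict) abort(msg) else warn(msg)
  }
  if (!(min(z) <= boundaries$z_l || max(z) >= boundaries$z_u))
    abort("series does not cover the boundary region")
  cc <- cpp_detect_crossings(z, boundaries$z_l, boundaries$z_0,
                             boundaries$z_u, as.integer(log_events))
  time_ns <- (length(z) - 1) * dt / 1000
  events <- tibble(
    time = cc$ev_frame * dt,
    boundary = c("z_l", "z_0", "z_u")[cc$ev_bnd + 2L],
    position = c(boundaries$z_l, boundaries$z_0,
                 boundaries$z_u)[cc$ev_bnd + 2L],
    direction = ifelse(cc$ev_dir > 0, "up", "down"),
    fate = c(NA_character_, "reached", "returned")[cc$ev_fate + 1L])
  binom_se <- function(k, n) if (n > 0) sqrt(k / n * (1 - k / n) / n) else NA_real_
  exits <- cc$exit_u + cc$exit_l
  structure(list(
    k_lu = cc$kl_up / time_ns, k_ul = cc$ku_down / time_ns,
    n_k_lu = cc$kl_up, n_k_ul = cc$ku_down,
    p_0l = if (cc$n0_down > 0) cc$n0_down_reach_l / cc$n0_down else NA_real_,
    p_0l_se = binom_se(cc$n0_down_reach_l, cc$n0_down),
    p_0u = if (cc$n0_up > 0) cc$n0_up_reach_u / cc$n0_up else NA_real_,
    p_0u_se = binom_se(cc$n0_up_reach_u, cc$n0_up),
    n_0_down = cc$n0_down, n_0_up = cc$n0_up,
    f_0u = if (exits > 0) cc$exit_u / exits else NA_real_,
    f_0l = if (exits > 0) cc$exit_l / exits else NA_real_,
    f_se = binom_se(cc$exit_u, exits), n_exits = exits,
    full_up = cc$full_up, full_down = cc$full_down,
    events = events,
    time_ns = time_ns, boundaries = boundaries, dt = dt),
    class = "crossing_stats")
}

#' @export
print.crossing_stats <- function(x, ...) {
  cat("<crossing_stats>\n")
  cat(sprintf("  k(z_l;z_u) = %.4g /ns (%d), k(z_u;z_l) = %.4g /ns (%d)\n",
              x$k_lu, x$n_k_lu, x$k_ul, x$n_k_ul))
  cat(sprintf("  p(z_0->z_l) = %.4g +/- %.2g,  p(z_0->z_u) = %.4g +/- %.2g\n",
              x$p_0l, x$p_0l_se, x$p_0u, x$p_0u_se))
  cat(sprintf("  f(z_0->z_u) = %.4g +/- %.2g  (%d exits)\n",
              x$f_0u, x$f_se, x$n_exits))
  cat(sprintf("  full passages: %d up, %d down in %.4g ns\n",
              x$full_up, x$full_down, x$time_ns))
  invisible(x)
}

#' Solute boundary-crossing rate from the water rate
#'
#' At low solute concentration the solute crossing rate at a boundary is
#' estimated from the water crossing rate as
#' \eqn{k \approx \rho k_w e^{F_w - F}}, where \eqn{\rho} is the solute
#' fraction and \eqn{F_w}, \eqn{F} are the bulk-referenced free energies of
#' water and solute at the boundary. This assumes equal attempt rates for
#' the two species; `attempt_scale` rescales that assumption.
#'
#' @param k_w Water crossing rate (per ns), >= 0.
#' @param rho Solute fraction n/N in (0, 1].
#' @param F_w,F Free energies at the boundary, \eqn{k_B T}.
#' @param attempt_scale Multiplicative correction for unequal attempt
#'   rates. Default 1.
#' @return Solute crossing rate, per ns.
#' @export
#' @examples
#' solute_crossing_rate(10, 1, 2, 2)   # = k_w
#' solute_crossing_rate(10, 0.5, 0, 0) # = k_w / 2
solute_crossing_rate <- function(k_w, rho, F_w, F, attempt_scale = 1) {
  stopifnot(k_w >= 0, rho > 0, rho <= 1)
  attempt_scale * rho * k_w * exp(F_w - F)
}

#' Solute fraction from counts or concentration
#'
#' The solute fraction entering the crossing-rate estimate is
#' \eqn{\rho = n/N} (solute over total mobile molecules); in the dilute
#' limit it equals \eqn{c v_w} for a number concentration c.
#'
#' @param n,N Solute and total mobile-particle counts.
#' @param c Number concentration in cm^-3 (alternative to `n`/`N`).
#' @param v_w Water molecular volume, cm^3.
#' @return The fraction rho in (0, 1].
#' @export
#' @examples
#' solute_fraction(n = 1, N = 100)
solute_fraction <- function(n = NULL, N = NULL, c = NULL,
                            v_w = water_volume()) {
  rho <- if (!is.null(c)) c * v_w else {
    stopifnot(!is.null(n), !is.null(N), N > 0)
    n / N
  }
  if (rho <= 0 || rho > 1) abort("rho must lie in (0, 1]")
  rho
}

interp_profile <- function(profile, z) {
  ok <- is.finite(profile$F)
  approx(profile$z[ok], profile$F[ok], xout = z, rule = 2)$y
}

interp_profile_se <- function(profile, z) {
  if (all(is.na(profile$se))) return(0)
  ok <- is.finite(profile$F) & is.finite(profile$se)
  approx(profile$z[ok], profile$se[ok], xout = z, rule = 2)$y
}

#' Kinetic estimate of the diffusion permeability
#'
#' Assembles the factorized one-way permeation rate
#' \deqn{p_d \approx v_w\, k_w(z_l; z_u)\, e^{F_w(z_l) - F(z_l)}\,
#'   p(z_0 \to z_l)\, e^{F(z_l) - F(z_0)}\, f(z_0 \to z_u)}
#' for the upward direction (the downward expression follows by the
#' symmetric substitution \eqn{z_l \leftrightarrow z_u}). The reversal
#' \eqn{p(z_l \to z_0) = p(z_0 \to z_l) e^{F(z_l) - F(z_0)}} uses detailed
#' balance, so upward and downward estimates must agree on equilibrium
#' data. Uncertainties are combined first order (independent relative
#' variances of the binomial factors, the Poisson crossing count and the
#' profile uncertainties).
#'
#' @param stats A [detect_crossings()] result for the solute.
#' @param profile Bulk-referenced solute `fe_profile` (F).
#' @param water_profile Bulk-referenced water `fe_profile` (F_w); defaults
#'   to `profile` (solute statistically identical to water).
#' @param water_stats Optional [detect_crossings()] result for water whose
#'   crossing rates supply \eqn{k_w}; defaults to `stats`.
#' @param boundaries A [find_boundaries()] object; defaults to the one
#'   stored in `stats`.
#' @param v_w Water molecular volume, cm^3.
#' @param direction `"up"`, `"down"` or `"both"` (default).
#' @return A `kinetic_estimate` tibble with one row per direction:
#'   `direction`, `p_d` (1e-14 cm^3/s), `se`, and the assembled components.
#' @export
kinetic_pd <- function(stats, profile, water_profile = profile,
                       water_stats = stats, boundaries = NULL,
                       v_w = water_volume(),
                       direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(stats, "crossing_stats"),
            inherits(profile, "fe_profile"))
  b <- boundaries %||% stats$boundaries

  one <- function(dir) {
    if (dir == "up") {
      zb <- b$z_l; k_w <- water_stats$k_lu; n_k <- water_stats$n_k_lu
      p <- stats$p_0l; p_se <- stats$p_0l_se
      f <- stats$f_0u
    } else {
      zb <- b$z_u; k_w <- water_stats$k_ul; n_k <- water_stats$n_k_ul
      p <- stats$p_0u; p_se <- stats$p_0u_se
      f <- stats$f_0l
    }
    f_se <- stats$f_se
    if (!isTRUE(n_k > 0) || !is.finite(p) || !is.finite(f))
      abort("zero observed crossings: kinetic estimate undefined")
    Fb <- interp_profile(profile, zb)
    F0 <- interp_profile(profile, b$z_0)
    Fwb <- interp_profile(water_profile, zb)
    rate_ns <- k_w * exp(Fwb - Fb) * p * exp(Fb - F0) * f # per ns
    pd <- rate_ns * 1e9 * v_w / 1e-14
    # delta-method: independent relative variances; F(z_l) cancels between
    # the two exponential factors, so only F(z_0) and F_w(z_l) contribute
    relvar <- (p_se / p)^2 + (f_se / f)^2 + 1 / n_k +
      interp_profile_se(profile, b$z_0)^2 +
      interp_profile_se(water_profile, zb)^2
    tibble(direction = dir, p_d = pd, se = pd * sqrt(relvar),
           k_w = k_w, p_split = p, f_exit = f,
           dF_wb = Fwb - Fb, dF_b0 = Fb - F0)
  }
  dirs <- if (direction == "both") c("up", "down") else direction
  out <- list_rbind(map(dirs, one))
  attr(out, "v_w") <- v_w
  attr(out, "boundaries") <- b
  class(out) <- c("kinetic_estimate", class(out))
  out
}

#' Inverse-variance weighted mean of the directional kinetic estimates
#'
#' @param estimate A [kinetic_pd()] result with both directions.
#' @return A one-row tibble: `p_d`, `se`.
#' @export
kinetic_pd_combined <- function(estimate) {
  stopifnot(inherits(estimate, "kinetic_estimate"), nrow(estimate) >= 1)
  w <- 1 / estimate$se^2
  tibble(p_d = sum(estimate$p_d * w) / sum(w), se = sqrt(1 / sum(w)))
}
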