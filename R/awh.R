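#' Configuration of the adaptive-weight-histogram sampler
#'
#' The bias couples the walker position z to a dynamic coupling point
#' \eqn{\lambda} through a harmonic potential
#' \eqn{V_i(z) = \frac{1}{2} k (z - z_i)^2}; \eqn{\lambda} is driven toward
#' a uniform target distribution over the sampling interval while the free
#' energy along z is estimated online. A flat-bottom radial restraint
#' \eqn{V(d_{xy}) = \frac{1}{2} k (d_{xy} - d_{xy,max})^2} for
#' \eqn{d_{xy} > d_{xy,max}} (zero otherwise) keeps the walker near the
#' pore axis.
#'
#' @param interval Sampling interval along z, Angstrom.
#'   Default `c(-20, 20)`.
#' @param n_points Number of coupling points uniformly covering the
#'   interval. Default 237.
#' @param force_constant Harmonic force constant k in kJ mol^-1 A^-2.
#'   Default 10.
#' @param eps0 Initial free-energy error estimate \eqn{\hat\epsilon_0} in
#'   \eqn{k_B T}. Default 3.
#' @param D_hat Diffusion estimate \eqn{\hat D} along the coordinate,
#'   A^2/ps. Default 1e-2. (Both `eps0` and `D_hat` only set the initial
#'   rate of change of the bias, not the result.)
#' @param d_xy_max Flat-bottom radial restraint onset, Angstrom. Default 6.
#' @param target Target distribution; only `"uniform"` is supported.
#' @param temperature Temperature in K. Default 310.
#' @return An `awh_config` list; grid spacing is
#'   `diff(interval)/(n_points - 1)`.
#' @export
#' @examples
#' cfg <- awh_config()
#' diff(cfg$interval) / (cfg$n_points - 1) # ~0.1695 A spacing
awh_config <- function(interval = c(-20, 20), n_points = 237,
                       force_constant = 10, eps0 = 3, D_hat = 1e-2,
                       d_xy_max = 6, target = "uniform",
                       temperature = 310) {
  stopifnot(length(interval) == 2, interval[1] < interval[2],
            n_points >= 2, force_constant > 0, eps0 > 0, D_hat > 0)
  target <- match.arg(target, "uniform")
  spacing <- diff(interval) / (n_points - 1)
  if (diff(interval) < 2 * spacing)
    abort("sampling interval narrower than 2 grid spacings")
  structure(list(interval = interval, n_points = as.integer(n_points),
                 force_constant = force_constant, eps0 = eps0,
                 D_hat = D_hat, d_xy_max = d_xy_max, target = target,
                 temperature = temperature, spacing = spacing),
            class = "awh_config")
}

# initial reference histogram size derived from the initial error estimate
# and the diffusion estimate, taken directly as a samples-equivalent count:
#   N0 = (kBT/eps0)^2 * |interval|^2 / (2 D_hat)
# larger initial uncertainty or faster expected diffusion = smaller N0 =
# larger early updates
awh_n0 <- function(config, dt) {
  len <- diff(config$interval)
  (1 / config$eps0)^2 * len^2 / (2 * config$D_hat)
}

#' Initialise an AWH state
#'
#' The free-energy estimate starts at zero everywhere; the initial
#' reference histogram size is derived from `eps0` and `D_hat` (larger
#' initial error = smaller histogram = larger early updates).
#'
#' @param config An [awh_config()].
#' @param dt Sampler time step in ps (sets the samples-equivalent of the
#'   initial histogram). Default 0.01.
#' @return An `awh_state` list with the coupling-point grid `grid_z`, the
#'   estimate `fhat` (\eqn{k_B T}), reference weight histogram `W`, stage
#'   flag and bookkeeping counters.
#' @export
awh_init <- function(config = awh_config(), dt = 0.01) {
  stopifnot(inherits(config, "awh_config"))
  grid_z <- seq(config$interval[1], config$interval[2],
                length.out = config$n_points)
  structure(list(config = config, grid_z = grid_z,
                 fhat = rep(0, config$n_points),
                 W = rep(0, config$n_points),
                 hist = rep(0, config$n_points),
                 visited = rep(FALSE, config$n_points),
                 N = awh_n0(config, dt), dt = dt,
                 stage = "initial", samples = 0L, coverings = 0L,
                 lambda = as.integer(ceiling(config$n_points / 2))),
            class = "awh_state")
}

#' Flat-bottom radial restraint energy and force
#'
#' @param d_xy Radial distance, Angstrom.
#' @param config An [awh_config()].
#' @return A tibble with `energy` (\eqn{k_B T}) and `force`
#'   (\eqn{k_B T}/Angstrom, acting to reduce `d_xy`); both zero for
#'   `d_xy <= d_xy_max`.
#' @export
awh_radial_restraint <- function(d_xy, config = awh_config()) {
  k <- config$force_constant / kBT(config$temperature) # kBT / A^2
  over <- pmax(0, d_xy - config$d_xy_max)
  tibble(energy = 0.5 * k * over^2, force = -k * over)
}

#' Advance the AWH estimate by one observation (reference implementation)
#'
#' Gibbs-resamples \eqn{\lambda} from its conditional distribution given
#' the walker position (weights \eqn{\propto \exp(-V_i(z)/k_BT + g_i)} with
#' bias \eqn{g = \hat F}), updates the free-energy estimate with the
#' zero-drift weight-histogram rule
#' \eqn{\hat F_i \mathrel{+}= (1/N)(1 - M \omega_i)} and returns the
#' harmonic bias force on the walker. [awh_run()] couples the identical
#' update to the Langevin sampler in compiled code.
#'
#' @param state An [awh_init()] state.
#' @param z Walker position, Angstrom.
#' @param d_xy Walker radial distance (for the flat-bottom restraint).
#'   Default 0.
#' @return The updated state, with elements `bias_force` (\eqn{k_B T}/A,
#'   harmonic plus radial component along d_xy in `radial_force`) attached.
#' @export
awh_step <- function(state, z, d_xy = 0) {
  stopifnot(inherits(state, "awh_state"))
  cfg <- state$config
  k <- cfg$force_constant / kBT(cfg$temperature)
  M <- cfg$n_points
  e <- state$fhat - 0.5 * k * (z - state$grid_z)^2
  w <- exp(e - max(e))
  S_abs <- sum(exp(e)) # absolute scale for the reweighted histogram
  w <- w / sum(w)
  lam <- sample.int(M, 1, prob = w)

  state$fhat <- state$fhat + (1 / state$N) * (1 - M * w)
  state$W <- state$W + w
  zb <- min(M, max(1, round((z - cfg$interval[1]) / cfg$spacing) + 1))
  state$hist[zb] <- state$hist[zb] + 1 / S_abs
  state$samples <- state$samples + 1L
  state$visited[lam] <- TRUE
  if (state$stage == "initial" && all(state$visited)) {
    state$N <- 2 * state$N
    state$coverings <- state$coverings + 1L
    state$visited[] <- FALSE
    if (state$N >= state$samples) state$stage <- "final"
  } else if (state$stage == "final") {
    state$N <- state$N + 1
  }
  state$lambda <- lam
  state$bias_force <- -k * (z - state$grid_z[lam])
  state$radial_force <- awh_radial_restraint(d_xy, cfg)$force
  state
}

#' Run the AWH sampler on a pore model
#'
#' Couples the AWH bias to a single overdamped Langevin walker in the model
#' potential (walker and \eqn{\lambda} updates interleave 1:1 at the fine
#' time step) and returns the bias-reweighted free-energy profile along z
#' together with convergence diagnostics. Deterministic under a fixed seed.
#'
#' @param model A [build_pore_model()].
#' @param config An [awh_config()].
#' @param n_steps Number of steps. Default 1e6.
#' @param seed RNG seed (mandatory).
#' @param dt Time step, ps. Default 0.01.
#' @return An `fe_profile` (source `"awh"`) with attributes `traversals`
#'   (end-to-end interval sweeps of the walker), `coverings`, `stage`,
#'   `samples`, and `converged` (`FALSE` with a warning metadata flag when
#'   no traversal completed).
#' @export
awh_run <- function(model, config = awh_config(), n_steps = 1e6, seed = 1,
                    dt = 0.01) {
  stopifnot(inherits(model, "pore_model"), inherits(config, "awh_config"))
  if (is.null(seed) || is.na(seed)) abort("a fixed `seed` is mandatory")
  grid_z <- seq(config$interval[1], config$interval[2],
                length.out = config$n_points)
  g <- model_grid(model, lim = max(abs(config$interval)))
  k <- config$force_constant / kBT(config$temperature)
  res <- with_seed(seed,
    cpp_awh_run(grid_z, g$z, g$F, k, model$D, dt,
                awh_n0(config, dt), as.integer(n_steps), 0))
  prof <- free_energy_profile(
    grid_z, res$pmf, se = NA_real_, count = NA_real_,
    bin_width = config$spacing, source = "awh",
    bulk_region = NULL, temperature = config$temperature)
  attr(prof, "traversals") <- res$traversals
  attr(prof, "coverings") <- res$coverings
  attr(prof, "stage") <- if (res$final_stage) "final" else "initial"
  attr(prof, "samples") <- res$samples
  attr(prof, "fhat") <- res$fhat
  attr(prof, "W") <- res$W
  attr(prof, "occupancy") <- list(first_third = res$occ_first,
                                  last_third = res$occ_last)
  attr(prof, "converged") <- res$traversals > 0
  if (res$traversals == 0)
    warn("no end-to-end traversal completed; AWH estimate not converged")
  prof
}

#' Combine independent AWH walkers
#'
#' Delegates to [combine_monomer_profiles()] (self-consistent exponential
#' average with jackknife errors).
#'
#' @param profiles List of `fe_profile` from [awh_run()] on the same grid.
#' @inheritParams combine_monomer_profiles
#' @return A combined `fe_profile`.
#' @export
combine_walkers <- function(profiles, tol = 1e-8, max_iter = 100) {
  combine_monomer_profiles(profiles, tol = tol, max_iter = max_iter)
}
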