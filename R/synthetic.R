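#' Build a model pore free-energy landscape
#'
#' A pore model is a smooth 1D potential F(z) in \eqn{k_B T} (the axial
#' potential of mean force, zero in bulk) built as a sum of Gaussian wells
#' and barriers, plus a radial confinement profile giving the maximal
#' \eqn{d_{xy}} at each z, a diffusion coefficient and a temperature.
#'
#' The `"wildtype_like"` landscape has four lower minima spaced 2.5 Angstrom
#' with inter-well barriers of 1-2 \eqn{k_B T}, a smoother upper section with
#' two broad shallow wells, and a top barrier (default 2 \eqn{k_B T}
#' relative to bulk) near the upper pore mouth. `"double_mutant_like"`
#' additionally carves three upper minima spaced 2.5 Angstrom and raises the
#' maximum barrier by exactly `mutant_extra` (default 1 \eqn{k_B T}).
#' `"flat"` is F = 0 everywhere; `"custom"` takes explicit well/barrier lists.
#'
#' @param kind One of `"wildtype_like"`, `"double_mutant_like"`, `"flat"`,
#'   `"custom"`.
#' @param wells,barriers For `kind = "custom"`: data frames with columns
#'   `center`, `height` (well depth / barrier height, \eqn{k_B T}, both
#'   positive) and `sigma` (Gaussian width, Angstrom).
#' @param top_barrier Maximum barrier height relative to bulk for the
#'   wildtype-like landscape, \eqn{k_B T}. Default 2 (a water-like
#'   landscape; use ~3 for a slower-permeating solute).
#' @param mutant_extra Barrier increase of the double-mutant-like landscape
#'   over the wildtype-like one, \eqn{k_B T}. Default 1.
#' @param D Diffusion coefficient along z, Angstrom^2/ps. Default 0.25.
#' @param temperature Temperature in K. Default 310.
#' @param L Pore length in Angstrom. Default 18.
#' @param radial A function of z returning the maximal d_xy (Angstrom), or
#'   `NULL` for the built-in profile (narrow cylinder inside the pore with a
#'   constriction at z = 8, wide bulk).
#' @return A `pore_model` with elements `F` and `dF` (vectorised functions
#'   of z), `radial`, `wells` (minima positions), `n_wells`, `f_b` (maximum
#'   barrier, \eqn{k_B T}), `D`, `L`, `temperature`, `interval`.
#' @export
#' @examples
#' m <- build_pore_model("wildtype_like")
#' m$F(c(-7.5, -5, 0, 15))
build_pore_model <- function(kind = c("wildtype_like", "double_mutant_like",
                                      "flat", "custom"),
                             wells = NULL, barriers = NULL,
                             top_barrier = 2, mutant_extra = 1,
                             D = 0.25, temperature = 310, L = 18,
                             radial = NULL) {
  kind <- match.arg(kind)
  lower_wells <- tibble(center = c(-7.5, -5, -2.5, 0), height = -1.0,
                        sigma = 0.7)
  lower_bumps <- tibble(center = c(-8.75, -6.25, -3.75, -1.25), height = 0.5,
                        sigma = 0.6)
  upper_wells <- tibble(center = c(3, 6), height = -0.6, sigma = 1.2)
  # lower-mouth entrance barrier, kept just under the top barrier so the
  # profile crosses any threshold below the maximum on both sides
  mouth_bump <- tibble(center = -10, height = max(0.5, top_barrier - 0.4),
                       sigma = 0.7)

  terms <- switch(kind,
    flat = tibble(center = numeric(), height = numeric(), sigma = numeric()),
    custom = {
      if (is.null(wells) && is.null(barriers))
        abort("custom models need explicit `wells` and/or `barriers`")
      w <- if (!is.null(wells))
        mutate(as_tibble(wells), height = -abs(.data$height)) else NULL
      b <- if (!is.null(barriers))
        mutate(as_tibble(barriers), height = abs(.data$height)) else NULL
      tt <- bind_rows(w, b)
      if (!is.null(w) && nrow(w) > 1) {
        cw <- sort(w$center)
        if (any(diff(cw) < 1e-9)) abort("overlapping wells in custom model")
      }
      tt
    },
    wildtype_like = bind_rows(lower_wells, lower_bumps, upper_wells,
                              mouth_bump),
    double_mutant_like = bind_rows(
      lower_wells, lower_bumps,
      tibble(center = c(2.5, 5, 7.5), height = -1.0, sigma = 0.7),
      mouth_bump))

  gsum <- function(z, tt) {
    if (nrow(tt) == 0) return(rep(0, length(z)))
    Reduce(`+`, map(seq_len(nrow(tt)), \(i)
      tt$height[i] * exp(-(z - tt$center[i])^2 / (2 * tt$sigma[i]^2))))
  }
  dgsum <- function(z, tt) {
    if (nrow(tt) == 0) return(rep(0, length(z)))
    Reduce(`+`, map(seq_len(nrow(tt)), \(i)
      -tt$height[i] * (z - tt$center[i]) / tt$sigma[i]^2 *
        exp(-(z - tt$center[i])^2 / (2 * tt$sigma[i]^2))))
  }

  # top barrier near the upper mouth, amplitude set so that the global
  # maximum over the pore hits the requested height exactly
  if (kind %in% c("wildtype_like", "double_mutant_like")) {
    target <- if (kind == "wildtype_like") top_barrier else {
      wt <- build_pore_model("wildtype_like", top_barrier = top_barrier,
                             D = D, temperature = temperature, L = L)
      wt$f_b + mutant_extra
    }
    zg <- seq(-12, 12, by = 0.01)
    base <- gsum(zg, terms)
    # the double-mutant top barrier sits further out so its upper wells at
    # 2.5/5/7.5 A survive as distinct minima
    bc <- if (kind == "wildtype_like") 8 else 9.5
    bs <- if (kind == "wildtype_like") 0.9 else 0.6
    bump <- exp(-(zg - bc)^2 / (2 * bs^2))
    amp <- stats::uniroot(\(a) max(base + a * bump) - target,
                          interval = c(0, target + 6))$root
    terms <- bind_rows(terms, tibble(center = bc, height = amp, sigma = bs))
  }

  Ffun <- function(z) gsum(z, terms)
  dFfun <- function(z) dgsum(z, terms)

  zg <- seq(-12, 12, by = 0.01)
  Fg <- Ffun(zg)
  # local minima of the landscape = candidate single-file positions
  i <- which(diff(sign(diff(Fg))) == 2) + 1
  minima <- zg[i][Fg[i] < -0.05]

  if (is.null(radial))
    radial <- function(z) ifelse(abs(z) >= 9, 7,
                                 ifelse(abs(z - 8) < 0.75, 1.4, 2.5))
  structure(
    list(kind = kind, terms = terms, F = Ffun, dF = dFfun, radial = radial,
         wells = minima, n_wells = length(minima),
         f_b = max(Fg), D = D, L = L, temperature = temperature,
         interval = c(-20, 20)),
    class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("<pore_model '%s'>  %d wells, max barrier %.3g kBT, D = %.3g A^2/ps\n",
              x$kind, x$n_wells, x$f_b, x$D))
  invisible(x)
}

#' Simulation parameters for the Langevin sampler
#'
#' @param dt Integration time step, ps. Default 0.01.
#' @param out_interval Output interval, ps (integer multiple of `dt`).
#'   Default 50 ps (the coarse permeability frame spacing); use 0.01 ps for
#'   kinetics runs.
#' @param n_steps Number of integration steps.
#' @param seed RNG seed (mandatory: runs are bit-reproducible).
#' @param n_particles Number of particles. Default 1.
#' @param n_solute How many of the particles are the solute species.
#'   Default 0.
#' @param single_file Enforce the single-file (no-passing) constraint.
#' @param repulsion_eps Strength of the soft neighbour repulsion,
#'   \eqn{k_B T}. Default 4.
#' @param repulsion_rc Range of the repulsion, Angstrom. Default 2.5.
#' @param boundary `"reflect"` (closed reservoir, default for single-file
#'   runs) or `"reinject"` (particles beyond the wall re-enter uniformly in
#'   a bulk slab).
#' @param single_file_region Half-width of the |z| region where the
#'   no-passing constraint acts, Angstrom. Default 9 (the pore): the 1D
#'   reservoirs stand in for passable 3D bulk, so particles may exchange
#'   order there. Use `Inf` for a fully single-file domain.
#' @param monomer Monomer label attached to the output. Default 0.
#' @return A `langevin_params` list.
#' @export
langevin_params <- function(dt = 0.01, out_interval = 50, n_steps = 1e5,
                            seed = 1, n_particles = 1, n_solute = 0,
                            single_file = n_particles > 1,
                            repulsion_eps = 4, repulsion_rc = 2.5,
                            boundary = c("reflect", "reinject"),
                            single_file_region = 9,
                            monomer = 0L) {
  boundary <- match.arg(boundary)
  k <- out_interval / dt
  if (abs(k - round(k)) > 1e-9)
    abort("`out_interval` must be an integer multiple of `dt`")
  if (is.null(seed) || is.na(seed)) abort("a fixed `seed` is mandatory")
  stopifnot(n_solute <= n_particles, n_steps >= 1)
  structure(list(dt = dt, out_interval = out_interval,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 n_particles = as.integer(n_particles),
                 n_solute = as.integer(n_solute), single_file = single_file,
                 repulsion_eps = repulsion_eps, repulsion_rc = repulsion_rc,
                 boundary = boundary,
                 single_file_region = single_file_region,
                 monomer = as.integer(monomer)),
            class = "langevin_params")
}

model_grid <- function(model, lim = 20, by = 0.02) {
  zg <- seq(-lim, lim, by = by)
  list(z = zg, F = model$F(zg))
}

#' Simulate overdamped single-file Langevin dynamics in a pore model
#'
#' Particles follow \eqn{z \leftarrow z - D F'(z)\,dt + \sqrt{2 D dt}\,\eta}
#' under the model potential (in \eqn{k_B T}), with an optional single-file
#' constraint (soft neighbour repulsion plus an exact no-passing rule).
#' Radial positions are drawn from the equilibrium distribution of the
#' radial confinement (uniform over the accessible disk at each z). Runs are
#' bit-reproducible for a fixed seed.
#'
#' @param model A [build_pore_model()] object.
#' @param params A [langevin_params()] object.
#' @param raw Return the bare frame-by-particle matrix of z positions
#'   (attributes `dt_out`, `times`) instead of a `traj_tbl`; intended for
#'   long fine-resolution kinetics runs where the full table would be
#'   needlessly large. Default `FALSE`.
#' @return A `traj_tbl` with one row per output frame and particle (or a
#'   numeric matrix when `raw = TRUE`).
#' @export
simulate_langevin <- function(model, params, raw = FALSE) {
  stopifnot(inherits(model, "pore_model"), inherits(params, "langevin_params"))
  wall <- model$interval[2]
  g <- model_grid(model, lim = wall)
  np <- params$n_particles
  res <- with_seed(params$seed, {
    # initial positions: spread over the domain, non-degenerate order
    z0 <- seq(-wall + 1, wall - 1, length.out = np + 2)[-c(1, np + 2)]
    z0 <- z0 + runif(np, -0.2, 0.2)
    out_every <- as.integer(round(params$out_interval / params$dt))
    zs <- cpp_langevin(g$z, g$F, model$D, params$dt, params$n_steps,
                       out_every, z0, params$single_file,
                       params$repulsion_eps, params$repulsion_rc, wall,
                       params$boundary, wall - 8, wall - 2,
                       min(params$single_file_region, 1e6))
    list(zs = zs, d_u = if (raw) NULL else runif(length(zs)))
  })
  zs <- res$zs
  n_frames <- nrow(zs)
  times <- seq_len(n_frames) * params$out_interval
  if (raw) {
    attr(zs, "dt_out") <- params$out_interval
    attr(zs, "times") <- times
    return(zs)
  }
  species <- c(rep("solute", params$n_solute),
               rep("water", np - params$n_solute))
  zvec <- as.vector(t(zs)) # row-major: frame-by-frame
  rmax <- model$radial(zvec)
  d_xy <- rmax * sqrt(as.vector(t(matrix(res$d_u, n_frames, np))))
  trajectory_table(
    tibble(time = rep(times, each = np),
           id = rep(seq_len(np), times = n_frames),
           species = rep(species, times = n_frames),
           monomer = params$monomer, z = zvec, d_xy = d_xy),
    dt = params$out_interval, temperature = model$temperature)
}

#' Construct a donor-hydrogen-acceptor geometry
#'
#' Returns three 3D points realising exactly the requested donor-acceptor
#' distance and donor-hydrogen-acceptor angle (hydrogen placed 1 Angstrom
#' from the donor along the donor-acceptor direction, then the acceptor
#' rotated to the requested angle about the hydrogen).
#'
#' @param distance Donor-acceptor distance, Angstrom (> 0).
#' @param angle Donor-hydrogen-acceptor angle, degrees (0-180; 180 is
#'   linear).
#' @return A 3x3 matrix with rows `donor`, `hydrogen`, `acceptor`.
#' @export
#' @examples
#' make_hbond_fixture(2.8, 180)
make_hbond_fixture <- function(distance, angle) {
  stopifnot(distance > 0, angle >= 0, angle <= 180)
  dh <- 1.0
  donor <- c(0, 0, 0)
  hydrogen <- c(dh, 0, 0)
  # acceptor at angle `angle` at the hydrogen, constrained to the requested
  # donor-acceptor distance: solve for the hydrogen-acceptor distance
  th <- angle * pi / 180
  if (distance < dh * abs(sin(th)))
    abort("requested distance is unreachable with a 1 Angstrom D-H bond")
  # law of cosines: d_DA^2 = d_DH^2 + d_HA^2 - 2 d_DH d_HA cos(angle)
  ha <- dh * cos(th) + sqrt(distance^2 - dh^2 * sin(th)^2)
  acceptor <- hydrogen + ha * c(cos(pi - th), sin(pi - th), 0)
  out <- rbind(donor = donor, hydrogen = hydrogen, acceptor = acceptor)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Construct four points with a prescribed dihedral angle
#'
#' Standard construction: the two central atoms define the rotation axis and
#' the outer atoms are placed so that the signed dihedral equals the request.
#'
#' @param angle Dihedral angle in degrees, in (-180, 180].
#' @param bond Bond length used for all three bonds, Angstrom. Default 1.5.
#' @return A 4x3 matrix of coordinates (rows `a1`..`a4`).
#' @export
#' @examples
#' make_dihedral_fixture(-94)
make_dihedral_fixture <- function(angle, bond = 1.5) {
  stopifnot(angle > -180, angle <= 180)
  phi <- angle * pi / 180
  a2 <- c(0, 0, 0)
  a3 <- c(bond, 0, 0)
  a1 <- a2 + bond * c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  # a4 in the plane rotated by phi about the a2->a3 axis
  a4 <- a3 + bond * c(cos(pi - 70 * pi / 180),
                      sin(70 * pi / 180) * cos(phi),
                      -sin(70 * pi / 180) * sin(phi))
  out <- rbind(a1 = a1, a2 = a2, a3 = a3, a4 = a4)
  colnames(out) <- c("x", "y", "z")
  out
}
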