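# shared fixtures built in code

# minimal two-frame trajectory
tiny_traj <- function() {
  trajectory_table(tibble::tibble(
    time = rep(c(0, 50), each = 3), id = rep(1:3, 2),
    species = "water", monomer = 0L,
    z = c(-1, 0, 1, -0.5, 0.5, 1.5), d_xy = 0.5))
}

# single-molecule trajectory from a z series at a given frame interval
z_traj <- function(z, dt = 50, species = "water", d_xy = 0.5,
                   monomer = 0L) {
  trajectory_table(tibble::tibble(
    time = seq_along(z) * dt, id = 1L, species = species,
    monomer = monomer, z = z, d_xy = rep_len(d_xy, length(z))))
}

# symmetric birth-death chain on unit-spaced sites; returns the transition
# matrix (Metropolis rates, reflecting ends) and site positions
toy_chain <- function(Fs, sites = NULL) {
  m <- length(Fs)
  if (is.null(sites)) sites <- seq(-(m - 1) / 2, (m - 1) / 2, 1)
  P <- matrix(0, m, m)
  for (i in seq_len(m)) {
    if (i < m) P[i, i + 1] <- 0.5 * min(1, exp(-(Fs[i + 1] - Fs[i])))
    if (i > 1) P[i, i - 1] <- 0.5 * min(1, exp(-(Fs[i - 1] - Fs[i])))
    P[i, i] <- 1 - sum(P[i, ])
  }
  list(P = P, sites = sites, Fs = Fs, pi = exp(-Fs) / sum(exp(-Fs)))
}

# simulate the chain and return the z path
toy_path <- function(chain, n_steps, seed, init = NULL) {
  if (is.null(init)) init <- as.integer(ceiling(length(chain$sites) / 2))
  set.seed(seed)
  path <- poreperm:::cpp_markov_chain(chain$P, init, as.integer(n_steps))
  chain$sites[path]
}

# cache expensive simulations across test blocks within one run
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .sim_cache)) assign(key, force(expr), .sim_cache)
  get(key, .sim_cache)
}

# standard multi-monomer single-file water run on the wildtype-like model
wildtype_sf_run <- function() {
  cached("wildtype_sf", {
    m <- build_pore_model("wildtype_like")
    trs <- lapply(1:2, function(s) {
      p <- langevin_params(dt = 0.01, out_interval = 50, n_steps = 2e7,
                           seed = s, n_particles = 14, single_file = TRUE,
                           monomer = s - 1L)
      simulate_langevin(m, p)
    })
    tr <- dplyr::bind_rows(trs)
    tr <- trajectory_table(dplyr::mutate(tr, id = id + 100L * monomer))
    attr(tr, "dt") <- 50
    tr
  })
}

# hydrogen-bond fixture plumbing
hb_coords <- function(p, frame = 0L) {
  tibble::tibble(frame = frame, atom = rownames(p),
                 x = unname(p[, 1]), y = unname(p[, 2]),
                 z = unname(p[, 3]))
}
hb_donors <- tibble::tibble(donor = "donor", hydrogen = "hydrogen")

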