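#' Construct a binned free-energy profile
#'
#' A profile is a tibble with one row per z bin: bin centre `z`, free energy
#' `F` in units of \eqn{k_B T} referenced to bulk, per-bin uncertainty `se`
#' and sample count `count`. Bins with zero counts are masked (`F = NA`),
#' never assigned an infinite value.
#'
#' @param z Bin centres (uniform spacing), Angstrom.
#' @param F Free energy per bin, \eqn{k_B T} (NA = masked).
#' @param se Per-bin uncertainty, \eqn{k_B T}.
#' @param count Samples per bin.
#' @param bin_width Bin width in Angstrom (inferred from `z` when `NULL`).
#' @param source `"density"` or `"awh"`.
#' @param bulk_region |z| interval used as bulk reference, or `NULL`.
#' @param temperature Temperature (K) the \eqn{k_B T} scale refers to.
#' @return An `fe_profile` tibble.
#' @export
free_energy_profile <- function(z, F, se = NA_real_, count = NA_real_,
                                bin_width = NULL, source = "density",
                                bulk_region = NULL, temperature = 310) {
  F <- rep_len(as.numeric(F), length(z))
  if (is.null(bin_width)) {
    if (length(z) < 2) abort("cannot infer bin width from a single bin")
    dz <- diff(z)
    if (max(dz) - min(dz) > 1e-8 * max(dz)) abort("bin widths must be uniform")
    bin_width <- dz[1]
  }
  out <- tibble(z = as.numeric(z), F = as.numeric(F),
                se = rep_len(as.numeric(se), length(z)),
                count = rep_len(as.numeric(count), length(z)))
  attr(out, "bin_width") <- bin_width
  attr(out, "source") <- source
  attr(out, "bulk_region") <- bulk_region
  attr(out, "temperature") <- temperature
  class(out) <- c("fe_profile", class(out))
  out
}

fe_keep_attrs <- function(new, old) {
  for (a in c("bin_width", "source", "bulk_region", "temperature"))
    attr(new, a) <- attr(old, a)
  class(new) <- unique(c("fe_profile", class(new)))
  new
}

bulk_bins <- function(profile) {
  br <- attr(profile, "bulk_region")
  if (is.null(br)) return(rep(FALSE, nrow(profile)))
  abs(profile$z) > br[1] & abs(profile$z) < br[2]
}

#' Write / read a free-energy profile as TSV
#'
#' Columns are `bin_center`, `value`, `uncertainty`, `n_samples`; masked bins
#' carry the sentinel `NA` in the value column. Values survive a write/read
#' roundtrip at full printed precision.
#'
#' @param profile An `fe_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fe_profile"))
  if (any(is.infinite(profile$F), na.rm = TRUE))
    abort("profile bins must be finite or masked (NA)")
  br <- attr(profile, "bulk_region")
  header <- c("# free-energy profile (bin_center in Angstrom, value in kBT)",
              sprintf("# bin_width = %.17g, source = %s, temperature = %g",
                      attr(profile, "bin_width"), attr(profile, "source"),
                      attr(profile, "temperature") %||% 310),
              if (!is.null(br)) sprintf("# bulk_region = %.17g %.17g",
                                        br[1], br[2]))
  ok <- try(writeLines(header, path), silent = TRUE)
  if (inherits(ok, "try-error")) abort(paste0("cannot write to ", path))
  readr::write_tsv(
    tibble(bin_center = profile$z, value = profile$F,
           uncertainty = profile$se, n_samples = profile$count),
    path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  hdr <- grep("^#", readLines(path, n = 10), value = TRUE)
  meta <- function(key) {
    ln <- grep(paste0(key, " ="), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    trimws(sub(paste0(".*", key, " = "), "", ln[1]))
  }
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  bw <- meta("bin_width")
  src <- regmatches(hdr, regexpr("source = [a-z]+", hdr))
  br <- meta("bulk_region")
  tmp <- regmatches(hdr, regexpr("temperature = [-0-9.eE+]+", hdr))
  free_energy_profile(
    z = x$bin_center, F = x$value, se = x$uncertainty, count = x$n_samples,
    bin_width = if (!is.null(bw))
      as.numeric(strsplit(bw, ",")[[1]][1]) else NULL,
    source = if (length(src)) sub("source = ", "", src[1]) else "density",
    bulk_region = if (!is.null(br)) as.numeric(strsplit(br, " ")[[1]]) else NULL,
    temperature = if (length(tmp))
      as.numeric(sub("temperature = ", "", tmp[1])) else 310)
}

fe_bin_edges <- function(zlim, bin_width) {
  n <- max(1L, round(diff(zlim) / bin_width))
  seq(zlim[1], zlim[2], length.out = n + 1L)
}

#' Free-energy profile along the channel axis from sample densities
#'
#' Counts molecules of one species in bins along z (inside the radial
#' cutoff) and takes \eqn{F_j = -\ln(\rho_j/\rho_\mathrm{bulk})} in
#' \eqn{k_B T}, with the bulk reference density taken as the mean density
#' over the bulk-region bins. One profile is returned per monomer.
#'
#' @param traj A `traj_tbl`.
#' @param species Species to bin, default `"water"`.
#' @param pore A [pore_definition()].
#' @param bin_width Bin width in Angstrom, default 0.25.
#' @param zlim z range to histogram; default spans the bulk region on both
#'   sides.
#' @return An `fe_profile` for a single-monomer trajectory, otherwise a named
#'   list of `fe_profile` (class `fe_profile_list`), one per monomer.
#' @export
density_free_energy_1d <- function(traj, species = "water",
                                   pore = pore_definition(),
                                   bin_width = 0.25, zlim = NULL) {
  stopifnot(inherits(traj, "traj_tbl"))
  if (is.null(zlim)) zlim <- c(-1, 1) * pore$bulk_region[2]
  x <- filter(as_tibble(traj), .data$species == !!species,
              .data$d_xy <= pore$radial_cutoff)
  if (nrow(x) == 0) abort(paste0("trajectory contains no ", species, " samples"))
  edges <- fe_bin_edges(zlim, bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  temp <- attr(traj, "temperature") %||% 310

  one <- function(zz) {
    counts <- tabulate(findInterval(zz, edges, rightmost.closed = TRUE,
                                    all.inside = FALSE),
                       nbins = length(centers))
    bulk <- abs(centers) > pore$bulk_region[1] &
      abs(centers) < pore$bulk_region[2]
    if (!any(bulk) || sum(counts[bulk]) == 0)
      abort("bulk reference region contains no samples")
    ref <- mean(counts[bulk])
    F <- ifelse(counts > 0, -log(counts / ref), NA_real_)
    se <- ifelse(counts > 0, 1 / sqrt(counts), NA_real_)
    free_energy_profile(centers, F, se, counts, bin_width = diff(edges)[1],
                        source = "density", bulk_region = pore$bulk_region,
                        temperature = temp)
  }
  mons <- sort(unique(x$monomer))
  if (length(mons) == 1) return(one(x$z))
  out <- map(mons, \(m) one(x$z[x$monomer == m]))
  names(out) <- as.character(mons)
  class(out) <- c("fe_profile_list", "list")
  out
}

#' Two-dimensional free-energy map in (z, d_xy)
#'
#' Per-bin counts are divided by the annular bin volume
#' \eqn{2\pi \bar d_{xy} \Delta d \Delta z} (once), then bulk-referenced as
#' in [density_free_energy_1d()]. Set `normalize = FALSE` to reproduce the
#' unnormalised count-based variant.
#'
#' @inheritParams density_free_energy_1d
#' @param bin_width Length-2: bin widths along z and d_xy, Angstrom.
#' @param normalize Apply the annular volume normalisation (default `TRUE`).
#' @return An `fe_map` tibble with columns `z`, `d_xy`, `F`, `count`.
#' @export
density_free_energy_2d <- function(traj, species = "water",
                                   pore = pore_definition(),
                                   bin_width = c(0.25, 0.25), zlim = NULL,
                                   normalize = TRUE) {
  stopifnot(inherits(traj, "traj_tbl"))
  bin_width <- rep_len(bin_width, 2)
  if (is.null(zlim)) zlim <- c(-1, 1) * pore$bulk_region[2]
  x <- filter(as_tibble(traj), .data$species == !!species,
              .data$d_xy <= pore$radial_cutoff)
  if (nrow(x) == 0) abort(paste0("trajectory contains no ", species, " samples"))
  ze <- fe_bin_edges(zlim, bin_width[1])
  de <- fe_bin_edges(c(0, pore$radial_cutoff), bin_width[2])
  zc <- (ze[-1] + ze[-length(ze)]) / 2
  dc <- (de[-1] + de[-length(de)]) / 2
  iz <- findInterval(x$z, ze, rightmost.closed = TRUE)
  id <- findInterval(x$d_xy, de, rightmost.closed = TRUE)
  ok <- iz >= 1 & iz <= length(zc) & id >= 1 & id <= length(dc)
  cnt <- matrix(0, length(zc), length(dc))
  tab <- table(factor(iz[ok], levels = seq_along(zc)),
               factor(id[ok], levels = seq_along(dc)))
  cnt[] <- as.numeric(tab)
  vol <- if (normalize)
    outer(rep(diff(ze)[1], length(zc)), 2 * pi * dc * diff(de)[1]) else
      matrix(1, length(zc), length(dc))
  rho <- cnt / vol
  bulk <- abs(zc) > pore$bulk_region[1] & abs(zc) < pore$bulk_region[2]
  if (!any(bulk) || sum(cnt[bulk, ]) == 0)
    abort("bulk reference region contains no samples")
  ref <- mean(rho[bulk, ][cnt[bulk, ] > 0])
  Fm <- ifelse(cnt > 0, -log(rho / ref), NA_real_)
  out <- tibble(z = rep(zc, times = length(dc)),
                d_xy = rep(dc, each = length(zc)),
                F = as.vector(Fm), count = as.vector(cnt))
  attr(out, "bin_width") <- bin_width
  attr(out, "normalized") <- normalize
  attr(out, "bulk_region") <- pore$bulk_region
  class(out) <- c("fe_map", class(out))
  out
}

align_offsets <- function(mat, wt, tol = 1e-8, max_iter = 100) {
  # additive constants c_i minimising count-weighted squared differences to
  # the running exponential average
  n <- nrow(mat)
  cs <- rep(0, n)
  for (it in seq_len(max_iter)) {
    avg <- -log(colMeans(exp(-(mat + cs)), na.rm = TRUE))
    new <- vapply(seq_len(n), function(i) {
      d <- avg - (mat[i, ] + cs[i])
      w <- wt[i, ]
      ok <- is.finite(d) & is.finite(w) & w > 0
      if (!any(ok)) return(cs[i])
      cs[i] + sum(d[ok] * w[ok]) / sum(w[ok])
    }, numeric(1))
    new <- new - mean(new)
    if (max(abs(new - cs)) < tol) return(new)
    cs <- new
  }
  abort("offset alignment did not converge within `max_iter` iterations")
}

exp_average <- function(mat, wt, tol = 1e-8, max_iter = 100, align = TRUE) {
  cs <- if (align) align_offsets(mat, wt, tol, max_iter) else
    rep(0, nrow(mat))
  -log(colMeans(exp(-(mat + cs)), na.rm = TRUE))
}

reref_bulk <- function(F, bulk) {
  ok <- bulk & is.finite(F)
  if (any(ok)) F + log(mean(exp(-F[ok]))) else F - min(F, na.rm = TRUE)
}

#' Combine per-monomer profiles by self-consistent exponential averaging
#'
#' Profiles are first aligned by additive constants (free energies are
#' defined up to an offset per monomer), then averaged bin-wise as
#' \eqn{-\ln\,\mathrm{mean}_i\, e^{-F_i}}; per-bin error bars are
#' leave-one-monomer-out jackknife standard errors, and the result is
#' re-referenced so that the bulk region averages to zero.
#'
#' @param profiles A list of `fe_profile` on identical bins (at least 2),
#'   e.g. the output of [density_free_energy_1d()] on a multi-monomer
#'   trajectory.
#' @param tol Convergence tolerance of the alignment constants,
#'   \eqn{k_B T}. Default 1e-8.
#' @param max_iter Maximal alignment iterations. Default 100.
#' @param align Perform the additive-constant alignment (default `TRUE`);
#'   set `FALSE` for profiles that are already mutually aligned.
#' @return An `fe_profile` with jackknife `se`.
#' @export
combine_monomer_profiles <- function(profiles, tol = 1e-8, max_iter = 100,
                                     align = TRUE) {
  if (inherits(profiles, "fe_profile")) abort("need at least 2 profiles")
  profiles <- unclass(profiles)
  stopifnot(is.list(profiles), length(profiles) >= 2)
  z <- profiles[[1]]$z
  for (p in profiles)
    if (nrow(p) != length(z) || max(abs(p$z - z)) > 1e-8)
      abort("profiles must share identical bins")
  mat <- do.call(rbind, map(profiles, \(p) p$F))
  wt <- do.call(rbind, map(profiles, \(p) {
    w <- p$count
    if (all(is.na(w))) rep(1, nrow(p)) else ifelse(is.na(w), 0, w)
  }))
  n <- nrow(mat)

  bulk <- bulk_bins(profiles[[1]])
  comb <- reref_bulk(exp_average(mat, wt, tol, max_iter, align), bulk)
  jack <- do.call(rbind, map(seq_len(n), \(i)
    reref_bulk(exp_average(mat[-i, , drop = FALSE], wt[-i, , drop = FALSE],
                           tol, max_iter, align), bulk)))
  jbar <- colMeans(jack)
  se <- sqrt((n - 1) / n * colSums(sweep(jack, 2, jbar)^2))
  counts <- colSums(wt)
  out <- free_energy_profile(
    z, ifelse(is.finite(comb), comb, NA_real_),
    ifelse(is.finite(comb), se, NA_real_), counts,
    bin_width = attr(profiles[[1]], "bin_width"),
    source = attr(profiles[[1]], "source") %||% "density",
    bulk_region = attr(profiles[[1]], "bulk_region"),
    temperature = attr(profiles[[1]], "temperature") %||% 310)
  out
}

#' Maximum free-energy barrier of a profile
#'
#' The maximum of F over the pore-interior bins (\eqn{|z| < L/2}) relative
#' to the bulk reference (0).
#'
#' @param profile An `fe_profile` (bulk-referenced).
#' @param pore A [pore_definition()].
#' @return Barrier height in \eqn{k_B T}.
#' @export
barrier_height <- function(profile, pore = pore_definition()) {
  stopifnot(inherits(profile, "fe_profile"))
  inside <- abs(profile$z) < pore$half_length & !is.na(profile$F)
  if (!any(inside)) abort("no unmasked bins inside the pore")
  max(profile$F[inside])
}

#' Relative permeability predicted from barrier heights
#'
#' Under the barrier model the permeability is proportional to
#' \eqn{e^{-F_b/k_B T}}; the predicted permeability of system A relative to
#' system B is therefore \eqn{e^{F_{b,B} - F_{b,A}}}.
#'
#' @param F_b_A,F_b_B Barrier heights in \eqn{k_B T}.
#' @return The ratio \eqn{p_A/p_B}.
#' @export
#' @examples
#' barrier_permeability_factor(1, 1)      # 1
#' barrier_permeability_factor(0, log(2)) # exactly 2
barrier_permeability_factor <- function(F_b_A, F_b_B) {
  stopifnot(is.finite(F_b_A), is.finite(F_b_B))
  exp(F_b_B - F_b_A)
}

#' Root-mean-square deviation between a profile and a reference
#'
#' Profiles are defined up to an additive constant, so the comparison first
#' aligns the profile to the reference by the (count-weighted) mean offset
#' over unmasked bins, then reports the RMSE over those bins.
#'
#' @param profile An `fe_profile`.
#' @param reference A function of z (\eqn{k_B T}), or a second `fe_profile`
#'   on the same bins.
#' @param zlim Optional z interval restricting the comparison.
#' @return RMSE in \eqn{k_B T}.
#' @export
profile_rmse <- function(profile, reference, zlim = NULL) {
  stopifnot(inherits(profile, "fe_profile"))
  ref <- if (is.function(reference)) reference(profile$z) else {
    stopifnot(inherits(reference, "fe_profile"),
              nrow(reference) == nrow(profile))
    reference$F
  }
  ok <- is.finite(profile$F) & is.finite(ref)
  if (!is.null(zlim)) ok <- ok & profile$z >= zlim[1] & profile$z <= zlim[2]
  if (!any(ok)) abort("no overlapping unmasked bins")
  w <- profile$count[ok]
  if (all(is.na(w))) w <- rep(1, sum(ok))
  d <- profile$F[ok] - ref[ok]
  off <- sum(d * w, na.rm = TRUE) / sum(w, na.rm = TRUE)
  sqrt(mean((d - off)^2))
}
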