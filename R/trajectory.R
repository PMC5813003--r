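#' Build a channel-frame trajectory table
#'
#' The universal input of every estimator in the package: one row per
#' (frame, molecule) with the axial coordinate `z` and radial distance
#' `d_xy` in the channel frame of a monomer.
#'
#' @param x A data frame with columns `time` (ps), `id` (integer molecule id),
#'   `species` (`"water"`, `"solute"` or `"site"`), `monomer` (integer, 0-based
#'   or any consistent labels), `z` (Angstrom) and `d_xy` (Angstrom, >= 0).
#' @param dt Frame interval in ps; inferred from `time` when `NULL`.
#' @param temperature Temperature in K stored as metadata. Default 310.
#' @return A `traj_tbl` tibble with attributes `dt` and `temperature`.
#' @export
#' @examples
#' trajectory_table(tibble::tibble(
#'   time = rep(c(0, 50), each = 2), id = rep(1:2, 2),
#'   species = "water", monomer = 0L,
#'   z = c(-1, 2, -0.5, 2.5), d_xy = 0.5))
trajectory_table <- function(x, dt = NULL, temperature = 310) {
  x <- as_tibble(x)
  need <- c("time", "id", "species", "monomer", "z", "d_xy")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    abort(paste0("missing trajectory columns: ", paste(miss, collapse = ", ")))
  x$species <- as.character(x$species)
  bad <- setdiff(unique(x$species), c("water", "solute", "site"))
  if (length(bad) > 0)
    abort(paste0("unknown species: ", paste(bad, collapse = ", ")))
  if (any(x$d_xy < 0)) abort("d_xy must be >= 0")

  ft <- x$time[!duplicated(x$time)]
  if (any(diff(ft) <= 0))
    abort(sprintf("frame times must be strictly increasing (offending frame at t = %g ps)",
                  ft[which(diff(ft) <= 0)[1] + 1]))
  times <- sort(unique(x$time))
  if (length(times) > 1) {
    dts <- diff(times)
    if (max(dts) - min(dts) > 1e-6 * max(dts))
      abort(sprintf("non-uniform time spacing (first offending frame at t = %g ps)",
                    times[which.max(abs(dts - dts[1])) + 1]))
    dt_obs <- dts[1]
    if (is.null(dt)) dt <- dt_obs
  } else if (is.null(dt)) {
    dt <- NA_real_
  }
  if (anyDuplicated(x[c("time", "id")]) > 0) {
    d <- x[duplicated(x[c("time", "id")]), ]
    abort(sprintf("duplicate (frame, molecule) pair at t = %g ps, id = %s",
                  d$time[1], d$id[1]))
  }
  per_id <- x |>
    summarise(ns = dplyr::n_distinct(.data$species),
              nm = dplyr::n_distinct(.data$monomer), .by = "id")
  if (any(per_id$ns > 1 | per_id$nm > 1))
    abort("species and monomer labels must be constant per molecule id")

  x <- arrange(x, .data$time, .data$id)
  attr(x, "dt") <- dt
  attr(x, "temperature") <- temperature
  class(x) <- c("traj_tbl", class(x))
  x
}

traj_dt <- function(traj) {
  dt <- attr(traj, "dt")
  if (is.null(dt) || is.na(dt)) {
    times <- sort(unique(traj$time))
    if (length(times) < 2) abort("trajectory has fewer than 2 frames")
    dt <- diff(times)[1]
  }
  dt
}

#' Read and write channel-frame trajectories
#'
#' The `"table"` dialect is tab-separated text with a header row
#' (`time  id  species  monomer  z  d_xy`) and `#` comment lines; the
#' `"xyz"` format is a multi-frame XYZ coordinate file which is projected
#' into the channel frame using a site map (see [project_to_pore_frame()]).
#'
#' @param path File path.
#' @param format `"table"` (default) or `"xyz"`.
#' @param site_map For `format = "xyz"`: a data frame mapping atom names to
#'   `molecule`, `species`, `monomer` and `role` (`"reference"` atoms define
#'   the monomer frame, `"mobile"` atoms are projected).
#' @param ... Passed on to [project_to_pore_frame()] for XYZ input.
#' @return A `traj_tbl` (see [trajectory_table()]).
#' @export
read_trajectory <- function(path, format = c("table", "xyz"),
                            site_map = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "table") {
    x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
    trajectory_table(x)
  } else {
    if (is.null(site_map)) abort("XYZ input requires a `site_map`")
    coords <- read_xyz_frames(path)
    project_to_pore_frame(coords, site_map, ...)
  }
}

#' @rdname read_trajectory
#' @param traj A `traj_tbl`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "traj_tbl"))
  writeLines(c("# channel-frame trajectory (z, d_xy in Angstrom; time in ps)",
               sprintf("# dt = %g ps, temperature = %g K",
                       traj_dt(traj), attr(traj, "temperature") %||% 310)),
             path)
  readr::write_tsv(as_tibble(traj)[c("time", "id", "species", "monomer",
                                     "z", "d_xy")], path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a multi-frame XYZ coordinate file
#'
#' Frames follow the standard layout: atom count line, comment line (a
#' `time = <ps>` token is honoured, otherwise frames are numbered), then one
#' `name x y z` line per atom.
#'
#' @param path File path.
#' @return A tibble with columns `frame`, `time`, `atom`, `x`, `y`, `z`.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0)
      abort(sprintf("malformed XYZ atom-count line %d: '%s'", i, lines[i]))
    if (i + 1L + nat > length(lines))
      abort(sprintf("truncated XYZ frame starting at line %d", i))
    comment <- lines[i + 1L]
    tm <- regmatches(comment,
                     regexec("time\\s*=?\\s*([-0-9.eE+]+)", comment))[[1]]
    time <- if (length(tm) == 2) as.numeric(tm[2]) else NA_real_
    rows <- lines[(i + 2L):(i + 1L + nat)]
    fields <- strsplit(trimws(rows), "\\s+")
    if (any(lengths(fields) < 4))
      abort(sprintf("malformed XYZ atom line in frame %d", frame + 1L))
    out[[length(out) + 1L]] <- tibble(
      frame = frame,
      time = time,
      atom = vapply(fields, `[[`, "", 1L),
      x = as.numeric(vapply(fields, `[[`, "", 2L)),
      y = as.numeric(vapply(fields, `[[`, "", 3L)),
      z = as.numeric(vapply(fields, `[[`, "", 4L)))
    frame <- frame + 1L
    i <- i + 2L + nat
  }
  res <- list_rbind(out)
  if (all(is.na(res$time))) res$time <- res$frame
  res
}

#' Project 3D coordinates into the channel frame of each monomer
#'
#' For every frame and monomer the origin is placed at the centre of the
#' monomer's reference atoms (geometric centre by default, mass-weighted when
#' masses are given); `z` is the coordinate of each mobile molecule along the
#' channel axis relative to that origin and `d_xy` its distance from the axis
#' through the origin.
#'
#' @param coords A tibble as returned by [read_xyz_frames()] (columns `frame`,
#'   `time`, `atom`, `x`, `y`, `z`).
#' @param site_map Data frame with columns `atom`, `role` (`"reference"` /
#'   `"mobile"`), `monomer`, and for mobile atoms `molecule` (id) and
#'   `species`.
#' @param axis Channel axis as a length-3 vector (normalised internally).
#'   Default the laboratory z axis.
#' @param masses Optional named vector of atomic masses (by atom name); when
#'   supplied the reference centre is mass-weighted.
#' @param temperature Metadata temperature (K).
#' @return A `traj_tbl`.
#' @export
project_to_pore_frame <- function(coords, site_map, axis = c(0, 0, 1),
                                  masses = NULL, temperature = 310) {
  coords <- as_tibble(coords)
  site_map <- as_tibble(site_map)
  stopifnot(all(c("atom", "role", "monomer") %in% names(site_map)))
  axis <- as.numeric(axis)
  if (length(axis) != 3 || sum(axis^2) == 0)
    abort("`axis` must be a non-zero length-3 vector")
  axis <- axis / sqrt(sum(axis^2))

  refs <- filter(site_map, .data$role == "reference")
  if (nrow(refs) == 0) abort("empty reference selection")
  for (m in unique(site_map$monomer))
    if (!any(refs$monomer == m))
      abort(sprintf("empty reference selection for monomer %s", m))

  w <- if (is.null(masses)) rep(1, nrow(refs)) else {
    if (!all(refs$atom %in% names(masses)))
      abort("`masses` must name every reference atom")
    unname(masses[refs$atom])
  }
  refs$mass <- w

  ref_xyz <- coords |>
    inner_join(refs[c("atom", "monomer", "mass")], by = "atom",
               relationship = "many-to-many") |>
    summarise(cx = sum(.data$x * .data$mass) / sum(.data$mass),
              cy = sum(.data$y * .data$mass) / sum(.data$mass),
              cz = sum(.data$z * .data$mass) / sum(.data$mass),
              .by = c("frame", "time", "monomer"))

  mob <- filter(site_map, .data$role == "mobile")
  if (!all(c("molecule", "species") %in% names(mob)))
    abort("mobile rows of `site_map` need `molecule` and `species`")
  res <- coords |>
    inner_join(mob[c("atom", "molecule", "species", "monomer")], by = "atom",
               relationship = "many-to-many") |>
    inner_join(ref_xyz, by = c("frame", "time", "monomer")) |>
    mutate(dx = .data$x - .data$cx, dy = .data$y - .data$cy,
           dz = .data$z - .data$cz,
           zproj = .data$dx * axis[1] + .data$dy * axis[2] + .data$dz * axis[3],
           d_xy = sqrt(pmax(0, .data$dx^2 + .data$dy^2 + .data$dz^2 -
                              .data$zproj^2))) |>
    transmute(time = .data$time, id = .data$molecule,
              species = .data$species, monomer = .data$monomer,
              z = .data$zproj, d_xy = .data$d_xy)
  trajectory_table(res, temperature = temperature)
}

#' Mean and standard error over monomers
#'
#' The uncertainty of a per-monomer average \eqn{\mu} is reported as
#' \eqn{\sigma_\mu = \sigma/\sqrt{n}}, with \eqn{\sigma} the sample standard
#' deviation (n - 1 denominator) across the n monomers.
#'
#' @param values One value per monomer (n >= 2).
#' @return A one-row `monomer_stat` tibble: `mean`, `sem`, `sd`, `n`.
#' @export
#' @examples
#' monomer_mean_sem(c(1, 2, 3, 4))
monomer_mean_sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2)
    abort("need at least 2 monomer values for a standard error")
  s <- sd(values)
  out <- tibble(mean = mean(values), sem = s / sqrt(length(values)),
                sd = s, n = length(values))
  class(out) <- c("monomer_stat", class(out))
  out
}
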