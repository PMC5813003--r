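#' Tidy a permeability result
#'
#' @param x A `permeability_result` from [osmotic_permeability()] or
#'   [diffusion_permeability()].
#' @param ... Unused.
#' @return One row per monomer with the per-monomer permeability.
#' @export
tidy.permeability_result <- function(x, ...) {
  as_tibble(x$per_monomer)
}

#' @rdname tidy.permeability_result
#' @export
glance.permeability_result <- function(x, ...) {
  tibble(quantity = x$what, estimate = x$mean, sem = x$sem,
         n_monomers = x$n, v_w = x$v_w)
}

#' Tidy a kinetic estimate
#'
#' @param x A `kinetic_estimate` from [kinetic_pd()].
#' @param ... Unused.
#' @return The per-direction tibble (`tidy`) or the inverse-variance
#'   weighted combination (`glance`).
#' @export
tidy.kinetic_estimate <- function(x, ...) {
  new_tibble(as.data.frame(x))
}

#' @rdname tidy.kinetic_estimate
#' @export
glance.kinetic_estimate <- function(x, ...) {
  kinetic_pd_combined(x)
}

#' Tidy a free-energy profile
#'
#' @param x An `fe_profile`.
#' @param ... Unused.
#' @return `tidy`: the per-bin tibble; `glance`: one row with the barrier
#'   height, bin width, source and number of unmasked bins.
#' @export
tidy.fe_profile <- function(x, ...) {
  new_tibble(as.data.frame(x))
}

#' @rdname tidy.fe_profile
#' @param pore A [pore_definition()] for the barrier computation.
#' @export
glance.fe_profile <- function(x, pore = pore_definition(), ...) {
  fb <- tryCatch(barrier_height(x, pore), error = function(e) NA_real_)
  tibble(barrier = fb, bin_width = attr(x, "bin_width"),
         source = attr(x, "source"),
         n_bins = nrow(x), n_masked = sum(is.na(x$F)),
         traversals = attr(x, "traversals") %||% NA_real_)
}
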