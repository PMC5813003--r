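#' Define the pore geometry used by all estimators
#'
#' The pore is a cylinder in the channel frame: axial extent
#' \eqn{|z| < L/2} and radial extent \eqn{d_{xy} \le} `radial_cutoff`.
#' The selectivity-filter (SF) region and the bulk reference region (used to
#' zero free-energy profiles) are carried along as z-intervals.
#'
#' @param half_length Pore half length L/2 in Angstrom. Default 9.
#' @param radial_cutoff Maximal radial distance from the channel axis in
#'   Angstrom for a molecule to count as in-pore. Default 7.
#' @param sf_region Numeric length-2: z-interval of the SF region, Angstrom.
#'   Default `c(6, 9)`.
#' @param bulk_region Numeric length-2: interval of |z| used as the bulk
#'   free-energy reference. Must lie outside the pore. Default `c(12, 18)`.
#' @return An object of class `pore_definition`.
#' @export
#' @examples
#' pore_definition()
pore_definition <- function(half_length = 9, radial_cutoff = 7,
                            sf_region = c(6, 9), bulk_region = c(12, 18)) {
  stopifnot(half_length > 0, radial_cutoff > 0,
            length(sf_region) == 2, length(bulk_region) == 2)
  if (sf_region[1] >= sf_region[2])
    abort("`sf_region` must be an increasing interval")
  if (max(abs(sf_region)) > half_length + 1)
    abort("SF region must lie inside |z| < L/2 (+1 Angstrom margin)")
  if (bulk_region[1] <= half_length)
    abort("bulk region must be disjoint from the pore interior")
  structure(
    list(half_length = half_length, radial_cutoff = radial_cutoff,
         sf_region = sf_region, bulk_region = bulk_region),
    class = "pore_definition")
}

#' @export
print.pore_definition <- function(x, ...) {
  cat("<pore_definition>\n")
  cat(sprintf("  |z| < %.6g A (L = %.6g A), d_xy <= %.6g A\n",
              x$half_length, 2 * x$half_length, x$radial_cutoff))
  cat(sprintf("  SF region: %.6g < z < %.6g A\n",
              x$sf_region[1], x$sf_region[2]))
  cat(sprintf("  bulk reference: %.6g < |z| < %.6g A\n",
              x$bulk_region[1], x$bulk_region[2]))
  invisible(x)
}

#' Read or write a pore definition as YAML/JSON
#'
#' @param path File path; format is inferred from the extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return `read_pore_definition()` returns a [pore_definition()];
#'   `write_pore_definition()` returns `path` invisibly.
#' @export
read_pore_definition <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- yaml::read_yaml(path) # reads JSON too (YAML superset)
  pore_definition(
    half_length = x$half_length %||% 9,
    radial_cutoff = x$radial_cutoff %||% 7,
    sf_region = unlist(x$sf_region %||% c(6, 9)),
    bulk_region = unlist(x$bulk_region %||% c(12, 18)))
}

#' @rdname read_pore_definition
#' @param pore A [pore_definition()].
#' @export
write_pore_definition <- function(pore, path) {
  stopifnot(inherits(pore, "pore_definition"))
  yaml::write_yaml(unclass(pore), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

in_pore <- function(z, d_xy, pore) {
  abs(z) < pore$half_length & d_xy <= pore$radial_cutoff
}

in_sf <- function(z, d_xy, pore) {
  z > pore$sf_region[1] & z < pore$sf_region[2] & d_xy < pore$radial_cutoff
}

in_bulk <- function(z, d_xy, pore) {
  abs(z) > pore$bulk_region[1] & abs(z) < pore$bulk_region[2] &
    d_xy <= pore$radial_cutoff
}
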