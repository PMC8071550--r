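#' Radial finite-volume grid over the Krogh annulus
#'
#' Uniformly spaced shells between the capillary wall and the Krogh radius.
#' Shell volumes are per unit capillary length, `pi * (r_{i+1}^2 - r_i^2)`.
#'
#' @param tissue A [tissue_spec()].
#' @param n_shells Number of shells (`>= 4`).
#' @return An object of class `radial_grid` with elements `edges` (um,
#'   length `n_shells + 1`), `centers` (um), `volumes` (um^3 per um length)
#'   and the two bounding radii.
#' @export
build_grid <- function(tissue, n_shells = 100) {
  stopifnot(inherits(tissue, "tissue_spec"))
  if (n_shells < 4) stop("n_shells must be >= 4")
  r0 <- tissue$capillary_radius
  r1 <- tissue$krogh_radius
  if (r1 <= r0) stop("krogh_radius must exceed capillary_radius")
  edges <- seq(r0, r1, length.out = n_shells + 1)
  structure(
    list(
      edges = edges,
      centers = (edges[-1] + edges[-length(edges)]) / 2,
      volumes = pi * diff(edges^2),
      capillary_radius = r0,
      krogh_radius = r1,
      n_shells = n_shells
    ),
    class = "radial_grid"
  )
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("<radial_grid> %d shells, %g-%g um, spacing %.3g um\n",
              x$n_shells, x$capillary_radius, x$krogh_radius,
              diff(x$edges[1:2])))
  invisible(x)
}

#' Volume-weighted average of a per-shell field
#'
#' @param x Per-shell values (or a matrix with one row per shell).
#' @param grid A `radial_grid`.
#' @return Scalar (or per-column) average weighted by shell volume; the
#'   capillary lumen is not part of the domain.
#' @export
volume_average <- function(x, grid) {
  w <- grid$volumes / sum(grid$volumes)
  if (is.matrix(x)) as.numeric(crossprod(w, x)) else sum(w * x)
}

#' Transcapillary wall flux
#'
#' Extravasation across the capillary wall, driven by the difference between
#' the plasma concentration and the free interstitial concentration at the
#' wall (whole-tissue concentration divided by the void fraction).
#'
#' @param c_plasma Plasma concentration, molar.
#' @param c_int_surface Whole-tissue interstitial concentration in the
#'   innermost shell, molar.
#' @param P Permeability, um/h (already size-scaled and unit-converted).
#' @param void_fraction Interstitial volume fraction.
#' @return Flux in M um / h per unit wall area (positive into the tissue).
#' @export
wall_flux <- function(c_plasma, c_int_surface, P, void_fraction) {
  P * (c_plasma - c_int_surface / void_fraction)
}

#' Finite-volume transport operator for a mobile interstitial species
#'
#' Radial diffusion (central differences on the whole-tissue concentration)
#' plus optional radial convection with the incompressible velocity profile
#' `v(r) = v_wall * r_cap / r`, discretised upwind.  The inner boundary
#' receives `flux_in` (mol per wall area per time); the outer boundary is
#' closed to diffusion, and when `v_wall > 0` the convective flux leaves the
#' domain there (lymphatic drainage).
#'
#' @param field Whole-tissue concentration per shell, molar.
#' @param grid A `radial_grid`.
#' @param D Diffusivity, um^2/h.
#' @param v_wall Fluid velocity at the capillary wall, um/h.
#' @param flux_in Inner-boundary flux per wall area, M um/h.
#' @param outflow Logical; if `TRUE` (default) the convective flux leaves the
#'   domain at the Krogh radius (lymphatic sink), otherwise the outer
#'   boundary retains solute.
#' @return d(field)/dt per shell, M/h.
#' @export
transport_operator <- function(field, grid, D, v_wall, flux_in = 0,
                               outflow = TRUE) {
  n <- grid$n_shells
  edges <- grid$edges
  dr <- diff(edges[1:2])
  inner_edges <- edges[2:n]                     # interfaces between shells
  # diffusive interface fluxes, per unit capillary length (M um^2 / h)
  grad <- (field[-1] - field[-n]) / dr
  f_diff <- -D * grad * (2 * pi * inner_edges)
  # convective fluxes: v(r) * 2 pi r = 2 pi v_wall r_cap, upwind (outward flow)
  if (v_wall > 0) {
    conv_coef <- 2 * pi * v_wall * grid$capillary_radius
    f_conv <- conv_coef * field[-n]             # upwind donor = inner shell
    f_out <- if (outflow) conv_coef * field[n] else 0
  } else {
    f_conv <- 0
    f_out <- 0
  }
  f_face <- f_diff + f_conv                     # flux across interior faces
  f_in <- flux_in * 2 * pi * grid$capillary_radius
  net <- c(f_in, f_face) - c(f_face, f_out)
  net / grid$volumes
}
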