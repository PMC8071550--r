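#' Therapeutic agent description
#'
#' Bundles the engineerable properties of a targeted agent: its size (which
#' sets transport through [scale_transport()]), receptor binding, plasma and
#' cytosolic stability, endosomal escape efficiency, and mode of action.
#' A `binder` occupies its cytosolic target stoichiometrically; a `catalytic`
#' agent inactivates target molecules with turnover number `k_cat` and is
#' released intact.  A cold agent (`is_cold = TRUE`) carries no cargo and only
#' competes for the surface receptor.
#'
#' @param molecular_weight kDa.
#' @param kd_receptor Equilibrium dissociation constant for the surface
#'   receptor, molar.  `koff = kon_receptor * kd_receptor`.
#' @param kon_receptor Association rate constant for the receptor, 1/(M s).
#' @param plasma_half_life Hours; mono-exponential plasma decay.
#' @param cytosolic_half_life Hours; first-order loss of the delivered agent
#'   (free or in complex) in the cytosol.
#' @param mode `"binder"` or `"catalytic"`.
#' @param k_cat Catalytic turnover, 1/min.  Must be 0 for binders.
#' @param kd_target Dissociation constant for the cytosolic target, molar.
#' @param kon_target Association rate constant for the target, 1/(M s).
#' @param escape_fraction Fraction of internalized agent that reaches the
#'   cytosol; the remainder is degraded in the endolysosomal pathway.
#' @param is_cold Logical; cold competitor without cargo.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(molecular_weight = 70,
                       kd_receptor = 68e-12,
                       kon_receptor = 1e5,
                       plasma_half_life = 2.55,
                       cytosolic_half_life = 6,
                       mode = c("binder", "catalytic"),
                       k_cat = 0,
                       kd_target = 3e-10,
                       kon_target = 1e6,
                       escape_fraction = 0.012,
                       is_cold = FALSE) {
  mode <- match.arg(mode)
  stopifnot(
    molecular_weight > 0, kd_receptor > 0, kon_receptor > 0,
    plasma_half_life > 0, cytosolic_half_life > 0,
    kd_target > 0, kon_target > 0,
    is.logical(is_cold), length(is_cold) == 1L
  )
  if (escape_fraction < 0 || escape_fraction > 1) {
    stop("escape_fraction must lie in [0, 1]")
  }
  if (mode == "binder" && k_cat != 0) {
    stop("k_cat must be 0 in binder mode")
  }
  if (mode == "catalytic" && k_cat <= 0) {
    stop("catalytic mode requires k_cat > 0 (1/min)")
  }
  koff <- kon_receptor * kd_receptor
  koff_t <- kon_target * kd_target
  if (!is.finite(koff) || koff <= 0 || !is.finite(koff_t) || koff_t <= 0) {
    stop("derived koff rates must be finite and positive")
  }
  structure(
    list(
      molecular_weight = molecular_weight,
      kd_receptor = kd_receptor,
      kon_receptor = kon_receptor,
      plasma_half_life = plasma_half_life,
      cytosolic_half_life = cytosolic_half_life,
      mode = mode,
      k_cat = k_cat,
      kd_target = kd_target,
      kon_target = kon_target,
      escape_fraction = escape_fraction,
      is_cold = is_cold
    ),
    class = "agent_spec"
  )
}

#' @export
print.agent_spec <- function(x, ...) {
  cat(sprintf(
    "<agent_spec> %s kDa %s%s | Kd(receptor) %.3g M | t1/2 plasma %.3g h, cytosol %.3g h\n",
    format(x$molecular_weight), x$mode,
    if (x$is_cold) " (cold)" else "",
    x$kd_receptor, x$plasma_half_life, x$cytosolic_half_life
  ))
  if (x$mode == "catalytic") cat(sprintf("  k_cat %.3g /min\n", x$k_cat))
  invisible(x)
}

#' Tissue description for the Krogh cylinder
#'
#' Geometry, transport and receptor biology of a tissue preset.  Transport
#' coefficients (`vascular_permeability`, `interstitial_diffusivity`) are
#' reference values at `reference_mw` kDa and are rescaled to the agent's
#' size via [scale_transport()].
#'
#' @param capillary_radius,krogh_radius Inner/outer radius of the annulus, um.
#' @param void_fraction Interstitial volume fraction accessible to the agent.
#' @param vascular_permeability Capillary wall permeability, cm/s, at
#'   `reference_mw`.
#' @param interstitial_diffusivity Interstitial diffusivity, cm^2/s, at
#'   `reference_mw`.
#' @param reference_mw kDa at which the transport pair was measured.
#' @param fluid_velocity_at_wall Interstitial fluid velocity at the capillary
#'   wall, um/s (0 = purely diffusive tissue; > 0 when lymphatics drain the
#'   periphery and sustain radial convection).
#' @param cell_density Cells per mL of tissue.
#' @param receptors_per_cell Surface receptors per cell.
#' @param k_internalize Internalization rate of the receptor--agent complex,
#'   1/min.
#' @param receptor_steady_state Logical; if `TRUE` recycling/synthesis exactly
#'   matches the internalization flux so the surface receptor pool is
#'   conserved.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(capillary_radius = 8,
                        krogh_radius = 108,
                        void_fraction = 0.1,
                        vascular_permeability = 7e-7,
                        interstitial_diffusivity = 1e-8,
                        reference_mw = 70,
                        fluid_velocity_at_wall = 0,
                        cell_density = 2.9e8,
                        receptors_per_cell = 5.4e5,
                        k_internalize = 0.002,
                        receptor_steady_state = TRUE) {
  if (!(krogh_radius > capillary_radius) || capillary_radius <= 0) {
    stop("need krogh_radius > capillary_radius > 0 (um)")
  }
  if (void_fraction <= 0 || void_fraction >= 1) {
    stop("void_fraction must lie in (0, 1)")
  }
  stopifnot(
    vascular_permeability > 0, interstitial_diffusivity > 0, reference_mw > 0,
    fluid_velocity_at_wall >= 0, cell_density >= 0, receptors_per_cell >= 0,
    k_internalize >= 0, is.logical(receptor_steady_state)
  )
  structure(
    list(
      capillary_radius = capillary_radius,
      krogh_radius = krogh_radius,
      void_fraction = void_fraction,
      vascular_permeability = vascular_permeability,
      interstitial_diffusivity = interstitial_diffusivity,
      reference_mw = reference_mw,
      fluid_velocity_at_wall = fluid_velocity_at_wall,
      cell_density = cell_density,
      receptors_per_cell = receptors_per_cell,
      k_internalize = k_internalize,
      receptor_steady_state = receptor_steady_state
    ),
    class = "tissue_spec"
  )
}

#' @export
print.tissue_spec <- function(x, ...) {
  cat(sprintf(
    "<tissue_spec> annulus %g-%g um | P %.2g cm/s, D %.2g cm2/s @ %g kDa | v_wall %g um/s\n",
    x$capillary_radius, x$krogh_radius, x$vascular_permeability,
    x$interstitial_diffusivity, x$reference_mw, x$fluid_velocity_at_wall
  ))
  cat(sprintf(
    "  %.3g cells/mL, %.3g receptors/cell, ke %.3g /min%s\n",
    x$cell_density, x$receptors_per_cell, x$k_internalize,
    if (x$receptor_steady_state) " (receptor pool at steady state)" else ""
  ))
  invisible(x)
}

#' Cytosolic target description
#'
#' @param copies_per_cell Number of target molecules per cell before dosing.
#' @param cytosol_volume_per_cell Picolitres; 1 pL makes ~6000 copies == 10 nM,
#'   consistent with typical cellular protein abundances of 2000--8000
#'   copies/cell (~2--10 nM).
#' @param target_half_life Hours; turnover of the target.  Synthesis is set so
#'   the pre-dose steady state equals `copies_per_cell`.
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(copies_per_cell = 1e4,
                        cytosol_volume_per_cell = 1,
                        target_half_life = 24) {
  stopifnot(copies_per_cell >= 0, cytosol_volume_per_cell > 0, target_half_life > 0)
  structure(
    list(
      copies_per_cell = copies_per_cell,
      cytosol_volume_per_cell = cytosol_volume_per_cell,
      target_half_life = target_half_life
    ),
    class = "target_spec"
  )
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf(
    "<target_spec> %.3g copies/cell (%.3g nM cytosolic), t1/2 %g h\n",
    x$copies_per_cell,
    1e9 * copies_to_molar(x$copies_per_cell, x$cytosol_volume_per_cell),
    x$target_half_life
  ))
  invisible(x)
}
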