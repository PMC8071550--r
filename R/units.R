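#' @keywords internal
#' Avogadro constant, 1/mol
.N_AVOGADRO <- 6.02214076e23

# internal unit conversion factors: the solver works in micrometres, hours,
# molar.  User-facing parameters keep the units of the field's literature
# (cm/s for permeability, cm^2/s for diffusivity, 1/min for cellular rates).
.CM_S_TO_UM_H <- 1e4 * 3600        # cm/s -> um/h
.CM2_S_TO_UM2_H <- 1e8 * 3600      # cm^2/s -> um^2/h
.UM_S_TO_UM_H <- 3600              # um/s -> um/h
.PER_MIN_TO_PER_H <- 60
.PER_M_S_TO_PER_M_H <- 3600

#' Convert a per-cell receptor count to a molar tissue concentration
#'
#' Surface receptors are counted per cell and cells per millilitre of tissue;
#' the reaction network needs the receptor pool as a concentration on the
#' whole-tissue-volume basis used for the interstitial and surface species.
#'
#' @param receptors_per_cell Number of receptors displayed per cell.
#' @param cell_density Cells per millilitre of tissue.
#' @return Receptor concentration in mol/L of whole tissue.
#' @examples
#' receptors_to_molar(5.4e5, 2.9e8) # ~2.6e-7 M for a high-cellularity tumor
#' @export
receptors_to_molar <- function(receptors_per_cell, cell_density) {
  stopifnot(receptors_per_cell >= 0, cell_density >= 0)
  receptors_per_cell * cell_density * 1e3 / .N_AVOGADRO
}

#' Convert a per-cell copy number to a molar cytosolic concentration
#'
#' @param copies_per_cell Number of molecules per cell.
#' @param cytosol_volume_per_cell Cytosolic volume per cell in picolitres.
#' @return Concentration in mol/L of cytosol.
#' @examples
#' copies_to_molar(6022, 1) # 1e-8 M: ~6000 copies in 1 pL is 10 nM
#' @export
copies_to_molar <- function(copies_per_cell, cytosol_volume_per_cell) {
  stopifnot(copies_per_cell >= 0)
  if (cytosol_volume_per_cell <= 0) {
    stop("cytosol_volume_per_cell must be > 0 (picolitres)")
  }
  copies_per_cell / (.N_AVOGADRO * cytosol_volume_per_cell * 1e-12)
}

#' Scale transport coefficients with molecular weight
#'
#' Interstitial diffusivity follows a Stokes--Einstein cube-root law on
#' molecular mass, D ~ MW^(-1/3).  Transcapillary permeability falls more
#' steeply with size because of pore hindrance at the vessel wall; the
#' default exponent is 2/3 (configurable).
#'
#' @param reference List with elements `P` (cm/s), `D` (cm^2/s) and
#'   `MW_ref` (kDa): the measured transport pair at a reference size.
#' @param MW Molecular weight of the agent, kDa.
#' @param permeability_exponent Exponent for the permeability scaling
#'   (default 2/3; diffusivity always uses 1/3).
#' @return List with elements `P` (cm/s) and `D` (cm^2/s) at `MW`.
#' @export
scale_transport <- function(reference, MW, permeability_exponent = 2 / 3) {
  stopifnot(is.list(reference), all(c("P", "D", "MW_ref") %in% names(reference)))
  if (!is.numeric(MW) || MW <= 0) stop("MW must be a positive molecular weight in kDa")
  ratio <- reference$MW_ref / MW
  list(
    P = reference$P * ratio^permeability_exponent,
    D = reference$D * ratio^(1 / 3)
  )
}
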