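# Assembly of the coupled reaction network.
#
# Concentration bases: the interstitial agent, free receptor and surface
# complex live on the whole-tissue-volume basis (M of tissue); the cytosolic
# agent, free target and inhibitory complex live on the cytosol-volume basis
# (M of cytosol), which is the basis on which their second-order kinetics and
# the copies/cell calibration are physical.  The two are linked by
# phi = cell_density * cytosol_volume_per_cell (cytosol volume fraction).

.species_names <- function(cold = FALSE) {
  base <- c("A_int", "R_free", "RC_surf", "A_cyt", "T_free", "TC_cyt")
  if (cold) c(base, "A_int_cold", "RC_surf_cold") else base
}

# resolve specs into the flat parameter list used by the solver (um, h, M)
.build_params <- function(agent, tissue, target, grid, cold_agent = NULL) {
  tr <- scale_transport(
    list(P = tissue$vascular_permeability, D = tissue$interstitial_diffusivity,
         MW_ref = tissue$reference_mw),
    agent$molecular_weight
  )
  phi <- tissue$cell_density * 1e3 * target$cytosol_volume_per_cell * 1e-12
  if (phi <= 0) phi <- 1  # acellular tissue: cytosolic species are inert
  p <- list(
    grid = grid,
    eps = tissue$void_fraction,
    P = tr$P * .CM_S_TO_UM_H,
    D = tr$D * .CM2_S_TO_UM2_H,
    v = tissue$fluid_velocity_at_wall * .UM_S_TO_UM_H,
    kon = agent$kon_receptor * .PER_M_S_TO_PER_M_H,
    koff = agent$kon_receptor * agent$kd_receptor * .PER_M_S_TO_PER_M_H,
    ke = tissue$k_internalize * .PER_MIN_TO_PER_H,
    receptor_ss = tissue$receptor_steady_state,
    R_tot = receptors_to_molar(tissue$receptors_per_cell, tissue$cell_density),
    fesc = agent$escape_fraction,
    phi = phi,
    kdeg_a = log(2) / agent$cytosolic_half_life,
    kon_t = agent$kon_target * .PER_M_S_TO_PER_M_H,
    koff_t = agent$kon_target * agent$kd_target * .PER_M_S_TO_PER_M_H,
    kcat = agent$k_cat * .PER_MIN_TO_PER_H,
    T0 = copies_to_molar(target$copies_per_cell, target$cytosol_volume_per_cell),
    kdeg_T = log(2) / target$target_half_life,
    cold = !is.null(cold_agent)
  )
  p$ksyn <- p$T0 * p$kdeg_T
  if (p$cold) {
    trc <- scale_transport(
      list(P = tissue$vascular_permeability, D = tissue$interstitial_diffusivity,
           MW_ref = tissue$reference_mw),
      cold_agent$molecular_weight
    )
    p$P_cold <- trc$P * .CM_S_TO_UM_H
    p$D_cold <- trc$D * .CM2_S_TO_UM2_H
    p$kon_cold <- cold_agent$kon_receptor * .PER_M_S_TO_PER_M_H
    p$koff_cold <- cold_agent$kon_receptor * cold_agent$kd_receptor *
      .PER_M_S_TO_PER_M_H
  }
  p$nspec <- if (p$cold) 8L else 6L
  p
}

#' Reaction-rate contributions for one tissue shell
#'
#' The pure reaction part of the model (no transport): reversible surface
#' binding, internalization with endosomal escape, receptor recycling,
#' cytosolic decay of the agent, target synthesis/turnover, reversible target
#' engagement, and catalytic turnover in catalytic mode.  Exposed mainly for
#' inspection and testing; [simulate_delivery()] assembles the same terms for
#' all shells.
#'
#' @param state Named numeric vector with entries `A_int`, `R_free`,
#'   `RC_surf` (whole-tissue molar) and `A_cyt`, `T_free`, `TC_cyt`
#'   (cytosolic molar); optionally `A_int_cold`, `RC_surf_cold`.
#' @param agent,tissue,target Spec objects.
#' @param cold_agent Optional cold competitor [agent_spec()].
#' @return Named vector of d/dt contributions, per hour, same basis as the
#'   corresponding state entry.
#' @export
reaction_terms <- function(state, agent, tissue, target, cold_agent = NULL) {
  grid <- build_grid(tissue, 4)  # geometry is irrelevant to the reactions
  p <- .build_params(agent, tissue, target, grid, cold_agent)
  nm <- .species_names(p$cold)
  stopifnot(all(nm %in% names(state)))
  y <- matrix(state[nm], nrow = length(nm))
  d <- .reaction_rhs(y, p)
  stats::setNames(as.numeric(d), nm)
}

# y: matrix nspec x n_shells; returns matrix of reaction d/dt (same shape)
.reaction_rhs <- function(y, p) {
  A <- y[1, ]; R <- y[2, ]; C <- y[3, ]
  Ac <- y[4, ]; Tf <- y[5, ]; B <- y[6, ]
  bind <- p$kon * (A / p$eps) * R - p$koff * C
  intern <- p$ke * C
  dA <- -bind
  dC <- bind - intern
  dR <- -bind + if (p$receptor_ss) intern else 0
  esc <- p$fesc * intern / p$phi
  cap <- p$kon_t * Ac * Tf - p$koff_t * B
  dAc <- esc - p$kdeg_a * Ac - cap + p$kcat * B
  dT <- p$ksyn - p$kdeg_T * Tf - cap
  dB <- cap - p$kcat * B
  out <- rbind(dA, dR, dC, dAc, dT, dB)
  if (p$cold) {
    A2 <- y[7, ]; C2 <- y[8, ]
    bind2 <- p$kon_cold * (A2 / p$eps) * R - p$koff_cold * C2
    intern2 <- p$ke * C2
    out[2, ] <- out[2, ] - bind2 + if (p$receptor_ss) intern2 else 0
    out <- rbind(out, -bind2, bind2 - intern2)
  }
  out
}

#' Pre-dose initial state
#'
#' All agent species zero; the free receptor at the full receptor
#' concentration; the free target at its synthesis/turnover steady state.
#'
#' @param tissue,target Spec objects.
#' @param grid A `radial_grid`.
#' @param cold Logical; include the two cold-competitor fields.
#' @return Matrix `n_species x n_shells` with rownames from the species set.
#' @export
initial_state <- function(tissue, target, grid, cold = FALSE) {
  nm <- .species_names(cold)
  n <- grid$n_shells
  y <- matrix(0, nrow = length(nm), ncol = n, dimnames = list(nm, NULL))
  y["R_free", ] <- receptors_to_molar(tissue$receptors_per_cell,
                                      tissue$cell_density)
  y["T_free", ] <- copies_to_molar(target$copies_per_cell,
                                   target$cytosol_volume_per_cell)
  y
}
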