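#' Fractional inhibition field
#'
#' `1 - T_free(r, t) / T0`, clipped to `[0, 1]`.  In catalytic mode
#' inactivated target has left the system, so depletion by turnover counts as
#' inhibition, matching the functional equivalence of blocking and
#' degradation.
#'
#' @param traj A `trajectory`.
#' @return Matrix `n_shells x n_times` of inhibition fractions.
#' @export
inhibition_field <- function(traj) {
  T0 <- traj$params$T0
  if (T0 <= 0) stop("inhibition is undefined for a zero baseline target")
  inh <- 1 - species_field(traj, "T_free") / T0
  inh[inh < 0] <- 0
  inh[inh > 1] <- 1
  inh
}

#' Maximum inhibition
#'
#' Largest volume-averaged inhibition at any single time point.
#'
#' @param traj A `trajectory`.
#' @return Fraction in `[0, 1]`.
#' @export
max_inhibition <- function(traj) {
  if (length(traj$times) < 2) stop("need at least two time points")
  max(volume_average(inhibition_field(traj), traj$grid))
}

#' Inhibitory effect (time-integrated inhibition)
#'
#' Trapezoidal time integral of the volume-averaged inhibition over the
#' simulated interval; units of fraction-hours, bounded by `t_end`.
#'
#' @param traj A `trajectory`.
#' @return Fraction-hours.
#' @export
inhibitory_effect <- function(traj) {
  avg <- volume_average(inhibition_field(traj), traj$grid)
  t <- traj$times
  sum(diff(t) * (avg[-1] + avg[-length(avg)]) / 2)
}

#' Time of maximal delivery
#'
#' The time at which the volume-averaged free cytosolic target is lowest.
#' If the target never drops measurably below baseline (e.g. a zero dose),
#' delivery never happened and `NA` is returned.
#'
#' @param traj A `trajectory`.
#' @param tol Minimum relative depression of the target required to call a
#'   delivery event (default 1e-9).
#' @return Hours, or `NA_real_` for the degenerate no-delivery case.
#' @export
time_of_max_delivery <- function(traj, tol = 1e-9) {
  avg <- volume_average(species_field(traj, "T_free"), traj$grid)
  T0 <- traj$params$T0
  if (min(avg) > T0 * (1 - tol)) return(NA_real_)
  traj$times[which.min(avg)]
}

#' Penetration depth of the delivered agent
#'
#' Smallest depth from the capillary wall such that the shells within it hold
#' at least `mass_fraction` of all tissue-associated agent (interstitial +
#' surface-bound + cytosolic pools, annular volume weighting) at time `t`.
#'
#' @param traj A `trajectory`.
#' @param mass_fraction Fraction in (0, 1); default 0.5.
#' @param t Hours; defaults to the time of maximal delivery.
#' @return Depth in micrometres, or `NA_real_` if no agent is in the tissue.
#' @export
penetration_depth <- function(traj, mass_fraction = 0.5, t = NULL) {
  if (mass_fraction <= 0 || mass_fraction > 1) {
    stop("mass_fraction must lie in (0, 1]")
  }
  if (is.null(t)) t <- time_of_max_delivery(traj)
  if (is.na(t)) return(NA_real_)
  it <- which.min(abs(traj$times - t))
  m <- tissue_agent(traj)[, it] * traj$grid$volumes
  total <- sum(m)
  if (total <= 0) return(NA_real_)
  cum <- cumsum(m) / total
  k <- which(cum >= mass_fraction - 1e-12)[1]
  traj$grid$edges[k + 1] - traj$grid$capillary_radius
}

#' Full outcome report
#'
#' @param traj A `trajectory`.
#' @return Object of class `outcome_report`: the inhibition field plus the
#'   scalar metrics.
#' @export
outcome_report <- function(traj) {
  structure(
    list(
      inhibition = inhibition_field(traj),
      times = traj$times,
      radii = traj$grid$centers,
      max_inhibition = max_inhibition(traj),
      inhibitory_effect = inhibitory_effect(traj),
      t_max_delivery = time_of_max_delivery(traj),
      penetration_depth_50 = penetration_depth(traj)
    ),
    class = "outcome_report"
  )
}

#' @export
print.outcome_report <- function(x, ...) {
  cat("<outcome_report>\n")
  cat(sprintf("  max inhibition      : %.1f %%\n", 100 * x$max_inhibition))
  cat(sprintf("  inhibitory effect   : %.2f fraction-hours\n", x$inhibitory_effect))
  cat(sprintf("  time of max delivery: %s h\n",
              if (is.na(x$t_max_delivery)) "NA" else format(x$t_max_delivery)))
  cat(sprintf("  50%% penetration     : %s um\n",
              if (is.na(x$penetration_depth_50)) "NA"
              else format(x$penetration_depth_50)))
  invisible(x)
}
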