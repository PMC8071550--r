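#' Dose regimen: timed plasma boluses
#'
#' Plasma pharmacokinetics follow a one-compartment mono-exponential model;
#' each bolus instantly raises the plasma concentration by its peak and decays
#' with the species' half-life.  Doses superpose.  Plasma is a forcing
#' function: tissue uptake does not deplete it.
#'
#' @param times Hours of each dose.
#' @param peaks Peak plasma concentration added by each dose, molar.
#' @param species `"warm"` or `"cold"` per dose.
#' @param half_life_warm,half_life_cold Plasma half-lives, hours.  The cold
#'   competitor by convention shares the warm species' plasma profile, so
#'   `half_life_cold` defaults to `half_life_warm`.
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(times, peaks, species = "warm",
                         half_life_warm, half_life_cold = half_life_warm) {
  stopifnot(length(times) == length(peaks), all(times >= 0), all(peaks >= 0),
            half_life_warm > 0, half_life_cold > 0)
  species <- rep_len(species, length(times))
  if (!all(species %in% c("warm", "cold"))) stop("species must be 'warm' or 'cold'")
  ord <- order(times)
  structure(
    list(
      times = as.numeric(times)[ord],
      peaks = as.numeric(peaks)[ord],
      species = species[ord],
      half_life = c(warm = half_life_warm, cold = half_life_cold)
    ),
    class = "dose_regimen"
  )
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("<dose_regimen> %d dose(s), t1/2 warm %g h\n",
              length(x$times), x$half_life[["warm"]]))
  for (i in seq_along(x$times)) {
    cat(sprintf("  t = %6.2f h  %-4s  peak %.3g M\n",
                x$times[i], x$species[i], x$peaks[i]))
  }
  invisible(x)
}

#' Build a single or repeated dosing regimen
#'
#' @param pattern `"single"` or `"repeated"`.
#' @param peak Peak plasma concentration per dose, molar.
#' @param half_life Plasma half-life of the warm agent, hours.
#' @param interval Hours between repeated doses.
#' @param n_doses Number of warm doses (`>= 1`).
#' @param cold_offset If not `NULL`, one cold dose accompanies each warm dose
#'   at `time + cold_offset` hours, with `cold_peak` molar peak.
#' @param cold_peak Peak of each cold dose (default: same as warm, a 1:1
#'   warm:cold peak ratio).
#' @return A [dose_regimen()].
#' @examples
#' # twice-daily binder dosing to 1 uM over a week:
#' make_regimen("repeated", peak = 1e-6, half_life = 2.55,
#'              interval = 12, n_doses = 14)
#' @export
make_regimen <- function(pattern = c("single", "repeated"), peak,
                         half_life, interval = NULL, n_doses = 1,
                         cold_offset = NULL, cold_peak = peak) {
  pattern <- match.arg(pattern)
  if (n_doses < 1) stop("n_doses must be >= 1")
  if (pattern == "single") {
    times <- 0
  } else {
    if (is.null(interval) || interval <= 0) stop("repeated pattern needs interval > 0")
    times <- (seq_len(n_doses) - 1) * interval
  }
  peaks <- rep(peak, length(times))
  species <- rep("warm", length(times))
  if (!is.null(cold_offset)) {
    times <- c(times, times + cold_offset)
    peaks <- c(peaks, rep(cold_peak, length(species)))
    species <- c(species, rep("cold", length(species)))
  }
  dose_regimen(times, peaks, species, half_life_warm = half_life)
}

#' Plasma concentration of one species at time t
#'
#' Sum over past doses of `peak * 2^(-(t - t_dose)/t_half)`; zero before the
#' first dose.  Vectorised over `t`.
#'
#' @param regimen A [dose_regimen()].
#' @param species `"warm"` or `"cold"`.
#' @param t Hours.
#' @return Molar plasma concentration(s).
#' @export
plasma_concentration <- function(regimen, species = "warm", t) {
  stopifnot(inherits(regimen, "dose_regimen"))
  keep <- regimen$species == species
  times <- regimen$times[keep]
  peaks <- regimen$peaks[keep]
  th <- regimen$half_life[[species]]
  vapply(t, function(tt) {
    past <- times <= tt
    if (!any(past)) return(0)
    sum(peaks[past] * 2^(-(tt - times[past]) / th))
  }, numeric(1))
}

#' Plasma exposure (AUC) of one species up to t_end
#'
#' Closed-form sum of per-dose exponential integrals truncated at `t_end`:
#' each dose contributes `peak * th/ln2 * (1 - 2^(-(t_end - t_dose)/th))`.
#'
#' @inheritParams plasma_concentration
#' @param t_end Hours; must not precede the species' last dose.
#' @return Exposure in molar-hours.
#' @export
plasma_auc <- function(regimen, species = "warm", t_end) {
  stopifnot(inherits(regimen, "dose_regimen"))
  keep <- regimen$species == species
  times <- regimen$times[keep]
  peaks <- regimen$peaks[keep]
  if (!length(times)) return(0)
  if (t_end < max(times)) stop("t_end must be >= the species' last dose time")
  th <- regimen$half_life[[species]]
  sum(peaks * th / log(2) * (1 - 2^(-(t_end - times) / th)))
}
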