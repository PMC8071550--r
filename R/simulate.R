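#' Simulate delivery in the Krogh cylinder
#'
#' Method-of-lines integration of the full coupled system: the interstitial
#' agent diffuses (and optionally convects) through the annulus and
#' extravasates across the capillary wall against the plasma forcing from the
#' regimen; every shell carries the reaction network of [reaction_terms()].
#' Integration restarts at each dose time, where the plasma concentration is
#' discontinuous.
#'
#' @param agent An [agent_spec()] (the warm, cargo-carrying species).
#' @param tissue A [tissue_spec()].
#' @param target A [target_spec()].
#' @param regimen A [dose_regimen()].
#' @param cold_agent Optional [agent_spec()] for a cold competitor; required
#'   when the regimen contains cold doses.
#' @param n_shells Radial resolution (default 100).
#' @param t_end Hours of simulated time (default 168, one week).
#' @param dt_out Output time step, hours (default 0.25).
#' @param rtol,atol Integrator tolerances (molar).
#' @param outer_boundary `"outflow"` (convective lymphatic sink, the default)
#'   or `"reflective"`.
#' @return An object of class `trajectory`: `times` (hours), `conc` (array
#'   species x shell x time, molar), `grid`, the specs, and solver settings.
#' @export
simulate_delivery <- function(agent, tissue, target, regimen,
                              cold_agent = NULL,
                              n_shells = 100, t_end = 168, dt_out = 0.25,
                              rtol = 1e-8, atol = 1e-12,
                              outer_boundary = c("outflow", "reflective")) {
  stopifnot(inherits(agent, "agent_spec"), inherits(tissue, "tissue_spec"),
            inherits(target, "target_spec"), inherits(regimen, "dose_regimen"),
            t_end > 0)
  outer_boundary <- match.arg(outer_boundary)
  # the agent spec is the single source of truth for the warm plasma
  # half-life; the cold competitor shares the warm plasma profile
  regimen <- dose_regimen(regimen$times, regimen$peaks, regimen$species,
                          half_life_warm = agent$plasma_half_life)
  has_cold_doses <- any(regimen$species == "cold" & regimen$peaks > 0)
  if (has_cold_doses && is.null(cold_agent)) {
    cold_agent <- agent_spec(molecular_weight = 10,
                             kd_receptor = agent$kd_receptor,
                             kon_receptor = agent$kon_receptor,
                             plasma_half_life = regimen$half_life[["cold"]],
                             is_cold = TRUE)
  }
  if (!has_cold_doses) cold_agent <- NULL

  grid <- build_grid(tissue, n_shells)
  p <- .build_params(agent, tissue, target, grid, cold_agent)
  if (outer_boundary == "reflective") p$reflective <- TRUE
  nspec <- p$nspec
  y0 <- initial_state(tissue, target, grid, cold = p$cold)

  times_out <- seq(0, t_end, by = dt_out)
  dose_times <- sort(unique(regimen$times[regimen$times < t_end]))
  breaks <- sort(unique(c(0, dose_times, t_end)))

  rhs <- function(t, y, parms) {
    Y <- matrix(y, nrow = nspec)
    d <- .reaction_rhs(Y, parms)
    cp <- plasma_concentration(regimen, "warm", t)
    fw <- wall_flux(cp, Y[1, 1], parms$P, parms$eps)
    ofl <- !isTRUE(parms$reflective)
    d[1, ] <- d[1, ] + transport_operator(Y[1, ], parms$grid, parms$D, parms$v,
                                          fw, outflow = ofl)
    if (parms$cold) {
      cpc <- plasma_concentration(regimen, "cold", t)
      fc <- wall_flux(cpc, Y[7, 1], parms$P_cold, parms$eps)
      d[7, ] <- d[7, ] + transport_operator(Y[7, ], parms$grid, parms$D_cold,
                                            parms$v, fc, outflow = ofl)
    }
    list(as.numeric(d))
  }

  y <- as.numeric(y0)  # shell-major: all species of shell 1, then shell 2, ...
  conc <- array(NA_real_, dim = c(nspec, n_shells, length(times_out)),
                dimnames = list(.species_names(p$cold), NULL, NULL))
  conc[, , 1] <- y0
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    seg_out <- times_out[times_out > t0 & times_out <= t1]
    seg_times <- sort(unique(c(t0, seg_out, t1)))
    sol <- deSolve::lsoda(
      y = y, times = seg_times, func = rhs, parms = p,
      rtol = rtol, atol = atol,
      jactype = "bandint", bandup = nspec, banddown = nspec,
      maxsteps = 50000
    )
    if (attr(sol, "istate")[1] < 0) {
      stop("stiff integrator failed in segment [", t0, ", ", t1, "] h; ",
           "istate = ", attr(sol, "istate")[1])
    }
    m <- sol[, -1, drop = FALSE]
    if (min(m) < -1e3 * atol - 1e-6 * max(abs(m))) {
      stop("negative concentrations beyond tolerance produced by the solver")
    }
    for (tt in seg_out) {
      conc[, , match(tt, times_out)] <- matrix(m[match(tt, seg_times), ],
                                               nrow = nspec)
    }
    y <- m[nrow(m), ]
  }

  structure(
    list(
      times = times_out,
      conc = conc,
      grid = grid,
      agent = agent, tissue = tissue, target = target, regimen = regimen,
      cold_agent = cold_agent,
      params = p,
      solver = list(n_shells = n_shells, dt_out = dt_out, rtol = rtol,
                    atol = atol, outer_boundary = outer_boundary)
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d species x %d shells x %d times (0-%g h)\n",
    dim(x$conc)[1], dim(x$conc)[2], dim(x$conc)[3], max(x$times)
  ))
  invisible(x)
}

#' Extract one species as a shell x time matrix
#'
#' @param traj A `trajectory`.
#' @param species Species name, e.g. `"T_free"`.
#' @return Matrix `n_shells x n_times`, molar.
#' @export
species_field <- function(traj, species) {
  stopifnot(inherits(traj, "trajectory"))
  if (!species %in% dimnames(traj$conc)[[1]]) {
    stop("unknown species: ", species)
  }
  traj$conc[species, , ]
}

#' Total tissue-associated agent per shell and time
#'
#' Sum of the interstitial, surface-bound and cytosolic agent pools on the
#' whole-tissue basis (cytosolic species are converted with the cytosol
#' volume fraction).  Cold agent is excluded: it carries no cargo.
#'
#' @param traj A `trajectory`.
#' @return Matrix `n_shells x n_times`, molar (whole-tissue basis).
#' @export
tissue_agent <- function(traj) {
  phi <- traj$params$phi
  species_field(traj, "A_int") + species_field(traj, "RC_surf") +
    phi * (species_field(traj, "A_cyt") + species_field(traj, "TC_cyt"))
}

#' Tidy long-format export of a trajectory
#'
#' @param x A `trajectory`.
#' @param row.names,optional Ignored (base generic signature).
#' @param ... Ignored.
#' @return `data.frame` with columns `time_h`, `radius_um`, `species`,
#'   `concentration_M`.
#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  nm <- dimnames(x$conc)[[1]]
  data.frame(
    time_h = rep(x$times, each = length(nm) * x$grid$n_shells),
    radius_um = rep(rep(x$grid$centers, each = length(nm)), length(x$times)),
    species = rep(nm, x$grid$n_shells * length(x$times)),
    concentration_M = as.numeric(x$conc)
  )
}

#' Global agent mass audit
#'
#' Recomputes, by trapezoidal quadrature on the output grid, the cumulative
#' transcapillary influx, convective outflow and degradation of the warm
#' agent, and compares their balance with the agent currently resident in the
#' tissue.  Amounts are per unit capillary length (mol/um scaled by 1e-15 L
#' per um^3; units cancel in the relative residual).
#'
#' @param traj A `trajectory`.
#' @return List with `influx`, `outflow`, `degraded`, `resident` and the
#'   relative residual `|influx - outflow - degraded - resident| / influx`.
#' @export
mass_audit <- function(traj) {
  p <- traj$params
  g <- traj$grid
  times <- traj$times
  A <- species_field(traj, "A_int")
  C <- species_field(traj, "RC_surf")
  Ac <- species_field(traj, "A_cyt")
  B <- species_field(traj, "TC_cyt")
  cp <- plasma_concentration(traj$regimen, "warm", times)
  wall_area <- 2 * pi * g$capillary_radius
  influx_rate <- wall_area * p$P * (cp - A[1, ] / p$eps)
  out_rate <- if (p$v > 0 && !isTRUE(p$reflective)) {
    2 * pi * p$v * g$capillary_radius * A[g$n_shells, ]
  } else {
    rep(0, length(times))
  }
  # degradation: endolysosomal loss of internalized agent + decay of the free
  # cytosolic agent (target-complexed agent is protected)
  vol <- g$volumes
  deg_rate <- as.numeric(
    crossprod(vol, (1 - p$fesc) * p$ke * C + p$phi * p$kdeg_a * Ac)
  )
  trapz <- function(y) sum(diff(times) * (y[-1] + y[-length(y)]) / 2)
  influx <- trapz(influx_rate)
  outflow <- trapz(out_rate)
  degraded <- trapz(deg_rate)
  resident <- as.numeric(crossprod(vol, A[, ncol(A)] + C[, ncol(C)] +
                                     p$phi * (Ac[, ncol(Ac)] + B[, ncol(B)])))
  resident0 <- as.numeric(crossprod(vol, A[, 1] + C[, 1] +
                                      p$phi * (Ac[, 1] + B[, 1])))
  residual <- abs(influx - outflow - degraded - (resident - resident0))
  list(
    influx = influx, outflow = outflow, degraded = degraded,
    resident = resident - resident0,
    relative_residual = if (influx > 0) residual / influx else residual
  )
}
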