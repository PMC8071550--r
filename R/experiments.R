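#' Bundle a complete simulation scenario
#'
#' @param agent,tissue,target,regimen Spec objects.
#' @param n_shells,t_end,dt_out Solver settings passed to
#'   [simulate_delivery()].
#' @param cold_agent Optional cold competitor.
#' @return Object of class `scenario`.
#' @export
scenario <- function(agent, tissue, target, regimen,
                     n_shells = 100, t_end = 72, dt_out = 0.25,
                     cold_agent = NULL) {
  structure(
    list(agent = agent, tissue = tissue, target = target, regimen = regimen,
         n_shells = n_shells, t_end = t_end, dt_out = dt_out,
         cold_agent = cold_agent),
    class = "scenario"
  )
}

#' Run the simulation of a scenario
#'
#' @param sc A [scenario()].
#' @param cache Optional environment used to memoise simulations by parameter
#'   fingerprint; pass the same environment across calls to reuse results.
#' @return A `trajectory`.
#' @export
run_scenario <- function(sc, cache = NULL) {
  stopifnot(inherits(sc, "scenario"))
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(deparse(sc, control = c("all", "digits17")), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  traj <- simulate_delivery(
    sc$agent, sc$tissue, sc$target, sc$regimen,
    cold_agent = sc$cold_agent,
    n_shells = sc$n_shells, t_end = sc$t_end, dt_out = sc$dt_out
  )
  if (!is.null(cache)) cache[[key]] <- traj
  traj
}

# set a field addressed by a dotted path, e.g. "agent.kd_receptor"
.set_by_path <- function(sc, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("parameter path must be '<component>.<field>'")
  comp <- parts[1]; field <- parts[2]
  if (!comp %in% names(sc)) stop("unknown scenario component: ", comp)
  if (!field %in% names(sc[[comp]])) {
    stop("unknown field '", field, "' in scenario component '", comp, "'")
  }
  sc[[comp]][[field]] <- value
  sc
}

.metric_fun <- function(metric) {
  switch(metric,
    max_inhibition = max_inhibition,
    inhibitory_effect = inhibitory_effect,
    time_of_max_delivery = time_of_max_delivery,
    min_free_target = function(traj) {
      min(volume_average(species_field(traj, "T_free"), traj$grid))
    },
    stop("unknown metric: ", metric)
  )
}

#' Parameter sweep over a scenario
#'
#' One full simulation per grid value; a failed simulation is reported with
#' its parameter value and the sweep continues.
#'
#' @param sc A [scenario()].
#' @param param Dotted parameter path, e.g. `"agent.kd_receptor"`.
#' @param values Numeric grid (log-spaced for affinities by convention).
#' @param metric One of `"max_inhibition"`, `"inhibitory_effect"`,
#'   `"time_of_max_delivery"`, `"min_free_target"`.
#' @param cache Optional memoisation environment (see [run_scenario()]).
#' @return `data.frame` with columns `value`, `metric` (NA where a
#'   simulation failed).
#' @export
run_sweep <- function(sc, param, values, metric = "max_inhibition",
                      cache = NULL) {
  if (length(values) < 1) stop("need at least one sweep value")
  f <- .metric_fun(metric)
  out <- vapply(values, function(v) {
    sci <- .set_by_path(sc, param, v)
    # solver chatter from a failing point is folded into the failure report
    tryCatch(suppressWarnings(f(run_scenario(sci, cache))),
             error = function(e) {
               warning("simulation failed at ", param, " = ", format(v), ": ",
                       conditionMessage(e))
               NA_real_
             })
  }, numeric(1))
  data.frame(value = values, metric = out)
}

#' Optimal receptor affinity for a scenario
#'
#' Coarse log-spaced Kd scan followed by golden-section refinement on
#' log10(Kd).  The default objective is maximal delivery: the Kd minimising
#' the minimum-over-time volume-averaged free target.  Alternatively the
#' time-integrated inhibitory effect can be maximised.
#'
#' @param sc A [scenario()].
#' @param kd_bounds Length-2 molar bounds, spanning at least 4 orders of
#'   magnitude.
#' @param objective `"delivery"` (default) or `"inhibitory_effect"`.
#' @param n_coarse Points in the coarse scan (default 13).
#' @param tol_log10 Width of the final golden-section bracket in log10 Kd
#'   (default 0.02).
#' @param cache Optional memoisation environment.
#' @return List with `kd_opt` (molar), `objective_value`, `on_boundary`
#'   (flag: the coarse optimum sat on a bound), and the coarse scan table.
#' @export
optimal_affinity <- function(sc, kd_bounds = c(1e-12, 1e-5),
                             objective = c("delivery", "inhibitory_effect"),
                             n_coarse = 13, tol_log10 = 0.02, cache = NULL) {
  objective <- match.arg(objective)
  stopifnot(length(kd_bounds) == 2, all(kd_bounds > 0))
  lb <- log10(min(kd_bounds)); ub <- log10(max(kd_bounds))
  if (ub - lb < 4) stop("kd_bounds must span at least 4 orders of magnitude")
  # maximise `score`
  score <- if (objective == "delivery") {
    f <- .metric_fun("min_free_target")
    function(traj) -f(traj)
  } else {
    inhibitory_effect
  }
  eval_log_kd <- function(lk) {
    sci <- .set_by_path(sc, "agent.kd_receptor", 10^lk)
    score(run_scenario(sci, cache))
  }
  grid_lk <- seq(lb, ub, length.out = n_coarse)
  coarse <- vapply(grid_lk, eval_log_kd, numeric(1))
  if (max(coarse) - min(coarse) < 1e-12 * max(abs(coarse), 1e-300)) {
    warning("objective surface is flat; optimum is degenerate")
    return(list(kd_opt = NA_real_, objective_value = NA_real_,
                on_boundary = TRUE, degenerate = TRUE,
                coarse = data.frame(kd = 10^grid_lk, score = coarse)))
  }
  i <- which.max(coarse)
  on_boundary <- i == 1 || i == n_coarse
  a <- grid_lk[max(1, i - 1)]; b <- grid_lk[min(n_coarse, i + 1)]
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- eval_log_kd(x1); f2 <- eval_log_kd(x2)
  while (b - a > tol_log10) {
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- eval_log_kd(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- eval_log_kd(x2)
    }
  }
  lk_opt <- (a + b) / 2
  list(
    kd_opt = 10^lk_opt,
    objective_value = eval_log_kd(lk_opt),
    on_boundary = on_boundary,
    degenerate = FALSE,
    coarse = data.frame(kd = 10^grid_lk, score = coarse)
  )
}

#' Affinity x receptor-density map of maximum inhibition
#'
#' For one internalization rate, simulates every (receptor density, Kd) pair
#' and reports the matrix of maximum inhibition together with the per-density
#' optimal Kd trace under the delivery objective.
#'
#' @param sc A [scenario()] providing the fixed backdrop.
#' @param k_internalize Internalization rate, 1/min (e.g. EGFR 0.08,
#'   HER2 0.01, EpCAM 0.002).
#' @param receptor_density_grid Receptors/cell (log-spaced).
#' @param kd_grid Molar Kd values (log-spaced).
#' @param convection Logical; overrides the scenario tissue's fluid velocity
#'   with the convection default (0.1 um/s) or 0.
#' @param cache Optional memoisation environment.
#' @return List with `max_inhibition` (matrix densities x kds),
#'   `min_free_target` (same shape) and `optimal_kd` (per density, by the
#'   delivery objective on the grid).
#' @export
affinity_density_heatmap <- function(sc, k_internalize,
                                     receptor_density_grid, kd_grid,
                                     convection = FALSE, cache = NULL) {
  sc$tissue$k_internalize <- k_internalize
  sc$tissue$fluid_velocity_at_wall <- if (convection) 0.1 else 0
  nd <- length(receptor_density_grid); nk <- length(kd_grid)
  mi <- matrix(NA_real_, nd, nk,
               dimnames = list(format(receptor_density_grid, digits = 3),
                               format(kd_grid, digits = 3)))
  mft <- mi
  fmin <- .metric_fun("min_free_target")
  for (i in seq_len(nd)) {
    sci <- sc
    sci$tissue$receptors_per_cell <- receptor_density_grid[i]
    for (j in seq_len(nk)) {
      scij <- .set_by_path(sci, "agent.kd_receptor", kd_grid[j])
      traj <- tryCatch(run_scenario(scij, cache), error = function(e) NULL)
      if (!is.null(traj)) {
        mi[i, j] <- max_inhibition(traj)
        mft[i, j] <- fmin(traj)
      }
    }
  }
  list(
    max_inhibition = mi,
    min_free_target = mft,
    optimal_kd = kd_grid[apply(mft, 1, which.min)],
    receptor_density_grid = receptor_density_grid,
    kd_grid = kd_grid
  )
}

#' Side-by-side comparison of delivery strategies
#'
#' Runs the same scenario under the baseline agent, the affinity-optimised
#' agent, cold co-dosing, a 100x cytosolic half-life, and a catalytic cargo,
#' and tabulates the outcome metrics with plasma exposure.
#'
#' @param sc A [scenario()] (the baseline).
#' @param strategies Subset of `c("baseline", "optimal_kd", "cold_dose",
#'   "cyto_t100", "catalytic")`.
#' @param kd_opt Optional precomputed optimal Kd (molar); computed via
#'   [optimal_affinity()] when needed and missing.
#' @param k_cat Catalytic rate for the catalytic arm, 1/min (default 2.35).
#' @param cache Optional memoisation environment.
#' @return `data.frame` with one row per strategy: `inhibitory_effect`,
#'   `max_inhibition`, `plasma_auc`.
#' @export
compare_strategies <- function(sc,
                               strategies = c("baseline", "optimal_kd",
                                              "cold_dose", "cyto_t100",
                                              "catalytic"),
                               kd_opt = NULL, k_cat = 2.35, cache = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if ("optimal_kd" %in% strategies && is.null(kd_opt)) {
    kd_opt <- optimal_affinity(sc, cache = cache)$kd_opt
  }
  variant <- function(strategy) {
    sci <- sc
    if (strategy == "optimal_kd") {
      sci$agent$kd_receptor <- kd_opt
    } else if (strategy == "cold_dose") {
      r <- sci$regimen
      warm <- r$species == "warm"
      sci$regimen <- dose_regimen(
        c(r$times, r$times[warm]), c(r$peaks, r$peaks[warm]),
        c(r$species, rep("cold", sum(warm))),
        half_life_warm = r$half_life[["warm"]]
      )
    } else if (strategy == "cyto_t100") {
      sci$agent$cytosolic_half_life <- 100 * sci$agent$cytosolic_half_life
    } else if (strategy == "catalytic") {
      sci$agent$mode <- "catalytic"
      sci$agent$k_cat <- k_cat
    }
    sci
  }
  rows <- lapply(strategies, function(s) {
    sci <- variant(s)
    traj <- run_scenario(sci, cache)
    data.frame(
      strategy = s,
      inhibitory_effect = inhibitory_effect(traj),
      max_inhibition = max_inhibition(traj),
      plasma_auc = plasma_auc(sci$regimen, "warm", sc$t_end) +
        plasma_auc(sci$regimen, "cold", sc$t_end)
    )
  })
  do.call(rbind, rows)
}
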