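# Config files are YAML with unit-suffixed keys; each suffixed key maps onto
# one field of the corresponding spec constructor, which performs the
# physical validation (positivity, ranges, geometry).

.agent_keys <- c(
  molecular_weight_kda = "molecular_weight",
  kd_receptor_m = "kd_receptor",
  kon_receptor_per_m_s = "kon_receptor",
  plasma_half_life_h = "plasma_half_life",
  cytosolic_half_life_h = "cytosolic_half_life",
  mode = "mode",
  k_cat_per_min = "k_cat",
  kd_target_m = "kd_target",
  kon_target_per_m_s = "kon_target",
  escape_fraction = "escape_fraction",
  is_cold = "is_cold"
)

.tissue_keys <- c(
  capillary_radius_um = "capillary_radius",
  krogh_radius_um = "krogh_radius",
  void_fraction = "void_fraction",
  vascular_permeability_cm_s = "vascular_permeability",
  interstitial_diffusivity_cm2_s = "interstitial_diffusivity",
  reference_mw_kda = "reference_mw",
  fluid_velocity_um_s = "fluid_velocity_at_wall",
  cell_density_per_ml = "cell_density",
  receptors_per_cell = "receptors_per_cell",
  k_internalize_per_min = "k_internalize",
  receptor_steady_state = "receptor_steady_state"
)

.target_keys <- c(
  copies_per_cell = "copies_per_cell",
  cytosol_volume_per_cell_pl = "cytosol_volume_per_cell",
  target_half_life_h = "target_half_life"
)

.regimen_keys <- c(
  pattern = "pattern",
  peak_m = "peak",
  interval_h = "interval",
  n_doses = "n_doses",
  cold_offset_h = "cold_offset",
  cold_peak_m = "cold_peak"
)

.simulation_keys <- c(
  n_shells = "n_shells",
  t_end_h = "t_end",
  dt_out_h = "dt_out"
)

.map_section <- function(section, keymap, where) {
  if (is.null(section)) return(list())
  unknown <- setdiff(names(section), names(keymap))
  if (length(unknown)) {
    stop("unknown or mis-suffixed key(s) in '", where, "': ",
         paste0(where, ".", unknown, collapse = ", "))
  }
  out <- section
  names(out) <- keymap[names(section)]
  out
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario with unit-suffixed keys (`plasma_half_life_h`,
#' `vascular_permeability_cm_s`, ...), rejects unknown keys with their key
#' path, fills missing fields from the constructor defaults, and returns a
#' ready-to-run [scenario()].
#'
#' @param path Path to a YAML file, or the name of a bundled preset (see
#'   [preset_names()]).
#' @return A [scenario()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    bundled <- system.file("extdata", "presets", paste0(path, ".yaml"),
                           package = "cytodeliver")
    if (nzchar(bundled)) path <- bundled
  }
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known_sections <- c("agent", "tissue", "target", "regimen", "simulation",
                      "cold_agent")
  unknown <- setdiff(names(cfg), known_sections)
  if (length(unknown)) {
    stop("unknown top-level section(s): ", paste(unknown, collapse = ", "))
  }
  agent <- do.call(agent_spec, .map_section(cfg$agent, .agent_keys, "agent"))
  tissue <- do.call(tissue_spec, .map_section(cfg$tissue, .tissue_keys, "tissue"))
  target <- do.call(target_spec, .map_section(cfg$target, .target_keys, "target"))
  rargs <- .map_section(cfg$regimen, .regimen_keys, "regimen")
  rargs$half_life <- agent$plasma_half_life
  regimen <- do.call(make_regimen, rargs)
  cold_agent <- if (!is.null(cfg$cold_agent)) {
    do.call(agent_spec, .map_section(cfg$cold_agent, .agent_keys, "cold_agent"))
  }
  sargs <- .map_section(cfg$simulation, .simulation_keys, "simulation")
  do.call(scenario, c(
    list(agent = agent, tissue = tissue, target = target, regimen = regimen,
         cold_agent = cold_agent),
    sargs
  ))
}

#' Serialise a scenario back to the canonical config form
#'
#' Inverse of [load_config()] up to default-filling: every field of every
#' spec is written with its unit-suffixed key, so
#' `dump_config(load_config(f))` is the canonical form of `f` and loading it
#' again reproduces the same scenario.
#'
#' @param sc A [scenario()].
#' @param path Optional file to write; when `NULL` the YAML text is returned.
#' @return The YAML text, invisibly when written to a file.
#' @export
dump_config <- function(sc, path = NULL) {
  stopifnot(inherits(sc, "scenario"))
  invert <- function(x, keymap) {
    out <- unclass(x)[keymap]
    names(out) <- names(keymap)
    out[!vapply(out, is.null, logical(1))]
  }
  r <- sc$regimen
  warm <- r$species == "warm"
  n_warm <- sum(warm)
  reg <- list(
    pattern = if (n_warm > 1) "repeated" else "single",
    peak_m = r$peaks[warm][1],
    n_doses = n_warm
  )
  if (n_warm > 1) reg$interval_h <- diff(r$times[warm][1:2])
  if (any(!warm)) {
    reg$cold_offset_h <- r$times[!warm][1] - r$times[warm][1]
    reg$cold_peak_m <- r$peaks[!warm][1]
  }
  cfg <- list(
    agent = invert(sc$agent, .agent_keys),
    tissue = invert(sc$tissue, .tissue_keys),
    target = invert(sc$target, .target_keys),
    regimen = reg,
    simulation = list(n_shells = sc$n_shells, t_end_h = sc$t_end,
                      dt_out_h = sc$dt_out)
  )
  if (!is.null(sc$cold_agent)) {
    cfg$cold_agent <- invert(sc$cold_agent, .agent_keys)
  }
  txt <- yaml::as.yaml(cfg)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Names of the bundled presets
#'
#' @return Character vector of preset names usable with [load_config()].
#' @export
preset_names <- function() {
  files <- list.files(system.file("extdata", "presets", package = "cytodeliver"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' Run manifest for reproducible provenance
#'
#' @param sc A [scenario()].
#' @return List with the resolved parameter tree (canonical config text),
#'   package version, a config fingerprint and a timestamp.  Re-running from
#'   the embedded config reproduces outputs (the model is deterministic).
#' @export
run_manifest <- function(sc) {
  txt <- dump_config(sc)
  list(
    config = txt,
    config_fingerprint = sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 997 + 1)),
    package_version = as.character(utils::packageVersion("cytodeliver")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}
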