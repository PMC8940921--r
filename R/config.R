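## Declarative configuration: nested key-value (YAML) with strict schema
## validation. All defaults are the package's calibrated study conditions.

#' Default configuration
#'
#' Nested list of every tunable parameter, in the package's documented units
#' (days, uM, mm, ul, cells ml^-1; diffusivities m^2 s^-1).
#'
#' @return Named nested list.
#' @export
defaultConfig <- function() {
  list(
    medium = list(d_doc = 6.7e-10, d_nitrate = 1.7e-9,
                  bulk_doc = 0, bulk_nitrate = 882),
    wall = list(thickness_mm = 0.9, area_mm2 = 10, porosity_factor = 0.5),
    reservoir = list(nitrate = 882, doc = 10, volume_ml = 25, fixed = TRUE),
    alga = list(n0 = 1e6, mu_max = 1.0, km_n = 2, q_exu = 60, u_max = 60,
                km_uptake = 2),
    plate = list(preset = "community_layers", volume_ul = NA, days = 7,
                 dt_out = 0.25),
    community = list(n_replicates = 3, geo_sd = 1.3,
                     sequencing_depth = 1e5, overdispersion = 0.2)
  )
}

.validateConfig <- function(cfg, ref = defaultConfig(), path = "") {
  for (key in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(ref)) {
      stop("unknown configuration key: ", full)
    }
    if (is.list(ref[[key]]) && !is.null(cfg[[key]])) {
      if (!is.list(cfg[[key]])) stop(full, " must be a section")
      .validateConfig(cfg[[key]], ref[[key]], full)
    }
  }
  invisible(TRUE)
}

.mergeConfig <- function(user, ref) {
  for (key in names(user)) {
    ref[[key]] <- if (is.list(ref[[key]]) && is.list(user[[key]])) {
      .mergeConfig(user[[key]], ref[[key]])
    } else user[[key]]
  }
  ref
}

#' Load and validate a configuration file
#'
#' Reads a YAML file, rejects unknown keys (naming the offending key),
#' merges over the documented defaults, and enforces physical bounds
#' (the wall porosity factor cannot exceed 1, i.e. effective diffusivity
#' cannot exceed free solution).
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return Validated configuration list.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    .validateConfig(user)
    cfg <- .mergeConfig(user, cfg)
  }
  if (cfg$wall$porosity_factor <= 0 || cfg$wall$porosity_factor > 1) {
    stop("wall.porosity_factor must be in (0, 1]: effective diffusivity ",
         "cannot exceed the free-solution value")
  }
  if (cfg$medium$d_doc <= 0 || cfg$medium$d_nitrate <= 0) {
    stop("medium diffusivities must be > 0 (m^2 s^-1)")
  }
  cfg
}

#' Save a configuration to YAML
#'
#' \code{loadConfig(saveConfig(cfg, path))} reproduces \code{cfg}.
#'
#' @param cfg Configuration list.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
saveConfig <- function(cfg, path) {
  .validateConfig(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## Materialise S4 parameter objects from a configuration.
.configMedium <- function(cfg) {
  mediumParams(d_doc = cfg$medium$d_doc, d_nitrate = cfg$medium$d_nitrate,
               bulk_doc = cfg$medium$bulk_doc,
               bulk_nitrate = cfg$medium$bulk_nitrate)
}

.configWall <- function(cfg) {
  wallParams(thickness_mm = cfg$wall$thickness_mm,
             area_mm2 = cfg$wall$area_mm2,
             d_eff_doc = cfg$wall$porosity_factor * cfg$medium$d_doc,
             d_eff_nitrate = cfg$wall$porosity_factor * cfg$medium$d_nitrate)
}

.configAlga <- function(cfg) {
  algalPopulation(n0 = cfg$alga$n0, mu_max = cfg$alga$mu_max,
                  km_n = cfg$alga$km_n, q_exu = cfg$alga$q_exu,
                  u_max = cfg$alga$u_max, km_uptake = cfg$alga$km_uptake)
}

.configLayout <- function(cfg, preset = cfg$plate$preset,
                          center_role = "alga") {
  vol <- cfg$plate$volume_ul
  if (!is.null(vol) && is.na(vol)) vol <- NULL # NA = preset default
  buildLayout(preset, wall = .configWall(cfg),
              reservoir = cfg$reservoir,
              volume_ul = vol,
              center_role = center_role)
}
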