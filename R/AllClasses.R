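#' @import methods
NULL

## ---------------------------------------------------------------------------
## Phycosphere-scale classes
## ---------------------------------------------------------------------------

#' CellParams: per-species phytoplankton source/sink parameters
#'
#' Holds the radius, dissolved organic carbon (DOC) exudation rate and
#' nitrate uptake kinetics of a single phytoplankton cell, per growth phase.
#'
#' @slot species_name Character label.
#' @slot radius_um Cell radius in micrometres.
#' @slot q_exu DOC exudation rate, fmol C cell^-1 d^-1.
#' @slot u_max Maximal nitrate uptake rate, fmol N cell^-1 d^-1.
#' @slot km_uptake Half-saturation concentration of nitrate uptake, uM.
#' @slot growth_phase Either \code{"exponential"} or \code{"stationary"}.
#'
#' @exportClass CellParams
setClass("CellParams",
  representation(
    species_name = "character",
    radius_um = "numeric",
    q_exu = "numeric",
    u_max = "numeric",
    km_uptake = "numeric",
    growth_phase = "character"
  ),
  prototype(growth_phase = "exponential")
)

setValidity("CellParams", function(object) {
  msg <- character()
  if (length(object@radius_um) != 1 || !is.finite(object@radius_um) ||
      object@radius_um <= 0) {
    msg <- c(msg, "radius_um must be a single positive number")
  }
  if (object@q_exu < 0) msg <- c(msg, "q_exu must be >= 0")
  if (object@u_max < 0) msg <- c(msg, "u_max must be >= 0")
  if (object@km_uptake <= 0) msg <- c(msg, "km_uptake must be > 0")
  if (!object@growth_phase %in% c("exponential", "stationary")) {
    msg <- c(msg, "growth_phase must be 'exponential' or 'stationary'")
  }
  if (length(msg)) msg else TRUE
})

#' MediumParams: solute diffusivities and bulk concentrations
#'
#' @slot d_doc Free-solution diffusivity of the DOC proxy, m^2 s^-1.
#' @slot d_nitrate Free-solution diffusivity of nitrate, m^2 s^-1.
#' @slot bulk_doc Far-field labile DOC concentration, uM C.
#' @slot bulk_nitrate Far-field nitrate concentration, uM.
#'
#' @exportClass MediumParams
setClass("MediumParams",
  representation(
    d_doc = "numeric",
    d_nitrate = "numeric",
    bulk_doc = "numeric",
    bulk_nitrate = "numeric"
  ),
  prototype(d_doc = 6.7e-10, d_nitrate = 1.7e-9, bulk_doc = 0,
            bulk_nitrate = 882)
)

setValidity("MediumParams", function(object) {
  msg <- character()
  if (object@d_doc <= 0 || object@d_nitrate <= 0) {
    msg <- c(msg, "diffusivities must be > 0")
  }
  if (object@bulk_doc < 0 || object@bulk_nitrate < 0) {
    msg <- c(msg, "bulk concentrations must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' RadialProfile: a concentration profile around a cell
#'
#' @slot r_um Distances from the cell centre (um), strictly increasing;
#'   dimensionless in [0, 1] after normalisation.
#' @slot conc Concentration at each distance (uM; dimensionless after
#'   normalisation).
#' @slot solute Either \code{"DOC"} or \code{"nitrate"}.
#' @slot normalized Logical; TRUE after \code{normalizeProfile}.
#'
#' @exportClass RadialProfile
setClass("RadialProfile",
  representation(
    r_um = "numeric",
    conc = "numeric",
    solute = "character",
    normalized = "logical"
  ),
  prototype(normalized = FALSE)
)

setValidity("RadialProfile", function(object) {
  msg <- character()
  if (length(object@r_um) != length(object@conc)) {
    msg <- c(msg, "r_um and conc must have equal length")
  }
  if (length(object@r_um) > 1 && any(diff(object@r_um) <= 0)) {
    msg <- c(msg, "r_um must be strictly increasing")
  }
  if (any(object@conc < 0)) msg <- c(msg, "conc must be >= 0 everywhere")
  if (!object@solute %in% c("DOC", "nitrate")) {
    msg <- c(msg, "solute must be 'DOC' or 'nitrate'")
  }
  if (isTRUE(object@normalized) && length(object@conc) &&
      max(object@conc) > 0 &&
      (abs(max(object@conc) - 1) > 1e-12 || abs(max(object@r_um) - 1) > 1e-12)) {
    msg <- c(msg, "normalized profile must have max(conc) = 1 and max(r) = 1")
  }
  if (length(msg)) msg else TRUE
})

#' TransportParams: stirring-number ingredients
#'
#' @slot spacing_l Intermolecular spacing, m.
#' @slot swim_speed_v Swimming speed, m s^-1.
#' @slot diffusivity_d Molecular diffusivity, m^2 s^-1.
#'
#' @exportClass TransportParams
setClass("TransportParams",
  representation(
    spacing_l = "numeric",
    swim_speed_v = "numeric",
    diffusivity_d = "numeric"
  )
)

setValidity("TransportParams", function(object) {
  msg <- character()
  if (object@spacing_l <= 0) msg <- c(msg, "spacing_l must be > 0")
  if (object@swim_speed_v < 0) msg <- c(msg, "swim_speed_v must be >= 0")
  if (object@diffusivity_d <= 0) msg <- c(msg, "diffusivity_d must be > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Microplate-scale classes
## ---------------------------------------------------------------------------

#' WallParams: porous-wall transport parameters
#'
#' @slot thickness_mm Wall thickness, mm (0.9 mm in the reference device).
#' @slot area_mm2 Shared cross-section, mm^2.
#' @slot d_eff_doc Effective DOC diffusivity through the copolymer, m^2 s^-1.
#' @slot d_eff_nitrate Effective nitrate diffusivity, m^2 s^-1.
#'
#' @exportClass WallParams
setClass("WallParams",
  representation(
    thickness_mm = "numeric",
    area_mm2 = "numeric",
    d_eff_doc = "numeric",
    d_eff_nitrate = "numeric"
  )
)

setValidity("WallParams", function(object) {
  msg <- character()
  if (object@thickness_mm <= 0) msg <- c(msg, "thickness_mm must be > 0")
  if (object@area_mm2 <= 0) msg <- c(msg, "area_mm2 must be > 0")
  if (object@d_eff_doc <= 0 || object@d_eff_nitrate <= 0) {
    msg <- c(msg, "effective diffusivities must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' PlateLayout: the well graph of a porous microplate
#'
#' Wells are well-mixed compartments; edges are porous walls (between two
#' wells, or between a well and the external medium reservoir, denoted
#' \code{"RESERVOIR"}).
#'
#' @slot wells data.frame with columns id, x_mm, y_mm, distance_mm (from the
#'   centre well), volume_ul, role (one of alga, bacteria, blank,
#'   medium-control).
#' @slot edges data.frame with columns from, to, thickness_mm, area_mm2,
#'   d_eff_doc, d_eff_nitrate.
#' @slot reservoir list with elements nitrate (uM), doc (uM C), volume_ml and
#'   fixed (logical; TRUE = infinite bath held at the stated concentrations).
#' @slot preset Character label of the preset used, or "custom".
#'
#' @exportClass PlateLayout
setClass("PlateLayout",
  representation(
    wells = "data.frame",
    edges = "data.frame",
    reservoir = "list",
    preset = "character"
  )
)

setValidity("PlateLayout", function(object) {
  msg <- character()
  w <- object@wells
  e <- object@edges
  need_w <- c("id", "x_mm", "y_mm", "distance_mm", "volume_ul", "role")
  need_e <- c("from", "to", "thickness_mm", "area_mm2", "d_eff_doc",
              "d_eff_nitrate")
  if (!all(need_w %in% names(w))) {
    msg <- c(msg, paste("wells must have columns:", paste(need_w, collapse = ", ")))
  }
  if (!all(need_e %in% names(e))) {
    msg <- c(msg, paste("edges must have columns:", paste(need_e, collapse = ", ")))
  }
  if (!length(msg)) {
    if (anyDuplicated(w$id)) msg <- c(msg, "well ids must be unique")
    if (any(w$volume_ul <= 0)) msg <- c(msg, "well volumes must be > 0")
    bad <- setdiff(c(e$from, e$to), c(w$id, "RESERVOIR"))
    if (length(bad)) {
      msg <- c(msg, paste("edge endpoints not in layout:", paste(bad, collapse = ", ")))
    }
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    # pairwise distinct positions
    if (nrow(w) > 1) {
      dd <- as.matrix(stats::dist(w[, c("x_mm", "y_mm")]))
      diag(dd) <- Inf
      if (any(dd < 1e-6)) msg <- c(msg, "overlapping wells (identical positions)")
    }
    # connectivity (treating RESERVOIR as a node when present)
    if (nrow(w) > 1) {
      nodes <- unique(c(w$id, if (any(e$to == "RESERVOIR") || any(e$from == "RESERVOIR")) "RESERVOIR"))
      adj <- lapply(stats::setNames(nodes, nodes), function(n) {
        unique(c(e$to[e$from == n], e$from[e$to == n]))
      })
      seen <- nodes[1]
      frontier <- nodes[1]
      while (length(frontier)) {
        nxt <- setdiff(unique(unlist(adj[frontier])), seen)
        seen <- c(seen, nxt)
        frontier <- nxt
      }
      if (!all(w$id %in% seen)) msg <- c(msg, "well graph is disconnected")
    }
    res <- object@reservoir
    if (!all(c("nitrate", "doc", "volume_ml", "fixed") %in% names(res))) {
      msg <- c(msg, "reservoir must have nitrate, doc, volume_ml, fixed")
    }
  }
  if (length(msg)) msg else TRUE
})

#' AlgalPopulation: algal growth and exchange parameters in the plate model
#'
#' @slot n0 Initial density, cells ml^-1.
#' @slot mu_max Maximal specific growth rate, d^-1.
#' @slot km_n Monod half-saturation on nitrate, uM.
#' @slot q_exu Per-cell DOC exudation, fmol C cell^-1 d^-1.
#' @slot u_max Per-cell maximal nitrate uptake, fmol N cell^-1 d^-1.
#' @slot km_uptake Uptake half-saturation, uM.
#'
#' @exportClass AlgalPopulation
setClass("AlgalPopulation",
  representation(
    n0 = "numeric",
    mu_max = "numeric",
    km_n = "numeric",
    q_exu = "numeric",
    u_max = "numeric",
    km_uptake = "numeric"
  )
)

setValidity("AlgalPopulation", function(object) {
  msg <- character()
  if (object@n0 < 0) msg <- c(msg, "n0 must be >= 0")
  if (object@mu_max <= 0) msg <- c(msg, "mu_max must be > 0")
  if (object@km_n <= 0 || object@km_uptake <= 0) {
    msg <- c(msg, "half-saturation constants must be > 0")
  }
  if (object@q_exu < 0 || object@u_max < 0) {
    msg <- c(msg, "per-cell rates must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' WellTimeSeries: simulated plate trajectories
#'
#' Matrices are time (rows) by well (columns); bacterial densities are a
#' named list of such matrices, one per taxon.
#'
#' @slot time Output times, days, strictly increasing.
#' @slot wells Character vector of well ids (column order of the matrices).
#' @slot doc DOC concentration, uM C.
#' @slot nitrate Nitrate concentration, uM.
#' @slot algae Algal density, cells ml^-1.
#' @slot bacteria Named list of matrices, cells ml^-1.
#' @slot layout The PlateLayout that generated the run.
#'
#' @exportClass WellTimeSeries
setClass("WellTimeSeries",
  representation(
    time = "numeric",
    wells = "character",
    doc = "matrix",
    nitrate = "matrix",
    algae = "matrix",
    bacteria = "list",
    layout = "PlateLayout"
  )
)

setValidity("WellTimeSeries", function(object) {
  msg <- character()
  if (length(object@time) > 1 && any(diff(object@time) <= 0)) {
    msg <- c(msg, "time must be strictly increasing")
  }
  for (nm in c("doc", "nitrate", "algae")) {
    m <- slot(object, nm)
    if (nrow(m) != length(object@time) || ncol(m) != length(object@wells)) {
      msg <- c(msg, sprintf("%s must be time x wells", nm))
    }
    if (any(m < -1e-8)) msg <- c(msg, sprintf("%s has negative values", nm))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Community-synthesis classes
## ---------------------------------------------------------------------------

#' TaxonParams: a bacterial taxon's growth strategy
#'
#' Growth is additive over two substitutable resources: the algal DOC proxy
#' and inorganic nitrogen. An exudate specialist has \code{mu_max_n = 0}.
#'
#' @slot name Taxon label.
#' @slot strategy "exudate_specialist" or "generalist".
#' @slot mu_max_doc Maximal growth rate on DOC, d^-1.
#' @slot km_doc Monod constant on DOC, uM C.
#' @slot mu_max_n Maximal growth rate on inorganic N, d^-1 (0 for specialist).
#' @slot km_n Monod constant on nitrate, uM.
#' @slot yield_doc Cells produced per umol DOC consumed.
#' @slot yield_n Cells produced per umol nitrate consumed.
#' @slot mortality First-order mortality, d^-1.
#' @slot initial_density Inoculum, cells ml^-1.
#'
#' @exportClass TaxonParams
setClass("TaxonParams",
  representation(
    name = "character",
    strategy = "character",
    mu_max_doc = "numeric",
    km_doc = "numeric",
    mu_max_n = "numeric",
    km_n = "numeric",
    yield_doc = "numeric",
    yield_n = "numeric",
    mortality = "numeric",
    initial_density = "numeric"
  )
)

setValidity("TaxonParams", function(object) {
  msg <- character()
  rates <- c(object@mu_max_doc, object@mu_max_n, object@mortality)
  if (any(rates < 0)) msg <- c(msg, "rates must be >= 0")
  if (!object@strategy %in% c("exudate_specialist", "generalist")) {
    msg <- c(msg, "strategy must be 'exudate_specialist' or 'generalist'")
  }
  if (object@strategy == "exudate_specialist" && object@mu_max_n != 0) {
    msg <- c(msg, "an exudate specialist must have mu_max_n = 0")
  }
  if (object@km_doc <= 0 || object@km_n <= 0) {
    msg <- c(msg, "Monod constants must be > 0")
  }
  if (object@yield_doc <= 0 || object@yield_n <= 0) {
    msg <- c(msg, "yields must be > 0")
  }
  if (object@initial_density < 0) msg <- c(msg, "initial_density must be >= 0")
  if (length(msg)) msg else TRUE
})

#' AbundanceTable: tidy per-well, per-taxon abundances
#'
#' @slot data data.frame with columns well_id, layer, distance_mm, treatment
#'   (with_alga/control), taxon, density (cells ml^-1), rel_abundance,
#'   replicate, timepoint (days).
#'
#' @exportClass AbundanceTable
setClass("AbundanceTable", representation(data = "data.frame"))

setValidity("AbundanceTable", function(object) {
  msg <- character()
  d <- object@data
  need <- c("well_id", "layer", "distance_mm", "treatment", "taxon",
            "density", "rel_abundance", "replicate", "timepoint")
  if (!all(need %in% names(d))) {
    msg <- c(msg, paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  } else {
    if (any(d$density < 0, na.rm = TRUE)) msg <- c(msg, "densities must be >= 0")
    if (!all(d$treatment %in% c("with_alga", "control"))) {
      msg <- c(msg, "treatment must be 'with_alga' or 'control'")
    }
    has_rel <- !is.na(d$rel_abundance)
    if (any(has_rel)) {
      key <- interaction(d$well_id, d$treatment, d$replicate, d$timepoint,
                         drop = TRUE)
      sums <- tapply(d$rel_abundance[has_rel], key[has_rel], sum)
      # all-zero samples (zero total density, flagged upstream) are allowed
      if (any(abs(sums - 1) > 1e-9 & abs(sums) > 1e-9)) {
        msg <- c(msg, "relative abundances must sum to 1 per sample")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' CytometrySample: flow-cytometry-like counts with calibration beads
#'
#' @slot bead_events Bead event count.
#' @slot cell_events Cell event count.
#' @slot dilution_factor Sample dilution before analysis (>= 1).
#' @slot bead_density Bead density in the analysed mix, beads ml^-1.
#' @slot estimated_density Back-calculated cell density, cells ml^-1 (NA when
#'   bead_events = 0).
#'
#' @exportClass CytometrySample
setClass("CytometrySample",
  representation(
    bead_events = "numeric",
    cell_events = "numeric",
    dilution_factor = "numeric",
    bead_density = "numeric",
    estimated_density = "numeric"
  )
)

setValidity("CytometrySample", function(object) {
  msg <- character()
  if (object@bead_events < 0 || object@cell_events < 0) {
    msg <- c(msg, "event counts must be >= 0")
  }
  if (object@dilution_factor < 1) msg <- c(msg, "dilution_factor must be >= 1")
  if (object@bead_density <= 0) msg <- c(msg, "bead_density must be > 0")
  if (length(msg)) msg else TRUE
})
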