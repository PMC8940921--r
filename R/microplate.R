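## Microplate-scale model: wells are well-mixed compartments coupled by
## Fickian diffusion through porous copolymer walls and (for outer wells)
## to an external medium reservoir. Solved as a stiff ODE system.

#' Construct porous-wall parameters
#'
#' Effective diffusivities default to a porosity/tortuosity factor of 0.5
#' times the free-solution values of the medium (high-water-content
#' nanoporous hydrogel).
#'
#' @param thickness_mm Wall thickness, mm (0.9 in the reference device).
#' @param area_mm2 Shared cross-section, mm^2.
#' @param d_eff_doc,d_eff_nitrate Effective diffusivities, m^2 s^-1.
#' @param medium Optional \linkS4class{MediumParams} used to bound d_eff.
#' @return A \linkS4class{WallParams}.
#' @export
wallParams <- function(thickness_mm = 0.9, area_mm2 = 10,
                       d_eff_doc = 0.5 * 6.7e-10,
                       d_eff_nitrate = 0.5 * 1.7e-9,
                       medium = NULL) {
  if (!is.null(medium)) {
    if (d_eff_doc > medium@d_doc || d_eff_nitrate > medium@d_nitrate) {
      stop("effective wall diffusivity cannot exceed the free-solution value")
    }
  }
  new("WallParams", thickness_mm = thickness_mm, area_mm2 = area_mm2,
      d_eff_doc = d_eff_doc, d_eff_nitrate = d_eff_nitrate)
}

#' Construct algal population parameters
#'
#' Defaults are the calibrated P. tricornutum-like set used throughout the
#' package: Monod growth on nitrate (mu_max 1.0 d^-1, km 2 uM), a per-cell
#' nitrate quota u_max/mu_max of 60 fmol N, and DOC exudation of
#' 60 fmol C cell^-1 d^-1.
#'
#' @param n0 Initial density, cells ml^-1.
#' @param mu_max Maximal specific growth rate, d^-1.
#' @param km_n Monod half-saturation on nitrate, uM.
#' @param q_exu Per-cell DOC exudation, fmol C cell^-1 d^-1.
#' @param u_max Per-cell maximal nitrate uptake, fmol N cell^-1 d^-1.
#' @param km_uptake Uptake half-saturation, uM.
#' @return An \linkS4class{AlgalPopulation}.
#' @export
algalPopulation <- function(n0 = 1e6, mu_max = 1.0, km_n = 2,
                            q_exu = 60, u_max = 60, km_uptake = 2) {
  new("AlgalPopulation", n0 = n0, mu_max = mu_max, km_n = km_n,
      q_exu = q_exu, u_max = u_max, km_uptake = km_uptake)
}

.hexRing <- function(prefix, n, radius_mm) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(
    id = paste0(prefix, seq_len(n)),
    x_mm = radius_mm * cos(ang),
    y_mm = radius_mm * sin(ang),
    stringsAsFactors = FALSE
  )
}

.edgeRow <- function(from, to, wall) {
  data.frame(from = from, to = to, thickness_mm = wall@thickness_mm,
             area_mm2 = wall@area_mm2, d_eff_doc = wall@d_eff_doc,
             d_eff_nitrate = wall@d_eff_nitrate, stringsAsFactors = FALSE)
}

#' Build a plate layout from a named preset or a custom configuration
#'
#' Presets:
#' \describe{
#'   \item{hex7}{One centre + six outer wells (75 ul) at 8 mm, all carrying
#'     the alga; outer wells face the reservoir, the centre does not.}
#'   \item{isolate_rings}{Central algal well plus six radial arms of
#'     bacterial wells at 7, 14 and 21 mm.}
#'   \item{community_layers}{Central well (alga or medium control), bacterial
#'     layer 1 at 8 mm and layer 2 at 16 mm, outermost blank wells at 24 mm
#'     facing the reservoir (100 ul wells).}
#'   \item{single_well}{One well coupled to the reservoir.}
#' }
#' Reservoir-facing walls get 0.8 of the inter-well wall area (only part of
#' the outer arc of an outer well faces open medium below the liquid line).
#'
#' @param preset One of "hex7", "isolate_rings", "community_layers",
#'   "single_well", or "custom".
#' @param wall Inter-well \linkS4class{WallParams}.
#' @param reservoir List(nitrate, doc, volume_ml, fixed).
#' @param volume_ul Well volume override (preset default if NULL).
#' @param center_role Role of the centre well ("alga" or "medium-control"),
#'   used by isolate_rings and community_layers.
#' @param wells,edges For \code{preset = "custom"}: data.frames as stored in
#'   \linkS4class{PlateLayout}.
#' @return A validated \linkS4class{PlateLayout}.
#' @examples
#' layout <- buildLayout("hex7")
#' nrow(wellsOf(layout))  # 7
#' @export
buildLayout <- function(preset = c("hex7", "isolate_rings",
                                   "community_layers", "single_well",
                                   "custom"),
                        wall = wallParams(),
                        reservoir = list(nitrate = 882, doc = 10,
                                         volume_ml = 25, fixed = TRUE),
                        volume_ul = NULL,
                        center_role = "alga",
                        wells = NULL, edges = NULL) {
  preset <- match.arg(preset)
  rwall <- new("WallParams", thickness_mm = wall@thickness_mm,
               area_mm2 = wall@area_mm2 * 0.8,
               d_eff_doc = wall@d_eff_doc,
               d_eff_nitrate = wall@d_eff_nitrate)
  if (preset == "custom") {
    if (is.null(wells) || is.null(edges)) {
      stop("custom layout needs 'wells' and 'edges' data.frames")
    }
    obj <- new("PlateLayout", wells = wells, edges = edges,
               reservoir = reservoir, preset = "custom")
    validObject(obj)
    return(obj)
  }

  if (preset == "single_well") {
    v <- if (is.null(volume_ul)) 100 else volume_ul
    w <- data.frame(id = "W1", x_mm = 0, y_mm = 0, distance_mm = 0,
                    volume_ul = v, role = center_role,
                    stringsAsFactors = FALSE)
    e <- .edgeRow("W1", "RESERVOIR", rwall)
  } else if (preset == "hex7") {
    v <- if (is.null(volume_ul)) 75 else volume_ul
    ring <- .hexRing("O", 6, 8)
    w <- rbind(
      data.frame(id = "C0", x_mm = 0, y_mm = 0, stringsAsFactors = FALSE),
      ring[, c("id", "x_mm", "y_mm")]
    )
    w$distance_mm <- round(sqrt(w$x_mm^2 + w$y_mm^2), 6)
    w$volume_ul <- v
    w$role <- "alga"
    e <- do.call(rbind, c(
      lapply(ring$id, function(id) .edgeRow("C0", id, wall)),
      lapply(seq_len(6), function(i) {
        .edgeRow(ring$id[i], ring$id[if (i == 6) 1 else i + 1], wall)
      }),
      lapply(ring$id, function(id) .edgeRow(id, "RESERVOIR", rwall))
    ))
  } else if (preset == "isolate_rings") {
    v <- if (is.null(volume_ul)) 100 else volume_ul
    r1 <- .hexRing("R1_", 6, 7); r2 <- .hexRing("R2_", 6, 14)
    r3 <- .hexRing("R3_", 6, 21)
    w <- rbind(
      data.frame(id = "C0", x_mm = 0, y_mm = 0, stringsAsFactors = FALSE),
      r1[, c("id", "x_mm", "y_mm")], r2[, c("id", "x_mm", "y_mm")],
      r3[, c("id", "x_mm", "y_mm")]
    )
    w$distance_mm <- round(sqrt(w$x_mm^2 + w$y_mm^2), 6)
    w$volume_ul <- v
    w$role <- ifelse(w$id == "C0", center_role, "bacteria")
    e <- do.call(rbind, c(
      lapply(r1$id, function(id) .edgeRow("C0", id, wall)),
      lapply(seq_len(6), function(i) .edgeRow(r1$id[i], r2$id[i], wall)),
      lapply(seq_len(6), function(i) .edgeRow(r2$id[i], r3$id[i], wall)),
      lapply(r3$id, function(id) .edgeRow(id, "RESERVOIR", rwall))
    ))
  } else { # community_layers
    v <- if (is.null(volume_ul)) 100 else volume_ul
    l1 <- .hexRing("L1_", 6, 8); l2 <- .hexRing("L2_", 6, 16)
    bk <- .hexRing("B", 6, 24)
    w <- rbind(
      data.frame(id = "C0", x_mm = 0, y_mm = 0, stringsAsFactors = FALSE),
      l1[, c("id", "x_mm", "y_mm")], l2[, c("id", "x_mm", "y_mm")],
      bk[, c("id", "x_mm", "y_mm")]
    )
    w$distance_mm <- round(sqrt(w$x_mm^2 + w$y_mm^2), 6)
    w$volume_ul <- v
    w$role <- ifelse(w$id == "C0", center_role,
                     ifelse(grepl("^B", w$id), "blank", "bacteria"))
    e <- do.call(rbind, c(
      lapply(l1$id, function(id) .edgeRow("C0", id, wall)),
      lapply(seq_len(6), function(i) .edgeRow(l1$id[i], l2$id[i], wall)),
      lapply(seq_len(6), function(i) .edgeRow(l2$id[i], bk$id[i], wall)),
      lapply(bk$id, function(id) .edgeRow(id, "RESERVOIR", rwall))
    ))
  }
  rownames(w) <- rownames(e) <- NULL
  obj <- new("PlateLayout", wells = w, edges = e, reservoir = reservoir,
             preset = preset)
  validObject(obj)
  obj
}

#' Seal a layout (remove all reservoir edges)
#'
#' Produces the batch-culture equivalent of a plate: same well graph, no
#' exchange with the external medium.
#'
#' @param layout A \linkS4class{PlateLayout}.
#' @return A \linkS4class{PlateLayout} without reservoir edges.
#' @export
sealLayout <- function(layout) {
  e <- layout@edges
  e <- e[e$from != "RESERVOIR" & e$to != "RESERVOIR", , drop = FALSE]
  obj <- new("PlateLayout", wells = layout@wells, edges = e,
             reservoir = layout@reservoir, preset = layout@preset)
  validObject(obj)
  obj
}

#' Fickian flux through a porous wall
#'
#' J = d_eff * A * (c_i - c_j) / L, reported in nmol d^-1. Positive flux
#' flows from side i to side j; the function is antisymmetric in (i, j).
#'
#' @param c_i,c_j Concentrations on the two sides, uM.
#' @param wall A \linkS4class{WallParams}.
#' @param solute "DOC" or "nitrate" (selects the effective diffusivity).
#' @return Flux in nmol d^-1.
#' @examples
#' w <- wallParams(d_eff_doc = 1e-10, area_mm2 = 10, thickness_mm = 0.9)
#' diffusiveFlux(100, 0, w, "DOC")  # ~9.6 nmol/d
#' @export
diffusiveFlux <- function(c_i, c_j, wall, solute = c("DOC", "nitrate")) {
  solute <- match.arg(solute)
  validObject(wall)
  d_eff <- if (solute == "DOC") wall@d_eff_doc else wall@d_eff_nitrate
  .wallConductance(d_eff, wall@area_mm2, wall@thickness_mm) * (c_i - c_j)
}

#' Peclet-number check for advective transport through the wall
#'
#' Pe = v L / D; transport by fluid flow is negligible relative to
#' gradient-driven diffusion when Pe falls below the threshold.
#'
#' @param flow_speed Flow speed through the wall, m s^-1.
#' @param length Transport length (wall thickness), m.
#' @param diffusivity Solute diffusivity, m^2 s^-1.
#' @param threshold Negligibility threshold (default 0.1).
#' @return list(Pe = numeric, negligible = logical).
#' @examples
#' pecletCheck(1e-8, 9e-4, 1e-9)  # Pe = 9e-3, negligible
#' @export
pecletCheck <- function(flow_speed, length, diffusivity, threshold = 0.1) {
  if (diffusivity <= 0) stop("diffusivity must be > 0")
  if (length <= 0) stop("length must be > 0")
  if (flow_speed < 0) stop("flow_speed must be >= 0")
  pe <- flow_speed * length / diffusivity
  list(Pe = pe, negligible = pe < threshold)
}

## ---------------------------------------------------------------------------
## ODE engine (shared by simulatePlate and simulateCocultures)
## ---------------------------------------------------------------------------

## Precompute conductance matrices (nmol/d/uM) between wells and to the
## reservoir for both solutes.
.layoutConductances <- function(layout) {
  w <- layout@wells; e <- layout@edges
  nw <- nrow(w)
  idx <- stats::setNames(seq_len(nw), w$id)
  Gd <- Gn <- matrix(0, nw, nw)
  Rd <- Rn <- numeric(nw)
  for (k in seq_len(nrow(e))) {
    gd <- .wallConductance(e$d_eff_doc[k], e$area_mm2[k], e$thickness_mm[k])
    gn <- .wallConductance(e$d_eff_nitrate[k], e$area_mm2[k], e$thickness_mm[k])
    a <- e$from[k]; b <- e$to[k]
    if (a == "RESERVOIR" || b == "RESERVOIR") {
      i <- idx[[if (a == "RESERVOIR") b else a]]
      Rd[i] <- Rd[i] + gd
      Rn[i] <- Rn[i] + gn
    } else {
      i <- idx[[a]]; j <- idx[[b]]
      Gd[i, j] <- Gd[i, j] + gd; Gd[j, i] <- Gd[j, i] + gd
      Gn[i, j] <- Gn[i, j] + gn; Gn[j, i] <- Gn[j, i] + gn
    }
  }
  list(Gd = Gd, Gn = Gn, Rd = Rd, Rn = Rn)
}

.simulateEngine <- function(layout, alga, medium, taxa, t_span, dt_out,
                            init_doc = NULL, init_nitrate = NULL,
                            hold_resources = FALSE, taxa_placement = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(layout, "PlateLayout"))
  validObject(layout)
  w <- layout@wells
  nw <- nrow(w)
  nt <- length(taxa)
  cond <- .layoutConductances(layout)
  V <- w$volume_ul
  res <- layout@reservoir
  fixed_res <- isTRUE(res$fixed)
  uM_per_nmol_ul <- 1e3 # nmol per ul equals 1e3 uM
  fmol_to_uM <- 1e-6    # cells/ml * fmol/cell/d -> uM/d
  yield_to_uM <- 1e3    # (cells/ml/d) / (cells/umol) -> uM/d

  algal_init <- if (is.null(alga)) numeric(nw) else
    ifelse(w$role == "alga", alga@n0, 0)
  if (is.null(init_doc)) init_doc <- res$doc
  if (is.null(init_nitrate)) init_nitrate <- res$nitrate
  init_doc <- rep(init_doc, length.out = nw)
  init_nitrate <- rep(init_nitrate, length.out = nw)
  if (nt && is.null(taxa_placement)) {
    taxa_placement <- rep(list(w$id[w$role == "bacteria"]), nt)
  }
  taxa_init <- if (nt) {
    unlist(lapply(seq_len(nt), function(k) {
      ifelse(w$id %in% taxa_placement[[k]], taxa[[k]]@initial_density, 0)
    }))
  } else numeric(0)

  y0 <- c(init_doc, init_nitrate, algal_init, taxa_init)
  if (!fixed_res) y0 <- c(y0, res$doc, res$nitrate)
  if (any(y0 < 0)) stop("initial state must be non-negative")

  i_doc <- seq_len(nw)
  i_no3 <- nw + seq_len(nw)
  i_alg <- 2 * nw + seq_len(nw)
  i_tax <- if (nt) lapply(seq_len(nt), function(k) (2 + k) * nw + seq_len(nw))
  i_res <- if (!fixed_res) (3 + nt) * nw + 1:2

  deriv <- function(t, y, parms) {
    doc <- y[i_doc]; no3 <- y[i_no3]; alg <- y[i_alg]
    res_doc <- if (fixed_res) res$doc else y[i_res[1]]
    res_no3 <- if (fixed_res) res$nitrate else y[i_res[2]]

    flux_doc <- cond$Gd %*% doc - rowSums(cond$Gd) * doc +
      cond$Rd * (res_doc - doc)
    flux_no3 <- cond$Gn %*% no3 - rowSums(cond$Gn) * no3 +
      cond$Rn * (res_no3 - no3)
    ddoc <- as.numeric(flux_doc) / V * uM_per_nmol_ul
    dno3 <- as.numeric(flux_no3) / V * uM_per_nmol_ul

    dalg <- numeric(nw)
    if (!is.null(alga)) {
      m_n <- no3 / (alga@km_n + no3)
      dalg <- alga@mu_max * m_n * alg
      ddoc <- ddoc + alga@q_exu * alg * fmol_to_uM
      dno3 <- dno3 - alga@u_max * (no3 / (alga@km_uptake + no3)) * alg * fmol_to_uM
    }

    dtax <- numeric(0)
    if (nt) {
      dtax <- numeric(nt * nw)
      for (k in seq_len(nt)) {
        tx <- taxa[[k]]
        B <- y[i_tax[[k]]]
        g_doc <- tx@mu_max_doc * doc / (tx@km_doc + doc)
        g_n <- tx@mu_max_n * no3 / (tx@km_n + no3)
        dtax[(k - 1) * nw + seq_len(nw)] <- (g_doc + g_n - tx@mortality) * B
        ddoc <- ddoc - g_doc * B / tx@yield_doc * yield_to_uM
        dno3 <- dno3 - g_n * B / tx@yield_n * yield_to_uM
      }
    }

    if (hold_resources) {
      ddoc <- numeric(nw); dno3 <- numeric(nw)
    }
    out <- c(ddoc, dno3, dalg, dtax)
    if (!fixed_res) {
      vres_ul <- res$volume_ml * 1e3
      dres_doc <- -sum(cond$Rd * (res_doc - doc)) / vres_ul * uM_per_nmol_ul
      dres_no3 <- -sum(cond$Rn * (res_no3 - no3)) / vres_ul * uM_per_nmol_ul
      if (hold_resources) dres_doc <- dres_no3 <- 0
      out <- c(out, dres_doc, dres_no3)
    }
    list(out)
  }

  times <- seq(t_span[1], t_span[2], by = dt_out)
  if (times[length(times)] < t_span[2]) times <- c(times, t_span[2])
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf(
      "ODE solver failed (istate = %d); wells = %d, taxa = %d, t_span = [%g, %g]",
      attr(sol, "istate")[1], nw, nt, t_span[1], t_span[2]))
  }
  y <- sol[, -1, drop = FALSE]
  if (min(y) < -1e-6) {
    stop(sprintf("negative state detected (min = %g); tighten tolerances",
                 min(y)))
  }
  y[y < 0] <- 0 # sub-tolerance integrator wiggle only

  bac <- list()
  if (nt) {
    bac <- lapply(seq_len(nt), function(k) {
      m <- y[, i_tax[[k]], drop = FALSE]
      colnames(m) <- w$id
      m
    })
    names(bac) <- vapply(taxa, function(tx) tx@name, character(1))
  }
  mk <- function(cols) {
    m <- y[, cols, drop = FALSE]
    colnames(m) <- w$id
    m
  }
  out <- new("WellTimeSeries", time = sol[, 1], wells = w$id,
             doc = mk(i_doc), nitrate = mk(i_no3), algae = mk(i_alg),
             bacteria = bac, layout = layout)
  if (!fixed_res) attr(out, "reservoir_final") <- y[nrow(y), i_res]
  validObject(out)
  out
}

#' Simulate DOC and nitrate dynamics in a porous microplate
#'
#' Integrates the well-compartment ODE system: Fickian wall fluxes between
#' wells and to the reservoir, plus algal Monod growth on nitrate,
#' Michaelis-Menten nitrate uptake and constant per-cell DOC exudation in
#' wells whose role is \code{"alga"}. The run is deterministic.
#'
#' @param layout A \linkS4class{PlateLayout}.
#' @param alga An \linkS4class{AlgalPopulation}, or NULL for an abiotic run.
#' @param medium A \linkS4class{MediumParams} (kept for interface symmetry;
#'   the reservoir concentrations of the layout define the boundary values).
#' @param t_span Numeric length-2, start and end time in days.
#' @param dt_out Output interval, days (daily grid by default).
#' @param init_doc,init_nitrate Optional per-well initial concentrations
#'   (default: reservoir values everywhere, i.e. wells prefilled with fresh
#'   medium).
#' @param rtol,atol Solver tolerances.
#' @return A \linkS4class{WellTimeSeries}.
#' @examples
#' layout <- buildLayout("single_well")
#' ts <- simulatePlate(layout, alga = NULL, t_span = c(0, 2), dt_out = 0.5,
#'                     init_nitrate = 0)
#' @export
simulatePlate <- function(layout, alga = algalPopulation(),
                          medium = mediumParams(), t_span = c(0, 20),
                          dt_out = 1, init_doc = NULL, init_nitrate = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  .simulateEngine(layout, alga, medium, taxa = list(), t_span = t_span,
                  dt_out = dt_out, init_doc = init_doc,
                  init_nitrate = init_nitrate, rtol = rtol, atol = atol)
}

#' DOC fold-decrease across wells at a given time
#'
#' Ratio of DOC in the well nearest the plate centre (the alga-located well)
#' to DOC in the farthest well, at time t.
#'
#' @param series A \linkS4class{WellTimeSeries}.
#' @param t Time (days); defaults to the last output time.
#' @return Numeric fold; +Inf with \code{attr(,"depleted")} when the far
#'   field is zero.
#' @export
docFoldAcrossWells <- function(series, t = max(series@time)) {
  w <- series@layout@wells
  dists <- w$distance_mm
  if (length(unique(dists)) < 2) {
    stop("need >= 2 wells at distinct distances from the algal well")
  }
  ti <- which.min(abs(series@time - t))
  row <- series@doc[ti, ]
  near <- mean(row[w$id[dists == min(dists)]])
  far <- mean(row[w$id[dists == max(dists)]])
  if (far <= 0) {
    out <- Inf
    attr(out, "depleted") <- TRUE
    return(out)
  }
  near / far
}

#' First time a well's nitrate falls below a fraction of its initial value
#'
#' Linear interpolation between output points; exact grid-point crossings are
#' returned as-is. Returns +Inf when the threshold is never reached.
#'
#' @param series A \linkS4class{WellTimeSeries}.
#' @param well_id Well to examine.
#' @param threshold_fraction Fraction of the initial concentration (default
#'   0.01).
#' @return Time in days, or +Inf.
#' @export
nitrateDepletionTime <- function(series, well_id, threshold_fraction = 0.01) {
  if (!well_id %in% series@wells) stop("unknown well id: ", well_id)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)")
  }
  conc <- series@nitrate[, well_id]
  thr <- threshold_fraction * conc[1]
  below <- which(conc <= thr)
  if (!length(below)) return(Inf)
  i <- below[1]
  if (i == 1) return(series@time[1])
  t0 <- series@time[i - 1]; t1 <- series@time[i]
  c0 <- conc[i - 1]; c1 <- conc[i]
  if (c1 == thr || c0 == c1) return(series@time[i])
  t0 + (c0 - thr) / (c0 - c1) * (t1 - t0)
}

## ---- accessors / show ------------------------------------------------------

#' Wells of a layout or run
#' @param x A \linkS4class{PlateLayout} or \linkS4class{WellTimeSeries}.
#' @return data.frame of wells.
#' @name wellsOf
NULL

#' Edges (porous walls) of a layout
#' @param x A \linkS4class{PlateLayout}.
#' @return data.frame of edges.
#' @name edgesOf
NULL

#' @describeIn wellsOf Wells of a layout.
#' @export
setMethod("wellsOf", "PlateLayout", function(x) x@wells)

#' @describeIn wellsOf Wells of a simulation run.
#' @export
setMethod("wellsOf", "WellTimeSeries", function(x) x@layout@wells)

#' @describeIn edgesOf Edges of a layout.
#' @export
setMethod("edgesOf", "PlateLayout", function(x) x@edges)

#' @describeIn timePoints Output times of a run.
#' @export
setMethod("timePoints", "WellTimeSeries", function(x) x@time)

#' @describeIn wellMatrix Extract a time-by-well matrix.
#' @export
setMethod("wellMatrix", "WellTimeSeries", function(x, what) {
  if (what %in% c("doc", "nitrate", "algae")) return(slot(x, what))
  if (what %in% names(x@bacteria)) return(x@bacteria[[what]])
  stop("unknown variable/taxon: ", what)
})

#' @describeIn asDataFrame Tidy (time, well_id, variable, value) view of a
#'   plate run, including per-taxon bacterial densities.
#' @export
setMethod("asDataFrame", "WellTimeSeries", function(x, ...) {
  blocks <- c(list(doc = x@doc, nitrate = x@nitrate, algae = x@algae),
              x@bacteria)
  do.call(rbind, lapply(names(blocks), function(nm) {
    m <- blocks[[nm]]
    data.frame(
      time = rep(x@time, times = ncol(m)),
      well_id = rep(colnames(m), each = nrow(m)),
      variable = nm,
      value = as.vector(m),
      stringsAsFactors = FALSE
    )
  }))
})

setMethod("show", "PlateLayout", function(object) {
  cat(sprintf("PlateLayout '%s': %d wells, %d walls (%d to reservoir)\n",
              object@preset, nrow(object@wells), nrow(object@edges),
              sum(object@edges$from == "RESERVOIR" |
                  object@edges$to == "RESERVOIR")))
})

setMethod("show", "WellTimeSeries", function(object) {
  cat(sprintf(
    "WellTimeSeries: %d wells x %d times (%.3g-%.3g d), %d bacterial taxa\n",
    length(object@wells), length(object@time), min(object@time),
    max(object@time), length(object@bacteria)))
})
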