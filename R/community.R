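## Synthetic bacterial community generator: Monod growth of
## exudate-specialist and generalist taxa on the simulated DOC / nitrate
## fields, replicate noise, and 16S-like relative-abundance sampling.

#' Construct bacterial taxon parameters
#'
#' @param name Label.
#' @param strategy "exudate_specialist" (grows only on algal DOC) or
#'   "generalist" (additive growth on DOC and inorganic N).
#' @param mu_max_doc,km_doc Monod parameters on DOC (d^-1, uM C).
#' @param mu_max_n,km_n Monod parameters on nitrate (d^-1, uM); mu_max_n is
#'   forced to 0 for a specialist.
#' @param yield_doc,yield_n Cells per umol of substrate.
#' @param mortality First-order mortality, d^-1.
#' @param initial_density Inoculum, cells ml^-1.
#' @return A \linkS4class{TaxonParams}.
#' @export
taxonParams <- function(name, strategy = c("generalist", "exudate_specialist"),
                        mu_max_doc, km_doc, mu_max_n = 0, km_n = 5,
                        yield_doc = 5e7, yield_n = 2e8, mortality = 0.1,
                        initial_density = 1e6) {
  strategy <- match.arg(strategy)
  if (strategy == "exudate_specialist") mu_max_n <- 0
  new("TaxonParams", name = name, strategy = strategy,
      mu_max_doc = mu_max_doc, km_doc = km_doc, mu_max_n = mu_max_n,
      km_n = km_n, yield_doc = yield_doc, yield_n = yield_n,
      mortality = mortality, initial_density = initial_density)
}

#' Two-strain isolate preset (Marinobacter-like generalist,
#' Algoriphagus-like exudate specialist)
#'
#' The calibrated pair used in the isolate co-culture experiment layout:
#' inocula of 4e6 (generalist) and 4e5 (specialist) cells ml^-1. The
#' specialist is an efficient degrader of algal exudate (high mu_max on DOC)
#' that cannot use inorganic N; the generalist uses DOC only weakly but
#' additionally grows on nitrate. All parameters are calibration, not
#' measurement.
#'
#' @return Named list of two \linkS4class{TaxonParams}.
#' @export
isolateTaxa <- function() {
  list(
    Marinobacter = taxonParams("Marinobacter", "generalist",
      mu_max_doc = 0.6, km_doc = 50, mu_max_n = 0.25, km_n = 5,
      yield_doc = 5e7, yield_n = 2e8, mortality = 0.1,
      initial_density = 4e6),
    Algoriphagus = taxonParams("Algoriphagus", "exudate_specialist",
      mu_max_doc = 2.5, km_doc = 50, yield_doc = 5e7, mortality = 0.1,
      initial_density = 4e5)
  )
}

#' Eight-genus community preset
#'
#' Genera observed in the mixed-community experiment, with strategy
#' assignments matching the direction of their distance/treatment response:
#' DOC-responsive taxa (Marinobacter, Algoriphagus, Muricauda, Oceanicaulis)
#' versus taxa more strongly favoured by inorganic nutrients
#' (Altererythrobacter, Rhodobacteraceae, Sphingomonadaceae, Alcanivorax).
#' All parameters are documented calibration.
#'
#' @return Named list of \linkS4class{TaxonParams}.
#' @export
communityTaxa <- function() {
  list(
    Marinobacter = taxonParams("Marinobacter", "generalist",
      mu_max_doc = 1.5, km_doc = 30, mu_max_n = 0.25,
      initial_density = 2e6),
    Algoriphagus = taxonParams("Algoriphagus", "exudate_specialist",
      mu_max_doc = 4, km_doc = 300, initial_density = 2e5),
    Muricauda = taxonParams("Muricauda", "exudate_specialist",
      mu_max_doc = 3, km_doc = 200, initial_density = 3e5),
    Oceanicaulis = taxonParams("Oceanicaulis", "exudate_specialist",
      mu_max_doc = 2.5, km_doc = 120, initial_density = 4e5),
    Altererythrobacter = taxonParams("Altererythrobacter", "generalist",
      mu_max_doc = 0.6, km_doc = 20, mu_max_n = 0.35,
      initial_density = 3e5),
    Rhodobacteraceae = taxonParams("Rhodobacteraceae", "generalist",
      mu_max_doc = 0.8, km_doc = 25, mu_max_n = 0.4,
      initial_density = 8e5),
    Sphingomonadaceae = taxonParams("Sphingomonadaceae", "generalist",
      mu_max_doc = 0.7, km_doc = 25, mu_max_n = 0.35,
      initial_density = 4e5),
    Alcanivorax = taxonParams("Alcanivorax", "generalist",
      mu_max_doc = 0.5, km_doc = 15, mu_max_n = 0.3,
      initial_density = 2e5)
  )
}

## Run expr with a local, restorable RNG state.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("an explicit integer seed is required for stochastic operations")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.bacterialLayers <- function(wells) {
  bw <- wells[wells$role == "bacteria", , drop = FALSE]
  dl <- sort(unique(bw$distance_mm))
  stats::setNames(match(bw$distance_mm, dl), bw$id)
}

#' Simulate algal-bacterial co-cultures in a plate
#'
#' Couples the plate transport/algal model with Monod growth of the supplied
#' bacterial taxa on the simulated DOC and nitrate fields (additive
#' substitutable resources, first-order mortality, resource drawdown through
#' fixed yields). Emits the full deterministic trajectories plus an
#' \linkS4class{AbundanceTable} of replicate observations at the requested
#' timepoints, with multiplicative lognormal replicate noise.
#'
#' @param layout A \linkS4class{PlateLayout}; wells with role "bacteria"
#'   receive the inocula, wells with role "alga" the alga.
#' @param alga An \linkS4class{AlgalPopulation} or NULL (control plate; a
#'   layout whose centre role is "medium-control" is equivalent).
#' @param taxa Named list of \linkS4class{TaxonParams}.
#' @param medium A \linkS4class{MediumParams}.
#' @param t_span Length-2 numeric, days.
#' @param seed Integer seed (required whenever \code{geo_sd > 1}).
#' @param timepoints Times (days) at which abundance observations are drawn;
#'   default: end of run.
#' @param n_replicates Replicate observations per well and timepoint.
#' @param geo_sd Geometric standard deviation of the replicate noise
#'   (1 = noise off).
#' @param dt_out Output interval of the trajectories.
#' @param hold_resources If TRUE, DOC and nitrate are held at their initial
#'   values (chemostat-like; used for closed-form growth checks).
#' @param placement "mixed" inoculates every taxon into every bacterial
#'   well (community experiment); "arms" distributes the taxa round-robin
#'   over the radial arms of a ring layout, so that each well carries a
#'   monoculture (isolate experiment); or a named list mapping taxon names
#'   to well ids.
#' @return list(series = WellTimeSeries, abundance = AbundanceTable).
#' @export
simulateCocultures <- function(layout, alga = algalPopulation(n0 = 1e7),
                               taxa = isolateTaxa(),
                               medium = mediumParams(),
                               t_span = c(0, 20), seed = NULL,
                               timepoints = NULL, n_replicates = 3,
                               geo_sd = 1.3, dt_out = 0.25,
                               hold_resources = FALSE,
                               placement = "mixed") {
  if (!length(taxa)) stop("taxon list is empty")
  lapply(taxa, validObject)
  if (geo_sd > 1 && is.null(seed)) {
    stop("an explicit seed is required when replicate noise is enabled")
  }
  has_alga <- !is.null(alga) && any(layout@wells$role == "alga")
  bact_ids <- layout@wells$id[layout@wells$role == "bacteria"]
  place <- if (is.list(placement)) {
    if (!all(names(taxa) %in% names(placement))) {
      stop("placement list must name every taxon")
    }
    placement[names(taxa)]
  } else if (identical(placement, "arms")) {
    arms <- as.integer(sub(".*_", "", bact_ids))
    if (any(is.na(arms))) stop("'arms' placement needs a ring layout")
    lapply(seq_along(taxa), function(k) {
      bact_ids[(arms - 1) %% length(taxa) == (k - 1)]
    })
  } else {
    rep(list(bact_ids), length(taxa))
  }
  series <- .simulateEngine(layout, if (has_alga) alga else NULL, medium,
                            taxa, t_span = t_span, dt_out = dt_out,
                            hold_resources = hold_resources,
                            taxa_placement = place)
  names(place) <- names(taxa)
  if (is.null(timepoints)) timepoints <- max(series@time)
  layers <- .bacterialLayers(layout@wells)
  wells <- layout@wells
  treatment <- if (has_alga) "with_alga" else "control"

  draw <- function() {
    rows <- list()
    for (tp in timepoints) {
      ti <- which.min(abs(series@time - tp))
      for (tx in names(taxa)) {
        for (wid in place[[tx]]) {
          dens <- series@bacteria[[tx]][ti, wid]
          noise <- if (geo_sd > 1) {
            stats::rlnorm(n_replicates, meanlog = -log(geo_sd)^2 / 2,
                          sdlog = log(geo_sd))
          } else rep(1, n_replicates)
          rows[[length(rows) + 1]] <- data.frame(
            well_id = wid,
            layer = layers[[wid]],
            distance_mm = wells$distance_mm[wells$id == wid],
            treatment = treatment,
            taxon = tx,
            density = dens * noise,
            rel_abundance = NA_real_,
            replicate = seq_len(n_replicates),
            timepoint = series@time[ti],
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  }
  df <- if (geo_sd > 1) .withSeed(seed, draw()) else draw()
  rownames(df) <- NULL
  list(series = series, abundance = new("AbundanceTable", data = df))
}

#' Convert absolute densities to 16S-like relative abundances
#'
#' Per sample (well x treatment x replicate x timepoint), taxon read counts
#' are drawn from a multinomial at the given sequencing depth whose expected
#' proportions equal the density proportions, optionally overdispersed by a
#' mean-one lognormal factor per taxon. With \code{overdispersion = 0} and
#' \code{sequencing_depth = Inf} the proportions equal the density ratios
#' exactly.
#'
#' @param table An \linkS4class{AbundanceTable} with densities.
#' @param sequencing_depth Reads per sample (Inf for the analytic limit).
#' @param overdispersion Lognormal sdlog of the per-taxon compositional
#'   noise (0 = none).
#' @param seed Integer seed (required when sampling is stochastic).
#' @return An \linkS4class{AbundanceTable} with rel_abundance filled.
#' @export
toRelativeAbundance <- function(table, sequencing_depth = 1e5,
                                overdispersion = 0, seed = NULL) {
  stopifnot(is(table, "AbundanceTable"))
  d <- abundanceData(table)
  stochastic <- overdispersion > 0 || is.finite(sequencing_depth)
  if (stochastic && is.null(seed)) {
    stop("an explicit seed is required for stochastic relative-abundance sampling")
  }
  key <- interaction(d$well_id, d$treatment, d$replicate, d$timepoint,
                     drop = TRUE)
  fill <- function() {
    rel <- numeric(nrow(d))
    for (k in levels(key)) {
      i <- which(key == k)
      dens <- d$density[i]
      tot <- sum(dens)
      if (tot <= 0) {
        warning("zero total density in sample ", k, "; flagged as all-zero")
        rel[i] <- 0
        next
      }
      w <- dens
      if (overdispersion > 0) {
        w <- w * stats::rlnorm(length(w), -overdispersion^2 / 2,
                               overdispersion)
      }
      p <- w / sum(w)
      rel[i] <- if (is.finite(sequencing_depth)) {
        as.numeric(stats::rmultinom(1, size = sequencing_depth, prob = p)) /
          sequencing_depth
      } else p
    }
    rel
  }
  d$rel_abundance <- if (stochastic) .withSeed(seed, fill()) else fill()
  new("AbundanceTable", data = d)
}

## ---- accessors / show ------------------------------------------------------

#' @describeIn abundanceData Tidy table of abundances.
#' @export
setMethod("abundanceData", "AbundanceTable", function(x) x@data)

#' @describeIn asDataFrame The underlying tidy abundance table.
#' @export
setMethod("asDataFrame", "AbundanceTable", function(x, ...) x@data)

setMethod("show", "AbundanceTable", function(object) {
  d <- object@data
  cat(sprintf(
    "AbundanceTable: %d rows | %d taxa | %d wells | timepoints: %s\n",
    nrow(d), length(unique(d$taxon)), length(unique(d$well_id)),
    paste(signif(sort(unique(d$timepoint)), 3), collapse = ", ")))
})

setMethod("show", "TaxonParams", function(object) {
  cat(sprintf(
    "TaxonParams: %s (%s)\n  mu_doc %g/d (km %g uM C) | mu_n %g/d (km %g uM) | mort %g/d | N0 %.3g/ml\n",
    object@name, object@strategy, object@mu_max_doc, object@km_doc,
    object@mu_max_n, object@km_n, object@mortality, object@initial_density))
})
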