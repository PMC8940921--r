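## Flow-cytometry-like count sampling with calibration beads.
##
## The instrument analyses a diluted sample spiked with counting beads at a
## known density. Event counts for cells and beads are Poisson draws over
## the (unknown) analysed volume; the bead counts calibrate that volume out:
##   density-hat = cell_events / bead_events * bead_density * dilution.

#' Simulate a bead-calibrated cytometry measurement
#'
#' @param density True cell density of the undiluted sample, cells ml^-1.
#' @param dilution_factor Dilution before analysis (>= 1; 35 in the
#'   reference protocol).
#' @param bead_density Bead density in the analysed mix, beads ml^-1.
#' @param analyzed_volume_ul Volume actually interrogated, ul.
#' @param noise Poisson event noise on both populations (TRUE) or exact
#'   expectations (FALSE).
#' @param seed Integer seed (required when \code{noise = TRUE}).
#' @return A \linkS4class{CytometrySample}; slot \code{estimated_density} is
#'   the back-calculated density (NA, with a warning, when no bead events
#'   were recorded).
#' @examples
#' s <- sampleCytometry(1e6, noise = FALSE)
#' s@estimated_density  # exactly 1e6
#' @export
sampleCytometry <- function(density, dilution_factor = 35,
                            bead_density = 5e5, analyzed_volume_ul = 50,
                            noise = TRUE, seed = NULL) {
  if (density < 0) stop("density must be >= 0")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  v_ml <- analyzed_volume_ul / 1e3
  exp_cells <- density / dilution_factor * v_ml
  exp_beads <- bead_density * v_ml
  if (noise) {
    counts <- .withSeed(seed, stats::rpois(2, c(exp_cells, exp_beads)))
    cell_events <- counts[1]; bead_events <- counts[2]
  } else {
    cell_events <- exp_cells; bead_events <- exp_beads
  }
  est <- if (bead_events > 0) {
    cell_events / bead_events * bead_density * dilution_factor
  } else {
    warning("no bead events recorded: density estimate undefined")
    NA_real_
  }
  new("CytometrySample", bead_events = bead_events,
      cell_events = cell_events, dilution_factor = dilution_factor,
      bead_density = bead_density, estimated_density = est)
}

setMethod("show", "CytometrySample", function(object) {
  cat(sprintf(
    "CytometrySample: %g cell / %g bead events (dilution %gx) -> %.4g cells/ml\n",
    object@cell_events, object@bead_events, object@dilution_factor,
    object@estimated_density))
})
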