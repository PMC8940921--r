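#' Normalise a radial profile by its maxima
#'
#' @param profile A \linkS4class{RadialProfile}.
#' @return A normalised \linkS4class{RadialProfile}.
#' @export
setGeneric("normalizeProfile", function(profile) standardGeneric("normalizeProfile"))

#' Fold decrease of a radial profile between its endpoints
#'
#' @param profile A \linkS4class{RadialProfile}.
#' @return Numeric fold (>= 1 for monotone profiles); +Inf with attribute
#'   \code{depleted = TRUE} when the far field is fully depleted.
#' @export
setGeneric("foldDecrease", function(profile) standardGeneric("foldDecrease"))

#' Tidy data.frame view of a simulation object
#'
#' @param x Object to flatten.
#' @param ... Further arguments passed to methods.
#' @return A data.frame in long format.
#' @export
setGeneric("asDataFrame", function(x, ...) standardGeneric("asDataFrame"))

#' @rdname wellsOf
#' @export
setGeneric("wellsOf", function(x) standardGeneric("wellsOf"))

#' @rdname edgesOf
#' @export
setGeneric("edgesOf", function(x) standardGeneric("edgesOf"))

#' Output times of a simulation
#' @param x Object holding a time grid.
#' @return Numeric vector of days.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' Concentration / density matrix of a plate run
#'
#' @param x A \linkS4class{WellTimeSeries}.
#' @param what One of "doc", "nitrate", "algae", or a taxon name.
#' @return Matrix, time by well.
#' @export
setGeneric("wellMatrix", function(x, what) standardGeneric("wellMatrix"))

#' Underlying tidy table of an AbundanceTable
#' @param x An \linkS4class{AbundanceTable}.
#' @return data.frame.
#' @export
setGeneric("abundanceData", function(x) standardGeneric("abundanceData"))

#' Distances (um) of a radial profile
#' @param x A \linkS4class{RadialProfile}.
#' @return Numeric vector.
#' @export
setGeneric("rGrid", function(x) standardGeneric("rGrid"))

#' Concentrations of a radial profile
#' @param x A \linkS4class{RadialProfile}.
#' @return Numeric vector (uM, or dimensionless if normalised).
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))
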