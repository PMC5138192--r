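#' Accessor generics
#'
#' Accessors for the slots of the S4 classes in this package. Use these
#' instead of direct slot access.
#'
#' @param x An object of the appropriate class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mutationRate", function(x) standardGeneric("mutationRate"))

#' @rdname accessors
#' @export
setGeneric("generationsPerStep", function(x) standardGeneric("generationsPerStep"))

#' @rdname accessors
#' @export
setGeneric("enrichmentFactor", function(x) standardGeneric("enrichmentFactor"))

#' @rdname accessors
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' @rdname accessors
#' @export
setGeneric("coloniesSampled", function(x) standardGeneric("coloniesSampled"))

#' @rdname accessors
#' @export
setGeneric("rawFraction", function(x) standardGeneric("rawFraction"))

#' @rdname accessors
#' @export
setGeneric("cappedFraction", function(x) standardGeneric("cappedFraction"))

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname accessors
#' @export
setGeneric("segregationRule", function(x) standardGeneric("segregationRule"))

#' @rdname accessors
#' @export
setGeneric("nTetrads", function(x) standardGeneric("nTetrads"))

#' @rdname accessors
#' @export
setGeneric("longLivedSpores", function(x) standardGeneric("longLivedSpores"))

#' @rdname accessors
#' @export
setGeneric("curveDays", function(x) standardGeneric("curveDays"))

#' @rdname accessors
#' @export
setGeneric("viability", function(x) standardGeneric("viability"))

#' @rdname accessors
#' @export
setGeneric("curveSEM", function(x) standardGeneric("curveSEM"))

#' @rdname accessors
#' @export
setGeneric("strainName", function(x) standardGeneric("strainName"))

#' @rdname accessors
#' @export
setGeneric("meanCLS", function(x) standardGeneric("meanCLS"))

#' @rdname accessors
#' @export
setGeneric("maxCLS", function(x) standardGeneric("maxCLS"))

#' @rdname accessors
#' @export
setGeneric("mutantFraction", function(x) standardGeneric("mutantFraction"))

#' @rdname accessors
#' @export
setGeneric("replicateTrajectories", function(x) standardGeneric("replicateTrajectories"))

#' @rdname accessors
#' @export
setGeneric("ensembleSummary", function(x) standardGeneric("ensembleSummary"))
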