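#' @include AllClasses.R
NULL

#' Accessors for spectral objects
#'
#' `sampleId()`, `solventName()`, `excitationNm()`, `deltaLambdaNm()`,
#' `intensityMatrix()`, `intensityValues()`, `dilutionFactor()` and
#' `provenance()` read the corresponding slots of [SynchronousMap-class] and
#' [FluorescenceProfile-class] objects; `zoneNames()`, `zoneLower()` and
#' `zoneUpper()` read a [ZoneScheme-class].
#'
#' @param object a spectral object.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("solventName", function(object) standardGeneric("solventName"))

#' @rdname accessors
#' @export
setGeneric("excitationNm", function(object) standardGeneric("excitationNm"))

#' @rdname accessors
#' @export
setGeneric("deltaLambdaNm", function(object) standardGeneric("deltaLambdaNm"))

#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' @rdname accessors
#' @export
setGeneric("intensityValues", function(object) standardGeneric("intensityValues"))

#' @rdname accessors
#' @export
setGeneric("dilutionFactor", function(object) standardGeneric("dilutionFactor"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("zoneNames", function(object) standardGeneric("zoneNames"))

#' @rdname accessors
#' @export
setGeneric("zoneLower", function(object) standardGeneric("zoneLower"))

#' @rdname accessors
#' @export
setGeneric("zoneUpper", function(object) standardGeneric("zoneUpper"))

#' Collapse a synchronous map into a fluorescence profile
#'
#' At each excitation wavelength the profile records the maximum intensity
#' over the offset (delta lambda) axis, so the profile traces the envelope
#' of the synchronous scans.
#'
#' @param map a [SynchronousMap-class].
#' @return a [FluorescenceProfile-class] with provenance `"projection"`.
#' @export
setGeneric("maxProjection", function(map) standardGeneric("maxProjection"))

#' Integrate a fluorescence profile over spectral zones
#'
#' @param profile a [FluorescenceProfile-class] whose grid spans 200-400 nm.
#' @param scheme a [ZoneScheme-class]; default [defaultZoneScheme()].
#' @param rule aggregation rule: `"trapezoid"` (default; trapezoidal integral
#'   in a.u. nm, split exactly at zone boundaries so that the zone values sum
#'   to the full-range integral), `"sum"` (sum of grid-point intensities,
#'   half-open zone membership) or `"mean"` (their mean).
#' @return named numeric vector, one value per zone.
#' @export
setGeneric("integrateZones",
           function(profile, scheme = defaultZoneScheme(),
                    rule = c("trapezoid", "sum", "mean"))
             standardGeneric("integrateZones"))
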