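#' @import methods
NULL

#' SynchronousMap: one sample's synchronous fluorescence map in one solvent
#'
#' A synchronous fluorescence spectrum scans emission at a fixed offset
#' (delta lambda) above the excitation wavelength; the family of scans over
#' offsets 30-170 nm forms a 3D map (the "fluorescent fingerprint") on an
#' excitation grid inside 200-400 nm. Intensities are arbitrary units; no
#' absolute calibration is attempted.
#'
#' @slot sampleId sample identifier.
#' @slot solvent `"PBS"` or `"PBS_DMSO"` (the 1:2500 dilution solvent).
#' @slot excitationNm strictly increasing excitation grid, within [200, 400].
#' @slot deltaLambdaNm strictly increasing offset grid, within [30, 170].
#' @slot intensity numeric matrix, excitation rows by offset columns, >= 0.
#' @slot dilutionFactor positive dilution factor (default 2500).
#' @slot meta free-text provenance (slit widths, scan speed, ...).
#'
#' @exportClass SynchronousMap
setClass("SynchronousMap",
  representation(
    sampleId = "character",
    solvent = "character",
    excitationNm = "numeric",
    deltaLambdaNm = "numeric",
    intensity = "matrix",
    dilutionFactor = "numeric",
    meta = "character"
  )
)

setValidity("SynchronousMap", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-empty string")
  if (length(object@solvent) != 1L || !object@solvent %in% .SOLVENTS)
    msg <- c(msg, sprintf("solvent must be one of %s",
                          paste(.SOLVENTS, collapse = ", ")))
  ex <- object@excitationNm; dl <- object@deltaLambdaNm
  if (length(ex) < 1L || any(!is.finite(ex)) || is.unsorted(ex, strictly = TRUE))
    msg <- c(msg, "excitationNm must be finite and strictly increasing")
  else if (ex[1L] < 200 || ex[length(ex)] > 400)
    msg <- c(msg, "excitationNm must lie within [200, 400] nm")
  if (length(dl) < 1L || any(!is.finite(dl)) || is.unsorted(dl, strictly = TRUE))
    msg <- c(msg, "deltaLambdaNm must be finite and strictly increasing")
  else if (dl[1L] < 30 || dl[length(dl)] > 170)
    msg <- c(msg, "deltaLambdaNm must lie within [30, 170] nm")
  if (!is.numeric(object@intensity))
    msg <- c(msg, "intensity must be numeric")
  if (nrow(object@intensity) != length(ex) ||
      ncol(object@intensity) != length(dl))
    msg <- c(msg, sprintf(
      "intensity is %d x %d but grids imply %d x %d",
      nrow(object@intensity), ncol(object@intensity), length(ex), length(dl)))
  bad <- which(!is.finite(object@intensity) | object@intensity < 0)
  if (length(bad))
    msg <- c(msg, sprintf("intensity must be finite and >= 0 (first offence at matrix index %d)",
                          bad[1L]))
  if (length(object@dilutionFactor) != 1L || !is.finite(object@dilutionFactor) ||
      object@dilutionFactor <= 0)
    msg <- c(msg, "dilutionFactor must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a SynchronousMap
#'
#' @param sampleId sample identifier.
#' @param solvent `"PBS"` or `"PBS_DMSO"`.
#' @param excitationNm excitation wavelength grid (nm), strictly increasing
#'   within [200, 400].
#' @param deltaLambdaNm wavelength-offset grid (nm), strictly increasing
#'   within [30, 170].
#' @param intensity matrix of fluorescence intensities (a.u.),
#'   `length(excitationNm)` rows by `length(deltaLambdaNm)` columns.
#' @param dilutionFactor dilution applied before measurement (default 2500).
#' @param meta free-text provenance string.
#' @return a validated [SynchronousMap-class] object.
#' @export
#' @examples
#' m <- synchronousMap("s1", "PBS", 280, 70, matrix(5))
#' intensityMatrix(m)
synchronousMap <- function(sampleId, solvent, excitationNm, deltaLambdaNm,
                           intensity, dilutionFactor = 2500, meta = "") {
  new("SynchronousMap", sampleId = as.character(sampleId),
      solvent = as.character(solvent),
      excitationNm = as.numeric(excitationNm),
      deltaLambdaNm = as.numeric(deltaLambdaNm),
      intensity = as.matrix(intensity),
      dilutionFactor = as.numeric(dilutionFactor),
      meta = as.character(meta))
}

#' FluorescenceProfile: 1-D intensity versus excitation wavelength
#'
#' Profiles are obtained by collapsing the offset axis of a
#' [SynchronousMap-class] ([maxProjection()]), by summing a sample's PBS and
#' PBS:DMSO profiles ([additiveProfile()]), or by averaging within a group
#' ([groupAverage()]); the `provenance` slot records which.
#'
#' @slot sampleId sample (or group) identifier.
#' @slot solvent `"PBS"`, `"PBS_DMSO"`, or `"both"` for additive profiles.
#' @slot excitationNm strictly increasing excitation grid (nm).
#' @slot intensity intensity vector (a.u.), same length as the grid.
#' @slot provenance one of `"projection"`, `"additive"`, `"group_average"`.
#' @slot backgroundSubtracted logical; when TRUE negative intensities are
#'   permitted (they arise after free-medium subtraction).
#'
#' @exportClass FluorescenceProfile
setClass("FluorescenceProfile",
  representation(
    sampleId = "character",
    solvent = "character",
    excitationNm = "numeric",
    intensity = "numeric",
    provenance = "character",
    backgroundSubtracted = "logical"
  )
)

setValidity("FluorescenceProfile", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (!object@solvent %in% c(.SOLVENTS, "both"))
    msg <- c(msg, "solvent must be PBS, PBS_DMSO or both")
  if (!object@provenance %in% c("projection", "additive", "group_average"))
    msg <- c(msg, "provenance must be projection, additive or group_average")
  if (length(object@excitationNm) != length(object@intensity))
    msg <- c(msg, "excitationNm and intensity lengths differ")
  if (length(object@excitationNm) &&
      is.unsorted(object@excitationNm, strictly = TRUE))
    msg <- c(msg, "excitationNm must be strictly increasing")
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensity must be finite")
  if (!isTRUE(object@backgroundSubtracted) && any(object@intensity < 0))
    msg <- c(msg, "negative intensity only permitted after background subtraction")
  if (length(msg)) msg else TRUE
})

#' Construct a FluorescenceProfile
#'
#' @param sampleId sample (or group) identifier.
#' @param solvent `"PBS"`, `"PBS_DMSO"` or `"both"`.
#' @param excitationNm excitation grid (nm).
#' @param intensity intensity vector (a.u.).
#' @param provenance `"projection"`, `"additive"` or `"group_average"`.
#' @param backgroundSubtracted set TRUE to permit negative intensities.
#' @return a validated [FluorescenceProfile-class] object.
#' @export
fluorescenceProfile <- function(sampleId, solvent, excitationNm, intensity,
                                provenance = "projection",
                                backgroundSubtracted = FALSE) {
  new("FluorescenceProfile", sampleId = as.character(sampleId),
      solvent = as.character(solvent),
      excitationNm = as.numeric(excitationNm),
      intensity = as.numeric(intensity),
      provenance = as.character(provenance),
      backgroundSubtracted = isTRUE(backgroundSubtracted))
}

#' ZoneScheme: partition of the excitation axis into spectral zones
#'
#' Zones are half-open intervals `[lower, upper)` except the last, which
#' includes its upper bound, so every grid point belongs to exactly one zone.
#' The default scheme is Z1 = 200-230, Z2 = 230-260, Z3 = 260-290,
#' Z4 = 290-330 and Z5 = 330-400 nm.
#'
#' @slot zoneName ordered zone names.
#' @slot lowerNm inclusive lower bounds (nm).
#' @slot upperNm upper bounds (nm); exclusive except for the last zone.
#'
#' @exportClass ZoneScheme
setClass("ZoneScheme",
  representation(zoneName = "character", lowerNm = "numeric",
                 upperNm = "numeric"))

setValidity("ZoneScheme", function(object) {
  msg <- character()
  n <- length(object@zoneName)
  if (n < 1L || length(object@lowerNm) != n || length(object@upperNm) != n)
    msg <- c(msg, "zoneName, lowerNm, upperNm must have equal positive length")
  else {
    if (anyDuplicated(object@zoneName))
      msg <- c(msg, "zone names must be unique")
    if (any(object@upperNm <= object@lowerNm))
      msg <- c(msg, "each zone must have upper > lower")
    if (n > 1L && any(object@lowerNm[-1L] != object@upperNm[-n]))
      msg <- c(msg, "zones must be contiguous and non-overlapping")
    if (object@lowerNm[1L] != 200 || object@upperNm[n] != 400)
      msg <- c(msg, "zones must cover [200, 400] nm")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ZoneScheme
#'
#' @param zoneName ordered zone names.
#' @param lowerNm lower bounds (nm), first must be 200.
#' @param upperNm upper bounds (nm), last must be 400; bounds must be
#'   contiguous.
#' @return a validated [ZoneScheme-class].
#' @export
#' @examples
#' defaultZoneScheme()
zoneScheme <- function(zoneName, lowerNm, upperNm) {
  new("ZoneScheme", zoneName = as.character(zoneName),
      lowerNm = as.numeric(lowerNm), upperNm = as.numeric(upperNm))
}

#' The Z1-Z5 partition of the 200-400 nm excitation axis
#'
#' @return the five-zone [ZoneScheme-class] Z1 = 200-230, Z2 = 230-260,
#'   Z3 = 260-290, Z4 = 290-330, Z5 = 330-400 nm.
#' @export
defaultZoneScheme <- function() {
  zoneScheme(paste0("Z", 1:5),
             c(200, 230, 260, 290, 330),
             c(230, 260, 290, 330, 400))
}
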