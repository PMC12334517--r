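#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("sampleId", "SynchronousMap", function(object) object@sampleId)
#' @rdname accessors
setMethod("sampleId", "FluorescenceProfile", function(object) object@sampleId)

#' @rdname accessors
setMethod("solventName", "SynchronousMap", function(object) object@solvent)
#' @rdname accessors
setMethod("solventName", "FluorescenceProfile", function(object) object@solvent)

#' @rdname accessors
setMethod("excitationNm", "SynchronousMap", function(object) object@excitationNm)
#' @rdname accessors
setMethod("excitationNm", "FluorescenceProfile",
          function(object) object@excitationNm)

#' @rdname accessors
setMethod("deltaLambdaNm", "SynchronousMap",
          function(object) object@deltaLambdaNm)

#' @rdname accessors
setMethod("intensityMatrix", "SynchronousMap", function(object) object@intensity)

#' @rdname accessors
setMethod("intensityValues", "FluorescenceProfile",
          function(object) object@intensity)

#' @rdname accessors
setMethod("dilutionFactor", "SynchronousMap",
          function(object) object@dilutionFactor)

#' @rdname accessors
setMethod("provenance", "FluorescenceProfile", function(object) object@provenance)

#' @rdname accessors
setMethod("zoneNames", "ZoneScheme", function(object) object@zoneName)
#' @rdname accessors
setMethod("zoneLower", "ZoneScheme", function(object) object@lowerNm)
#' @rdname accessors
setMethod("zoneUpper", "ZoneScheme", function(object) object@upperNm)

setMethod("show", "SynchronousMap", function(object) {
  cat("SynchronousMap:", object@sampleId, "in", object@solvent, "\n")
  cat(sprintf("  excitation %g-%g nm (%d points), offset %g-%g nm (%d points)\n",
              object@excitationNm[1L], object@excitationNm[length(object@excitationNm)],
              length(object@excitationNm),
              object@deltaLambdaNm[1L], object@deltaLambdaNm[length(object@deltaLambdaNm)],
              length(object@deltaLambdaNm)))
  cat(sprintf("  intensity range %.3g-%.3g a.u., dilution 1:%g\n",
              min(object@intensity), max(object@intensity),
              object@dilutionFactor))
  if (nzchar(object@meta)) cat("  meta:", object@meta, "\n")
})

setMethod("show", "FluorescenceProfile", function(object) {
  cat("FluorescenceProfile:", object@sampleId,
      sprintf("(%s, %s)\n", object@solvent, object@provenance))
  cat(sprintf("  %d points, %g-%g nm, intensity %.3g-%.3g a.u.%s\n",
              length(object@excitationNm),
              object@excitationNm[1L],
              object@excitationNm[length(object@excitationNm)],
              min(object@intensity), max(object@intensity),
              if (object@backgroundSubtracted) " (background-subtracted)" else ""))
})

setMethod("show", "ZoneScheme", function(object) {
  cat("ZoneScheme with", length(object@zoneName), "zones:\n")
  for (i in seq_along(object@zoneName))
    cat(sprintf("  %s = %g-%g nm\n", object@zoneName[i],
                object@lowerNm[i], object@upperNm[i]))
})
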