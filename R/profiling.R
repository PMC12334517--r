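#' @include AllGenerics.R
NULL

#' @rdname maxProjection
setMethod("maxProjection", "SynchronousMap", function(map) {
  if (ncol(map@intensity) < 1L) stop("empty offset grid")
  fluorescenceProfile(map@sampleId, map@solvent, map@excitationNm,
                      apply(map@intensity, 1L, max),
                      provenance = "projection")
})

#' Additive profile of a sample measured in both solvents
#'
#' The additive profile is the point-wise sum of a sample's PBS and PBS:DMSO
#' profiles and represents the sample's total fluorescence across both
#' dilutions; it is the input to zone integration and the Table-2 style
#' decomposition.
#'
#' @param pPbs profile of the sample in PBS.
#' @param pDmso profile of the same sample in PBS:DMSO.
#' @param resample if TRUE and the grids differ, `pDmso` is linearly
#'   resampled onto `pPbs`'s grid first; otherwise differing grids error.
#' @return a [FluorescenceProfile-class] with solvent `"both"` and
#'   provenance `"additive"`.
#' @export
additiveProfile <- function(pPbs, pDmso, resample = FALSE) {
  stopifnot(is(pPbs, "FluorescenceProfile"), is(pDmso, "FluorescenceProfile"))
  if (pPbs@sampleId != pDmso@sampleId)
    stop("profiles belong to different samples: '", pPbs@sampleId,
         "' vs '", pDmso@sampleId, "'")
  if (!isTRUE(all.equal(pPbs@excitationNm, pDmso@excitationNm))) {
    if (!resample)
      stop("profile grids differ; set resample = TRUE to interpolate")
    pDmso <- resampleProfile(pDmso, pPbs@excitationNm)
  }
  fluorescenceProfile(pPbs@sampleId, "both", pPbs@excitationNm,
                      pPbs@intensity + pDmso@intensity,
                      provenance = "additive",
                      backgroundSubtracted = pPbs@backgroundSubtracted ||
                        pDmso@backgroundSubtracted)
}

#' Average profiles within a group
#'
#' @param profiles non-empty list of [FluorescenceProfile-class] objects on a
#'   common excitation grid.
#' @param label identifier for the averaged profile (e.g. the group name).
#' @return a [FluorescenceProfile-class] with provenance `"group_average"`.
#' @export
groupAverage <- function(profiles, label = "average") {
  if (!length(profiles)) stop("no profiles to average")
  stopifnot(all(vapply(profiles, is, TRUE, "FluorescenceProfile")))
  grid <- profiles[[1L]]@excitationNm
  for (p in profiles[-1L])
    if (!isTRUE(all.equal(p@excitationNm, grid)))
      stop("profiles are not on a common excitation grid")
  mat <- vapply(profiles, intensityValues, numeric(length(grid)))
  solv <- unique(vapply(profiles, solventName, ""))
  fluorescenceProfile(label, if (length(solv) == 1L) solv else "both",
                      grid, rowMeans(as.matrix(mat)),
                      provenance = "group_average",
                      backgroundSubtracted =
                        any(vapply(profiles, function(p)
                          p@backgroundSubtracted, TRUE)))
}

#' Resample a profile onto a new excitation grid
#'
#' Linear interpolation; extrapolation outside the profile's span is refused.
#'
#' @param profile a [FluorescenceProfile-class].
#' @param targetNm strictly increasing grid inside the profile's span.
#' @return the resampled [FluorescenceProfile-class].
#' @export
resampleProfile <- function(profile, targetNm) {
  stopifnot(is(profile, "FluorescenceProfile"))
  x <- profile@excitationNm
  if (min(targetNm) < x[1L] || max(targetNm) > x[length(x)])
    stop("target grid requires extrapolation beyond [",
         x[1L], ", ", x[length(x)], "] nm")
  fluorescenceProfile(profile@sampleId, profile@solvent, targetNm,
                      approx(x, profile@intensity, xout = targetNm)$y,
                      provenance = profile@provenance,
                      backgroundSubtracted = profile@backgroundSubtracted)
}

#' Per-sample profiles (PBS, PBS:DMSO and additive) for a cohort of maps
#'
#' @param maps list of [SynchronousMap-class] objects containing, for every
#'   sample id, one PBS and one PBS_DMSO map.
#' @return named list (by sample id) of lists with elements `PBS`,
#'   `PBS_DMSO` and `additive`.
#' @export
cohortProfiles <- function(maps) {
  ids <- unique(vapply(maps, sampleId, ""))
  out <- lapply(ids, function(id) {
    mine <- maps[vapply(maps, sampleId, "") == id]
    solv <- vapply(mine, solventName, "")
    if (!all(.SOLVENTS %in% solv))
      stop("sample '", id, "' lacks a map in ",
           paste(setdiff(.SOLVENTS, solv), collapse = " and "))
    pPbs <- maxProjection(mine[[match("PBS", solv)]])
    pDmso <- maxProjection(mine[[match("PBS_DMSO", solv)]])
    list(PBS = pPbs, PBS_DMSO = pDmso,
         additive = additiveProfile(pPbs, pDmso))
  })
  names(out) <- ids
  out
}

#' Write cohort profiles as a long CSV
#'
#' @param profiles result of [cohortProfiles()].
#' @param path output CSV path (columns `sample_id`, `channel`,
#'   `excitation_nm`, `intensity`; `channel` is the solvent or `additive`).
#' @return the path, invisibly.
#' @export
writeProfilesCsv <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    do.call(rbind, lapply(c("PBS", "PBS_DMSO", "additive"), function(ch) {
      p <- profiles[[id]][[ch]]
      data.frame(sample_id = id, channel = ch,
                 excitation_nm = .fmtNum(p@excitationNm),
                 intensity = .fmtNum(p@intensity),
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
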