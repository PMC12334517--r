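#' @include AllGenerics.R
NULL

#' @rdname integrateZones
setMethod("integrateZones", "FluorescenceProfile",
  function(profile, scheme = defaultZoneScheme(),
           rule = c("trapezoid", "sum", "mean")) {
    rule <- match.arg(rule)
    x <- profile@excitationNm
    y <- profile@intensity
    lo <- scheme@lowerNm
    hi <- scheme@upperNm
    n <- length(lo)
    if (x[1L] > lo[1L] || x[length(x)] < hi[n])
      stop("profile span [", x[1L], ", ", x[length(x)],
           "] does not cover zone ",
           scheme@zoneName[if (x[1L] > lo[1L]) 1L else n])
    vals <- vapply(seq_len(n), function(i) {
      switch(rule,
        trapezoid = .trapzSegment(x, y, lo[i], hi[i]),
        sum = ,
        mean = {
          # half-open membership except the last zone keeps its upper bound
          inZone <- x >= lo[i] & (x < hi[i] | (i == n & x <= hi[i]))
          if (!any(inZone))
            stop("no grid points fall in zone ", scheme@zoneName[i])
          if (rule == "sum") sum(y[inZone]) else mean(y[inZone])
        })
    }, 0)
    names(vals) <- scheme@zoneName
    vals
  })

#' Subtract the free-medium (M) background from zone values
#'
#' @param zones named numeric vector of per-zone values for a sample.
#' @param zonesM named numeric vector of the free-medium group mean, same
#'   zone scheme.
#' @return named numeric vector of differences; negatives are permitted and
#'   carried in a `"backgroundSubtracted"` attribute.
#' @export
subtractBackground <- function(zones, zonesM) {
  if (!identical(names(zones), names(zonesM)))
    stop("zone scheme mismatch: ", paste(names(zones), collapse = ","),
         " vs ", paste(names(zonesM), collapse = ","))
  out <- zones - zonesM
  attr(out, "backgroundSubtracted") <- TRUE
  out
}

#' Sum per-zone values measured in the two solvents
#'
#' Equals zone integration of the additive profile exactly when both
#' profiles share a grid (linearity of the trapezoid rule).
#'
#' @param zonesPbs,zonesDmso named numeric vectors on the same zone scheme.
#' @return named numeric vector of sums.
#' @export
sumSolventZones <- function(zonesPbs, zonesDmso) {
  if (!identical(names(zonesPbs), names(zonesDmso)))
    stop("zone scheme mismatch between solvents")
  zonesPbs + zonesDmso
}

#' Per-sample zone table for a cohort
#'
#' Integrates every per-sample profile (PBS, PBS:DMSO and additive) over the
#' zone scheme and, optionally, normalizes each (channel, zone) value to the
#' free-medium group: `"subtract"` removes the M-group mean (the default
#' reading of "normalized to free culture medium"); `"ratio"` divides by it.
#'
#' @param profiles result of [cohortProfiles()].
#' @param manifest manifest data.frame covering every sample.
#' @param scheme a [ZoneScheme-class].
#' @param rule integration rule, see [integrateZones()].
#' @param normalize `"none"`, `"subtract"` or `"ratio"`.
#' @return data.frame with columns `sample_id`, `group`, `channel`, `zone`,
#'   `value`, `background_subtracted`.
#' @export
cohortZoneTable <- function(profiles, manifest, scheme = defaultZoneScheme(),
                            rule = "trapezoid",
                            normalize = c("none", "subtract", "ratio")) {
  normalize <- match.arg(normalize)
  validateManifest(manifest)
  ids <- names(profiles)
  missing <- setdiff(ids, manifest$sample_id)
  if (length(missing))
    stop("sample(s) absent from manifest: ", paste(missing, collapse = ", "))
  grp <- manifest$group[match(ids, manifest$sample_id)]
  tab <- do.call(rbind, lapply(seq_along(ids), function(i) {
    do.call(rbind, lapply(c("PBS", "PBS_DMSO", "additive"), function(ch) {
      z <- integrateZones(profiles[[i]][[ch]], scheme, rule)
      data.frame(sample_id = ids[i], group = grp[i], channel = ch,
                 zone = names(z), value = unname(z),
                 background_subtracted = FALSE, stringsAsFactors = FALSE)
    }))
  }))
  rownames(tab) <- NULL
  if (normalize == "none") return(tab)
  mRows <- tab$group == "M"
  if (!any(mRows))
    stop("no free-medium baseline: manifest has no M samples")
  mMean <- tapply(tab$value[mRows],
                  paste(tab$channel[mRows], tab$zone[mRows]), mean)
  key <- paste(tab$channel, tab$zone)
  base <- as.numeric(mMean[key])
  tab$value <- if (normalize == "subtract") tab$value - base
               else tab$value / base
  tab$background_subtracted <- TRUE
  tab
}

#' Zone-ratio features for the correlation plot
#'
#' For each sample computes x = Z1(PBS)/Z5(PBS:DMSO) and
#' y = Z2(PBS)/Z4(PBS:DMSO); samples with a non-positive denominator are
#' dropped with a warning.
#'
#' @param zoneTable un-normalized zone table from [cohortZoneTable()].
#' @return data.frame with columns `sample_id`, `group`, `x`, `y`.
#' @export
ratioFeatures <- function(zoneTable) {
  wide <- function(ch, zn) {
    sel <- zoneTable$channel == ch & zoneTable$zone == zn
    setNames(zoneTable$value[sel], zoneTable$sample_id[sel])
  }
  z1p <- wide("PBS", "Z1"); z2p <- wide("PBS", "Z2")
  z4d <- wide("PBS_DMSO", "Z4"); z5d <- wide("PBS_DMSO", "Z5")
  ids <- names(z1p)
  grp <- zoneTable$group[match(ids, zoneTable$sample_id)]
  bad <- z5d[ids] <= 0 | z4d[ids] <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad),
            " sample(s) with non-positive denominator zones: ",
            paste(ids[bad], collapse = ", "))
  }
  keep <- !bad
  data.frame(sample_id = ids[keep], group = grp[keep],
             x = unname(z1p[ids[keep]] / z5d[ids[keep]]),
             y = unname(z2p[ids[keep]] / z4d[ids[keep]]),
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares trend of the zone-ratio correlation for one group
#'
#' @param points data.frame from [ratioFeatures()].
#' @param group group label to fit (`"F"`, `"N"` or `"M"`).
#' @return list with `slope`, `intercept`, `r` (Pearson) and `n`.
#' @export
groupTrend <- function(points, group) {
  d <- points[points$group == group, , drop = FALSE]
  if (nrow(d) < 2L)
    stop("need at least 2 points in group '", group, "'")
  if (stats::var(d$x) == 0)
    stop("zero variance in x for group '", group, "'")
  fit <- lm(y ~ x, data = d)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r = if (stats::var(d$y) == 0) 0 else cor(d$x, d$y), n = nrow(d))
}
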