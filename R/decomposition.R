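#' @include AllGenerics.R
NULL

#' HSA fluorescence calibration
#'
#' Linear-through-origin conversion from the photometrically determined HSA
#' concentration to its calculated fluorescence contribution.
#'
#' @param coefficient fluorescence per concentration (a.u. per g/L), > 0.
#' @param note free-text provenance of the calibration.
#' @return an `HsaCalibration` object.
#' @export
hsaCalibration <- function(coefficient, note = "") {
  .assertNumericScalar(coefficient, "coefficient", lower = 0)
  if (coefficient <= 0) stop("calibration coefficient must be > 0")
  structure(list(coefficient = coefficient, note = as.character(note)),
            class = "HsaCalibration")
}

#' @export
print.HsaCalibration <- function(x, ...) {
  cat(sprintf("HsaCalibration: %g a.u. per g/L", x$coefficient))
  if (nzchar(x$note)) cat(" (", x$note, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Total fluorescence of an additive profile
#'
#' `full_integral` (default) returns the sum of all five zone integrals of
#' the additive profile, i.e. its full-range trapezoidal integral;
#' `z3_peak` returns the maximum additive intensity within the Z3 zone
#' (260-290 nm, the 280 nm tryptophan region read as the sum of albumin,
#' other proteins, free tryptophan and its metabolites).
#'
#' @param profile an additive [FluorescenceProfile-class].
#' @param mode `"full_integral"` or `"z3_peak"`.
#' @param scheme zone scheme locating Z3 (default [defaultZoneScheme()]).
#' @return total fluorescence in a.u. (a.u. nm for the integral mode).
#' @export
totalFluorescence <- function(profile, mode = c("full_integral", "z3_peak"),
                              scheme = defaultZoneScheme()) {
  mode <- match.arg(mode)
  stopifnot(is(profile, "FluorescenceProfile"))
  if (mode == "full_integral")
    return(unname(sum(integrateZones(profile, scheme, "trapezoid"))))
  i <- match("Z3", scheme@zoneName)
  if (is.na(i)) stop("scheme has no Z3 zone")
  x <- profile@excitationNm
  inZ3 <- x >= scheme@lowerNm[i] & x < scheme@upperNm[i]
  if (!any(inZ3)) stop("profile has no grid points inside Z3")
  max(profile@intensity[inZ3])
}

#' Calculated HSA fluorescence from a photometric concentration
#'
#' @param conc HSA concentration (g/L), >= 0.
#' @param calib an [hsaCalibration()].
#' @return `coefficient * conc` (a.u.).
#' @export
hsaFluorescence <- function(conc, calib) {
  stopifnot(inherits(calib, "HsaCalibration"))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("HSA concentration must be finite and >= 0")
  calib$coefficient * conc
}

#' Metabolite fluorescence: total minus calculated HSA
#'
#' @param total total fluorescence (a.u.).
#' @param hsa calculated HSA fluorescence (a.u.).
#' @return `total - hsa` (a.u.).
#' @export
metaboliteFluorescence <- function(total, hsa) total - hsa

#' Embryo metabolic activity: metabolites minus the free-medium background
#'
#' @param metabSample metabolite fluorescence of the SECM sample/group (a.u.).
#' @param metabM metabolite fluorescence of the free culture medium (a.u.).
#' @return `metabSample - metabM` (a.u.).
#' @export
metabolicActivity <- function(metabSample, metabM) metabSample - metabM

#' Ratio of metabolic activities between groups
#'
#' @param actN metabolic activity of the unsuccessful-implantation group.
#' @param actF metabolic activity of the successful-implantation group.
#' @return `actN / actF` (dimensionless); negative activities produce a
#'   warning, a zero denominator an error.
#' @export
activityRatio <- function(actN, actF) {
  if (actF == 0) stop("zero denominator: F-group activity is 0")
  if (actN < 0 || actF < 0)
    warning("negative metabolic activity; ratio returned as-is")
  actN / actF
}

#' Decompose a cohort into total / HSA / metabolite / activity values
#'
#' Builds the group-average additive profile for each group, takes its total
#' fluorescence, subtracts the calculated HSA fluorescence (group-mean
#' photometric concentration times the calibration coefficient) to obtain
#' metabolite fluorescence, and subtracts the free-medium metabolite value
#' to obtain the embryo metabolic activity of F and N. The identities
#' `metabolites = total - hsa` and `activity = metabolites - metabolites(M)`
#' hold exactly by construction. A per-sample mode returns the same
#' decomposition for every sample against the M-group mean.
#'
#' @param profiles result of [cohortProfiles()].
#' @param manifest manifest with `hsa_conc` for every sample.
#' @param calib an [hsaCalibration()].
#' @param mode total-fluorescence mode, see [totalFluorescence()].
#' @param scheme zone scheme.
#' @param perSample if TRUE, return one row per sample instead of per group.
#' @return list with `table` (data.frame rows `total`, `hsa`, `metabolites`,
#'   `activity`; columns `F`, `N`, `M`, activity `NA` for M) and `ratioNF`
#'   (N/F activity ratio), or a per-sample data.frame when
#'   `perSample = TRUE`.
#' @export
decomposeCohort <- function(profiles, manifest, calib,
                            mode = "full_integral",
                            scheme = defaultZoneScheme(),
                            perSample = FALSE) {
  validateManifest(manifest)
  stopifnot(inherits(calib, "HsaCalibration"))
  ids <- names(profiles)
  grp <- manifest$group[match(ids, manifest$sample_id)]
  conc <- manifest$hsa_conc[match(ids, manifest$sample_id)]
  if (any(is.na(conc)))
    stop("hsa_conc missing for sample(s): ",
         paste(ids[is.na(conc)], collapse = ", "))
  if (!any(grp == "M")) stop("no free-medium baseline: no M samples")

  groupTotal <- function(g) {
    totalFluorescence(groupAverage(lapply(profiles[grp == g],
                                          `[[`, "additive"), label = g),
                      mode, scheme)
  }
  totM <- groupTotal("M")
  hsaM <- hsaFluorescence(mean(conc[grp == "M"]), calib)
  metabM <- metaboliteFluorescence(totM, hsaM)

  if (perSample) {
    tot <- vapply(ids, function(id)
      totalFluorescence(profiles[[id]]$additive, mode, scheme), 0)
    hsa <- hsaFluorescence(conc, calib)
    metab <- metaboliteFluorescence(tot, hsa)
    return(data.frame(sample_id = ids, group = grp, total = unname(tot),
                      hsa = hsa, metabolites = metab,
                      activity = ifelse(grp == "M", NA_real_,
                                        metabolicActivity(metab, metabM)),
                      stringsAsFactors = FALSE))
  }

  groupsPresent <- intersect(c("F", "N", "M"), unique(grp))
  tot <- vapply(groupsPresent, groupTotal, 0)
  hsa <- vapply(groupsPresent, function(g)
    hsaFluorescence(mean(conc[grp == g]), calib), 0)
  metab <- metaboliteFluorescence(tot, hsa)
  act <- ifelse(groupsPresent == "M", NA_real_,
                metabolicActivity(metab, metabM))
  tab <- as.data.frame(rbind(total = tot, hsa = hsa, metabolites = metab,
                             activity = act))
  ratio <- if (all(c("F", "N") %in% groupsPresent))
    activityRatio(tab["activity", "N"], tab["activity", "F"]) else NA_real_
  list(table = tab, ratioNF = ratio, mode = mode)
}
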