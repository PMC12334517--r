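#' @include AllClasses.R
NULL

#' Define a fluorophore band for the spectral forward model
#'
#' Bands are separable Gaussians in (excitation, offset): intensity
#' `A * exp(-(ex-centerEx)^2/(2*widthEx^2)) * exp(-(dl-centerDl)^2/(2*widthDl^2))`,
#' multiplied by `solventFactor` in PBS:DMSO (0 = fully quenched, as for the
#' tyrosine band; >1 = enhanced, as for tryptophan).
#'
#' @param name band name.
#' @param centerExNm band position on the excitation axis (nm).
#' @param widthExNm Gaussian SD along excitation (nm), > 0.
#' @param centerDlNm preferred wavelength offset (nm).
#' @param widthDlNm Gaussian SD along the offset axis (nm), > 0.
#' @param amplitude peak amplitude (a.u.), >= 0.
#' @param solventFactor multiplier applied in PBS:DMSO, >= 0.
#' @return one-row data.frame; band libraries are built with `rbind()`.
#' @export
fluorophoreBand <- function(name, centerExNm, widthExNm, centerDlNm = 70,
                            widthDlNm = 35, amplitude = 1, solventFactor = 1) {
  .assertNumericScalar(widthExNm, "widthExNm", lower = 1e-12)
  .assertNumericScalar(widthDlNm, "widthDlNm", lower = 1e-12)
  .assertNumericScalar(amplitude, "amplitude", lower = 0)
  .assertNumericScalar(solventFactor, "solventFactor", lower = 0)
  data.frame(name = as.character(name), centerExNm = centerExNm,
             widthExNm = widthExNm, centerDlNm = centerDlNm,
             widthDlNm = widthDlNm, amplitude = amplitude,
             solventFactor = solventFactor, stringsAsFactors = FALSE)
}

.emptyBands <- function() fluorophoreBand("x", 280, 10)[0L, ]

.validateBands <- function(bands) {
  req <- c("name", "centerExNm", "widthExNm", "centerDlNm", "widthDlNm",
           "amplitude", "solventFactor")
  missing <- setdiff(req, names(bands))
  if (length(missing))
    stop("band table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(bands)) {
    stopifnot(all(bands$widthExNm > 0), all(bands$widthDlNm > 0),
              all(bands$amplitude >= 0), all(bands$solventFactor >= 0))
  }
  bands
}

#' Simulate one synchronous fluorescence map
#'
#' Forward model: `baseline + sum of separable Gaussian bands` (each scaled
#' by its `solventFactor` when `solvent = "PBS_DMSO"`), plus optional
#' Gaussian instrument noise truncated at zero. With `noiseSd = 0` the map
#' is deterministic and additive in bands.
#'
#' @param bands band table (rows from [fluorophoreBand()]); may be empty.
#' @param solvent `"PBS"` or `"PBS_DMSO"`.
#' @param excitationNm excitation grid (default 200-400 nm, 1 nm step).
#' @param deltaLambdaNm offset grid (default 30-170 nm, 10 nm step).
#' @param noiseSd Gaussian noise SD (a.u.), >= 0.
#' @param baseline constant offset (a.u.).
#' @param seed optional integer; identical seed and arguments give an
#'   identical map. `NULL` draws from the current RNG stream.
#' @param sampleId sample identifier for the returned map.
#' @param dilutionFactor dilution recorded on the map.
#' @return a [SynchronousMap-class].
#' @export
simulateMap <- function(bands, solvent = "PBS",
                        excitationNm = seq(200, 400, by = 1),
                        deltaLambdaNm = seq(30, 170, by = 10),
                        noiseSd = 0, baseline = 0, seed = NULL,
                        sampleId = "sim", dilutionFactor = 2500) {
  .validateBands(bands)
  .assertNumericScalar(noiseSd, "noiseSd", lower = 0)
  .assertNumericScalar(baseline, "baseline", lower = 0)
  signal <- matrix(baseline, length(excitationNm), length(deltaLambdaNm))
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    amp <- b$amplitude * if (solvent == "PBS_DMSO") b$solventFactor else 1
    if (amp == 0) next
    fx <- exp(-(excitationNm - b$centerExNm)^2 / (2 * b$widthExNm^2))
    fd <- exp(-(deltaLambdaNm - b$centerDlNm)^2 / (2 * b$widthDlNm^2))
    signal <- signal + amp * outer(fx, fd)
  }
  if (noiseSd > 0)
    signal <- .withSeed(seed, pmax(signal + rnorm(length(signal),
                                                  sd = noiseSd), 0))
  synchronousMap(sampleId, solvent, excitationNm, deltaLambdaNm, signal,
                 dilutionFactor = dilutionFactor,
                 meta = "simulated; separable Gaussian band model")
}

#' Additive-profile integral contributed by a band table
#'
#' For bands sharing the offset response, the max-over-offset projection is
#' additive and each band contributes
#' `amplitude * (1 + solventFactor) * max_dl_response * trapz(excitation Gaussian)`
#' to the additive (PBS + PBS:DMSO) profile integral over the excitation
#' grid. Used to calibrate the generator and as the closed-form expected
#' value in recovery checks.
#'
#' @param bands band table.
#' @param excitationNm excitation grid.
#' @param deltaLambdaNm offset grid (determines the attainable offset-response
#'   maximum when a band's `centerDlNm` is off-grid).
#' @return total contribution in a.u. nm.
#' @export
bandAdditiveIntegral <- function(bands,
                                 excitationNm = seq(200, 400, by = 1),
                                 deltaLambdaNm = seq(30, 170, by = 10)) {
  .validateBands(bands)
  if (!nrow(bands)) return(0)
  sum(vapply(seq_len(nrow(bands)), function(i) {
    b <- bands[i, ]
    fx <- exp(-(excitationNm - b$centerExNm)^2 / (2 * b$widthExNm^2))
    fdMax <- max(exp(-(deltaLambdaNm - b$centerDlNm)^2 / (2 * b$widthDlNm^2)))
    b$amplitude * (1 + b$solventFactor) * fdMax * .trapz(excitationNm, fx)
  }, 0))
}

## scale a unit-amplitude band so its additive-profile integral hits `target`
.calibrateBand <- function(band, target, excitationNm, deltaLambdaNm) {
  unit <- bandAdditiveIntegral(band, excitationNm, deltaLambdaNm)
  band$amplitude <- target / unit
  band
}

#' Specification of a synthetic SECM cohort
#'
#' Describes the study conditions the generator emulates: group sizes
#' matching the fluorescence study (30 F, 36 N, 3 M), a culture-medium band
#' library with a tyrosine-like band at 223 nm (quenched in PBS:DMSO) and a
#' tryptophan-like band at 280 nm (more pronounced in PBS:DMSO), an
#' HSA band whose amplitude is tied to the sample's photometric HSA
#' concentration through `hsaCoefficient`, embryo metabolite bands feeding
#' zones Z1, Z2, Z4 and Z5, and group-N effect multipliers on the Z1/Z2/Z4
#' bands. Default amplitudes are calibrated so that the noiseless group-mean
#' decomposition reproduces the reference magnitudes: total fluorescence
#' 301,582.6 (F) / 312,698.6 (N) / 259,570.1 (M) a.u. and embryo metabolic
#' activity 16,805.2 (F) / 27,836.0 (N) a.u.
#'
#' @param nF,nN,nM group sizes (defaults 30, 36, 3).
#' @param excitationNm,deltaLambdaNm measurement grids.
#' @param baseline constant medium baseline (a.u.).
#' @param mediumBands bands present in every sample, including free medium.
#' @param embryoBands embryo-secretome bands present in F and N samples only.
#' @param hsaBand unit HSA band; its per-sample amplitude is
#'   `hsaCoefficient * hsa_conc / (unit additive integral)` so that HSA
#'   contributes exactly `hsaCoefficient * hsa_conc` to the additive-profile
#'   integral.
#' @param hsaCoefficient HSA fluorescence per concentration (a.u. per g/L).
#' @param hsaConcMean,hsaConcSd named (`F`,`N`,`M`) mean and SD of the
#'   photometric HSA concentration (g/L).
#' @param zoneMultipliers named multipliers applied to embryo band
#'   amplitudes in group N (default >1 on the Z1, Z2 and Z4 bands, chosen so
#'   the noiseless N activity is 27,836.0 a.u.).
#' @param mediumCv lognormal coefficient of variation of the medium band
#'   amplitudes in every sample (technical: pipetting/dilution; the medium
#'   itself is one lot, so this is small).
#' @param embryoCv lognormal coefficient of variation of the embryo band
#'   amplitudes in F and N samples (biological variability of the
#'   secretome).
#' @param noiseSd instrument noise SD (a.u.).
#' @param seed integer seed driving all randomness in [simulateCohort()].
#' @return a `CohortSpec` list.
#' @export
cohortSpec <- function(nF = 30, nN = 36, nM = 3,
                       excitationNm = seq(200, 400, by = 1),
                       deltaLambdaNm = seq(30, 170, by = 10),
                       baseline = 50,
                       mediumBands = NULL, embryoBands = NULL,
                       hsaBand = fluorophoreBand("hsa", 280, 10),
                       hsaCoefficient = 1000,
                       hsaConcMean = c(F = 44.8423, N = 44.9275, M = 19.6350),
                       hsaConcSd = c(F = 1.5, N = 1.5, M = 0.5),
                       zoneMultipliers = NULL,
                       mediumCv = 0.02, embryoCv = 0.15,
                       noiseSd = 2, seed = 1) {
  stopifnot(nF >= 0, nN >= 0, nM >= 0, mediumCv >= 0, embryoCv >= 0,
            noiseSd >= 0)
  ## medium fluorescence target: reference M metabolite magnitude 239,935.1
  ## minus the flat baseline's additive integral (2 solvents x 200 nm).
  baselineIntegral <- 2 * (max(excitationNm) - min(excitationNm)) * baseline
  if (is.null(mediumBands)) {
    targets <- c(tyrosine = 90000, trp_medium = 100000,
                 medium_z5 = 239935.1 - baselineIntegral - 190000)
    mediumBands <- rbind(
      .calibrateBand(fluorophoreBand("tyrosine", 223, 10,
                                     solventFactor = 0.05),
                     targets["tyrosine"], excitationNm, deltaLambdaNm),
      .calibrateBand(fluorophoreBand("trp_medium", 280, 12,
                                     solventFactor = 1.3),
                     targets["trp_medium"], excitationNm, deltaLambdaNm),
      .calibrateBand(fluorophoreBand("medium_z5", 350, 20),
                     targets["medium_z5"], excitationNm, deltaLambdaNm))
  }
  if (is.null(embryoBands)) {
    etargets <- c(embryo_Z1 = 6000, embryo_Z2 = 5000, embryo_Z4 = 4000,
                  embryo_Z5 = 1805.2)
    embryoBands <- rbind(
      .calibrateBand(fluorophoreBand("embryo_Z1", 215, 6),
                     etargets["embryo_Z1"], excitationNm, deltaLambdaNm),
      .calibrateBand(fluorophoreBand("embryo_Z2", 245, 8),
                     etargets["embryo_Z2"], excitationNm, deltaLambdaNm),
      .calibrateBand(fluorophoreBand("embryo_Z4", 310, 10),
                     etargets["embryo_Z4"], excitationNm, deltaLambdaNm),
      .calibrateBand(fluorophoreBand("embryo_Z5", 355, 12),
                     etargets["embryo_Z5"], excitationNm, deltaLambdaNm))
    if (is.null(zoneMultipliers)) {
      ## N-group effect sized so noiseless N activity is 27,836.0 a.u.
      m <- (27836.0 - etargets["embryo_Z5"]) /
        sum(etargets[c("embryo_Z1", "embryo_Z2", "embryo_Z4")])
      zoneMultipliers <- c(embryo_Z1 = unname(m), embryo_Z2 = unname(m),
                           embryo_Z4 = unname(m))
    }
  }
  if (is.null(zoneMultipliers)) zoneMultipliers <- numeric()
  stopifnot(all(zoneMultipliers > 0))
  structure(list(
    nF = nF, nN = nN, nM = nM,
    excitationNm = excitationNm, deltaLambdaNm = deltaLambdaNm,
    baseline = baseline,
    mediumBands = .validateBands(mediumBands),
    embryoBands = .validateBands(embryoBands),
    hsaBand = .validateBands(hsaBand),
    hsaCoefficient = hsaCoefficient,
    hsaConcMean = hsaConcMean, hsaConcSd = hsaConcSd,
    zoneMultipliers = zoneMultipliers,
    mediumCv = mediumCv, embryoCv = embryoCv,
    noiseSd = noiseSd, seed = seed),
    class = "CohortSpec")
}

#' Simulate a full SECM cohort (both solvents) plus its manifest
#'
#' For every sample the PBS and PBS:DMSO maps share the sample-level band
#' amplitudes (lognormal variation around the library values), the HSA band
#' amplitude is tied to the sample's drawn photometric concentration through
#' `spec$hsaCoefficient`, group-N embryo bands are scaled by
#' `spec$zoneMultipliers`, and free-medium (M) samples carry only the medium
#' bands plus HSA. Transfer days are assigned 4/5 in the study's proportions
#' (6:24 for F, 7:29 for N).
#'
#' @param spec a [cohortSpec()].
#' @return list with `maps` (named list of [SynchronousMap-class], two per
#'   sample), `manifest` (data.frame) and `spec`.
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  groups <- c(rep("F", spec$nF), rep("N", spec$nN), rep("M", spec$nM))
  ids <- c(sprintf("F%02d", seq_len(spec$nF)),
           sprintf("N%02d", seq_len(spec$nN)),
           sprintf("M%02d", seq_len(spec$nM)))
  day4 <- c(if (spec$nF) seq_len(spec$nF) <= round(spec$nF * 6 / 30),
            if (spec$nN) seq_len(spec$nN) <= round(spec$nN * 7 / 36),
            rep(NA, spec$nM))
  days <- ifelse(is.na(day4), NA_integer_, ifelse(day4, 4L, 5L))
  ## lognormal multipliers with mean exactly 1 so group means stay calibrated
  lnorm1 <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s <- sqrt(log(1 + cv^2))
    exp(rnorm(n, -s^2 / 2, s))
  }
  hsaUnit <- bandAdditiveIntegral(spec$hsaBand, spec$excitationNm,
                                  spec$deltaLambdaNm)
  .withSeed(spec$seed, {
    maps <- list()
    conc <- numeric(length(ids))
    for (i in seq_along(ids)) {
      g <- groups[i]
      bands <- spec$mediumBands
      bands$amplitude <- bands$amplitude *
        lnorm1(nrow(bands), spec$mediumCv)
      if (g != "M") {
        eb <- spec$embryoBands
        if (g == "N" && length(spec$zoneMultipliers)) {
          j <- match(names(spec$zoneMultipliers), eb$name)
          eb$amplitude[j] <- eb$amplitude[j] * spec$zoneMultipliers
        }
        eb$amplitude <- eb$amplitude * lnorm1(nrow(eb), spec$embryoCv)
        bands <- rbind(bands, eb)
      }
      conc[i] <- max(rnorm(1, spec$hsaConcMean[g], spec$hsaConcSd[g]), 0.01)
      hsa <- spec$hsaBand
      hsa$amplitude <- spec$hsaCoefficient * conc[i] / hsaUnit
      bands <- rbind(bands, hsa)
      for (solv in .SOLVENTS)
        maps[[paste(ids[i], solv, sep = ".")]] <-
          simulateMap(bands, solv, spec$excitationNm, spec$deltaLambdaNm,
                      noiseSd = spec$noiseSd, baseline = spec$baseline,
                      sampleId = ids[i])
    }
    manifest <- data.frame(sample_id = ids, group = groups, day = days,
                           hsa_conc = conc, stringsAsFactors = FALSE)
    list(maps = maps, manifest = validateManifest(manifest), spec = spec)
  })
}

#' Simulate a qPCR Ct table for one miRNA
#'
#' Inverts the medium-normalized relative-expression formula:
#' `Ct(group) = ctMMean - trueLog2RelExpr(group) + noise`, with the free
#' medium (M) at `ctMMean`. Two technical duplicates per group by default.
#'
#' @param trueLog2RelExpr named numeric vector of true log2 relative
#'   expressions versus free medium, one per group (exclude `M`).
#' @param ctMMean mean Ct of the free-medium baseline (cycles).
#' @param duplicateSd SD of technical-duplicate noise (cycles), >= 0.
#' @param nDuplicates technical duplicates per group (default 2).
#' @param mirnaId miRNA identifier.
#' @param seed optional integer seed.
#' @return data.frame of Ct records (`mirna_id`, `group`, `replicate`, `ct`).
#' @export
simulateCtTable <- function(trueLog2RelExpr, ctMMean = 30, duplicateSd = 0,
                            nDuplicates = 2, mirnaId = "miR-sim",
                            seed = NULL) {
  .assertNumericScalar(duplicateSd, "duplicateSd", lower = 0)
  true <- c(trueLog2RelExpr, M = 0)
  .withSeed(seed, {
    rows <- do.call(rbind, lapply(names(true), function(g) {
      ct <- ctMMean - true[[g]] +
        if (duplicateSd > 0) rnorm(nDuplicates, sd = duplicateSd)
        else rep(0, nDuplicates)
      data.frame(mirna_id = mirnaId, group = g,
                 replicate = seq_len(nDuplicates), ct = ct,
                 stringsAsFactors = FALSE)
    }))
    validateCtTable(rows)
  })
}
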