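#' @include decomposition.R zones.R mirna.R synthetic.R
NULL

## Table-1 style defaults for the simulated qPCR stage: group means of the
## medium-normalized log2 relative expression of the two panel miRNAs.
.DEFAULT_TRUE_EXPR <- list(
  "miR-16-5p" = c("4D F" = -0.671, "4D N" = 0.490,
                  "5D F" = -0.328, "5D N" = 0.881),
  "miR-92a-3p" = c("4D F" = 0.710, "4D N" = 0.944,
                   "5D F" = 0.536, "5D N" = 0.581))

#' Build a pipeline run configuration
#'
#' All thresholds of the analysis are configuration, not constants: the zone
#' scheme, integration rule, total-fluorescence mode, HSA calibration
#' coefficient, ROUT Q and the seed. When `mapsCsv`/`manifestCsv` are NULL
#' the spectral cohort is simulated with [simulateCohort()]; when `ctCsv` is
#' NULL the qPCR table is simulated from the panel's reference group means.
#'
#' @param outDir output directory (created if needed).
#' @param mapsCsv optional long-format CSV of measured maps.
#' @param manifestCsv optional manifest CSV (required with `mapsCsv`).
#' @param ctCsv optional Ct table CSV.
#' @param seed integer seed driving every stochastic stage.
#' @param nF,nN,nM simulated group sizes.
#' @param noiseSd,mediumCv,embryoCv generator noise/variability settings.
#' @param duplicateSd technical-duplicate SD (cycles) for simulated qPCR.
#' @param hsaCoefficient HSA calibration (a.u. per g/L).
#' @param totalMode `"full_integral"` or `"z3_peak"`.
#' @param rule zone integration rule.
#' @param normalize free-medium normalization, `"subtract"` or `"ratio"`.
#' @param routQ ROUT FDR level in percent.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(outDir, mapsCsv = NULL, manifestCsv = NULL,
                      ctCsv = NULL, seed = 1, nF = 30, nN = 36, nM = 3,
                      noiseSd = 2, mediumCv = 0.02, embryoCv = 0.15,
                      duplicateSd = 0.15,
                      hsaCoefficient = 1000,
                      totalMode = "full_integral", rule = "trapezoid",
                      normalize = "subtract", routQ = 1) {
  structure(list(outDir = outDir, mapsCsv = mapsCsv,
                 manifestCsv = manifestCsv, ctCsv = ctCsv,
                 seed = as.integer(seed), nF = nF, nN = nN, nM = nM,
                 noiseSd = noiseSd, mediumCv = mediumCv,
                 embryoCv = embryoCv, duplicateSd = duplicateSd,
                 hsaCoefficient = hsaCoefficient, totalMode = totalMode,
                 rule = rule, normalize = normalize, routQ = routQ),
            class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [runConfig()] arguments.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

#' Run the full SECM analysis pipeline
#'
#' simulate/load -> profile -> zones -> ratios -> decompose -> stats ->
#' qPCR table, writing `profiles.csv`, `zones.csv`, `ratios.csv`,
#' `table2.csv`, `stats.csv`, `table1.csv` and `report.json` into the
#' configured output directory. Identical configuration and seed give a
#' byte-identical `report.json`. Any stage failure aborts with the stage
#' name and removes the partial outputs.
#'
#' @param config a [runConfig()] or [readRunConfig()] result.
#' @return the report, invisibly (a named list mirroring `report.json`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  out <- function(f) file.path(config$outDir, f)
  stage <- "setup"
  tryCatch({
    emit <- function(writer, f) {
      writer(out(f)); written <<- c(written, out(f))
    }
    stage <- "simulate/load"
    if (is.null(config$mapsCsv)) {
      cohort <- simulateCohort(cohortSpec(
        nF = config$nF, nN = config$nN, nM = config$nM,
        noiseSd = config$noiseSd, mediumCv = config$mediumCv,
        embryoCv = config$embryoCv,
        hsaCoefficient = config$hsaCoefficient, seed = config$seed))
      maps <- cohort$maps
      manifest <- cohort$manifest
    } else {
      if (is.null(config$manifestCsv))
        stop("manifestCsv is required when mapsCsv is given")
      maps <- readMapsCsv(config$mapsCsv)
      manifest <- readManifest(config$manifestCsv)
    }
    if (!any(manifest$group == "M"))
      stop("no free-medium baseline: manifest has no M samples")

    stage <- "profile"
    profiles <- cohortProfiles(maps)
    emit(function(f) writeProfilesCsv(profiles, f), "profiles.csv")

    stage <- "zones"
    zonesRaw <- cohortZoneTable(profiles, manifest, rule = config$rule)
    zonesNorm <- cohortZoneTable(profiles, manifest, rule = config$rule,
                                 normalize = config$normalize)
    emit(function(f) utils::write.csv(zonesNorm, f, row.names = FALSE),
         "zones.csv")

    stage <- "ratios"
    ratios <- ratioFeatures(zonesRaw)
    emit(function(f) utils::write.csv(ratios, f, row.names = FALSE),
         "ratios.csv")
    trends <- lapply(intersect(c("F", "N"), unique(ratios$group)),
                     function(g) c(group = g, groupTrend(ratios, g)))

    stage <- "decompose"
    calib <- hsaCalibration(config$hsaCoefficient,
                            "photometric HSA calibration")
    dec <- decomposeCohort(profiles, manifest, calib, mode = config$totalMode)
    emit(function(f) utils::write.csv(
      cbind(quantity = rownames(dec$table), dec$table), f,
      row.names = FALSE), "table2.csv")

    stage <- "stats"
    stats <- zoneStats(zonesNorm, Q = config$routQ)
    emit(function(f) utils::write.csv(stats, f, row.names = FALSE),
         "stats.csv")

    stage <- "qpcr"
    ct <- if (is.null(config$ctCsv)) {
      ids <- names(.DEFAULT_TRUE_EXPR)
      do.call(rbind, lapply(seq_along(ids), function(i)
        simulateCtTable(.DEFAULT_TRUE_EXPR[[i]],
                        duplicateSd = config$duplicateSd, mirnaId = ids[i],
                        seed = config$seed + i)))
    } else readCtTable(config$ctCsv)
    table1 <- relativeExpressionTable(ct)
    emit(function(f) utils::write.csv(table1, f, row.names = FALSE),
         "table1.csv")
    percentDiffs <- lapply(unique(table1$mirna_id), function(id) {
      d <- table1[table1$mirna_id == id, ]
      pairs <- list(c("5D N", "5D F"), c("5D F", "4D F"),
                    c("5D N", "4D N"), c("4D N", "5D N"),
                    c("4D N", "4D F"), c("4D F", "5D F"))
      vals <- lapply(pairs, function(pr) {
        if (!all(pr %in% d$group)) return(NULL)
        v <- percentDifference(d$log2_rel_expr[d$group == pr[1L]],
                               d$log2_rel_expr[d$group == pr[2L]])
        list(comparison = paste(pr, collapse = " vs "),
             percent = round(as.numeric(v), 1))
      })
      list(mirna = id, differences = Filter(Negate(is.null), vals))
    })

    stage <- "report"
    addStats <- stats[stats$channel == "additive", ]
    report <- list(
      seed = config$seed,
      n = as.list(table(manifest$group)),
      total_mode = config$totalMode,
      table2 = as.list(dec$table),
      activity_ratio_NF = dec$ratioNF,
      zone_p_additive = as.list(setNames(addStats$p, addStats$zone)),
      zone_test = as.list(setNames(addStats$test, addStats$zone)),
      ratio_trends = trends,
      percent_differences = percentDiffs)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, out("report.json"))
    invisible(report)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
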