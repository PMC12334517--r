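#' @include AllClasses.R
NULL

## full-precision decimal rendering so written maps round-trip bit-identically
.fmtNum <- function(x) sprintf("%.17g", x)

.readCsvStrict <- function(path, required, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = colClasses)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  df
}

.checkNumericColumn <- function(df, col, path) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !(is.na(df[[col]]) | df[[col]] == ""))
  if (length(bad))
    stop("non-numeric value in column '", col, "', row ", bad[1L],
         " of ", basename(path))
  x
}

#' Read one synchronous map from CSV
#'
#' Two dialects are supported. `long`: columns `sample_id`, `solvent`,
#' `excitation_nm`, `delta_lambda_nm`, `intensity`, one row per grid cell,
#' holding exactly one (sample, solvent) map (use [readMapsCsv()] for files
#' holding several). `wide`: one intensity matrix per file with an
#' `excitation_nm` first column and one `dl_<offset>` column per offset,
#' accompanied by a JSON sidecar `<path>.meta.json` carrying `sample_id`,
#' `solvent` and `dilution_factor`.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @return a validated [SynchronousMap-class].
#' @seealso [writeMapCsv()]
#' @export
readMapCsv <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    maps <- readMapsCsv(path)
    if (length(maps) != 1L)
      stop(basename(path), " holds ", length(maps),
           " (sample, solvent) maps; readMapCsv expects exactly one")
    return(maps[[1L]])
  }
  df <- .readCsvStrict(path, "excitation_nm")
  dlCols <- grep("^dl_", names(df), value = TRUE)
  if (!length(dlCols)) stop("wide dialect needs dl_<offset> columns in ", path)
  sidecar <- paste0(path, ".meta.json")
  if (!file.exists(sidecar)) stop("missing sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ex <- .checkNumericColumn(df, "excitation_nm", path)
  dl <- as.numeric(sub("^dl_", "", dlCols))
  o <- order(dl)
  mat <- as.matrix(df[, dlCols[o], drop = FALSE])
  storage.mode(mat) <- "double"
  dimnames(mat) <- NULL
  synchronousMap(meta$sample_id, meta$solvent, ex, dl[o], mat,
                 dilutionFactor = meta$dilution_factor %||% 2500,
                 meta = meta$meta %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read every synchronous map from a long-format CSV
#'
#' @param path long-format CSV (columns `sample_id`, `solvent`,
#'   `excitation_nm`, `delta_lambda_nm`, `intensity`).
#' @return named list of [SynchronousMap-class] objects, names
#'   `<sample_id>.<solvent>`.
#' @export
readMapsCsv <- function(path) {
  req <- c("sample_id", "solvent", "excitation_nm", "delta_lambda_nm",
           "intensity")
  df <- .readCsvStrict(path, req, colClasses = "character")
  if (!nrow(df)) stop("no data rows in ", path)
  badSolv <- which(!df$solvent %in% .SOLVENTS)
  if (length(badSolv))
    stop("unknown solvent '", df$solvent[badSolv[1L]], "' in row ",
         badSolv[1L], " of ", basename(path))
  for (col in c("excitation_nm", "delta_lambda_nm", "intensity"))
    df[[col]] <- .checkNumericColumn(df, col, path)
  key <- paste(df$sample_id, df$solvent, sep = ".")
  maps <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    dup <- anyDuplicated(d[, c("excitation_nm", "delta_lambda_nm")])
    if (dup)
      stop("duplicate (excitation_nm, delta_lambda_nm) pair for sample '",
           d$sample_id[1L], "' (", d$solvent[1L], "): ",
           d$excitation_nm[dup], "/", d$delta_lambda_nm[dup], " nm")
    ex <- sort(unique(d$excitation_nm))
    dl <- sort(unique(d$delta_lambda_nm))
    if (nrow(d) != length(ex) * length(dl))
      stop("incomplete grid for sample '", d$sample_id[1L], "' (",
           d$solvent[1L], "'): ", nrow(d), " cells, expected ",
           length(ex) * length(dl))
    mat <- matrix(NA_real_, length(ex), length(dl))
    mat[cbind(match(d$excitation_nm, ex), match(d$delta_lambda_nm, dl))] <-
      d$intensity
    synchronousMap(d$sample_id[1L], d$solvent[1L], ex, dl, mat)
  })
  names(maps) <- unique(key)
  maps
}

#' Write synchronous maps to CSV
#'
#' `writeMapCsv()` writes one map; in the wide dialect it also writes the
#' `<path>.meta.json` sidecar. `writeMapsCsv()` writes a list of maps into a
#' single long-format CSV. Values are rendered at full double precision so a
#' read/write cycle is value-identical.
#'
#' @param map a [SynchronousMap-class] (`writeMapCsv`).
#' @param maps list of maps (`writeMapsCsv`).
#' @param path output file path.
#' @param dialect `"long"` or `"wide"`.
#' @return the path, invisibly.
#' @export
writeMapCsv <- function(map, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(is(map, "SynchronousMap"))
  if (dialect == "long") return(writeMapsCsv(list(map), path))
  dl <- map@deltaLambdaNm
  df <- cbind(.fmtNum(map@excitationNm),
              matrix(.fmtNum(map@intensity), nrow(map@intensity)))
  colnames(df) <- c("excitation_nm", paste0("dl_", dl))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sample_id = map@sampleId, solvent = map@solvent,
         dilution_factor = map@dilutionFactor, meta = map@meta),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMapCsv
#' @export
writeMapsCsv <- function(maps, path) {
  rows <- lapply(maps, function(map) {
    stopifnot(is(map, "SynchronousMap"))
    grid <- expand.grid(excitation_nm = map@excitationNm,
                        delta_lambda_nm = map@deltaLambdaNm,
                        KEEP.OUT.ATTRS = FALSE)
    data.frame(sample_id = map@sampleId, solvent = map@solvent,
               excitation_nm = .fmtNum(grid$excitation_nm),
               delta_lambda_nm = .fmtNum(grid$delta_lambda_nm),
               intensity = .fmtNum(as.vector(map@intensity)),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest lists each sample with its outcome group (`F` successful
#' implantation, `N` unsuccessful, `M` free/unused culture medium), the
#' transfer day (4 or 5; empty for M) and the photometrically determined HSA
#' concentration in g/L (may be empty).
#'
#' @param path CSV with columns `sample_id`, `group`, `day`, `hsa_conc`.
#' @return data.frame with columns `sample_id` (character), `group`
#'   (character), `day` (integer, NA for M), `hsa_conc` (numeric).
#' @export
readManifest <- function(path) {
  ## read everything as text: single-letter group codes ("F") must not be
  ## parsed as logicals
  df <- .readCsvStrict(path, c("sample_id", "group", "day", "hsa_conc"),
                       colClasses = "character")
  if (!nrow(df)) {
    warning("manifest ", basename(path), " has no data rows")
    return(data.frame(sample_id = character(), group = character(),
                      day = integer(), hsa_conc = numeric()))
  }
  validateManifest(data.frame(
    sample_id = as.character(df$sample_id),
    group = as.character(df$group),
    day = suppressWarnings(as.integer(df$day)),
    hsa_conc = .checkNumericColumn(df, "hsa_conc", path),
    stringsAsFactors = FALSE))
}

#' Validate a sample manifest data.frame
#'
#' @param manifest data.frame with columns `sample_id`, `group`, `day`,
#'   `hsa_conc`.
#' @return the manifest, invisibly validated (errors name the offending row).
#' @export
validateManifest <- function(manifest) {
  req <- c("sample_id", "group", "day", "hsa_conc")
  missing <- setdiff(req, names(manifest))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(!manifest$group %in% c("F", "N", "M"))
  if (length(bad))
    stop("unknown group '", manifest$group[bad[1L]], "' in manifest row ",
         bad[1L])
  dup <- which(duplicated(manifest$sample_id))
  if (length(dup))
    stop("duplicate sample_id '", manifest$sample_id[dup[1L]],
         "' in manifest row ", dup[1L])
  bad <- which(!is.na(manifest$day) & !manifest$day %in% c(4L, 5L))
  if (length(bad))
    stop("day must be 4, 5 or empty; offending manifest row ", bad[1L])
  bad <- which(manifest$group == "M" & !is.na(manifest$day))
  if (length(bad))
    stop("free-medium (M) sample with a transfer day in manifest row ",
         bad[1L])
  bad <- which(!is.na(manifest$hsa_conc) & manifest$hsa_conc < 0)
  if (length(bad))
    stop("negative hsa_conc in manifest row ", bad[1L])
  manifest
}

#' @rdname readManifest
#' @param manifest manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
  validateManifest(manifest)
  out <- manifest
  out$day <- ifelse(is.na(out$day), "", as.character(out$day))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-group and per-day sample counts of a manifest
#'
#' @param manifest manifest data.frame.
#' @return data.frame with columns `group`, `day` and `n`.
#' @export
manifestCounts <- function(manifest) {
  key <- paste(manifest$group,
               ifelse(is.na(manifest$day), "", manifest$day))
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  data.frame(group = vapply(parts, `[`, "", 1L),
             day = suppressWarnings(as.integer(vapply(
               parts, function(p) if (length(p) > 1L) p[2L] else "", ""))),
             n = as.integer(tab), stringsAsFactors = FALSE)
}

#' Read a qPCR Ct table
#'
#' @param path CSV with columns `mirna_id`, `group`, `replicate`, `ct`.
#' @return validated data.frame of Ct records; Ct values must lie in (0, 45).
#' @export
readCtTable <- function(path) {
  df <- .readCsvStrict(path, c("mirna_id", "group", "replicate", "ct"),
                       colClasses = "character")
  df$ct <- .checkNumericColumn(df, "ct", path)
  df$replicate <- .checkNumericColumn(df, "replicate", path)
  validateCtTable(df)
}

#' Validate a Ct record data.frame
#'
#' @param ct data.frame with columns `mirna_id`, `group`, `replicate`, `ct`.
#' @return the data.frame, after checks (Ct in (0, 45), at least one
#'   replicate per (miRNA, group)).
#' @export
validateCtTable <- function(ct) {
  req <- c("mirna_id", "group", "replicate", "ct")
  missing <- setdiff(req, names(ct))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(ct$ct) | ct$ct <= 0 | ct$ct >= 45)
  if (length(bad))
    stop("Ct out of (0, 45) in row ", bad[1L])
  ct
}
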