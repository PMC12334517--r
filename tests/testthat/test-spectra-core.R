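test_that("map objects enforce their physical invariants", {
  m <- synchronousMap("s1", "PBS", 280, 70, matrix(5))
  expect_s4_class(m, "SynchronousMap")
  expect_identical(intensityMatrix(m)[1, 1], 5)
  expect_error(synchronousMap("s1", "PBS", 280, 70, matrix(-1)), ">= 0")
  expect_error(synchronousMap("s1", "water", 280, 70, matrix(1)), "solvent")
  expect_error(synchronousMap("s1", "PBS", 150, 70, matrix(1)), "200")
  expect_error(synchronousMap("s1", "PBS", 280, 20, matrix(1)), "30")
  expect_error(synchronousMap("s1", "PBS", c(280, 281), 70, matrix(1)),
               "grids imply")
  expect_error(synchronousMap("s1", "PBS", c(280, 280.5, 280.2), 70,
                              matrix(1:3, 3)), "strictly increasing")
})

test_that("a single-cell long CSV reads back as a 1x1 map", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,solvent,excitation_nm,delta_lambda_nm,intensity",
               "s1,PBS,280,70,5.0"), f)
  m <- readMapCsv(f, dialect = "long")
  expect_identical(sampleId(m), "s1")
  expect_identical(solventName(m), "PBS")
  expect_equal(dim(intensityMatrix(m)), c(1L, 1L))
  expect_identical(intensityMatrix(m)[1, 1], 5)
})

test_that("long and wide dialects round-trip a full-size map value-identically", {
  set.seed(101)
  ex <- seq(200, 400, by = 1)
  dl <- seq(30, 170, by = 10)
  m <- synchronousMap("rt", "PBS_DMSO", ex, dl,
                      matrix(runif(length(ex) * length(dl), 0, 900),
                             length(ex), length(dl)),
                      dilutionFactor = 2500, meta = "slit 5 nm")
  for (dialect in c("long", "wide")) {
    f <- withr::local_tempfile(fileext = ".csv")
    writeMapCsv(m, f, dialect = dialect)
    m2 <- readMapCsv(f, dialect = dialect)
    expect_identical(excitationNm(m2), excitationNm(m))
    expect_identical(deltaLambdaNm(m2), deltaLambdaNm(m))
    expect_identical(intensityMatrix(m2), unname(intensityMatrix(m)))
    expect_identical(sampleId(m2), "rt")
    expect_identical(solventName(m2), "PBS_DMSO")
    ## second cycle is bit-identical on disk too
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeMapCsv(m2, f2, dialect = dialect)
    expect_identical(readLines(f2), readLines(f))
  }
})

test_that("malformed map CSVs fail with errors naming the offence", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,solvent,excitation_nm,delta_lambda_nm,intensity",
               "s1,PBS,280,70,-1.0"), f)
  expect_error(readMapCsv(f), ">= 0")
  writeLines(c("sample_id,solvent,excitation_nm,delta_lambda_nm,intensity",
               "s1,PBS,280,70,5.0", "s1,PBS,280,70,6.0"), f)
  expect_error(readMapCsv(f), "duplicate")
  writeLines(c("sample_id,solvent,excitation_nm,intensity",
               "s1,PBS,280,5.0"), f)
  expect_error(readMapCsv(f), "delta_lambda_nm")
  writeLines(c("sample_id,solvent,excitation_nm,delta_lambda_nm,intensity",
               "s1,PBS,280,70,oops"), f)
  expect_error(readMapCsv(f), "row 1")
  writeLines(c("sample_id,solvent,excitation_nm,delta_lambda_nm,intensity",
               "s1,ethanol,280,70,5.0"), f)
  expect_error(readMapCsv(f), "solvent")
})

test_that("manifest reading reproduces the study group/day layout", {
  mk <- function(g, d, n, off = 0)
    data.frame(sample_id = sprintf("%s%d_%02d", g, d, seq_len(n) + off),
               group = g, day = d, hsa_conc = 44.8)
  manifest <- rbind(mk("F", 4L, 6), mk("F", 5L, 24),
                    mk("N", 4L, 7), mk("N", 5L, 29),
                    data.frame(sample_id = paste0("M", 1:3), group = "M",
                               day = NA_integer_, hsa_conc = 19.6))
  f <- withr::local_tempfile(fileext = ".csv")
  writeManifest(manifest, f)
  got <- readManifest(f)
  expect_equal(nrow(got), 69)
  counts <- manifestCounts(got)
  lookup <- function(g, d) counts$n[counts$group == g &
    (is.na(counts$day) & is.na(d) | !is.na(counts$day) & counts$day %in% d)]
  expect_equal(lookup("F", 4L), 6L)
  expect_equal(lookup("F", 5L), 24L)
  expect_equal(lookup("N", 4L), 7L)
  expect_equal(lookup("N", 5L), 29L)
  expect_equal(lookup("M", NA), 3L)
})

test_that("manifest validation rejects bad rows and warns on empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,group,day,hsa_conc", f)
  expect_warning(empty <- readManifest(f), "no data rows")
  expect_equal(nrow(empty), 0)
  writeLines(c("sample_id,group,day,hsa_conc", "s1,X,4,44"), f)
  expect_error(readManifest(f), "unknown group 'X' in manifest row 1")
  writeLines(c("sample_id,group,day,hsa_conc", "s1,F,4,44", "s1,F,5,44"), f)
  expect_error(readManifest(f), "duplicate sample_id 's1'")
  writeLines(c("sample_id,group,day,hsa_conc", "m1,M,4,19"), f)
  expect_error(readManifest(f), "free-medium")
})

test_that("the default zone scheme is the Z1-Z5 partition of 200-400 nm", {
  zs <- defaultZoneScheme()
  expect_identical(zoneNames(zs), paste0("Z", 1:5))
  widths <- zoneUpper(zs) - zoneLower(zs)
  expect_equal(widths, c(30, 30, 30, 40, 70))
  expect_equal(sum(widths), 200)
  expect_error(zoneScheme("Z1", 200, 390), "cover")
  expect_error(zoneScheme(c("Z1", "Z2"), c(200, 250), c(240, 400)),
               "contiguous")
})
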