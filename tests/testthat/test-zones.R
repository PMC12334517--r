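test_that("zone integrals of flat profiles are the zone widths times c", {
  p <- constProfile(3.5)
  z <- integrateZones(p)
  expect_equal(unname(z), 3.5 * c(30, 30, 30, 40, 70))
  expect_equal(names(z), paste0("Z", 1:5))
  expect_true(all(integrateZones(constProfile(0)) == 0))
})

test_that("zone integration conserves the full-range integral exactly", {
  set.seed(77)
  for (step in c(1, 2, 5)) {
    grid <- seq(200, 400, by = step)
    p <- vecProfile(runif(length(grid), 0, 50), grid)
    z <- integrateZones(p)
    full <- sum(diff(grid) * (head(intensityValues(p), -1) +
                                tail(intensityValues(p), -1)) / 2)
    expect_equal(sum(z), full, tolerance = 1e-13)
  }
})

test_that("trapezoid zone values match a fine-grid quadrature oracle", {
  grid <- seq(200, 400, by = 1)
  tri <- vecProfile(pmax(0, 100 - abs(grid - 280)), grid)
  z <- integrateZones(tri)
  ## oracle: Riemann midpoint sum on a 0.001 nm grid of the same
  ## piecewise-linear function
  zs <- defaultZoneScheme()
  oracle <- vapply(seq_along(zoneNames(zs)), function(i) {
    xs <- seq(zoneLower(zs)[i], zoneUpper(zs)[i], by = 0.001)
    mid <- (xs[-1] + xs[-length(xs)]) / 2
    sum(pmax(0, 100 - abs(mid - 280)) * diff(xs))
  }, 0)
  expect_equal(unname(z), oracle, tolerance = 1e-3)
})

test_that("sum and mean aggregation rules follow half-open membership", {
  grid <- seq(200, 400, by = 1)
  p <- vecProfile(rep(1, length(grid)), grid)
  zsum <- integrateZones(p, rule = "sum")
  ## Z1 owns 200..229 (30 points); Z5 owns 330..400 inclusive (71 points)
  expect_equal(unname(zsum), c(30, 30, 30, 40, 71))
  expect_true(all(integrateZones(p, rule = "mean") == 1))
})

test_that("profiles that do not span the scheme are refused", {
  short <- vecProfile(rep(1, 101), seq(250, 350, by = 1))
  expect_error(integrateZones(short), "does not cover zone")
})

test_that("background subtraction and solvent sums behave element-wise", {
  z <- c(Z1 = 100, Z2 = 50, Z3 = 20, Z4 = 10, Z5 = 5)
  m <- c(Z1 = 40, Z2 = 10, Z3 = 5, Z4 = 2, Z5 = 1)
  expect_equal(unname(subtractBackground(z, z)), rep(0, 5),
               ignore_attr = TRUE)
  d <- subtractBackground(z, m)
  expect_equal(unname(d)[1:2], c(60, 40))
  expect_true(attr(d, "backgroundSubtracted"))
  expect_error(subtractBackground(z, m[c(2, 1, 3, 4, 5)]), "mismatch")
  expect_equal(unname(sumSolventZones(z, m)), unname(z + m))
  expect_equal(sumSolventZones(z, 0 * z), z)
})

test_that("solvent zone sums commute with additive-profile integration", {
  grid <- seq(200, 400, by = 1)
  set.seed(15)
  p <- vecProfile(runif(length(grid), 0, 30), grid, solvent = "PBS")
  q <- vecProfile(runif(length(grid), 0, 30), grid, solvent = "PBS_DMSO")
  viaSum <- sumSolventZones(integrateZones(p), integrateZones(q))
  viaAdditive <- integrateZones(additiveProfile(p, q))
  expect_equal(viaSum, viaAdditive, tolerance = 1e-13)
})

test_that("subtracting the free-medium mean isolates the embryo signal", {
  ## expected: additive zone integrals of the embryo bands alone (HSA
  ## concentrations are made identical across groups here, so they cancel)
  spec0 <- noiselessSpec(nF = 2, nN = 0, nM = 2,
                         hsaConcMean = c(F = 30, N = 30, M = 30))
  co0 <- simulateCohort(spec0)
  zn0 <- cohortZoneTable(cohortProfiles(co0$maps), co0$manifest,
                         normalize = "subtract")
  embryoOnly <- simulateMap(spec0$embryoBands, "PBS",
                            spec0$excitationNm, spec0$deltaLambdaNm)
  embryoZ <- 2 * integrateZones(maxProjection(embryoOnly))  # both solvents
  fRows <- zn0$channel == "additive" & zn0$group == "F" &
    zn0$sample_id == "F01"
  got <- setNames(zn0$value[fRows], zn0$zone[fRows])[names(embryoZ)]
  expect_equal(got, embryoZ, tolerance = 1e-3)
  expect_true(all(abs(got - embryoZ) / max(embryoZ) < 0.01))
})

test_that("zone-ratio features and group trends compute as defined", {
  mkRow <- function(id, grp, ch, zone, val)
    data.frame(sample_id = id, group = grp, channel = ch, zone = zone,
               value = val, background_subtracted = FALSE)
  tab <- rbind(mkRow("a", "F", "PBS", "Z1", 30),
               mkRow("a", "F", "PBS", "Z2", 20),
               mkRow("a", "F", "PBS_DMSO", "Z4", 40),
               mkRow("a", "F", "PBS_DMSO", "Z5", 60),
               mkRow("b", "N", "PBS", "Z1", 5),
               mkRow("b", "N", "PBS", "Z2", 5),
               mkRow("b", "N", "PBS_DMSO", "Z4", 5),
               mkRow("b", "N", "PBS_DMSO", "Z5", 5))
  pts <- ratioFeatures(tab)
  expect_equal(pts$x[pts$sample_id == "a"], 0.5)
  expect_equal(pts$y[pts$sample_id == "a"], 0.5)
  expect_equal(pts$x[pts$sample_id == "b"], 1)
  expect_equal(pts$y[pts$sample_id == "b"], 1)

  bad <- tab
  bad$value[bad$sample_id == "b" & bad$zone == "Z5"] <- 0
  expect_warning(pts2 <- ratioFeatures(bad), "non-positive")
  expect_false("b" %in% pts2$sample_id)

  pts3 <- data.frame(sample_id = letters[1:4], group = "F",
                     x = c(0, 1, 2, 3), y = 2 * c(0, 1, 2, 3) + 1)
  tr <- groupTrend(pts3, "F")
  expect_equal(tr$slope, 2, tolerance = 1e-12)
  expect_equal(tr$intercept, 1, tolerance = 1e-12)
  expect_equal(tr$r, 1, tolerance = 1e-12)

  two <- data.frame(sample_id = c("a", "b"), group = "N",
                    x = c(1, 3), y = c(5, 1))
  tr2 <- groupTrend(two, "N")
  expect_equal(tr2$slope, -2)
  expect_equal(tr2$intercept, 7)
  expect_error(groupTrend(two[1, ], "N"), "at least 2")
  flat <- data.frame(sample_id = c("a", "b"), group = "N",
                     x = c(1, 1), y = c(0, 1))
  expect_error(groupTrend(flat, "N"), "variance")
})

test_that("ratio features separate F from N on the default cohort", {
  co <- simulateCohort(cohortSpec(seed = 19))
  zn <- cohortZoneTable(cohortProfiles(co$maps), co$manifest)
  pts <- ratioFeatures(zn)
  ## the N effect raises Z1(PBS) while leaving Z5(PBS:DMSO) alone, shifting
  ## the N cloud to larger x; the fitted lines must differ
  expect_gt(median(pts$x[pts$group == "N"]),
            median(pts$x[pts$group == "F"]))
  trF <- groupTrend(pts, "F")
  trN <- groupTrend(pts, "N")
  expect_true(is.finite(trF$slope) && is.finite(trN$slope))
  expect_false(isTRUE(all.equal(trF$intercept, trN$intercept)))
})
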