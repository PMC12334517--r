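# shared fixture builders; everything is generated in code at test time

constProfile <- function(value, sampleId = "s", solvent = "PBS",
                         grid = seq(200, 400, by = 1),
                         provenance = "projection") {
  fluorescenceProfile(sampleId, solvent, grid, rep(value, length(grid)),
                      provenance = provenance)
}

vecProfile <- function(values, grid = seq(200, 400, by = 1),
                       sampleId = "s", solvent = "PBS",
                       provenance = "projection", bg = FALSE) {
  fluorescenceProfile(sampleId, solvent, grid, values,
                      provenance = provenance, backgroundSubtracted = bg)
}

## deterministic noiseless cohort spec (no variability sources at all)
noiselessSpec <- function(nF = 2, nN = 2, nM = 2, seed = 3, noiseSd = 0,
                          ...) {
  cohortSpec(nF = nF, nN = nN, nM = nM, noiseSd = noiseSd, mediumCv = 0,
             embryoCv = 0, hsaConcSd = c(F = 0, N = 0, M = 0),
             seed = seed, ...)
}

## independent brute-force reference of the constant-model ROUT procedure:
## grid-search robust center, percentile RSDR, t-tail p, step-down FDR scan
routReference <- function(values, Q = 1) {
  n <- length(values)
  rsdrOf <- function(center)
    unname(quantile(abs(values - center), 0.6827)) * n / (n - 1)
  center <- median(values)
  rsdr <- rsdrOf(center)
  for (it in 1:50) {
    grid <- seq(min(values), max(values), length.out = 20001)
    merit <- vapply(grid, function(m)
      sum(log(1 + ((values - m) / rsdr)^2)), 0)
    centerNew <- grid[which.min(merit)]
    rsdrNew <- rsdrOf(centerNew)
    if (abs(centerNew - center) < 1e-8 * (1 + abs(center))) {
      center <- centerNew
      break
    }
    center <- centerNew
    if (rsdrNew > 0) rsdr <- rsdrNew
  }
  p <- 2 * pt(-abs(values - center) / rsdr, df = n - 1)
  ord <- order(p)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    if (p[ord[i]] < (Q / 100) * i / n) flagged[ord[i]] <- TRUE else break
  }
  flagged
}
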