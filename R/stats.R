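#' @include utils.R
NULL

#' ROUT outlier detection for a column of values (constant model)
#'
#' Robust regression and OUTlier removal specialised to a one-parameter
#' (constant) model: (1) the robust center minimises the Lorentzian merit
#' `sum(log(1 + (residual/RSDR)^2))`, initialised at the median and iterated
#' with the scale estimate; (2) the robust standard deviation of the
#' residuals (RSDR) is the 68.27th percentile of the absolute residuals
#' times `n/(n-1)`; (3) each residual is converted to a two-tailed t-tail
#' probability with `n - 1` degrees of freedom and screened largest-first
#' under the false-discovery-rate rule at level `Q` percent: the i-th
#' largest residual is flagged while `p < (Q/100) * i / n`, stopping at the
#' first failure.
#'
#' @param values numeric vector, `n >= 3`.
#' @param Q FDR level in percent, in (0, 100); default 1 (the Q = 1\% used
#'   for the fluorescence datasets).
#' @return an `OutlierReport` list: `values`, logical `outlier`, `Q`,
#'   `center`, `rsdr`, `p` (per-value tail probability).
#' @export
routOutliers <- function(values, Q = 1) {
  if (!is.numeric(values) || length(values) < 3L)
    stop("ROUT needs at least 3 numeric values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (Q <= 0 || Q >= 100) stop("Q must be in (0, 100) percent")
  n <- length(values)
  rsdrOf <- function(center)
    unname(quantile(abs(values - center), 0.6827)) * n / (n - 1)
  center <- median(values)
  rsdr <- rsdrOf(center)
  if (rsdr > 0) {
    for (it in 1:25) {
      centerNew <- optimize(function(m)
        sum(log1p(((values - m) / rsdr)^2)), range(values))$minimum
      rsdrNew <- rsdrOf(centerNew)
      done <- abs(centerNew - center) < 1e-10 * (1 + abs(center))
      center <- centerNew
      if (rsdrNew > 0) rsdr <- rsdrNew
      if (done) break
    }
  }
  resid <- values - center
  if (rsdr == 0) {
    ## massive tie: points identical to the center carry no evidence;
    ## any distinct value is infinitely many RSDRs away (p = 0)
    p <- ifelse(resid == 0, 1, 0)
  } else {
    p <- 2 * pt(-abs(resid) / rsdr, df = n - 1)
  }
  ord <- order(p)  # largest residuals first
  flagged <- logical(n)
  for (i in seq_len(n)) {
    if (p[ord[i]] < (Q / 100) * i / n) flagged[ord[i]] <- TRUE else break
  }
  structure(list(values = values, outlier = flagged, Q = Q,
                 center = center, rsdr = rsdr, p = p),
            class = "OutlierReport")
}

#' @export
print.OutlierReport <- function(x, ...) {
  cat(sprintf("ROUT (Q = %g%%): %d of %d value(s) flagged; center %.4g, RSDR %.4g\n",
              x$Q, sum(x$outlier), length(x$values), x$center, x$rsdr))
  invisible(x)
}

#' Drop ROUT-flagged outliers from a vector
#'
#' @param values numeric vector.
#' @param Q FDR level in percent.
#' @return the values with flagged outliers removed.
#' @export
removeOutliers <- function(values, Q = 1) {
  if (length(values) < 3L || length(unique(values)) == 1L) return(values)
  rep <- routOutliers(values, Q)
  values[!rep$outlier]
}

#' Shapiro-Wilk normality gate
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return the Shapiro-Wilk p-value. Downstream comparisons use the
#'   Mann-Whitney U test when any group's p is below 0.05, the unpaired
#'   t-test otherwise.
#' @export
shapiroGate <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  shapiro.test(values)$p.value
}

#' Mann-Whitney U comparison of two groups
#'
#' Exact two-tailed p when both groups are small and tie-free, a
#' tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param labels group labels for reporting.
#' @return a `GroupComparison` list: `labels`, `n`, `test`, `statistic`
#'   (U for the first group), `p` (two-tailed), `exact`.
#' @export
mannWhitney <- function(a, b, labels = c("a", "b")) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  U <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && n1 < 50 && n2 < 50
  if (exact) {
    p <- wilcox.test(a, b, exact = TRUE)$p.value
  } else {
    ## tie-corrected normal approximation with continuity correction
    tieTab <- table(ranks)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tieTab^3 - tieTab) /
         ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(list(labels = labels, n = c(n1, n2), test = "Mann-Whitney U",
                 statistic = unname(U), p = unname(p), exact = exact),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("%s: %s (n=%d) vs %s (n=%d), statistic %.4g, two-tailed p = %.4g%s\n",
              x$test, x$labels[1L], x$n[1L], x$labels[2L], x$n[2L],
              x$statistic, x$p,
              if (!is.null(x$exact) && x$exact) " (exact)" else ""))
  invisible(x)
}

#' Percent difference with the larger value as denominator
#'
#' `100 * (max(a,b) - min(a,b)) / |max(a,b)|`, the formula that reproduces
#' the reported expression increases (137\%, 104.6\%, 44.4\%, 38.5\%) from
#' the published relative-expression means. Symmetric in argument order and
#' invariant to positive rescaling.
#'
#' @param a,b real values; `max(a, b)` must be non-zero.
#' @param digits decimals for the `"reported"` attribute (default 1).
#' @return the percent difference (full precision), with a rounded
#'   `"reported"` attribute.
#' @export
percentDifference <- function(a, b, digits = 1) {
  hi <- max(a, b); lo <- min(a, b)
  if (hi == 0) stop("percent difference undefined: larger value is 0")
  out <- 100 * (hi - lo) / abs(hi)
  attr(out, "reported") <- round(out, digits)
  out
}

#' Per-zone F vs N comparisons after outlier removal and a normality gate
#'
#' For every (channel, zone) cell of a normalized zone table: ROUT outlier
#' removal per group at level `Q`, Shapiro-Wilk on each cleaned group, then
#' a Mann-Whitney U test if either group looks non-normal (p < 0.05) and an
#' unpaired t-test otherwise.
#'
#' @param zoneTable zone table from [cohortZoneTable()] (typically
#'   normalized with `normalize = "subtract"`).
#' @param Q ROUT FDR level in percent.
#' @param channels channels to test (default all present except none).
#' @return data.frame: `channel`, `zone`, `n_F`, `n_N`, `shapiro_p_F`,
#'   `shapiro_p_N`, `test`, `statistic`, `p`, `median_F`, `median_N`.
#' @export
zoneStats <- function(zoneTable, Q = 1, channels = NULL) {
  if (is.null(channels)) channels <- unique(zoneTable$channel)
  cells <- unique(zoneTable[zoneTable$channel %in% channels,
                            c("channel", "zone")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- zoneTable$channel == cells$channel[i] &
      zoneTable$zone == cells$zone[i]
    f <- removeOutliers(zoneTable$value[sel & zoneTable$group == "F"], Q)
    n <- removeOutliers(zoneTable$value[sel & zoneTable$group == "N"], Q)
    spF <- shapiroGate(f); spN <- shapiroGate(n)
    if (spF < 0.05 || spN < 0.05) {
      cmp <- mannWhitney(f, n, labels = c("F", "N"))
      stat <- cmp$statistic; p <- cmp$p; test <- cmp$test
    } else {
      tt <- t.test(f, n, var.equal = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
      test <- "unpaired t"
    }
    data.frame(channel = cells$channel[i], zone = cells$zone[i],
               n_F = length(f), n_N = length(n),
               shapiro_p_F = spF, shapiro_p_N = spN,
               test = test, statistic = stat, p = p,
               median_F = median(f), median_N = median(n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
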