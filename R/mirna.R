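#' @include stats.R
NULL

#' Medium-normalized relative expression of one miRNA in one group
#'
#' Cell-free culture medium has no housekeeping gene, so relative expression
#' is the log2 fold change versus the free-medium baseline:
#' `mean Ct(M) - mean Ct(group)` (one qPCR cycle = one log2 unit). Negative
#' values indicate higher signal in the free medium than in the SECM. The
#' SEM is propagated from the technical duplicates of both the group and the
#' baseline.
#'
#' @param ctRecords Ct record data.frame (`mirna_id`, `group`, `replicate`,
#'   `ct`).
#' @param mirna miRNA identifier to extract.
#' @param group group label (e.g. `"4D F"`, `"5D N"`); `"M"` returns 0 by
#'   construction.
#' @param baselineGroup label of the free-medium baseline (default `"M"`).
#' @return a `RelativeExpression` list: `mirna`, `group`, `log2RelExpr`,
#'   `sem`, `n` (duplicates in the group).
#' @export
relativeExpression <- function(ctRecords, mirna, group,
                               baselineGroup = "M") {
  validateCtTable(ctRecords)
  ctM <- ctRecords$ct[ctRecords$mirna_id == mirna &
                        ctRecords$group == baselineGroup]
  if (!length(ctM))
    stop("no free-medium (", baselineGroup, ") baseline records for ", mirna)
  ctG <- ctRecords$ct[ctRecords$mirna_id == mirna &
                        ctRecords$group == group]
  if (!length(ctG))
    stop("no records for ", mirna, " in group '", group, "'")
  semOf <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  structure(list(mirna = mirna, group = group,
                 log2RelExpr = mean(ctM) - mean(ctG),
                 sem = sqrt(semOf(ctM)^2 + semOf(ctG)^2),
                 n = length(ctG)),
            class = "RelativeExpression")
}

#' @export
print.RelativeExpression <- function(x, ...) {
  cat(sprintf("%s in %s: log2 relative expression %.3f +/- %.3f (n = %d duplicates)\n",
              x$mirna, x$group, x$log2RelExpr, x$sem, x$n))
  invisible(x)
}

#' Relative-expression table for every (miRNA, group) combination
#'
#' @param ctRecords Ct record data.frame.
#' @param baselineGroup free-medium baseline label.
#' @return data.frame with columns `mirna_id`, `group`, `log2_rel_expr`,
#'   `sem`, `n` (the baseline group itself is omitted).
#' @export
relativeExpressionTable <- function(ctRecords, baselineGroup = "M") {
  combos <- unique(ctRecords[ctRecords$group != baselineGroup,
                             c("mirna_id", "group")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    re <- relativeExpression(ctRecords, combos$mirna_id[i],
                             combos$group[i], baselineGroup)
    data.frame(mirna_id = re$mirna, group = re$group,
               log2_rel_expr = re$log2RelExpr, sem = re$sem, n = re$n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-tailed unpaired t-test
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @param welch use the Welch (unequal-variance) form; default FALSE
#'   (classical equal-variance t).
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
unpairedTTest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("unpaired t-test needs n >= 2 per group")
  tt <- t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Percent difference between two group expression values
#'
#' Delegates to [percentDifference()] (max-denominator formula).
#'
#' @param exprA,exprB relative-expression values (or `RelativeExpression`
#'   objects).
#' @return the percent difference.
#' @export
groupPercentReport <- function(exprA, exprB) {
  val <- function(e) if (inherits(e, "RelativeExpression")) e$log2RelExpr
                     else e
  percentDifference(val(exprA), val(exprB))
}
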