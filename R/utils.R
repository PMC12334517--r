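# internal numerics shared across modules

#' @importFrom stats approx median optimize pt quantile rnorm sd shapiro.test
#'   t.test wilcox.test lm coef cor complete.cases setNames
NULL

.SOLVENTS <- c("PBS", "PBS_DMSO")

#' Trapezoidal integral of y over x
#' @noRd
.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

## trapezoid over [lo, hi] with linear interpolation at the cut points;
## grid points exactly on a boundary are shared by both sides, so summing
## adjacent intervals telescopes to the full-range integral.
.trapzSegment <- function(x, y, lo, hi) {
  if (lo < x[1L] || hi > x[length(x)])
    stop("integration interval [", lo, ", ", hi, "] outside profile span [",
         x[1L], ", ", x[length(x)], "]")
  inner <- x > lo & x < hi
  xs <- c(lo, x[inner], hi)
  ys <- c(approx(x, y, xout = lo)$y, y[inner], approx(x, y, xout = hi)$y)
  .trapz(xs, ys)
}

## evaluate expr with a temporary RNG seed, restoring the caller's stream
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.assertNumericScalar <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower)
    stop("'", name, "' must be a finite numeric scalar",
         if (lower > -Inf) paste0(" >= ", lower))
  invisible(x)
}
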