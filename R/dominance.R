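# First- and second-order stochastic dominance on empirical distributions.
#
# Both tests work on the exact empirical (step) CDFs of two samples,
# evaluated on the merged grid of all observed values. The second-order
# test integrates the step CDFs exactly: between consecutive grid points
# the CDF is constant, so each segment contributes F(x_i) * (x_{i+1} -
# x_i). This equals the exact value of the integral for step functions
# (no quadrature error), and therefore matches a brute-force expected-
# shortfall computation.

#' Empirical cumulative distribution of a sample
#'
#' @param values Numeric vector (NAs are an error).
#' @return Object of class `empirical_cdf` with sorted `values`, `n`, and
#'   an evaluator usable through [cdf_eval()].
#' @export
empirical_cdf <- function(values) {
  if (anyNA(values)) stop("values must not contain NA")
  v <- sort(as.numeric(values))
  structure(list(values = v, n = length(v)), class = "empirical_cdf")
}

#' Evaluate an empirical CDF
#'
#' Right-continuous step function: `P(X <= x)`.
#'
#' @param cdf An [empirical_cdf()].
#' @param x Numeric vector of evaluation points.
#' @return `P(X <= x)` for each element of `x`.
#' @export
cdf_eval <- function(cdf, x) {
  findInterval(x, cdf$values) / cdf$n
}

#' @export
print.empirical_cdf <- function(x, ...) {
  cat(sprintf("empirical CDF on %d observations in [%g, %g]\n",
              x$n, x$values[1], x$values[x$n]))
  invisible(x)
}

merged_grid <- function(a, b) sort(unique(c(a$values, b$values)))

#' First-order stochastic dominance of A over B
#'
#' A dominates B (A FOSD B) when `F_A(x) <= F_B(x)` everywhere with strict
#' inequality somewhere: A's outcomes are unambiguously preferred by every
#' monotone decision maker. Checked on the merged grid of both samples,
#' where all CDF changes occur.
#'
#' @param a,b Samples (numeric vectors) or [empirical_cdf()] objects; `a`
#'   is the candidate dominant distribution.
#' @param tol_le Tolerance allowed on the `<=` direction (default 1e-12).
#' @param tol_strict Margin required for the strict part (default 1e-9).
#' @return List: `dominates` (logical), `max_violation` (largest amount by
#'   which `F_A` exceeds `F_B`), `max_gap` (largest `F_B - F_A`), `grid`.
#' @export
fosd <- function(a, b, tol_le = 1e-12, tol_strict = 1e-9) {
  if (!inherits(a, "empirical_cdf")) a <- empirical_cdf(a)
  if (!inherits(b, "empirical_cdf")) b <- empirical_cdf(b)
  g <- merged_grid(a, b)
  fa <- cdf_eval(a, g)
  fb <- cdf_eval(b, g)
  d <- fa - fb
  list(dominates = max(d) <= tol_le && min(d) < -tol_strict,
       max_violation = max(d), max_gap = -min(d), grid = g)
}

# Exact integral of an empirical CDF from the grid minimum up to each grid
# point: cumulative sum of F(x_i) * (x_{i+1} - x_i) over the segments.
cdf_integral <- function(f, g) {
  k <- length(g)
  if (k == 1) return(0)
  c(0, cumsum(f[-k] * diff(g)))
}

#' Second-order stochastic dominance of A over B
#'
#' A dominates B (A SOSD B) when the integrated CDFs satisfy
#' `int F_A <= int F_B` at every point with strict inequality somewhere:
#' A is preferred by every risk-averse decision maker. The integrals of
#' the empirical step CDFs are computed exactly on the merged grid.
#'
#' @inheritParams fosd
#' @return List: `dominates` (logical), `max_violation`, `max_gap`,
#'   `grid`, and the integrated CDFs `int_a`, `int_b`.
#' @export
sosd <- function(a, b, tol_le = 1e-12, tol_strict = 1e-9) {
  if (!inherits(a, "empirical_cdf")) a <- empirical_cdf(a)
  if (!inherits(b, "empirical_cdf")) b <- empirical_cdf(b)
  g <- merged_grid(a, b)
  ia <- cdf_integral(cdf_eval(a, g), g)
  ib <- cdf_integral(cdf_eval(b, g), g)
  d <- ia - ib
  list(dominates = max(d) <= tol_le && min(d) < -tol_strict,
       max_violation = max(d), max_gap = -min(d), grid = g,
       int_a = ia, int_b = ib)
}

#' Pairwise dominance report across scenarios
#'
#' Tests first- and second-order dominance for every ordered pair of the
#' supplied samples and tabulates the verdicts.
#'
#' @param samples Named list of numeric vectors (e.g. net profit draws per
#'   scenario).
#' @param ... Tolerances forwarded to [fosd()] and [sosd()].
#' @return `data.frame` with columns `a`, `b`, `fosd`, `sosd`,
#'   `fosd_violation`, `sosd_violation`.
#' @export
dominance_report <- function(samples, ...) {
  nms <- names(samples)
  if (is.null(nms) || any(nms == "")) stop("samples must be a named list")
  cdfs <- lapply(samples, empirical_cdf)
  rows <- list()
  for (i in nms) for (j in nms) {
    if (i == j) next
    f <- fosd(cdfs[[i]], cdfs[[j]], ...)
    s <- sosd(cdfs[[i]], cdfs[[j]], ...)
    rows[[paste(i, j)]] <- data.frame(
      a = i, b = j, fosd = f$dominates, sosd = s$dominates,
      fosd_violation = f$max_violation, sosd_violation = s$max_violation)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exceedance table of empirical distributions
#'
#' Probability that each sample exceeds each of a set of thresholds.
#'
#' @param samples Named list of numeric vectors.
#' @param thresholds Numeric vector of thresholds.
#' @return `data.frame` with a `threshold` column and one `P(X > t)`
#'   column per sample.
#' @export
exceedance_table <- function(samples, thresholds) {
  out <- data.frame(threshold = thresholds)
  for (nm in names(samples)) {
    cdf <- empirical_cdf(samples[[nm]])
    out[[nm]] <- 1 - cdf_eval(cdf, thresholds)
  }
  out
}

#' Write empirical CDFs of several samples as one CSV
#'
#' Evaluates every sample's CDF on the merged grid of all samples so the
#' curves can be plotted or compared directly.
#'
#' @param samples Named list of numeric vectors.
#' @param path Output CSV path.
#' @return Invisibly, the `data.frame` written.
#' @export
write_cdf_table <- function(samples, path) {
  cdfs <- lapply(samples, empirical_cdf)
  g <- sort(unique(unlist(lapply(cdfs, `[[`, "values"))))
  out <- data.frame(value = g)
  for (nm in names(cdfs)) out[[nm]] <- cdf_eval(cdfs[[nm]], g)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
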