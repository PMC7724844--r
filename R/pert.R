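#' Fit a bounded distribution to a (min, mean, max) triple
#'
#' Fits a modified-PERT distribution on `[min, max]` whose mean equals the
#' stated mean. For the standard shape `lambda = 4` the mode has the closed
#' form `mode = ((lambda + 2) * mean - min - max) / lambda`; when the stated
#' mean sits so close to a bound that this mode would fall outside
#' `[min, max]`, the mode is pinned at that bound and the shape `lambda`
#' solved from the mean instead. A degenerate triple (`min == max`) yields a
#' point mass.
#'
#' @param triple Numeric vector `c(min, mean, max)`.
#' @param name Optional variable name carried along for reporting.
#' @param lambda PERT shape parameter (default 4).
#' @return An object of class `stochastic_input` with elements `family`
#'   (`"pert"` or `"point"`), `min`, `mode`, `max`, `lambda`, `mean`,
#'   and the beta shapes `shape1`, `shape2`.
#' @export
fit_distribution <- function(triple, name = NULL, lambda = 4) {
  stopifnot(is.numeric(triple), length(triple) == 3L)
  mn <- triple[[1]]; mu <- triple[[2]]; mx <- triple[[3]]
  if (mn > mx) stop("min must not exceed max")
  if (mu < mn || mu > mx) stop("mean outside [min, max]")
  if (mn == mx) {
    return(structure(list(name = name, family = "point", min = mn, mode = mn,
                          max = mx, lambda = lambda, mean = mu,
                          shape1 = NA_real_, shape2 = NA_real_),
                     class = "stochastic_input"))
  }
  mode <- ((lambda + 2) * mu - mn - mx) / lambda
  if (mode < mn) {          # mean very close to min: pin mode, solve lambda
    mode <- mn
    lambda <- (mn + mx - 2 * mu) / (mu - mn)
  } else if (mode > mx) {   # mean very close to max
    mode <- mx
    lambda <- (2 * mu - mn - mx) / (mx - mu)
  }
  r <- mx - mn
  shape1 <- 1 + lambda * (mode - mn) / r
  shape2 <- 1 + lambda * (mx - mode) / r
  structure(list(name = name, family = "pert", min = mn, mode = mode,
                 max = mx, lambda = lambda, mean = mu,
                 shape1 = shape1, shape2 = shape2),
            class = "stochastic_input")
}

#' @export
print.stochastic_input <- function(x, ...) {
  if (x$family == "point") {
    cat(sprintf("%s: point mass at %.6g\n",
                if (is.null(x$name)) "input" else x$name, x$mean))
  } else {
    cat(sprintf("%s: PERT(min %.6g, mode %.6g, max %.6g, lambda %.3g), mean %.6g\n",
                if (is.null(x$name)) "input" else x$name,
                x$min, x$mode, x$max, x$lambda, x$mean))
  }
  invisible(x)
}

#' Theoretical mean of a fitted bounded input
#' @param spec A `stochastic_input` from [fit_distribution()].
#' @return The distribution mean.
#' @export
pert_mean <- function(spec) {
  stopifnot(inherits(spec, "stochastic_input"))
  if (spec$family == "point") return(spec$min)
  spec$min + (spec$max - spec$min) * spec$shape1 / (spec$shape1 + spec$shape2)
}

#' Sample from a fitted bounded input
#'
#' Draws from the beta representation of the modified-PERT distribution (or
#' repeats the point mass). Uses the current RNG stream.
#'
#' @param n Number of draws.
#' @param spec A `stochastic_input` from [fit_distribution()].
#' @return Numeric vector of length `n`, always within `[min, max]`.
#' @export
rpert <- function(n, spec) {
  stopifnot(inherits(spec, "stochastic_input"))
  if (spec$family == "point") return(rep(spec$min, n))
  spec$min + (spec$max - spec$min) * stats::rbeta(n, spec$shape1, spec$shape2)
}

# Truncated-normal draws via inverse CDF (exact, vectorised).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be non-negative")
  if (lower >= upper) stop("infeasible truncation bounds")
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("point mass outside truncation bounds")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12)
    stop("truncation bounds leave negligible probability mass")
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}
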