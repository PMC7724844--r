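#' Gompertz growth parameters
#'
#' Container for the three parameters of the Gompertz growth function
#' \deqn{BW(t) = W_0 \exp[\mu_0 (1 - e^{-Dt})/D]}
#' where `W0` is body weight at age 0 (kg), `mu0` the log relative growth
#' rate at age 0 (1/day) and `D` the decay slope of the log relative growth
#' rate (1/day). The mature (asymptotic) weight is `W0 * exp(mu0/D)`.
#'
#' @param w0 Body weight at age 0, kg. Must be positive.
#' @param mu0 Log relative growth rate at age 0, 1/day. Must be positive.
#' @param d Decay slope, 1/day. Must be positive.
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(w0, mu0, d) {
  stopifnot(is.numeric(w0), is.numeric(mu0), is.numeric(d))
  if (w0 <= 0 || mu0 <= 0 || d <= 0)
    stop("all Gompertz parameters must be positive")
  structure(list(w0 = w0, mu0 = mu0, d = d,
                 mature_weight = w0 * exp(mu0 / d)),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf(
    "Gompertz growth: W0 = %.4g kg, mu0 = %.5g /d, D = %.5g /d (mature %.1f kg)\n",
    x$w0, x$mu0, x$d, x$mature_weight))
  invisible(x)
}

#' Gompertz body weight at a given age
#'
#' @param t Age in days (vectorised, must be non-negative).
#' @param p A [gompertz_params()] object.
#' @return Body weight in kg.
#' @export
gompertz_bw <- function(t, p) {
  stopifnot(inherits(p, "gompertz_params"))
  if (any(t < 0)) stop("age must be non-negative")
  p$w0 * exp(p$mu0 * (1 - exp(-p$d * t)) / p$d)
}

#' Age at which the growth curve reaches a given weight
#'
#' Inverts the Gompertz curve. Weights must lie strictly between 0 and the
#' mature weight.
#'
#' @param w Body weight in kg (vectorised).
#' @param p A [gompertz_params()] object.
#' @return Age in days.
#' @export
gompertz_inverse <- function(w, p) {
  stopifnot(inherits(p, "gompertz_params"))
  if (any(w <= 0) || any(w >= p$mature_weight))
    stop("weight outside curve range (0, mature_weight)")
  k <- p$mu0 / p$d            # = log(mature/W0)
  -log(log(p$mature_weight / w) / k) / p$d
}

#' Calibrate a Gompertz curve to a weaning anchor and an ADG level
#'
#' Solves for the curve passing through `(age_wean, w_wean)` and
#' `(age_sale, w_sale)` with a fixed mature (asymptotic) weight, where the
#' sale age is implied by the scenario's wean-to-finish average daily gain:
#' `age_sale = age_wean + (w_sale - w_wean) * 1000 / adg`.
#'
#' With the asymptote fixed the two anchors determine the remaining two
#' parameters in closed form: writing `BW(t) = A exp(-k e^{-Dt})` with
#' `k = mu0/D = log(A/W0)`, the anchor ratio gives
#' `D = log(log(A/w_wean) / log(A/w_sale)) / (age_sale - age_wean)` and then
#' `k = log(A/w_wean) * exp(D * age_wean)`.
#'
#' @param adg Wean-to-finish average daily gain, g/day.
#' @param w_wean Weaning weight, kg (default 7).
#' @param age_wean Weaning age, days (default 28).
#' @param w_sale Live weight at sale, kg (default 110.8).
#' @param mature_weight Asymptotic weight, kg (default 230; typical of
#'   modern genotypes, and results over the 7-110.8 kg span are insensitive
#'   to it).
#' @return A [gompertz_params()] object with attribute `age_sale` (days).
#' @export
calibrate_gompertz <- function(adg, w_wean = 7, age_wean = 28,
                               w_sale = 110.8, mature_weight = 230) {
  if (adg <= 0) stop("adg must be positive")
  if (!(w_wean < w_sale && w_sale < mature_weight))
    stop("need w_wean < w_sale < mature_weight")
  age_sale <- age_wean + (w_sale - w_wean) * 1000 / adg
  if (age_sale <= age_wean) stop("adg implies a non-positive growing period")
  d <- log(log(mature_weight / w_wean) / log(mature_weight / w_sale)) /
    (age_sale - age_wean)
  k <- log(mature_weight / w_wean) * exp(d * age_wean)
  p <- gompertz_params(w0 = mature_weight * exp(-k), mu0 = k * d, d = d)
  attr(p, "age_sale") <- age_sale
  p
}

#' Days spent in each growth stage
#'
#' Inverts the growth curve at the weaning weight, each transfer weight and
#' the sale weight, and returns the day span of each stage. With the default
#' transfer weights these are the weaner stage-1 (7-19 kg), weaner stage-2
#' (19-38 kg) and finisher (38 kg to sale) spans.
#'
#' @param p A [gompertz_params()] object.
#' @param transfer_weights Stage-transfer live weights, kg, strictly
#'   increasing (default `c(19, 38)`). May be empty for a single span.
#' @param w_wean Weight at the start of the first stage, kg.
#' @param w_sale Weight at sale, kg.
#' @return Named numeric vector of day spans; they sum to
#'   `age(w_sale) - age(w_wean)`.
#' @export
stage_durations <- function(p, transfer_weights = c(19, 38),
                            w_wean = 7, w_sale = 110.8) {
  w <- c(w_wean, transfer_weights, w_sale)
  if (any(diff(w) <= 0)) stop("weights must be strictly increasing")
  ages <- gompertz_inverse(w, p)
  spans <- diff(ages)
  names(spans) <- if (length(transfer_weights) == 2L)
    c("weaner1", "weaner2", "finisher")
  else paste0("stage", seq_along(spans))
  spans
}

#' Age at slaughter in whole weeks
#'
#' Computes the exact age at which the sale weight is reached at a given
#' wean-to-finish ADG, and converts to whole weeks under a configurable
#' rounding rule. Pigs are sold in weekly batches so the default rule rounds
#' up; `"exact"` returns the unrounded age in weeks.
#'
#' @param adg Average daily gain, g/day.
#' @param weaning_age_days,weaning_weight_kg,sale_weight_kg Growth anchors.
#' @param rounding One of `"ceiling"`, `"nearest"`, `"floor"`, `"exact"`.
#' @return Age at slaughter in weeks.
#' @export
slaughter_age_weeks <- function(adg, weaning_age_days = 28,
                                weaning_weight_kg = 7,
                                sale_weight_kg = 110.8,
                                rounding = c("ceiling", "nearest",
                                             "floor", "exact")) {
  rounding <- match.arg(rounding)
  if (adg <= 0) stop("adg must be positive")
  age_days <- weaning_age_days +
    (sale_weight_kg - weaning_weight_kg) * 1000 / adg
  wk <- age_days / 7
  switch(rounding,
         ceiling = ceiling(wk),
         nearest = round(wk),
         floor = floor(wk),
         exact = wk)
}
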