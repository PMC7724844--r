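# Independent reference implementations used as oracles. Deliberately
# naive and O(n^2)-ish: their value is that they share no code with the
# package internals.

# Exhaustive best split: try every predictor and every midpoint between
# consecutive distinct values, computing both child SSEs from scratch.
oracle_best_split <- function(y, x, min_leaf) {
  sse <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  best <- NULL
  for (var in names(x)) {
    ux <- sort(unique(x[[var]]))
    if (length(ux) < 2) next
    for (i in seq_len(length(ux) - 1)) {
      thr <- (ux[i] + ux[i + 1]) / 2
      left <- x[[var]] < thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      red <- sse(y) - sse(y[left]) - sse(y[!left])
      if (is.null(best) || red > best$sse_reduction + 1e-9) {
        best <- list(var = var, threshold = thr, sse_reduction = red)
      }
    }
  }
  if (!is.null(best) && best$sse_reduction <= 1e-10 * max(sse(y), 1))
    best <- NULL
  best
}

# Expected-shortfall identity: the integral of the empirical CDF of a
# sample v up to x equals mean((x - v)^+). Second-order dominance verdict
# by comparing shortfalls at every merged sample point.
oracle_sosd <- function(a, b, tol_le = 1e-12, tol_strict = 1e-9) {
  shortfall <- function(v, x)
    vapply(x, function(xi) mean(pmax(0, xi - v)), 0)
  g <- sort(unique(c(a, b)))
  d <- shortfall(a, g) - shortfall(b, g)
  max(d) <= tol_le && min(d) < -tol_strict
}

reference_account_lplsc <- function() {
  pnl_account(
    sales = c(finisher_pigs = 2582595, culled_sows = 40972),
    variable = c(gestation_feed = 126460, lactation_feed = 94750,
                 creep_feed = 71235, link_feed = 84540,
                 weaner_feed = 296067, finisher_feed = 753112,
                 replacement_gilts = 60232, dead_disposal = 9170,
                 healthcare = 41961, reproduction = 37309,
                 manure = 16093, transport = 18183),
    fixed = c(admin = 2500, energy = 81614, insurance = 20533,
              repairs = 20533, epa_subscription = 10000, labour = 279136,
              loan_interest = 75780, depreciation = 175021),
    pigs_sold = 19188, meat_sold_kg = 1595100, scenario = "LPLSC")
}

reference_account_hp <- function() {
  pnl_account(
    sales = c(finisher_pigs = 2518277, culled_sows = 41059),
    variable = c(gestation_feed = 126348, lactation_feed = 94674,
                 creep_feed = 70506, link_feed = 83676,
                 weaner_feed = 326804, finisher_feed = 803019,
                 replacement_gilts = 60219, dead_disposal = 12213,
                 healthcare = 41547, reproduction = 37308,
                 manure = 15706, transport = 17603),
    fixed = c(admin = 2500, energy = 81614, insurance = 20533,
              repairs = 20533, epa_subscription = 10000, labour = 279136,
              loan_interest = 75780, depreciation = 175021),
    pigs_sold = 18564, meat_sold_kg = 1555400, scenario = "HP")
}
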