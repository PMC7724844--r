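# Weekly steady-state herd-flow model of a farrow-to-finish farm, and the
# feed-demand model driven by the Gompertz growth curve.
#
# The farm runs weekly farrowing batches in steady state, so every weekly
# flow is constant and annual aggregates are 52 times the weekly flows.
# Pigs move through four post-farrowing stages: suckling piglets (to weaning
# at 28 d / 7 kg), weaner stage 1 (7-19 kg), weaner stage 2 (19-38 kg) and
# finishers (38 kg to the 110.8 kg sale weight). Stage-transfer and sale
# ages are rounded up to whole weeks (pigs are housed and moved in weekly
# batches); body weights and stage spans come from the calibrated Gompertz
# curve. Within-stage mortality is modelled as a constant daily hazard
# calibrated so that the stage's recorded mortality rate is realised over
# the weight-defined stage span, and applied over the housed (whole-week)
# residence -- slower-growing pigs are housed longer and accrue
# proportionally more risk. The single recorded weaner mortality rate is a
# per-stage rate and applies in each of the two weaner stages.

#' Feed-demand parameters
#'
#' Per-diet coefficients of the feed-demand model. Weaner and finisher daily
#' intake is proportional to metabolic body weight,
#' `intake (kg/d) = scale * BW^0.75`, integrated over the housed stage
#' window on the scenario's growth curve; creep and link feed are fixed
#' amounts per weaned pig (they vary little with growth rate); sow feed is a
#' fixed amount per sow-year. Defaults are calibrated so that the
#' low-pleurisy / low-scar reference scenario reproduces 2017 Irish
#' farrow-to-finish feed tonnages; see [calibrate_feed_demand()].
#'
#' @param weaner_scale,finisher_scale Intake scale, kg feed per kg^0.75
#'   metabolic weight per day, for the weaner and finisher diets.
#' @param creep_kg_weaned,link_kg_weaned Creep and link feed, kg per weaned
#'   pig.
#' @param gestation_kg_sow_year,lactation_kg_sow_year Sow feed, kg per sow
#'   per year.
#' @return An object of class `feed_params`.
#' @export
feed_params <- function(weaner_scale, finisher_scale,
                        creep_kg_weaned, link_kg_weaned,
                        gestation_kg_sow_year, lactation_kg_sow_year) {
  vals <- c(weaner_scale, finisher_scale, creep_kg_weaned, link_kg_weaned,
            gestation_kg_sow_year, lactation_kg_sow_year)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all feed-demand coefficients must be positive")
  structure(list(weaner_scale = weaner_scale,
                 finisher_scale = finisher_scale,
                 creep_kg_weaned = creep_kg_weaned,
                 link_kg_weaned = link_kg_weaned,
                 gestation_kg_sow_year = gestation_kg_sow_year,
                 lactation_kg_sow_year = lactation_kg_sow_year),
            class = "feed_params")
}

#' @rdname feed_params
#' @export
default_feed_params <- function() {
  feed_params(weaner_scale = 0.09178835924,
              finisher_scale = 0.08172831437,
              creep_kg_weaned = 3.773533871,
              link_kg_weaned = 6.946621861,
              gestation_kg_sow_year = 742.4450549,
              lactation_kg_sow_year = 505.2197802)
}

#' Scenario specification
#'
#' Full parameterisation of one simulated 728-sow farrow-to-finish farm: the
#' wean-to-finish ADG level, the nine biological parameters as
#' `(min, mean, max)` triples (means drive the deterministic run; the full
#' triples parameterise the stochastic inputs of the risk analysis), growth
#' anchors, prices and fixed costs.
#'
#' @param name Scenario label.
#' @param adg Wean-to-finish average daily gain, g/day.
#' @param bio Named list of `(min, mean, max)` triples for: farrowing_rate,
#'   litters_per_sow_year, born_alive_per_litter, sow_culling_rate,
#'   sow_mortality, piglet_mortality, weaner_mortality, finisher_mortality,
#'   dressing_pct. A plain number is treated as a degenerate triple.
#' @param herd_size Number of sows (default 728).
#' @param condemnation_rate Carcass condemnation, % (default 1.5), applied
#'   to carcass weight before pricing.
#' @param weaning_age_days,weaning_weight_kg,sale_weight_kg,mature_weight_kg
#'   Growth anchors (defaults 28 d, 7 kg, 110.8 kg, 230 kg).
#' @param transfer_weights_kg Stage-transfer weights (default `c(19, 38)`).
#' @param prices A [price_schedule()].
#' @param fixed_costs A [fixed_cost_schedule()].
#' @param feed A [feed_params()].
#' @param slaughter_rounding Rounding rule for the sale week (default
#'   `"ceiling"`; see [slaughter_age_weeks()]).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, adg, bio, herd_size = 728,
                          condemnation_rate = 1.5,
                          weaning_age_days = 28, weaning_weight_kg = 7,
                          sale_weight_kg = 110.8, mature_weight_kg = 230,
                          transfer_weights_kg = c(19, 38),
                          prices = price_schedule(),
                          fixed_costs = fixed_cost_schedule(),
                          feed = default_feed_params(),
                          slaughter_rounding = "ceiling") {
  need <- .indicator_names
  bio <- lapply(bio, function(v) if (length(v) == 1L) rep(v, 3) else v)
  missing <- setdiff(need, names(bio))
  if (length(missing))
    stop("bio triples missing: ", paste(missing, collapse = ", "))
  for (nm in need) {
    tr <- bio[[nm]]
    if (length(tr) != 3L || !(tr[1] <= tr[2] && tr[2] <= tr[3]))
      stop("bio triple ", nm, " must satisfy min <= mean <= max")
  }
  rates <- c("farrowing_rate", "sow_culling_rate", "sow_mortality",
             "piglet_mortality", "weaner_mortality", "finisher_mortality",
             "dressing_pct")
  for (nm in rates)
    if (any(bio[[nm]] < 0 | bio[[nm]] > 100))
      stop(nm, " must lie in [0, 100]")
  if (adg <= 0 || herd_size <= 0) stop("adg and herd_size must be positive")
  if (any(diff(c(weaning_weight_kg, transfer_weights_kg,
                 sale_weight_kg)) <= 0))
    stop("transfer weights must be strictly increasing and below sale weight")
  structure(list(name = name, adg = adg, bio = bio[need],
                 herd_size = herd_size,
                 condemnation_rate = condemnation_rate,
                 weaning_age_days = weaning_age_days,
                 weaning_weight_kg = weaning_weight_kg,
                 sale_weight_kg = sale_weight_kg,
                 mature_weight_kg = mature_weight_kg,
                 transfer_weights_kg = transfer_weights_kg,
                 prices = prices, fixed_costs = fixed_costs, feed = feed,
                 slaughter_rounding = slaughter_rounding),
            class = "scenario_spec")
}

#' Default lesion scenarios
#'
#' The three 728-sow scenarios defined by the lesion-prevalence cut-offs:
#' `LPLSC` (pleurisy < 25%, scars < 8%, ADG 760 g/d), `LPHSC` (pleurisy
#' < 25%, scars >= 8%, ADG 725) and `HP` (pleurisy >= 25%, ADG 671), each
#' parameterised with its cluster's biological `(min, mean, max)` triples
#' from 2017 farm records.
#'
#' @param ... Passed on to [scenario_spec()] (e.g. a shared price schedule).
#' @return Named list of three [scenario_spec()] objects.
#' @export
default_scenarios <- function(...) {
  adg <- c(LPLSC = 760, LPHSC = 725, HP = 671)
  out <- lapply(names(adg), function(nm)
    scenario_spec(nm, adg[[nm]], .bio_triples[[nm]], ...))
  names(out) <- names(adg)
  out
}

bio_mean <- function(spec, nm) spec$bio[[nm]][2]

# Growth-derived constants of a scenario: Gompertz parameters, whole-week
# housing boundaries, weight-defined stage spans, and per-pig metabolic-
# weight integrals over the housed weaner and finisher feeding windows.
feed_windows <- function(spec) {
  p <- calibrate_gompertz(spec$adg, spec$weaning_weight_kg,
                          spec$weaning_age_days, spec$sale_weight_kg,
                          spec$mature_weight_kg)
  age_sale <- attr(p, "age_sale")
  tw <- gompertz_inverse(spec$transfer_weights_kg, p)
  t19 <- tw[1]; t38 <- tw[2]
  wean_day <- spec$weaning_age_days
  weaner_weeks <- ceiling((t38 - wean_day) / 7)
  wend <- wean_day + 7 * weaner_weeks
  sale_week <- slaughter_age_weeks(spec$adg, wean_day,
                                   spec$weaning_weight_kg,
                                   spec$sale_weight_kg,
                                   spec$slaughter_rounding)
  sale_day <- 7 * sale_week
  if (sale_day > 52 * 7) stop("stage durations exceed one year")
  if (sale_day <= wend) stop("finisher window is empty; check adg")
  mw_integral <- function(a, b) {
    tt <- seq(a, b, by = 0.1)
    v <- gompertz_bw(tt, p)^0.75
    (sum(v) - (v[1] + v[length(v)]) / 2) * 0.1
  }
  list(params = p, age_sale = age_sale, t19 = t19, t38 = t38,
       wean_day = wean_day, wend = wend, sale_day = sale_day,
       sale_week = sale_week,
       I_weaner = mw_integral(wean_day, wend),
       I_finisher = mw_integral(wend, sale_day))
}

# Core annual arithmetic, vectorised over biological-parameter overrides so
# the Monte Carlo engine can run all iterations at once. `ov` is a named
# list of equal-length vectors overriding the scenario's mean parameters.
annual_core <- function(spec, ov = list(), fw = feed_windows(spec),
                        check = TRUE) {
  g <- function(nm) if (!is.null(ov[[nm]])) ov[[nm]] else bio_mean(spec, nm)
  fr <- g("farrowing_rate"); lsy <- g("litters_per_sow_year")
  ba <- g("born_alive_per_litter"); cull <- g("sow_culling_rate")
  sm <- g("sow_mortality"); pm <- g("piglet_mortality")
  wm <- g("weaner_mortality"); fm <- g("finisher_mortality")
  dress <- g("dressing_pct")
  sows <- spec$herd_size
  farrowings <- sows * lsy
  services <- farrowings / (fr / 100)
  born <- farrowings * ba
  weaned <- born * (1 - pm / 100)
  # constant daily hazards over weight-defined spans, applied over housed
  # (whole-week) spans; the weaner rate applies once per weaner stage
  h_w <- -2 * log(1 - wm / 100) / (fw$t38 - fw$wean_day)
  h_f <- -log(1 - fm / 100) / (fw$age_sale - fw$t38)
  surv_w <- exp(-h_w * (fw$wend - fw$wean_day))
  surv_f <- exp(-h_f * (fw$sale_day - fw$wend))
  enter_finisher <- weaned * surv_w
  finished <- enter_finisher * surv_f
  gilts <- sows * (cull + sm) / 100
  pigs_sold <- finished - gilts
  if (check && any(pigs_sold < 0))
    stop("negative replacement demand: gilts required exceed finished pigs")
  meat_kg <- pigs_sold * spec$sale_weight_kg * dress / 100 *
    (1 - spec$condemnation_rate / 100)
  fd <- spec$feed
  feed_t <- list(
    gestation = rep_len(sows * fd$gestation_kg_sow_year / 1000,
                        length(pigs_sold)),
    lactation = rep_len(sows * fd$lactation_kg_sow_year / 1000,
                        length(pigs_sold)),
    creep = weaned * fd$creep_kg_weaned / 1000,
    link = weaned * fd$link_kg_weaned / 1000,
    weaner = weaned * (1 + surv_w) / 2 * fd$weaner_scale * fw$I_weaner / 1000,
    finisher = enter_finisher * (1 + surv_f) / 2 * fd$finisher_scale *
      fw$I_finisher / 1000)
  list(farrowings = farrowings, services = services, born = born,
       weaned = weaned, enter_finisher = enter_finisher,
       finished = finished, gilts = gilts, pigs_sold = pigs_sold,
       meat_kg = meat_kg,
       cull_sows_sold = sows * cull / 100, sow_deaths = sows * sm / 100,
       deaths_piglet = born - weaned,
       deaths_weaner = weaned - enter_finisher,
       deaths_finisher = enter_finisher - finished,
       feed_t = feed_t, dressing = dress)
}

#' Simulate one steady-state year of a farrow-to-finish farm
#'
#' Runs the weekly steady-state herd-flow model for the scenario and returns
#' the 52-week state table together with the annual physical aggregates
#' (head sold, meat sold, per-diet feed usage, deaths for disposal,
#' replacement gilts). Weekly flows are constant (one representative year of
#' an ongoing farm); fractional animals are carried in the flows and only
#' rounded for reporting.
#'
#' @param spec A [scenario_spec()].
#' @return List with elements `weekly` (a 52-row `data.frame` of class
#'   counts and flows) and `annual` (an `annual_physical` object).
#' @export
simulate_year <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  fw <- feed_windows(spec)
  a <- annual_core(spec, fw = fw)
  annual <- structure(
    list(scenario = spec$name,
         pigs_sold = a$pigs_sold, meat_sold_kg = a$meat_kg,
         cull_sows_sold = a$cull_sows_sold,
         feed_usage_t = unlist(a$feed_t),
         deaths = c(piglet = a$deaths_piglet, weaner = a$deaths_weaner,
                    finisher = a$deaths_finisher, sow = a$sow_deaths),
         replacement_gilts = a$gilts,
         born_alive = a$born, weaned = a$weaned,
         farrowings = a$farrowings, services = a$services,
         sale_week = fw$sale_week, windows = fw),
    class = "annual_physical")
  list(weekly = weekly_states(spec, a, fw), annual = annual)
}

# Constant weekly steady-state table. For each stage the weekly outflow is
# inflow minus deaths, so stock(t+1) = stock(t) + in - out - deaths holds
# exactly with constant stocks.
weekly_states <- function(spec, a, fw) {
  wk <- function(x) x / 52
  w1_weeks <- ceiling((fw$t19 - fw$wean_day) / 7)
  weaner_weeks <- (fw$wend - fw$wean_day) / 7
  w2_weeks <- weaner_weeks - w1_weeks
  fin_weeks <- (fw$sale_day - fw$wend) / 7
  # split weaner deaths between the two weaner stages by housed days
  d_w1 <- a$deaths_weaner * w1_weeks / weaner_weeks
  d_w2 <- a$deaths_weaner - d_w1
  in_w1 <- wk(a$weaned); out_w1 <- in_w1 - wk(d_w1)
  out_w2 <- wk(a$enter_finisher)
  sold <- wk(a$pigs_sold)
  stock <- function(inflow, outflow, weeks) weeks * (inflow + outflow) / 2
  lact_weeks <- 4
  df <- data.frame(
    week = 1:52,
    maiden_gilts = stock(wk(a$gilts), wk(a$gilts), 8),
    gestating = spec$herd_size - wk(a$farrowings) * lact_weeks,
    lactating = wk(a$farrowings) * lact_weeks,
    piglets = stock(wk(a$born), wk(a$weaned), 4),
    weaner1 = stock(in_w1, out_w1, w1_weeks),
    weaner2 = stock(out_w1, out_w2, w2_weeks),
    finishers = stock(out_w2, wk(a$finished), fin_weeks),
    services = wk(a$services),
    farrowings = wk(a$farrowings),
    births = wk(a$born),
    weanings = wk(a$weaned),
    transfers_w1_w2 = out_w1,
    transfers_w2_fin = out_w2,
    finishers_sold = sold,
    deaths_piglet = wk(a$deaths_piglet),
    deaths_weaner1 = wk(d_w1),
    deaths_weaner2 = wk(d_w2),
    deaths_finisher = wk(a$deaths_finisher),
    sows_culled = wk(a$cull_sows_sold),
    sow_deaths = wk(a$sow_deaths),
    gilts_retained = wk(a$gilts))
  df
}

#' @export
print.annual_physical <- function(x, ...) {
  cat(sprintf("Annual physical outputs, scenario %s\n", x$scenario))
  cat(sprintf("  Finisher pigs sold : %8.0f head\n", x$pigs_sold))
  cat(sprintf("  Meat sold          : %8.1f t\n", x$meat_sold_kg / 1000))
  cat(sprintf("  Cull sows sold     : %8.0f head\n", x$cull_sows_sold))
  cat("  Feed usage, t:\n")
  for (nm in names(x$feed_usage_t))
    cat(sprintf("    %-9s %9.1f\n", nm, x$feed_usage_t[[nm]]))
  cat(sprintf("  Replacement gilts  : %8.0f head\n", x$replacement_gilts))
  cat(sprintf("  Deaths (pig/wean/fin/sow): %.0f / %.0f / %.0f / %.0f\n",
              x$deaths[["piglet"]], x$deaths[["weaner"]],
              x$deaths[["finisher"]], x$deaths[["sow"]]))
  invisible(x)
}

#' Per-diet annual feed usage
#'
#' Computes the annual tonnes of each diet for a scenario: sow diets per
#' sow-year, creep and link per weaned pig, and weaner/finisher diets by
#' integrating metabolic-weight intake over the housed stage windows of the
#' scenario's growth curve.
#'
#' @param spec A [scenario_spec()].
#' @param fd Optional [feed_params()] overriding `spec$feed`.
#' @return Named numeric vector of tonnes per year (gestation, lactation,
#'   creep, link, weaner, finisher).
#' @export
annual_feed_usage <- function(spec, fd = NULL) {
  if (!is.null(fd)) spec$feed <- fd
  unlist(annual_core(spec)$feed_t)
}

#' Calibrate feed-demand coefficients to reference tonnages
#'
#' Solves the per-diet coefficients of the feed-demand model so that a
#' reference scenario reproduces given annual tonnages exactly.
#'
#' @param spec The reference [scenario_spec()].
#' @param target_t Named vector of annual tonnes with elements `gestation`,
#'   `lactation`, `creep`, `link`, `weaner`, `finisher`.
#' @return A [feed_params()] object.
#' @export
calibrate_feed_demand <- function(spec, target_t) {
  fw <- feed_windows(spec)
  a <- annual_core(spec, fw = fw)
  weaned <- a$weaned
  surv_w <- a$enter_finisher / a$weaned
  surv_f <- a$finished / a$enter_finisher
  feed_params(
    weaner_scale = target_t[["weaner"]] * 1000 /
      (weaned * (1 + surv_w) / 2 * fw$I_weaner),
    finisher_scale = target_t[["finisher"]] * 1000 /
      (a$enter_finisher * (1 + surv_f) / 2 * fw$I_finisher),
    creep_kg_weaned = target_t[["creep"]] * 1000 / weaned,
    link_kg_weaned = target_t[["link"]] * 1000 / weaned,
    gestation_kg_sow_year = target_t[["gestation"]] * 1000 / spec$herd_size,
    lactation_kg_sow_year = target_t[["lactation"]] * 1000 / spec$herd_size)
}
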