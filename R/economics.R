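# Deterministic enterprise budget: itemized sales, variable and fixed
# costs, gross margin and net profit, with per-pig and per-kg views.
# All account lines are held in exact cents so the account identities
# (totals = sums of lines, gross margin = sales - variable costs, net
# profit = gross margin - fixed costs) check to the euro cent.

round_cents <- function(x) round(x, 2)

#' Price schedule
#'
#' Unit prices and unit variable costs of the enterprise budget. Defaults
#' are calibrated against 2017 Irish farrow-to-finish enterprise records
#' (per-kg pork price and per-tonne diet prices recovered from annual
#' account lines divided by the corresponding physical quantities); they are
#' plain arguments and can be overridden individually.
#'
#' @param pork_eur_kg Pork price, EUR per kg cold carcass.
#' @param cull_sow_eur_head Sale price of a culled sow, EUR/head.
#' @param feed_eur_t Named vector of diet prices, EUR/tonne, with elements
#'   `gestation`, `lactation`, `creep`, `link`, `weaner`, `finisher`.
#' @param gilt_eur_head Cost of producing one replacement gilt, EUR/head.
#' @param disposal_eur_head Dead-animal disposal cost by weight class,
#'   EUR/head: `piglet`, `weaner`, `finisher`, `sow`.
#' @param vet_eur_year Annual veterinary visits, EUR/year (4 visits at 300).
#' @param healthcare_eur_weaned Vaccination and health plan, EUR per weaned
#'   pig.
#' @param reproduction_eur_sow Reproductive management, EUR per sow-year.
#' @param manure_eur_pig Manure handling, EUR per pig sold.
#' @param transport_eur_pig Transport to the abattoir, EUR per pig sold.
#' @return An object of class `price_schedule`.
#' @export
price_schedule <- function(pork_eur_kg = 1.61908,
                           cull_sow_eur_head = 120,
                           feed_eur_t = c(gestation = 233.97,
                                          lactation = 257.61,
                                          creep = 921.54, link = 594.10,
                                          weaner = 260.37,
                                          finisher = 237.96),
                           gilt_eur_head = 161.91,
                           disposal_eur_head = c(piglet = 1, weaner = 3,
                                                 finisher = 9, sow = 35),
                           vet_eur_year = 1200,
                           healthcare_eur_weaned = 1.9898,
                           reproduction_eur_sow = 51.25,
                           manure_eur_pig = 0.8387,
                           transport_eur_pig = 0.9476) {
  vals <- c(pork_eur_kg, cull_sow_eur_head, feed_eur_t, gilt_eur_head,
            disposal_eur_head, vet_eur_year, healthcare_eur_weaned,
            reproduction_eur_sow, manure_eur_pig, transport_eur_pig)
  if (any(vals < 0)) stop("prices must be non-negative")
  structure(list(pork_eur_kg = pork_eur_kg,
                 cull_sow_eur_head = cull_sow_eur_head,
                 feed_eur_t = feed_eur_t, gilt_eur_head = gilt_eur_head,
                 disposal_eur_head = disposal_eur_head,
                 vet_eur_year = vet_eur_year,
                 healthcare_eur_weaned = healthcare_eur_weaned,
                 reproduction_eur_sow = reproduction_eur_sow,
                 manure_eur_pig = manure_eur_pig,
                 transport_eur_pig = transport_eur_pig),
            class = "price_schedule")
}

#' Fixed-cost schedule
#'
#' Annual fixed costs, EUR/year, shared by all scenarios (infrastructure,
#' labour and capital do not vary with lesion prevalence).
#'
#' @param admin,energy,insurance,repairs,epa_subscription,labour,loan_interest,depreciation
#'   Annual amounts in EUR.
#' @return Named numeric vector of class `fixed_cost_schedule`.
#' @export
fixed_cost_schedule <- function(admin = 2500, energy = 81614,
                                insurance = 20533, repairs = 20533,
                                epa_subscription = 10000, labour = 279136,
                                loan_interest = 75780,
                                depreciation = 175021) {
  v <- c(admin = admin, energy = energy, insurance = insurance,
         repairs = repairs, epa_subscription = epa_subscription,
         labour = labour, loan_interest = loan_interest,
         depreciation = depreciation)
  if (any(v < 0)) stop("fixed costs must be non-negative")
  structure(v, class = c("fixed_cost_schedule", "numeric"))
}

# Itemized euro lines from an annual_core() result, vectorised over
# iterations so the Monte Carlo engine prices every draw at once. `price_ov`
# may carry equal-length vectors overriding pork_eur_kg or single diet
# prices (named e.g. "feed_weaner_eur_t"). build_pnl() delegates here so the
# deterministic account and the risk analysis share one pricing path.
pnl_lines <- function(a, pr, herd_size, price_ov = list()) {
  pork <- if (!is.null(price_ov$pork_eur_kg)) price_ov$pork_eur_kg
          else pr$pork_eur_kg
  feed_price <- function(diet) {
    key <- paste0("feed_", diet, "_eur_t")
    if (!is.null(price_ov[[key]])) price_ov[[key]] else pr$feed_eur_t[[diet]]
  }
  ft <- a$feed_t
  dh <- pr$disposal_eur_head
  sales <- list(
    finisher_pigs = a$meat_kg * pork,
    culled_sows = a$cull_sows_sold * pr$cull_sow_eur_head)
  variable <- list(
    gestation_feed = ft$gestation * feed_price("gestation"),
    lactation_feed = ft$lactation * feed_price("lactation"),
    creep_feed = ft$creep * feed_price("creep"),
    link_feed = ft$link * feed_price("link"),
    weaner_feed = ft$weaner * feed_price("weaner"),
    finisher_feed = ft$finisher * feed_price("finisher"),
    replacement_gilts = a$gilts * pr$gilt_eur_head,
    dead_disposal = a$deaths_piglet * dh[["piglet"]] +
      a$deaths_weaner * dh[["weaner"]] +
      a$deaths_finisher * dh[["finisher"]] + a$sow_deaths * dh[["sow"]],
    healthcare = pr$vet_eur_year + a$weaned * pr$healthcare_eur_weaned,
    reproduction = rep_len(herd_size * pr$reproduction_eur_sow,
                           length(a$pigs_sold)),
    manure = a$pigs_sold * pr$manure_eur_pig,
    transport = a$pigs_sold * pr$transport_eur_pig)
  list(sales = sales, variable = variable)
}

#' Build a profit-and-loss account from physical outputs
#'
#' Prices the annual physical outputs of a scenario: finisher sales are
#' meat sold times the pork price (carcass weight = live weight at sale
#' times dressing percentage, net of the condemnation rate), cull-sow sales
#' are head sold times the cull-sow price, each feed line is tonnes times
#' the diet price, and the remaining variable lines are unit costs times
#' their drivers. Fixed costs enter unchanged.
#'
#' @param phys An `annual_physical` object from [simulate_year()].
#' @param prices A [price_schedule()].
#' @param fixed A [fixed_cost_schedule()].
#' @param herd_size Sow count, used for the per-sow reproduction line.
#' @return A [pnl_account()].
#' @export
build_pnl <- function(phys, prices = price_schedule(),
                      fixed = fixed_cost_schedule(), herd_size = 728) {
  stopifnot(inherits(phys, "annual_physical"))
  a <- list(meat_kg = phys$meat_sold_kg,
            cull_sows_sold = phys$cull_sows_sold,
            feed_t = as.list(phys$feed_usage_t),
            gilts = phys$replacement_gilts,
            deaths_piglet = phys$deaths[["piglet"]],
            deaths_weaner = phys$deaths[["weaner"]],
            deaths_finisher = phys$deaths[["finisher"]],
            sow_deaths = phys$deaths[["sow"]],
            weaned = phys$weaned, pigs_sold = phys$pigs_sold)
  ln <- pnl_lines(a, prices, herd_size)
  pnl_account(unlist(ln$sales), unlist(ln$variable),
              stats::setNames(as.numeric(fixed), names(fixed)),
              pigs_sold = phys$pigs_sold,
              meat_sold_kg = phys$meat_sold_kg,
              scenario = phys$scenario)
}

#' Profit-and-loss account from itemized lines
#'
#' Assembles an account from named euro lines, verifying the account
#' identities: total sales, total variable and total fixed costs are the
#' sums of their lines; gross margin = total sales - total variable costs;
#' total costs = variable + fixed; net profit = gross margin - fixed costs.
#' Lines are held in exact cents. Per-pig and per-kg views divide every
#' line by pigs sold and kg of meat sold.
#'
#' @param sales,variable,fixed Named numeric vectors of annual euro lines.
#' @param pigs_sold,meat_sold_kg Annual denominators for the per-pig and
#'   per-kg views.
#' @param scenario Optional label.
#' @return An object of class `pnl_account`.
#' @export
pnl_account <- function(sales, variable, fixed, pigs_sold, meat_sold_kg,
                        scenario = NULL) {
  if (any(c(sales, variable, fixed) < 0)) stop("negative account line")
  if (pigs_sold < 0 || meat_sold_kg < 0) stop("negative denominator")
  sales <- round_cents(sales); variable <- round_cents(variable)
  fixed <- round_cents(fixed)
  totals <- list(total_sales = sum(sales),
                 total_variable = sum(variable),
                 total_fixed = sum(fixed))
  totals$gross_margin <- totals$total_sales - totals$total_variable
  totals$total_costs <- totals$total_variable + totals$total_fixed
  totals$net_profit <- totals$gross_margin - totals$total_fixed
  structure(list(scenario = scenario, sales = sales, variable = variable,
                 fixed = fixed, totals = totals, pigs_sold = pigs_sold,
                 meat_sold_kg = meat_sold_kg),
            class = "pnl_account")
}

account_line_vector <- function(acc) {
  c(acc$sales, total_sales = acc$totals$total_sales,
    acc$variable, total_variable = acc$totals$total_variable,
    gross_margin = acc$totals$gross_margin,
    acc$fixed, total_fixed = acc$totals$total_fixed,
    total_costs = acc$totals$total_costs,
    net_profit = acc$totals$net_profit)
}

#' Tabulate an account with annual, per-pig and per-kg columns
#'
#' @param acc A [pnl_account()].
#' @return `data.frame` with one row per line (sales, variable costs, fixed
#'   costs and totals) and columns `eur_year`, `eur_pig`, `eur_kg`.
#' @export
account_table <- function(acc) {
  v <- account_line_vector(acc)
  data.frame(line = names(v), eur_year = unname(v),
             eur_pig = unname(v) / acc$pigs_sold,
             eur_kg = unname(v) / acc$meat_sold_kg)
}

#' @export
print.pnl_account <- function(x, ...) {
  tb <- account_table(x)
  cat(sprintf("Profit & loss account%s (pigs sold %.0f, meat %.1f t)\n",
              if (is.null(x$scenario)) "" else paste0(" - ", x$scenario),
              x$pigs_sold, x$meat_sold_kg / 1000))
  cat(sprintf("  %-22s %14s %9s %8s\n", "line", "EUR/year", "EUR/pig",
              "EUR/kg"))
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-22s %14.2f %9.2f %8.3f\n", tb$line[i], tb$eur_year[i],
                tb$eur_pig[i], tb$eur_kg[i]))
  invisible(x)
}

#' Compare scenario accounts line by line
#'
#' Pairwise absolute and percentage differences of every account line
#' against a reference scenario (the first account).
#'
#' @param accounts Named list of at least two [pnl_account()] objects with
#'   identical line sets.
#' @return `data.frame` with the reference value and, per other scenario,
#'   its value, the absolute difference and the percentage difference
#'   (reference as base).
#' @export
compare_scenarios <- function(accounts) {
  if (length(accounts) < 2L) stop("need at least two accounts")
  ref <- accounts[[1]]
  ref_v <- account_line_vector(ref)
  out <- data.frame(line = names(ref_v), ref = unname(ref_v))
  names(out)[2] <- paste0(names(accounts)[1])
  for (i in seq_along(accounts)[-1]) {
    v <- account_line_vector(accounts[[i]])
    if (!identical(names(v), names(ref_v))) stop("mismatched line sets")
    nm <- names(accounts)[i]
    out[[nm]] <- unname(v)
    out[[paste0(nm, "_diff")]] <- unname(v - ref_v)
    out[[paste0(nm, "_pct")]] <- ifelse(ref_v == 0, NA_real_,
                                        round(100 * (v - ref_v) / ref_v, 1))
  }
  out
}

#' Write an account as CSV
#' @param acc A [pnl_account()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_pnl <- function(acc, path) {
  utils::write.csv(account_table(acc), path, row.names = FALSE)
  invisible(path)
}
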