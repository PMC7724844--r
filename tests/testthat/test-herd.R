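scen <- default_scenarios()

test_that("weekly steady state conserves animals in every stage", {
  for (spec in scen) {
    wk <- simulate_year(spec)$weekly
    expect_equal(nrow(wk), 52)
    # constant stocks: inflow = outflow + deaths, stage by stage
    expect_equal(wk$births, wk$weanings + wk$deaths_piglet)
    expect_equal(wk$weanings, wk$transfers_w1_w2 + wk$deaths_weaner1)
    expect_equal(wk$transfers_w1_w2,
                 wk$transfers_w2_fin + wk$deaths_weaner2)
    expect_equal(wk$transfers_w2_fin,
                 wk$finishers_sold + wk$deaths_finisher + wk$gilts_retained)
    # sow herd: culls + deaths replaced by retained gilts
    expect_equal(wk$gilts_retained, wk$sows_culled + wk$sow_deaths)
    expect_equal(wk$gestating + wk$lactating, rep(spec$herd_size, 52))
    expect_true(all(as.matrix(wk[-1]) >= 0))
  }
})

test_that("annual aggregates are 52 weekly flows and internally consistent", {
  for (spec in scen) {
    sim <- simulate_year(spec)
    a <- sim$annual
    wk <- sim$weekly
    expect_equal(a$pigs_sold, sum(wk$finishers_sold))
    expect_equal(a$born_alive, sum(wk$births))
    expect_equal(a$weaned, sum(wk$weanings))
    expect_equal(a$born_alive - sum(a$deaths[c("piglet", "weaner",
                                               "finisher")]),
                 a$pigs_sold + a$replacement_gilts)
    expect_equal(a$meat_sold_kg,
                 a$pigs_sold * spec$sale_weight_kg *
                   spec$bio$dressing_pct[2] / 100 *
                   (1 - spec$condemnation_rate / 100))
    expect_equal(a$cull_sows_sold,
                 spec$herd_size * spec$bio$sow_culling_rate[2] / 100)
    expect_equal(a$farrowings,
                 spec$herd_size * spec$bio$litters_per_sow_year[2])
    expect_true(a$services > a$farrowings)   # farrowing rate < 100%
  }
})

test_that("recorded mortality rates are recovered over weight-defined spans", {
  spec <- scen$LPLSC
  fw <- plucksim:::feed_windows(spec)
  a <- plucksim:::annual_core(spec, fw = fw)
  wm <- spec$bio$weaner_mortality[2] / 100
  fm <- spec$bio$finisher_mortality[2] / 100
  # the calibrated hazards reproduce the recorded rates exactly over the
  # weight-defined spans (wean-to-38 kg and 38 kg-to-sale-weight ages)
  h_w <- -2 * log(1 - wm) / (fw$t38 - fw$wean_day)
  h_f <- -log(1 - fm) / (fw$age_sale - fw$t38)
  expect_equal(1 - exp(-h_w * (fw$t38 - fw$wean_day)), 1 - (1 - wm)^2)
  expect_equal(1 - exp(-h_f * (fw$age_sale - fw$t38)), fm)
  # the same hazards applied over the housed (whole-week) spans
  expect_equal(a$enter_finisher / a$weaned,
               exp(-h_w * (fw$wend - fw$wean_day)))
  expect_equal(a$finished / a$enter_finisher,
               exp(-h_f * (fw$sale_day - fw$wend)))
})

test_that("default feed coefficients reproduce the reference tonnages", {
  target <- c(gestation = 540.5, lactation = 367.8, creep = 77.3,
              link = 142.3, weaner = 1137.1, finisher = 3164.9)
  got <- annual_feed_usage(scen$LPLSC)
  expect_equal(got[names(target)], target, tolerance = 1e-8)
})

test_that("feed calibration round-trips arbitrary targets", {
  target <- c(gestation = 600, lactation = 400, creep = 80, link = 150,
              weaner = 1200, finisher = 3300)
  fp <- calibrate_feed_demand(scen$LPHSC, target)
  got <- annual_feed_usage(scen$LPHSC, fp)
  expect_equal(got[names(target)], target, tolerance = 1e-9)
})

test_that("slower growth needs more finisher feed per pig", {
  per_pig <- vapply(scen, function(s) {
    a <- simulate_year(s)$annual
    a$feed_usage_t[["finisher"]] * 1000 / a$pigs_sold
  }, 0)
  expect_true(all(diff(per_pig[c("LPLSC", "LPHSC", "HP")]) > 0))
})

test_that("higher mortality sells fewer pigs, all else equal", {
  spec <- scen$LPLSC
  base <- plucksim:::annual_core(spec)
  worse <- plucksim:::annual_core(spec, list(finisher_mortality = 5))
  expect_lt(worse$pigs_sold, base$pigs_sold)
  worse_w <- plucksim:::annual_core(spec, list(weaner_mortality = 8))
  expect_lt(worse_w$pigs_sold, base$pigs_sold)
})

test_that("annual_core vectorises exactly over overrides", {
  spec <- scen$HP
  ov <- list(farrowing_rate = c(85, 90, 88),
             piglet_mortality = c(9, 11, 10),
             dressing_pct = c(76, 77, 76.5))
  vec <- plucksim:::annual_core(spec, ov)
  for (i in 1:3) {
    one <- plucksim:::annual_core(spec, lapply(ov, `[`, i))
    expect_equal(vec$pigs_sold[i], one$pigs_sold)
    expect_equal(vec$meat_kg[i], one$meat_kg)
    expect_equal(vec$feed_t$weaner[i], one$feed_t$weaner)
    expect_equal(vec$feed_t$finisher[i], one$feed_t$finisher)
  }
})

test_that("scenario validation rejects inconsistent inputs", {
  bio <- plucksim:::.bio_triples$LPLSC
  expect_error(scenario_spec("x", 0, bio), "positive")
  expect_error(scenario_spec("x", 700, bio[-1]), "missing")
  bad <- bio; bad$farrowing_rate <- c(80, 90, 120)
  expect_error(scenario_spec("x", 700, bad), "\\[0, 100\\]")
  expect_error(scenario_spec("x", 700, bio,
                             transfer_weights_kg = c(38, 19)), "increasing")
  expect_error(feed_params(0, 1, 1, 1, 1, 1), "positive")
  # infeasible growth: ADG so low the year is exceeded
  expect_error(simulate_year(scenario_spec("x", 250, bio)), "year")
})

test_that("replacement demand exceeding finished pigs is an error", {
  bio <- plucksim:::.bio_triples$LPLSC
  bio$born_alive_per_litter <- c(0.2, 0.2, 0.2)
  spec <- scenario_spec("x", 760, bio)
  expect_error(simulate_year(spec), "replacement")
})
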