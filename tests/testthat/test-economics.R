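test_that("account identities hold to the cent on random lines", {
  set.seed(10)
  for (i in 1:20) {
    sales <- round(runif(2, 1e4, 3e6), 2)
    variable <- round(runif(12, 1e3, 8e5), 2)
    fixed <- round(runif(8, 1e3, 3e5), 2)
    names(sales) <- paste0("s", 1:2)
    names(variable) <- paste0("v", 1:12)
    names(fixed) <- paste0("f", 1:8)
    acc <- pnl_account(sales, variable, fixed, 19000, 1.59e6)
    t <- acc$totals
    expect_identical(t$total_sales, sum(acc$sales))
    expect_identical(t$total_variable, sum(acc$variable))
    expect_identical(t$total_fixed, sum(acc$fixed))
    expect_identical(t$gross_margin, t$total_sales - t$total_variable)
    expect_identical(t$total_costs, t$total_variable + t$total_fixed)
    expect_identical(t$net_profit, t$gross_margin - t$total_fixed)
  }
})

test_that("lines are rounded to exact cents before totalling", {
  acc <- pnl_account(c(a = 10.004), c(b = 1.006), c(f = 0.5), 10, 100)
  expect_equal(acc$sales[["a"]], 10.00)
  expect_equal(acc$variable[["b"]], 1.01)
  expect_equal(acc$totals$gross_margin, 8.99)
  expect_error(pnl_account(c(a = -1), c(b = 1), c(f = 1), 10, 100),
               "negative")
})

test_that("per-pig and per-kg views divide every line by the denominators", {
  acc <- reference_account_lplsc()
  tb <- account_table(acc)
  expect_equal(tb$eur_pig, tb$eur_year / 19188)
  expect_equal(tb$eur_kg, tb$eur_year / 1595100)
  expect_equal(tb$eur_year[tb$line == "net_profit"], 349338)
})

test_that("build_pnl prices the physical outputs line by line", {
  spec <- default_scenarios()$LPLSC
  phys <- simulate_year(spec)$annual
  pr <- spec$prices
  acc <- build_pnl(phys, pr, spec$fixed_costs, spec$herd_size)
  expect_equal(acc$sales[["finisher_pigs"]],
               round(phys$meat_sold_kg * pr$pork_eur_kg, 2))
  expect_equal(acc$sales[["culled_sows"]],
               round(phys$cull_sows_sold * pr$cull_sow_eur_head, 2))
  for (diet in names(pr$feed_eur_t)) {
    expect_equal(acc$variable[[paste0(diet, "_feed")]],
                 round(phys$feed_usage_t[[diet]] * pr$feed_eur_t[[diet]], 2),
                 label = diet)
  }
  expect_equal(acc$variable[["replacement_gilts"]],
               round(phys$replacement_gilts * pr$gilt_eur_head, 2))
  expect_equal(acc$variable[["reproduction"]],
               round(spec$herd_size * pr$reproduction_eur_sow, 2))
  expect_equal(acc$variable[["dead_disposal"]],
               round(sum(phys$deaths * c(1, 3, 9, 35)), 2))
  expect_equal(sum(acc$fixed), 665117)
})

test_that("price overrides only move their own lines", {
  spec <- default_scenarios()$LPLSC
  fw <- plucksim:::feed_windows(spec)
  a <- plucksim:::annual_core(spec, fw = fw)
  base <- plucksim:::pnl_lines(a, spec$prices, spec$herd_size)
  bumped <- plucksim:::pnl_lines(a, spec$prices, spec$herd_size,
                                 list(feed_weaner_eur_t = 300))
  expect_equal(bumped$variable$weaner_feed, a$feed_t$weaner * 300)
  same <- setdiff(names(base$variable), "weaner_feed")
  expect_equal(bumped$variable[same], base$variable[same])
  expect_equal(bumped$sales, base$sales)
})

test_that("scenario comparison reports absolute and rounded % differences", {
  cmp <- compare_scenarios(list(LPLSC = reference_account_lplsc(),
                                HP = reference_account_hp()))
  np <- cmp[cmp$line == "net_profit", ]
  expect_equal(np$HP_diff, np$HP - np$LPLSC)
  expect_equal(np$HP_pct, round(100 * (np$HP - np$LPLSC) / np$LPLSC, 1))
  fx <- cmp[cmp$line == "total_fixed", ]
  expect_equal(fx$HP_pct, 0)            # fixed costs identical by design
  expect_error(compare_scenarios(list(a = reference_account_lplsc())),
               "two")
})

test_that("accounts export as CSV", {
  path <- tempfile(fileext = ".csv")
  write_pnl(reference_account_lplsc(), path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(account_table(reference_account_lplsc())))
  expect_equal(back$eur_year[back$line == "gross_margin"], 1014455)
})
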