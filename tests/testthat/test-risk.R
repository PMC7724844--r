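test_that("default stochastic inputs cover biology and prices", {
  spec <- default_scenarios()$LPLSC
  inputs <- default_stochastic_inputs(spec)
  bio <- plucksim:::.indicator_names
  expect_true(all(bio %in% names(inputs)))
  expect_true("pork_eur_kg" %in% names(inputs))
  expect_true(all(paste0("feed_", names(spec$prices$feed_eur_t), "_eur_t")
                  %in% names(inputs)))
  for (nm in bio) {
    tr <- spec$bio[[nm]]
    expect_equal(inputs[[nm]]$min, tr[1])
    expect_equal(pert_mean(inputs[[nm]]), tr[2], tolerance = 1e-10)
    expect_equal(inputs[[nm]]$max, tr[3])
  }
  pk <- inputs$pork_eur_kg
  expect_equal(pk$min, spec$prices$pork_eur_kg * 0.98, tolerance = 1e-12)
  expect_equal(pk$max, spec$prices$pork_eur_kg * 1.02, tolerance = 1e-12)
})

test_that("correlation induction preserves marginals exactly", {
  set.seed(5)
  x <- cbind(a = rnorm(500), b = rexp(500), c = runif(500))
  target <- diag(3); target[1, 2] <- target[2, 1] <- 0.7
  dimnames(target) <- list(colnames(x), colnames(x))
  y <- correlate_samples(x, target)
  for (j in 1:3) expect_identical(sort(y[, j]), sort(x[, j]))
})

test_that("induced Spearman correlation is within 0.03 of target at n = 10000", {
  set.seed(8)
  x <- cbind(a = rnorm(10000), b = rexp(10000), c = runif(10000))
  target <- matrix(c(1, 0.8, 0.3, 0.8, 1, 0, 0.3, 0, 1), 3, 3)
  y <- correlate_samples(x, target)
  got <- cor(y, method = "spearman")
  expect_true(max(abs(got - target)) < 0.03)
})

test_that("a non-PSD target is repaired rather than failing", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)
  set.seed(2)
  x <- matrix(rnorm(300), 100, 3)
  expect_silent(y <- correlate_samples(x, bad))
  for (j in 1:3) expect_identical(sort(y[, j]), sort(x[, j]))
  expect_error(correlate_samples(x, bad[, c(2, 1, 3)]), "symmetric")
  expect_error(correlate_samples(x, diag(2)), "dimension")
})

test_that("default correlation matrix is a valid PSD correlation", {
  spec <- default_scenarios()$LPLSC
  nms <- names(default_stochastic_inputs(spec))
  m <- default_correlation(nms, cohort = generate_cohort(seed = 3))
  expect_equal(dim(m), c(length(nms), length(nms)))
  expect_equal(diag(m), setNames(rep(1, length(nms)), nms))
  expect_equal(m, t(m))
  expect_true(min(eigen(m, symmetric = TRUE)$values) > -1e-10)
  feed <- grep("^feed_", nms, value = TRUE)
  off <- m[feed, feed][upper.tri(m[feed, feed])]
  expect_true(all(abs(off - 0.8) < 0.2))   # PSD repair may shrink slightly
})

test_that("monte carlo runs are deterministic in the seed", {
  spec <- default_scenarios()$HP
  r1 <- run_monte_carlo(spec, n_iter = 200, seed = 42)
  r2 <- run_monte_carlo(spec, n_iter = 200, seed = 42)
  expect_identical(r1$iterations, r2$iterations)
  r3 <- run_monte_carlo(spec, n_iter = 200, seed = 43)
  expect_false(identical(r1$iterations$net_profit,
                         r3$iterations$net_profit))
})

test_that("point-mass inputs collapse the output distribution to the deterministic run", {
  spec <- default_scenarios()$LPLSC
  inputs <- lapply(default_stochastic_inputs(spec), function(sp) {
    fit_distribution(rep(sp$mean, 3), name = sp$name)
  })
  r <- run_monte_carlo(spec, inputs = inputs, n_iter = 50, seed = 1)
  expect_equal(sd(r$iterations$net_profit), 0)
  det <- build_pnl(simulate_year(spec)$annual, spec$prices,
                   spec$fixed_costs, spec$herd_size)
  # rounding to cents happens per line only in the account path
  expect_equal(r$iterations$net_profit[1], det$totals$net_profit,
               tolerance = 1e-6)
})

test_that("iteration table carries inputs within bounds and coherent outputs", {
  spec <- default_scenarios()$LPHSC
  r <- run_monte_carlo(spec, n_iter = 500, seed = 9)
  it <- r$iterations
  inputs <- default_stochastic_inputs(spec)
  for (nm in names(inputs)) {
    expect_true(all(it[[nm]] >= inputs[[nm]]$min - 1e-12 &
                    it[[nm]] <= inputs[[nm]]$max + 1e-12), label = nm)
  }
  expect_equal(it$net_profit, it$gross_margin - sum(spec$fixed_costs))
  expect_equal(it$net_profit_pig, it$net_profit / it$pigs_sold)
  expect_equal(it$net_profit_kg, it$net_profit / it$meat_kg)
  expect_equal(r$n_infeasible, 0)
  s <- r$summary
  expect_equal(nrow(s), 6)
  np <- s[s$variable == "net_profit" & s$scale == "eur_year", ]
  expect_equal(np$mean, mean(it$net_profit))
  expect_true(np$min <= np$p05 && np$p05 <= np$p95 && np$p95 <= np$max)
})

test_that("unknown stochastic inputs are rejected", {
  spec <- default_scenarios()$LPLSC
  inputs <- default_stochastic_inputs(spec)
  inputs$bogus <- fit_distribution(c(0, 1, 2))
  expect_error(run_monte_carlo(spec, inputs = inputs, n_iter = 10, seed = 1),
               "bogus")
})

test_that("risk results export as CSV", {
  spec <- default_scenarios()$LPLSC
  r <- run_monte_carlo(spec, n_iter = 50, seed = 2)
  ip <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".csv")
  write_risk_result(r, ip, sp)
  expect_equal(nrow(utils::read.csv(ip)), 50)
  expect_equal(nrow(utils::read.csv(sp)), 6)
})
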