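# Monte Carlo risk analysis: bounded (modified-PERT) stochastic inputs
# fitted to (min, mean, max) triples, Spearman rank-correlation induction by
# Iman-Conover reordering, and fully vectorised propagation of all
# iterations through the herd-flow, growth/feed and budgeting stages.

#' Default stochastic inputs for a scenario
#'
#' One bounded input per biological parameter (fitted to the scenario's
#' `(min, mean, max)` triples) plus pork and per-diet feed prices sampled
#' from triples spanning +/- `price_spread` around the price-schedule
#' defaults. The default spread (2%) represents uncertainty in the annual
#' average price entering a steady-state yearly model -- not the much wider
#' within-year spot range -- and was calibrated so the simulated across-
#' iteration dispersion of annual net profit matches farm-level records
#' (standard deviations near 74,000/90,000/53,000 EUR for the three default
#' scenarios, which the biological triples alone almost fully explain).
#'
#' @param spec A [scenario_spec()].
#' @param price_spread Half-width of the price triples relative to the
#'   deterministic price (default 0.02).
#' @return Named list of `stochastic_input` objects; biological inputs map
#'   onto scenario fields, price inputs onto price-schedule fields.
#' @export
default_stochastic_inputs <- function(spec, price_spread = 0.02) {
  out <- lapply(.indicator_names, function(nm)
    fit_distribution(spec$bio[[nm]], name = nm))
  names(out) <- .indicator_names
  pr <- spec$prices
  ptrip <- function(x) c(x * (1 - price_spread), x, x * (1 + price_spread))
  out$pork_eur_kg <- fit_distribution(ptrip(pr$pork_eur_kg),
                                      name = "pork_eur_kg")
  for (diet in names(pr$feed_eur_t)) {
    key <- paste0("feed_", diet, "_eur_t")
    out[[key]] <- fit_distribution(ptrip(pr$feed_eur_t[[diet]]), name = key)
  }
  out
}

# Repair a correlation matrix to be positive semi-definite by clipping
# negative eigenvalues and rescaling to unit diagonal.
repair_psd <- function(m, floor = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values > floor)) return(m)
  v <- pmax(e$values, floor)
  m2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  dimnames(m2) <- dimnames(m)
  m2
}

#' Induce a target Spearman correlation by Iman-Conover reordering
#'
#' Reorders the rows within each column of an independently sampled matrix
#' so the empirical rank correlation approaches the target while every
#' marginal distribution is preserved exactly (each column keeps the same
#' multiset of values). A non-positive-semi-definite target is repaired by
#' eigenvalue clipping. Uses the current RNG stream for the reference
#' scores.
#'
#' @param x Numeric matrix, `n_iter x n_vars`, of independent draws.
#' @param target Symmetric Spearman correlation matrix with unit diagonal,
#'   `n_vars x n_vars`.
#' @return The reordered matrix (same dimnames as `x`).
#' @export
correlate_samples <- function(x, target) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (!is.matrix(target) || nrow(target) != ncol(target))
    stop("target must be a square matrix")
  if (ncol(target) != k) stop("dimension mismatch between x and target")
  if (max(abs(target - t(target))) > 1e-8 || any(abs(diag(target) - 1) > 1e-8))
    stop("target must be symmetric with unit diagonal")
  target <- repair_psd((target + t(target)) / 2)
  # reference matrix of normal scores in random column-wise order
  sc <- stats::qnorm(seq_len(n) / (n + 1))
  m <- vapply(seq_len(k), function(j) sample(sc), numeric(n))
  cm <- stats::cor(m)
  m_star <- m %*% solve(chol(cm)) %*% chol(target)
  out <- x
  for (j in seq_len(k)) {
    out[, j] <- sort(x[, j])[rank(m_star[, j], ties.method = "first")]
  }
  out
}

#' Default Spearman correlation for the stochastic inputs
#'
#' The biological block is the empirical Spearman correlation of the nine
#' performance indicators across a synthetic cohort (so the pipeline is
#' self-contained); the feed-price block uses a common co-movement of 0.8
#' (grain-driven commodity prices move together); the pork price and the
#' cross blocks are left uncorrelated. The result is PSD-repaired.
#'
#' @param input_names Names of the stochastic inputs, in sampling order.
#' @param cohort Optional cohort `data.frame`; defaults to a freshly
#'   generated default cohort.
#' @param seed Seed for the default cohort.
#' @param feed_price_rho Common Spearman correlation between feed prices.
#' @return Correlation matrix over `input_names`.
#' @export
default_correlation <- function(input_names,
                                cohort = generate_cohort(seed = seed),
                                seed = 20170101, feed_price_rho = 0.8) {
  k <- length(input_names)
  m <- diag(k)
  dimnames(m) <- list(input_names, input_names)
  bio <- intersect(input_names, .indicator_names)
  if (length(bio) > 1) {
    sp <- stats::cor(cohort[bio], method = "spearman")
    m[bio, bio] <- sp
  }
  feed <- grep("^feed_.*_eur_t$", input_names, value = TRUE)
  if (length(feed) > 1) m[feed, feed] <- feed_price_rho
  diag(m) <- 1
  repair_psd(m)
}

#' Monte Carlo risk analysis of a scenario
#'
#' Samples all stochastic inputs (correlated by Iman-Conover reordering),
#' runs the full deterministic pipeline -- herd flow, growth and feed
#' demand, enterprise budget -- for every iteration, and records the annual
#' gross margin and net profit (total, per pig and per kg). Iterations that
#' produce an infeasible farm (replacement demand exceeding finished pigs)
#' are recorded and reported, not silently dropped. Deterministic given the
#' seed.
#'
#' @param spec A [scenario_spec()].
#' @param inputs Named list of `stochastic_input` objects (default:
#'   [default_stochastic_inputs()]).
#' @param corr Spearman target matrix over the inputs (default:
#'   [default_correlation()]).
#' @param n_iter Number of iterations (default 10000).
#' @param seed Integer seed.
#' @return Object of class `risk_result`: `iterations` (a `data.frame` of
#'   sampled inputs and outputs), `summary` (mean, SD, 5th/95th percentile,
#'   min, max for gross margin and net profit on all three scales),
#'   `n_iter`, `seed`, `n_infeasible`.
#' @export
run_monte_carlo <- function(spec, inputs = default_stochastic_inputs(spec),
                            corr = NULL, n_iter = 10000, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (n_iter < 1) stop("n_iter must be positive")
  nms <- names(inputs)
  bad <- setdiff(nms, c(.indicator_names, "pork_eur_kg",
                        paste0("feed_", names(spec$prices$feed_eur_t),
                               "_eur_t")))
  if (length(bad))
    stop("stochastic inputs do not map to scenario or price fields: ",
         paste(bad, collapse = ", "))
  set.seed(seed)
  if (is.null(corr)) {
    corr <- default_correlation(nms, cohort = generate_cohort(seed = seed))
  }
  x <- vapply(inputs, function(sp) rpert(n_iter, sp), numeric(n_iter))
  x <- matrix(x, nrow = n_iter, dimnames = list(NULL, nms))
  if (n_iter > 1) x <- correlate_samples(x, corr[nms, nms])
  ov <- lapply(intersect(nms, .indicator_names), function(nm) x[, nm])
  names(ov) <- intersect(nms, .indicator_names)
  price_ov <- lapply(setdiff(nms, .indicator_names), function(nm) x[, nm])
  names(price_ov) <- setdiff(nms, .indicator_names)
  fw <- feed_windows(spec)
  a <- annual_core(spec, ov, fw = fw, check = FALSE)
  ln <- pnl_lines(a, spec$prices, spec$herd_size, price_ov)
  sales <- Reduce(`+`, ln$sales)
  variable <- Reduce(`+`, ln$variable)
  fixed_total <- sum(as.numeric(spec$fixed_costs))
  gross_margin <- sales - variable
  net_profit <- gross_margin - fixed_total
  infeasible <- a$pigs_sold <= 0 | a$meat_kg <= 0
  iters <- data.frame(iteration = seq_len(n_iter), x,
                      pigs_sold = a$pigs_sold, meat_kg = a$meat_kg,
                      gross_margin = gross_margin, net_profit = net_profit,
                      gross_margin_pig = gross_margin / a$pigs_sold,
                      net_profit_pig = net_profit / a$pigs_sold,
                      gross_margin_kg = gross_margin / a$meat_kg,
                      net_profit_kg = net_profit / a$meat_kg,
                      infeasible = infeasible)
  structure(list(scenario = spec$name, iterations = iters,
                 summary = risk_summary_table(iters),
                 n_iter = n_iter, seed = seed,
                 n_infeasible = sum(infeasible)),
            class = "risk_result")
}

summarise_draws <- function(v) {
  c(mean = mean(v), sd = stats::sd(v),
    p05 = unname(stats::quantile(v, 0.05)),
    p95 = unname(stats::quantile(v, 0.95)),
    min = min(v), max = max(v))
}

#' Summary table of a risk run
#'
#' Mean, SD, 5th and 95th percentile, minimum and maximum of the gross
#' margin and net profit per year, per pig and per kg of meat.
#'
#' @param iters An iteration `data.frame` from a `risk_result`.
#' @return `data.frame` with one row per (variable, scale).
#' @export
risk_summary_table <- function(iters) {
  vars <- c(gross_margin = "gross_margin", net_profit = "net_profit")
  scales <- c(eur_year = "", eur_pig = "_pig", eur_kg = "_kg")
  rows <- list()
  for (v in names(vars)) for (s in names(scales)) {
    col <- paste0(vars[[v]], scales[[s]])
    rows[[paste(v, s)]] <- data.frame(variable = v, scale = s,
                                      t(summarise_draws(iters[[col]])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("Monte Carlo risk analysis - %s (%d iterations, seed %d",
              x$scenario, x$n_iter, x$seed))
  if (x$n_infeasible > 0)
    cat(sprintf(", %d infeasible iterations", x$n_infeasible))
  cat(")\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %-8s mean %12.2f sd %11.2f  [5%%, 95%%] = [%.2f, %.2f]\n",
                s$variable[i], s$scale[i], s$mean[i], s$sd[i],
                s$p05[i], s$p95[i]))
  invisible(x)
}

#' Write risk iterations and summary as CSV
#' @param result A `risk_result`.
#' @param iter_path,summary_path Output file paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_risk_result <- function(result, iter_path = NULL, summary_path = NULL) {
  if (!is.null(iter_path))
    utils::write.csv(result$iterations, iter_path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(result$summary, summary_path, row.names = FALSE)
  invisible(c(iter_path, summary_path))
}
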