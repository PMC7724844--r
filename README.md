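# plucksim

Bio-economic simulation of pluck-lesion impacts on farrow-to-finish pig
farm performance.

## The problem

At slaughter, the "pluck" (lungs, heart, liver) of each pig can be scored
for lesions: pleurisy, enzootic-pneumonia-like lung lesions, healed lung
scars, abscesses, pericarditis, and liver milk spots. Batches with a high
prevalence of these lesions grow more slowly — respiratory disease in
particular depresses grower-finisher average daily gain (ADG) — and slower
growth propagates through the whole enterprise: pigs occupy houses longer,
eat more feed per kilogram gained, fewer pigs are finished per year, and
annual profit falls.

`plucksim` connects these pieces into one auditable pipeline:

1. **Lesion prevalence → growth.** A regression-tree engine (CART with
   cost-complexity pruning and cross-validated tree-size selection, written
   in-package) finds prevalence cut-offs that partition farm batches into
   growth classes. A synthetic cohort generator produces batch-level data
   with known, engineered structure so the tree's recovery behaviour can be
   tested end to end.
2. **Growth → physical flows.** A Gompertz growth curve is calibrated in
   closed form to each ADG class, and a weekly steady-state herd-flow model
   for a 728-sow farrow-to-finish farm converts growth into pigs weaned,
   transferred, finished and sold, deaths by stage, and feed demand by diet
   (metabolic-weight intake integrated over the housed windows).
3. **Flows → money.** An itemized profit-and-loss account prices every
   physical line (exact-cent arithmetic) and compares scenarios.
4. **Money → risk.** Monte Carlo simulation draws the biological and price
   inputs from modified-PERT distributions, induces rank correlation with
   the Iman-Conover method (marginals preserved exactly), and compares the
   resulting net-profit distributions with first- and second-order
   stochastic dominance on the merged empirical grid.

Three scenarios are built in, defined by grower-finisher ADG:

| Scenario | Meaning | ADG (g/day) | Sale age |
|---|---|---|---|
| `LPLSC` | low prevalence, low scar count | 760 | 24 weeks |
| `LPHSC` | low prevalence, high scar count | 725 | 25 weeks |
| `HP` | high prevalence | 671 | 27 weeks |

## Worked example

Deterministic year and enterprise budget for the best scenario:

```r
library(plucksim)
scen <- default_scenarios()
spec <- scen$LPLSC
sim  <- simulate_year(spec)
acc  <- build_pnl(sim$annual, spec$prices, spec$fixed_costs, spec$herd_size)
acc$totals
```

The printed account ends with:

```
  total_variable             1608595.26     85.28    1.025
  gross_margin                972078.77     51.54    0.620
  total_fixed                 665117.00     35.26    0.424
  net_profit                  306961.77     16.27    0.196
```

with 18,862 pigs sold and 1,568.6 t of meat. Comparing the three scenarios:

```r
accs <- lapply(scen, function(s)
  build_pnl(simulate_year(s)$annual, s$prices, s$fixed_costs, s$herd_size))
cmp <- compare_scenarios(accs)
cmp[cmp$line == "net_profit", ]
#>         line    LPLSC    LPHSC LPHSC_diff LPHSC_pct       HP   HP_diff HP_pct
#>   net_profit 306961.8 193504.7  -113457.0     -37.0  87641.51 -219320.3  -71.4
```

High lesion prevalence costs this farm roughly 219,000 EUR/year in net
profit relative to the low-prevalence, low-scar state.

Fitting the lesion tree to a synthetic cohort recovers the engineered
cut-offs:

```r
co  <- generate_cohort(seed = 1)
fit <- fit_lesion_tree(co, seed = 1)
fit$tree
#> prev_pleurisy < 26.56 (n=56 mean=724.5)
#>   prev_scars < 6.153 (n=46 mean=736.9)
#>     leaf: n=15 mean=764.3
#>     leaf: n=31 mean=723.6
#>   leaf: n=10 mean=667.6
partition_anova(fit$tree, co)   # both splits p < 1e-7
```

Monte Carlo risk for `LPLSC` (10,000 iterations):

```r
run_monte_carlo(spec, n_iter = 10000, seed = 1)
#> net_profit eur_year mean 307887.29 sd 83657.66  [5%, 95%] = [169307, 447392]
```

and stochastic dominance between scenario profit distributions:

```r
np <- lapply(scen, function(s)
  run_monte_carlo(s, n_iter = 10000, seed = 1)$iterations$net_profit)
fosd(np$LPLSC, np$HP)$dominates   # TRUE: LPLSC first-order dominates HP
```

## Command-line interface

`inst/cli/plucksim` exposes the pipeline as subcommands (`generate`,
`tree`, `simulate`, `risk`, `report`), each writing CSV/JSON plus a
`run_manifest.yaml` recording the command, seed and outputs:

```sh
plucksim risk --scenario LPLSC --n-iter 10000 --seed 1 --out outdir/
```
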