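# Synthetic farm-cohort generator.
#
# Emulates the statistical structure of a 56-farm farrow-to-finish cohort:
# three clusters of farms defined by pleurisy and lung-scar prevalence
# cut-offs (25% and 8%), with distinct wean-to-finish ADG levels, plus nine
# performance indicators drawn from bounded distributions parameterised by
# per-cluster (min, mean, max) triples.

# Per-cluster (min, mean, max) triples for the nine performance indicators,
# from 2017 Irish farrow-to-finish farm records grouped by lesion cluster.
.bio_triples <- list(
  LPLSC = list(
    farrowing_rate        = c(81,   89.3, 95.7),
    litters_per_sow_year  = c(2.09, 2.30, 2.43),
    born_alive_per_litter = c(12.4, 13.7, 15.2),
    sow_culling_rate      = c(34.3, 46.9, 58.0),
    sow_mortality         = c(2.3,  4.2,  9.3),
    piglet_mortality      = c(6.8,  10.7, 14.3),
    weaner_mortality      = c(0.5,  2.1,  6.8),
    finisher_mortality    = c(0.9,  1.7,  3.3),
    dressing_pct          = c(75.1, 76.2, 78.1)),
  LPHSC = list(
    farrowing_rate        = c(73,   88.2, 96.1),
    litters_per_sow_year  = c(2.11, 2.28, 2.50),
    born_alive_per_litter = c(11.6, 13.6, 15.3),
    sow_culling_rate      = c(37.8, 51.1, 63.9),
    sow_mortality         = c(1.8,  5.4,  9.2),
    piglet_mortality      = c(5.7,  10.8, 15.9),
    weaner_mortality      = c(0.9,  2.9,  8.9),
    finisher_mortality    = c(1.0,  2.1,  4.1),
    dressing_pct          = c(74.8, 76.2, 77.4)),
  HP = list(
    farrowing_rate        = c(81.8, 87.9, 91.2),
    litters_per_sow_year  = c(2.24, 2.33, 2.46),
    born_alive_per_litter = c(12.8, 13.4, 14.0),
    sow_culling_rate      = c(39.0, 47.0, 54.9),
    sow_mortality         = c(3.2,  4.7,  9.7),
    piglet_mortality      = c(5.6,  9.9,  14.0),
    weaner_mortality      = c(1.5,  3.7,  7.0),
    finisher_mortality    = c(1.3,  2.3,  3.0),
    dressing_pct          = c(76.0, 76.8, 77.8))
)

.lesion_names <- c("prev_pleurisy", "prev_ep_like", "prev_scars",
                   "prev_abscess", "prev_pericarditis", "prev_milk_spots")

.indicator_names <- names(.bio_triples$LPLSC)

#' Specification of one farm cluster
#'
#' Describes one cluster of farms for the synthetic-cohort generator: lesion
#' prevalences are truncated normals (clipped to `[0, 100]` and to the
#' cluster's side of the relevant prevalence cut-off), ADG is normal, and
#' each performance indicator is a modified-PERT distribution on its
#' `(min, mean, max)` triple.
#'
#' @param name Cluster label.
#' @param n_farms Number of farms (>= 1).
#' @param lesions Named list; each element `c(mean, sd, lower, upper)` for
#'   one of the six lesion-prevalence columns.
#' @param adg_mean,adg_sd Wean-to-finish ADG distribution, g/day. The
#'   default SD of 20 g/day is a stand-in (within-cluster ADG spread is not
#'   part of the reference summaries) chosen well below the between-cluster
#'   gaps so clusters stay statistically separable.
#' @param indicators Named list of `(min, mean, max)` triples for the nine
#'   performance indicators.
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(name, n_farms, lesions, adg_mean, adg_sd = 20,
                         indicators) {
  stopifnot(n_farms >= 1, adg_sd >= 0, adg_mean > 0)
  if (!setequal(names(lesions), .lesion_names))
    stop("lesions must be specified for exactly: ",
         paste(.lesion_names, collapse = ", "))
  if (!setequal(names(indicators), .indicator_names))
    stop("indicators must be specified for exactly: ",
         paste(.indicator_names, collapse = ", "))
  for (nm in names(lesions)) {
    l <- lesions[[nm]]
    if (length(l) != 4L || l[2] < 0 || l[3] >= l[4])
      stop("lesion spec ", nm, " must be c(mean, sd>=0, lower < upper)")
  }
  for (nm in names(indicators)) {
    tr <- indicators[[nm]]
    if (length(tr) != 3L || !(tr[1] <= tr[2] && tr[2] <= tr[3]))
      stop("indicator triple ", nm, " must satisfy min <= mean <= max")
  }
  structure(list(name = name, n_farms = as.integer(n_farms),
                 lesions = lesions[.lesion_names],
                 adg_mean = adg_mean, adg_sd = adg_sd,
                 indicators = indicators[.indicator_names]),
            class = "cluster_spec")
}

#' Default three-cluster cohort specification
#'
#' Three clusters of 17, 29 and 10 farms mirroring a 56-farm cohort:
#' low pleurisy / low scars (ADG 760 g/d; pleurisy 3.9% +/- 4.94 truncated
#' below the 25% cut-off, scars 2.8% +/- 3.32 below the 8% cut-off), low
#' pleurisy / high scars (ADG 725; pleurisy 7.5 +/- 6.17, scars 18.7 +/-
#' 8.34 at or above 8%), and high pleurisy (ADG 671; pleurisy 38.8 +/- 7.55
#' at or above 25%). Truncating each lesion to its cluster's side of the
#' cut-off reflects how the clusters are defined (post hoc, by the
#' cut-offs) and guarantees the tree-recoverable structure. Lesions with no
#' association to ADG (pneumonia-like, abscesses, pericarditis, milk spots)
#' share one distribution across clusters and act as noise predictors.
#'
#' @param adg_sd Within-cluster ADG standard deviation, g/day (default 20).
#' @return List of three [cluster_spec()] objects.
#' @export
default_cluster_specs <- function(adg_sd = 20) {
  noise <- list(prev_ep_like       = c(30, 15, 0, 100),
                prev_abscess       = c(3,  3,  0, 100),
                prev_pericarditis  = c(5,  4,  0, 100),
                prev_milk_spots    = c(10, 10, 0, 100))
  list(
    cluster_spec("LPLSC", 17,
                 lesions = c(list(prev_pleurisy = c(3.9, 4.94, 0, 25),
                                  prev_scars    = c(2.8, 3.32, 0, 8)), noise),
                 adg_mean = 760, adg_sd = adg_sd,
                 indicators = .bio_triples$LPLSC),
    cluster_spec("LPHSC", 29,
                 lesions = c(list(prev_pleurisy = c(7.5, 6.17, 0, 25),
                                  prev_scars    = c(18.7, 8.34, 8, 100)), noise),
                 adg_mean = 725, adg_sd = adg_sd,
                 indicators = .bio_triples$LPHSC),
    cluster_spec("HP", 10,
                 lesions = c(list(prev_pleurisy = c(38.8, 7.55, 25, 100),
                                  prev_scars    = c(19.3, 12.1, 0, 100)), noise),
                 adg_mean = 671, adg_sd = adg_sd,
                 indicators = .bio_triples$HP)
  )
}

# Deterministic sub-seeds fanned out from one master seed.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  s
}

#' Generate a synthetic farm cohort
#'
#' Draws one farm record per farm in each cluster. Lesion prevalences come
#' from truncated normals, ADG from a normal (floored at 1 g/day), and the
#' nine performance indicators from modified-PERT distributions on their
#' `(min, mean, max)` triples. Each cluster uses its own RNG stream derived
#' deterministically from the master seed, so the same seed always yields a
#' byte-identical table.
#'
#' @param clusters List of [cluster_spec()] objects.
#' @param seed Integer master seed.
#' @return A `data.frame` with one row per farm: `farm_id`, `cluster`, the
#'   six lesion-prevalence columns, `adg`, and the nine performance
#'   indicators.
#' @export
generate_cohort <- function(clusters = default_cluster_specs(), seed = 1L) {
  if (length(clusters) == 0L) stop("empty cluster list")
  stopifnot(all(vapply(clusters, inherits, TRUE, "cluster_spec")))
  seeds <- derive_seeds(seed, length(clusters))
  recs <- vector("list", length(clusters))
  offset <- 0L
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    set.seed(seeds[i])
    n <- cl$n_farms
    df <- data.frame(farm_id = sprintf("farm_%03d", offset + seq_len(n)),
                     cluster = cl$name, stringsAsFactors = FALSE)
    for (nm in .lesion_names) {
      l <- cl$lesions[[nm]]
      df[[nm]] <- rtruncnorm(n, l[1], l[2],
                             lower = max(0, l[3]), upper = min(100, l[4]))
    }
    df$adg <- pmax(1, stats::rnorm(n, cl$adg_mean, cl$adg_sd))
    for (nm in .indicator_names) {
      df[[nm]] <- rpert(n, fit_distribution(cl$indicators[[nm]], name = nm))
    }
    recs[[i]] <- df
    offset <- offset + n
  }
  cohort <- do.call(rbind, recs)
  rownames(cohort) <- NULL
  validate_cohort(cohort)
  cohort
}

#' Validate farm-record invariants
#'
#' Checks that all percentage columns lie in `[0, 100]`, ADG is positive and
#' litters per sow per year lies in `(0, 3]`.
#'
#' @param cohort A cohort `data.frame` as from [generate_cohort()].
#' @return The cohort, invisibly; stops on violation.
#' @export
validate_cohort <- function(cohort) {
  pct_cols <- c(.lesion_names, "farrowing_rate", "sow_culling_rate",
                "sow_mortality", "piglet_mortality", "weaner_mortality",
                "finisher_mortality", "dressing_pct")
  missing <- setdiff(c(pct_cols, "adg", "litters_per_sow_year",
                       "born_alive_per_litter"), names(cohort))
  if (length(missing))
    stop("cohort missing columns: ", paste(missing, collapse = ", "))
  for (nm in pct_cols)
    if (any(cohort[[nm]] < 0 | cohort[[nm]] > 100))
      stop("column ", nm, " outside [0, 100]")
  if (any(cohort$adg <= 0)) stop("adg must be positive")
  if (any(cohort$litters_per_sow_year <= 0 |
          cohort$litters_per_sow_year > 3))
    stop("litters_per_sow_year must lie in (0, 3]")
  invisible(cohort)
}

#' Write / read a cohort table as CSV
#'
#' Plain UTF-8 CSV with a header row and decimal points. Numeric values are
#' written with 17 significant digits so a write/read cycle round-trips
#' doubles exactly.
#'
#' @param cohort Cohort `data.frame`.
#' @param path File path.
#' @return `write_cohort` returns the path invisibly; `read_cohort` returns
#'   the cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  validate_cohort(df)
  df
}

#' Write / read cluster specifications as YAML
#'
#' @param clusters List of [cluster_spec()] objects.
#' @param path File path.
#' @return `write_cluster_specs` returns the path invisibly;
#'   `read_cluster_specs` a list of [cluster_spec()] objects.
#' @export
write_cluster_specs <- function(clusters, path) {
  payload <- lapply(clusters, function(cl) {
    list(name = cl$name, n_farms = cl$n_farms,
         lesions = lapply(cl$lesions, as.numeric),
         adg_mean = cl$adg_mean, adg_sd = cl$adg_sd,
         indicators = lapply(cl$indicators, as.numeric))
  })
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_cluster_specs
#' @export
read_cluster_specs <- function(path) {
  payload <- yaml::read_yaml(path)
  lapply(payload, function(p)
    cluster_spec(p$name, p$n_farms, lapply(p$lesions, as.numeric),
                 p$adg_mean, p$adg_sd, lapply(p$indicators, as.numeric)))
}
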