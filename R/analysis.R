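#' Fitness and selection statistics
#'
#' The analysis substrate is the fitness table: one row per agent ever
#' created, carrying its six scaled abilities, its lifetime reproductive
#' success (offspring count, the model's fitness measure), and a body-mass
#' statistic. The mass statistic is the lifetime mean body mass: mass at a
#' starvation death always sits just under the starvation floor and so
#' carries no information about the mass an agent actually operated at,
#' whereas the lifetime mean tracks the energetically sustained mass (the
#' quantity of interest for an adaptive-mass estimate). The final and peak
#' masses are kept alongside.
#'
#' @name analysis
NULL

#' Build the fitness table from a run or a records data.frame
#'
#' @param x an `allosim` object or its `records` data.frame.
#' @param mass which recorded mass statistic populates the `mass` column.
#' @return data.frame with columns `id`, `offspring`, `bin` (offspring
#'   count, capped at the maximum observed), the six ability columns named
#'   by trait, `mass` and `energy_budget` (daily meat requirement at
#'   `mass`).
#' @export
fitness_table <- function(x, mass = c("mean_mass", "final_mass",
                                      "max_mass")) {
  mass <- match.arg(mass)
  rec <- if (inherits(x, "allosim")) x$records else x
  stopifnot(is.data.frame(rec), nrow(rec) > 0)
  need <- c("id", "offspring", mass, trait_names())
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop("records are missing required columns: ",
         paste(miss, collapse = ", "))
  }
  out <- rec[c("id", "offspring", trait_names())]
  out$mass <- rec[[mass]]
  out$energy_budget <- daily_meat_requirement(out$mass)
  out$bin <- out$offspring
  out
}

#' Fraction of agents that never reproduced
#'
#' @param table a fitness table (or anything [fitness_table()] accepts).
#' @return proportion in `[0, 1]`.
#' @export
zero_offspring_fraction <- function(table) {
  table <- as_fitness_table(table)
  if (nrow(table) == 0L) stop("empty fitness table")
  mean(table$offspring == 0)
}

as_fitness_table <- function(x) {
  if (is.data.frame(x) && "offspring" %in% names(x)) {
    if (!"bin" %in% names(x)) x[["bin"]] <- x[["offspring"]]
    return(x)
  }
  fitness_table(x)
}

#' Trait-stratified reproduction probability
#'
#' Splits the population at an ability threshold and returns the empirical
#' probability of producing `k` offspring (exactly `k` by default, or at
#' least `k`) in each stratum.
#'
#' @param table fitness table.
#' @param trait one of [trait_names()].
#' @param threshold ability threshold (trait units) defining the "above"
#'   stratum (strictly greater).
#' @param k offspring count.
#' @param mode `"exact"` for `P(offspring == k)`, `"at_least"` for
#'   `P(offspring >= k)`.
#' @return named numeric `c(above = , below = )`; a stratum that is empty
#'   yields `NA` with a warning.
#' @export
offspring_probability <- function(table, trait, threshold, k = 1,
                                  mode = c("exact", "at_least")) {
  mode <- match.arg(mode)
  table <- as_fitness_table(table)
  stopifnot(trait %in% trait_names() || trait %in% names(table))
  hi <- table[[trait]] > threshold
  hit <- if (mode == "exact") table$offspring == k else table$offspring >= k
  p <- function(sel) {
    if (!any(sel)) {
      warning("empty stratum; probability undefined")
      return(NA_real_)
    }
    mean(hit[sel])
  }
  c(above = p(hi), below = p(!hi))
}

#' Trait fitness ratio
#'
#' Ratio of the above-threshold to the below-threshold reproduction
#' probability from [offspring_probability()]. Values above 1 indicate
#' positive selection on the trait, below 1 negative selection.
#'
#' @inheritParams offspring_probability
#' @return scalar ratio (`NA` if a stratum is empty, `Inf` if the below
#'   stratum never reproduces at `k`).
#' @export
fitness_ratio <- function(table, trait, threshold, k = 1,
                          mode = c("exact", "at_least")) {
  p <- offspring_probability(table, trait, threshold, k, mode)
  unname(p["above"] / p["below"])
}

#' Mean trait and mass values by offspring bin
#'
#' @param table fitness table.
#' @return data.frame with one row per observed offspring count: `bin`,
#'   `n`, mean of each of the six abilities, `mass` and `energy_budget`.
#' @export
bin_summary <- function(table) {
  table <- as_fitness_table(table)
  if (nrow(table) == 0L) stop("empty fitness table")
  cols <- intersect(c(trait_names(), "mass", "energy_budget"), names(table))
  bins <- sort(unique(table$bin))
  out <- data.frame(bin = bins,
                    n = as.integer(tabulate(match(table$bin, bins),
                                            length(bins))))
  for (cl in cols) {
    out[[cl]] <- vapply(bins, function(b) mean(table[[cl]][table$bin == b]),
                        numeric(1))
  }
  out
}

#' Mean mass (and fat-storage ability) of reproductively successful agents
#'
#' @param table fitness table.
#' @return list with `mass` (kg), `tailfat` (kg/day) and `n` (stratum
#'   size), over agents with at least one offspring.
#' @export
successful_mass_mean <- function(table) {
  table <- as_fitness_table(table)
  s <- table[table$offspring >= 1, ]
  if (nrow(s) == 0L) {
    warning("no reproductively successful agents")
    return(list(mass = NA_real_, tailfat = NA_real_, n = 0L))
  }
  list(mass = mean(s$mass), tailfat = mean(s$tailfat), n = nrow(s))
}

#' Kernel density of lifetime reproductive success
#'
#' Gaussian KDE over integer offspring counts, with Silverman's
#' rule-of-thumb bandwidth (a fixed fallback handles degenerate
#' zero-variance strata). The returned `pdf` closure is the exact normal
#' mixture and integrates to 1 over the real line.
#'
#' @param table fitness table (optionally pre-filtered to a stratum).
#' @param bw bandwidth; default Silverman.
#' @param n grid size.
#' @return list of class `rs_density`: grid `x`, `y`, the `bw` used, and
#'   the `pdf` function.
#' @export
reproductive_success_density <- function(table, bw = NULL, n = 512L) {
  table <- as_fitness_table(table)
  v <- table$offspring
  if (length(v) == 0L) stop("empty stratum")
  if (is.null(bw)) {
    bw <- stats::bw.nrd0(v)
    if (!is.finite(bw) || bw <= 0) bw <- 0.3
  }
  pdf <- function(t) {
    vapply(t, function(ti) mean(stats::dnorm(ti, mean = v, sd = bw)),
           numeric(1))
  }
  x <- seq(min(v) - 4 * bw, max(v) + 4 * bw, length.out = n)
  structure(list(x = x, y = pdf(x), bw = bw, n_obs = length(v), pdf = pdf),
            class = "rs_density")
}

#' Yearly expression-class composition
#'
#' Distribution of expression classes per trait among agents alive on each
#' year's final day; frequencies sum to 1 within every trait-year (years in
#' which the population was extinct carry `NA`).
#'
#' @param x an `allosim` object or its `yearly` data.frame.
#' @return long data.frame `year`, `trait`, `class`, `n`, `freq`, `alive`.
#' @export
composition_timeseries <- function(x) {
  y <- if (inherits(x, "allosim")) x$yearly else x
  stopifnot(is.data.frame(y),
            all(c("year", "trait", "class", "n", "freq") %in% names(y)))
  y[c("year", "trait", "class", "n", "freq", "alive")]
}

#' Expand a binned reproductive-success tabulation into per-agent counts
#'
#' Utility for validating the summary statistics against published binned
#' tabulations: turns a (offspring count, bin size) table into the implied
#' vector of per-agent offspring counts.
#'
#' @param offspring integer vector of offspring counts.
#' @param n integer vector of bin sizes.
#' @return integer vector of length `sum(n)`.
#' @export
lrs_from_bins <- function(offspring, n) {
  stopifnot(length(offspring) == length(n), all(n >= 0))
  rep(as.integer(offspring), times = as.integer(n))
}
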