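#' Run the foraging-evolution simulation
#'
#' Executes the daily cycle — carcass spawning, perception and movement,
#' carcass-site feeding contests, prey pursuit, metabolic update and
#' starvation, births, carcass decay and removal, prey replenishment — for
#' the configured horizon and returns the complete life-history record set:
#' one immutable row for every agent ever created, plus yearly
#' phenotype-composition snapshots, per-day population series, conservation
#' counters, and (optionally) a per-event log.
#'
#' @param config an [allosim_config()] object.
#' @param seed integer seed; every source of randomness in the run flows
#'   from it, so identical `config` and `seed` give a bit-identical
#'   trajectory. `NULL` leaves the current RNG state untouched.
#' @return An object of class `allosim`: a list with elements
#'   \describe{
#'     \item{records}{data.frame, one row per agent: `id`, `parent` (0 for
#'       founders), `born_day`, `died_day` (`NA` when censored at the end
#'       of the run), `cause` (`"starvation"` or `"censored"`),
#'       `offspring`, `final_mass`, `mean_mass` (lifetime mean body mass,
#'       kg), `max_mass`, `lifespan` (days), then per trait an expression
#'       class (`<trait>_class`), an advantage factor (`<trait>_factor`)
#'       and the scaled ability under the trait's own name.}
#'     \item{yearly}{long data.frame of end-of-year expression-class counts
#'       and frequencies per trait, plus mean abilities and mean mass of
#'       the standing population.}
#'     \item{annual_spawns}{integer vector, sauropod carcasses generated
#'       per simulated year.}
#'     \item{daily}{matrix of per-day series (population sizes, intake,
#'       consumption, births, deaths).}
#'     \item{counters}{named list of run totals (meat conservation ledger,
#'       births, starvations, pursuit/strike/kill counts).}
#'     \item{events}{data.frame event log (empty unless
#'       `config$log_events`).}
#'     \item{config, seed}{inputs echoed for reproducibility.}
#'   }
#' @examples
#' \donttest{
#' fit <- allosim(allosim_config(years = 2), seed = 1)
#' print(fit)
#' }
#' @export
allosim <- function(config = allosim_config(), seed = NULL) {
  stopifnot(inherits(config, "allosim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  tt <- config$trait_table[match(trait_names(), config$trait_table$trait), ]
  b <- factor_bounds()
  ecfg <- c(unclass(config)[setdiff(names(config),
                                    c("trait_table", "factor_inheritance"))],
            list(copy_same = config$factor_inheritance == "copy_when_same",
                 trait_scale = tt$scale,
                 trait_offset = tt$offset,
                 bound_lo = unname(b[, "lo"]),
                 bound_hi = unname(b[, "hi"]),
                 transition = expression_transition_matrix()))
  raw <- .run_engine(ecfg)

  rec <- as.data.frame(raw$records)
  names(rec) <- c("id", "parent", "born_day", "died_day", "cause_code",
                  "offspring", "final_mass", "mean_mass", "max_mass",
                  paste0(trait_names(), "_rank"),
                  paste0(trait_names(), "_factor"),
                  trait_names())
  rec$died_day[rec$died_day < 0] <- NA
  rec$cause <- c("starvation", "censored")[rec$cause_code + 1L]
  rec$lifespan <- ifelse(is.na(rec$died_day),
                         config$days - rec$born_day,
                         rec$died_day - rec$born_day + 1L)
  lv <- expression_levels()
  for (tr in trait_names()) {
    rec[[paste0(tr, "_class")]] <- lv[rec[[paste0(tr, "_rank")]] + 1L]
    rec[[paste0(tr, "_rank")]] <- NULL
  }
  rec$cause_code <- NULL

  yearly <- build_yearly(raw, config)

  ev <- as.data.frame(raw$events)
  if (nrow(ev)) {
    codes <- c("carcass_spawn", "feed", "kill", "strike_fail",
               "carcass_removed", "starve", "birth", "pursuit_lost",
               "pursuit_abandoned", "refound")
    ev$type <- codes[ev$type]
    ev$agent <- ifelse(ev$agent >= 0, ev$agent + 1L, NA_integer_)
  }

  daily <- raw$daily
  colnames(daily) <- c("allosaurs", "prey", "sauropod_carcasses",
                       "prey_carcasses", "intake", "consumed", "births",
                       "deaths")

  structure(list(records = rec,
                 yearly = yearly,
                 annual_spawns = as.integer(raw$annual_spawns),
                 daily = daily,
                 counters = raw$counters,
                 events = ev,
                 config = config,
                 seed = seed),
            class = "allosim")
}

build_yearly <- function(raw, config) {
  lv <- expression_levels()
  trs <- trait_names()
  nyr <- length(raw$snap_alive)
  full_years <- which(seq_len(nyr) * config$days_per_year <= config$days)
  out <- vector("list", length(full_years) * 6L)
  k <- 0L
  for (y in full_years) {
    n <- raw$snap_alive[y]
    for (g in seq_len(6L)) {
      cnt <- raw$snap_counts[y, ((g - 1L) * 5L + 1L):(g * 5L)]
      k <- k + 1L
      out[[k]] <- data.frame(
        year = y, trait = trs[g], class = lv,
        n = as.integer(cnt),
        freq = if (n > 0) cnt / n else NA_real_,
        alive = n,
        mean_ability = if (n > 0) raw$snap_abil[y, g] / n else NA_real_,
        mean_mass = if (n > 0) raw$snap_mass[y] / n else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.allosim <- function(x, ...) {
  n <- nrow(x$records)
  zf <- mean(x$records$offspring == 0)
  cat("Foraging-evolution simulation (allosim)\n")
  cat(sprintf("  %d days (%.1f years), seed %s\n",
              x$config$days, x$config$days / x$config$days_per_year,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  cat(sprintf("  agents produced: %d (%d founders)\n",
              n, x$config$init_allosaurs))
  cat(sprintf("  zero-offspring fraction: %.3f\n", zf))
  cat(sprintf("  kills: %d of %d strikes (%d pursuits)\n",
              as.integer(x$counters$kills), as.integer(x$counters$strikes),
              as.integer(x$counters$pursuits)))
  invisible(x)
}

#' @export
summary.allosim <- function(object, ...) {
  tab <- fitness_table(object)
  succ <- successful_mass_mean(tab)
  s <- list(
    agents_produced = nrow(tab),
    zero_offspring_fraction = zero_offspring_fraction(tab),
    max_offspring = max(tab$offspring),
    tailfat_fitness_ratio = fitness_ratio(tab, "tailfat", 35, k = 1),
    bite_force_fitness_ratio = fitness_ratio(tab, "bite_force", 0.11, k = 1),
    successful_mean_mass = succ$mass,
    successful_mean_tailfat = succ$tailfat,
    mean_annual_spawns = mean(object$annual_spawns),
    kills = object$counters$kills,
    seed = object$seed
  )
  class(s) <- "summary.allosim"
  s
}

#' @export
print.summary.allosim <- function(x, ...) {
  cat("allosim run summary\n")
  cat(sprintf("  agents produced:            %d\n", x$agents_produced))
  cat(sprintf("  zero-offspring fraction:    %.3f\n",
              x$zero_offspring_fraction))
  cat(sprintf("  max offspring:              %d\n", x$max_offspring))
  cat(sprintf("  tailfat fitness ratio:      %.2f  (> 35 kg vs rest, k = 1)\n",
              x$tailfat_fitness_ratio))
  cat(sprintf("  bite-force fitness ratio:   %.2f  (> 0.11 vs rest, k = 1)\n",
              x$bite_force_fitness_ratio))
  cat(sprintf("  successful agents: mean mass %.0f kg, mean tailfat %.1f kg\n",
              x$successful_mean_mass, x$successful_mean_tailfat))
  cat(sprintf("  sauropod carcasses/year:    %.1f\n", x$mean_annual_spawns))
  invisible(x)
}

#' Plot method for simulation runs
#'
#' `type = "composition"` draws the yearly expression-class frequencies of
#' one trait among the standing population; `type = "lrs"` draws the
#' kernel-density estimate of lifetime reproductive success for a
#' high-ability stratum against the rest.
#'
#' @param x an `allosim` object.
#' @param type which panel to draw.
#' @param trait trait shown.
#' @param threshold stratum boundary (ability units) for `type = "lrs"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.allosim <- function(x, type = c("composition", "lrs"),
                         trait = "tailfat", threshold = 35, ...) {
  type <- match.arg(type)
  if (type == "composition") {
    comp <- composition_timeseries(x)
    comp <- comp[comp$trait == trait, ]
    lv <- expression_levels()
    cols <- grDevices::hcl.colors(5, "Zissou 1")
    graphics::plot(NULL, xlim = range(comp$year), ylim = c(0, 1),
                   xlab = "year", ylab = "class frequency",
                   main = paste0(trait, ": standing-population composition"),
                   ...)
    for (i in seq_along(lv)) {
      d <- comp[comp$class == lv[i], ]
      graphics::lines(d$year, d$freq, col = cols[i], lwd = 1.5)
    }
    graphics::legend("topright", legend = lv, col = cols, lwd = 1.5,
                     cex = 0.7, bg = "white")
  } else {
    tab <- fitness_table(x)
    hi <- tab[tab[[trait]] > threshold, ]
    lo <- tab[tab[[trait]] <= threshold, ]
    dh <- reproductive_success_density(hi)
    dl <- reproductive_success_density(lo)
    graphics::plot(dh$x, dh$y, type = "l", col = "firebrick", lwd = 2,
                   xlab = "lifetime offspring", ylab = "density",
                   main = paste0("reproductive success: ", trait,
                                 " > ", threshold, " vs rest"),
                   ylim = c(0, max(dh$y, dl$y)), ...)
    graphics::lines(dl$x, dl$y, col = "grey40", lwd = 2, lty = 2)
    graphics::legend("topright",
                     legend = c(paste0(trait, " > ", threshold), "rest"),
                     col = c("firebrick", "grey40"), lwd = 2, lty = c(1, 2))
  }
  invisible(x)
}
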