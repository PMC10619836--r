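#' Simulation configuration
#'
#' All defaults are the study conditions: a 70 km torus, 279 years of 365
#' days, 12 founders, a standing cap of 30 agents, a per-agent daily birth
#' probability of 0.02, at least 20 prey maintained, at most 5 concurrent
#' sauropod carcasses of 10--25 t spawned only in the seasonal windows, a
#' 20% inedible carcass residual, and a 0.02 daily random carcass-removal
#' probability. Quantities the study leaves open (daily decay 0.5% of
#' initial carcass mass, in-window spawn probability 0.12/day, 0.1 km
#' capture radius, a 5-day pursuit give-up horizon, 5 carcasses standing at
#' initialization) are fixed here once and documented in the methods
#' vignette. Every field can be overridden.
#'
#' @param years simulated years.
#' @param days total simulated days; defaults to `years * days_per_year`
#'   (override for short smoke runs).
#' @param days_per_year calendar length.
#' @param grid_km torus edge, km.
#' @param init_allosaurs founder count.
#' @param max_allosaurs standing population cap.
#' @param birth_rate per-agent, per-day reproduction probability (gated by
#'   the cap and the condition floor).
#' @param birth_cost_kg maternal mass drawn down by one reproduction event
#'   (clutch investment), kg.
#' @param birth_min_mass body-condition floor for breeding, kg: agents
#'   below it skip reproduction attempts. Defaults to the initialization
#'   mass, so breeding is confined to fed, healthy-condition animals.
#' @param min_prey prey population floor (replenished daily).
#' @param move_km agent and prey daily travel limit, km.
#' @param wiggle_deg undirected movement is a correlated random walk: each
#'   day the persistent heading changes by at most this many degrees in
#'   either direction (the search style of the wolf-sheep family of
#'   foraging models; 180 recovers an uncorrelated walk).
#' @param capture_km strike radius ending a pursuit, km.
#' @param max_pursuit_days give-up horizon for an unresolved chase.
#' @param init_mass agent initialization mass, kg.
#' @param starvation_frac starvation floor as a fraction of `init_mass`.
#' @param fmr_anchor_mass,fmr_anchor_req,fmr_exponent daily-requirement
#'   allometry `N(M) = req * (M/anchor)^exp`.
#' @param carcass_cap maximum concurrent sauropod carcasses.
#' @param p_spawn daily in-window spawn probability while below the cap.
#' @param carcass_mass_min,carcass_mass_max sauropod carcass mass range, kg.
#' @param prey_carcass_mass mass of a killed-prey carcass, kg.
#' @param residual_frac inedible residual fraction of a carcass.
#' @param decay_frac daily decay, fraction of initial carcass mass.
#' @param removal_prob random carcass-removal probability; see
#'   `removal_mode`.
#' @param removal_mode `"lifetime"` (default): a fraction `removal_prob`
#'   of carcasses is fated to vanish early, at a uniform random day of the
#'   decay-limited life, so random interruption touches only some feeding
#'   events while typical carcasses persist for months. `"daily"`: every
#'   carcass faces an independent Bernoulli(`removal_prob`) hazard each
#'   day (expected lifetime `1/removal_prob` days), a much harsher regime
#'   kept for sensitivity analysis.
#' @param init_carcasses sauropod carcasses standing at day 0.
#' @param spawn_windows restrict carcass generation to the seasonal
#'   windows ([in_spawn_window()]). The default is continuous, year-round
#'   generation: giant-herbivore background mortality operates throughout
#'   the year, and the delivered carcass throughput (rather than its
#'   seasonal phasing) is what the foraging economy depends on; see the
#'   methods vignette for the reconstruction analysis behind this default.
#' @param refound_on_extinction on local extinction, a fresh founder
#'   cohort (of `init_allosaurs`) immigrates from the regional
#'   metapopulation and joins the standing carrion field. The simulated
#'   landscape is an open window onto a larger region, so local
#'   extinction-recolonization dynamics are part of the modelled system.
#' @param factor_inheritance advantage-factor inheritance policy.
#' @param trait_table trait scaling table, see [default_trait_table()].
#' @param log_events record per-event rows (feeding, kills, spawns, ...);
#'   off by default for full-length runs.
#' @return an object of class `allosim_config` (a validated list).
#' @export
allosim_config <- function(years = 279L,
                           days = NULL,
                           days_per_year = 365L,
                           grid_km = 70,
                           init_allosaurs = 12L,
                           max_allosaurs = 30L,
                           birth_rate = 0.02,
                           birth_cost_kg = 200,
                           birth_min_mass = NULL,
                           min_prey = 20L,
                           move_km = 3,
                           wiggle_deg = 50,
                           capture_km = 0.1,
                           max_pursuit_days = 30L,
                           init_mass = 2000,
                           starvation_frac = 0.92,
                           fmr_anchor_mass = 2000,
                           fmr_anchor_req = 29,
                           fmr_exponent = 0.681,
                           carcass_cap = 5L,
                           p_spawn = 0.25,
                           carcass_mass_min = 10000,
                           carcass_mass_max = 25000,
                           prey_carcass_mass = 2000,
                           residual_frac = 0.2,
                           decay_frac = 0.002,
                           removal_prob = 0.02,
                           removal_mode = c("daily", "lifetime"),
                           init_carcasses = 5L,
                           spawn_windows = FALSE,
                           refound_on_extinction = TRUE,
                           factor_inheritance = c("redraw", "copy_when_same"),
                           trait_table = default_trait_table(),
                           log_events = FALSE) {
  cfg <- list(
    years = as.integer(years),
    days_per_year = as.integer(days_per_year),
    grid_km = as.numeric(grid_km),
    init_allosaurs = as.integer(init_allosaurs),
    max_allosaurs = as.integer(max_allosaurs),
    birth_rate = as.numeric(birth_rate),
    birth_cost_kg = as.numeric(birth_cost_kg),
    birth_min_mass = if (is.null(birth_min_mass)) as.numeric(init_mass)
                     else as.numeric(birth_min_mass),
    min_prey = as.integer(min_prey),
    move_km = as.numeric(move_km),
    wiggle_deg = as.numeric(wiggle_deg),
    capture_km = as.numeric(capture_km),
    max_pursuit_days = as.integer(max_pursuit_days),
    init_mass = as.numeric(init_mass),
    starvation_frac = as.numeric(starvation_frac),
    fmr_anchor_mass = as.numeric(fmr_anchor_mass),
    fmr_anchor_req = as.numeric(fmr_anchor_req),
    fmr_exponent = as.numeric(fmr_exponent),
    carcass_cap = as.integer(carcass_cap),
    p_spawn = as.numeric(p_spawn),
    carcass_mass_min = as.numeric(carcass_mass_min),
    carcass_mass_max = as.numeric(carcass_mass_max),
    prey_carcass_mass = as.numeric(prey_carcass_mass),
    residual_frac = as.numeric(residual_frac),
    decay_frac = as.numeric(decay_frac),
    removal_prob = as.numeric(removal_prob),
    removal_mode = match.arg(removal_mode),
    init_carcasses = as.integer(init_carcasses),
    spawn_windows = isTRUE(spawn_windows),
    refound_on_extinction = isTRUE(refound_on_extinction),
    factor_inheritance = match.arg(factor_inheritance),
    trait_table = trait_table,
    log_events = isTRUE(log_events)
  )
  cfg$days <- if (is.null(days)) cfg$years * cfg$days_per_year
              else as.integer(days)
  validate_config(cfg)
  structure(cfg, class = "allosim_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid config field `", field, "`: ", what, call. = FALSE)
  }
  chk(cfg$years >= 1L, "years", "must be >= 1")
  chk(cfg$days >= 1L, "days", "must be >= 1")
  chk(cfg$days_per_year >= 1L, "days_per_year", "must be >= 1")
  chk(cfg$grid_km > 0, "grid_km", "must be positive")
  chk(cfg$init_allosaurs >= 0L, "init_allosaurs", "must be >= 0")
  chk(cfg$max_allosaurs >= cfg$init_allosaurs, "max_allosaurs",
      "must be >= init_allosaurs")
  chk(cfg$birth_rate >= 0 && cfg$birth_rate <= 1, "birth_rate",
      "must be a probability")
  chk(cfg$birth_cost_kg >= 0, "birth_cost_kg", "must be non-negative")
  chk(cfg$birth_min_mass >= 0, "birth_min_mass", "must be non-negative")
  chk(cfg$min_prey >= 0L, "min_prey", "must be >= 0")
  chk(cfg$move_km > 0, "move_km", "must be positive")
  chk(cfg$wiggle_deg > 0 && cfg$wiggle_deg <= 180, "wiggle_deg",
      "must be in (0, 180]")
  chk(cfg$capture_km > 0, "capture_km", "must be positive")
  chk(cfg$max_pursuit_days >= 1L, "max_pursuit_days", "must be >= 1")
  chk(cfg$init_mass > 0, "init_mass", "must be positive")
  chk(cfg$starvation_frac > 0 && cfg$starvation_frac < 1, "starvation_frac",
      "must be in (0, 1)")
  chk(cfg$fmr_anchor_mass > 0 && cfg$fmr_anchor_req > 0, "fmr_anchor_mass",
      "anchors must be positive")
  chk(cfg$fmr_exponent > 0, "fmr_exponent", "must be positive")
  chk(cfg$carcass_cap >= 0L, "carcass_cap", "must be >= 0")
  chk(cfg$p_spawn >= 0 && cfg$p_spawn <= 1, "p_spawn", "must be a probability")
  chk(cfg$carcass_mass_min > 0 &&
        cfg$carcass_mass_max >= cfg$carcass_mass_min, "carcass_mass_min",
      "need 0 < min <= max")
  chk(cfg$prey_carcass_mass > 0, "prey_carcass_mass", "must be positive")
  chk(cfg$residual_frac >= 0 && cfg$residual_frac < 1, "residual_frac",
      "must be in [0, 1)")
  chk(cfg$decay_frac >= 0 && cfg$decay_frac < 1, "decay_frac",
      "must be in [0, 1)")
  chk(cfg$removal_prob >= 0 && cfg$removal_prob <= 1, "removal_prob",
      "must be a probability")
  chk(cfg$init_carcasses >= 0L && cfg$init_carcasses <= cfg$carcass_cap,
      "init_carcasses", "must be in [0, carcass_cap]")
  tt <- cfg$trait_table
  chk(is.data.frame(tt) && all(c("trait", "scale", "offset") %in% names(tt)) &&
        identical(sort(tt$trait), sort(trait_names())),
      "trait_table", "must map all six traits to scale/offset")
  invisible(cfg)
}

#' @export
print.allosim_config <- function(x, ...) {
  cat("allosim configuration\n")
  cat(sprintf("  horizon: %d days (%d-day years, %d y)\n",
              x$days, x$days_per_year, x$years))
  cat(sprintf("  landscape: %.0f x %.0f km torus\n", x$grid_km, x$grid_km))
  cat(sprintf("  agents: %d founders, cap %d, birth p %.3g/agent/day\n",
              x$init_allosaurs, x$max_allosaurs, x$birth_rate))
  cat(sprintf("  prey: floor %d at %.1f km/day\n", x$min_prey, x$move_km))
  cat(sprintf(
    "  carrion: cap %d, spawn p %.2f (windowed), mass %.0f-%.0f kg,\n",
    x$carcass_cap, x$p_spawn, x$carcass_mass_min, x$carcass_mass_max))
  cat(sprintf("           decay %.3g/day of initial, removal p %.2f, residual %.0f%%\n",
              x$decay_frac, x$removal_prob, 100 * x$residual_frac))
  cat(sprintf("  metabolism: N(M) = %.3g * (M/%.0f)^%.3g kg/day, floor %.0f kg\n",
              x$fmr_anchor_req, x$fmr_anchor_mass, x$fmr_exponent,
              x$starvation_frac * x$init_mass))
  invisible(x)
}
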