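#' Perception, carcass-site contests, and predation
#'
#' Foraging is carrion-first: an agent targets the nearest carcass inside
#' its carcass-detection radius; only with no carrion in range does it
#' target the nearest unclaimed prey inside its (much shorter) binocular
#' vision radius; otherwise it random-walks. At a carcass, attendees feed
#' sequentially in descending dominance order, each taking at most its
#' fat-storage capacity and never drawing the carcass below its inedible
#' residual. Prey pursuit is a daily-step chase: a detected prey flees
#' directly away at a speed reduced by the pursuer's hearing; a strike fires
#' once the gap closes below the capture radius and kills with probability
#' equal to the bite-force ability.
#'
#' @name behavior
NULL

#' Choose a foraging target
#'
#' @param pos agent position, length-2 numeric.
#' @param detection_range carcass-detection radius, km.
#' @param binocular_vision prey-detection radius, km.
#' @param carcass_pos,prey_pos 2-column matrices of candidate positions
#'   (0 rows allowed).
#' @param size torus edge, km.
#' @return list with `kind` (`"carcass"`, `"prey"` or `"none"`), `index`
#'   (row in the matching matrix) and `distance` (km).
#' @export
perceive <- function(pos, detection_range, binocular_vision,
                     carcass_pos, prey_pos, size = 70) {
  pick <- function(mat, radius) {
    if (is.null(mat) || nrow(mat) == 0L) return(NULL)
    d <- torus_distance(matrix(pos, nrow(mat), 2, byrow = TRUE), mat, size)
    i <- which.min(d)
    if (d[i] <= radius) list(index = i, distance = d[i]) else NULL
  }
  hit <- pick(carcass_pos, detection_range)
  if (!is.null(hit)) return(c(kind = "carcass", hit))
  hit <- pick(prey_pos, binocular_vision)
  if (!is.null(hit)) return(c(kind = "prey", hit))
  list(kind = "none", index = NA_integer_, distance = NA_real_)
}

#' Resolve a day's feeding contest at one carcass
#'
#' Attendees are ordered by descending dominance (ties broken at random);
#' each in turn consumes `min(tailfat capacity, mass still above the
#' residual floor)`. One feeding event per agent per day.
#'
#' @param current_mass,initial_mass carcass masses, kg.
#' @param dominance numeric vector, one dominance score per attendee.
#' @param tailfat numeric vector, per-attendee daily intake cap, kg.
#' @param residual_frac inedible residual fraction of `initial_mass`.
#' @return numeric vector of intakes (kg), in the order of the input
#'   attendees.
#' @export
resolve_feeding <- function(current_mass, initial_mass, dominance, tailfat,
                            residual_frac = 0.2) {
  stopifnot(length(dominance) == length(tailfat))
  n <- length(dominance)
  intake <- numeric(n)
  if (n == 0L) return(intake)
  ord <- order(dominance, stats::runif(n), decreasing = TRUE)
  avail <- current_mass - residual_frac * initial_mass
  for (i in ord) {
    take <- max(0, min(tailfat[i], avail))
    intake[i] <- take
    avail <- avail - take
  }
  intake
}

#' Flight speed of a pursued prey
#'
#' Hearing is an ambush proxy: a pursuer with hearing ability `h` (centred
#' factor, in `[-0.7, 0.7]`) slows a detected prey to
#' `base_speed * clamp(1 - h, 0.3, 1.7)` km/day. At `h = 0` prey and
#' pursuer are equally fast and a pure chase never closes the gap.
#'
#' @param hearing_ability pursuer hearing ability (dimensionless).
#' @param base_speed unpursued prey speed, km/day.
#' @return prey speed while pursued, km/day.
#' @export
prey_flight_speed <- function(hearing_ability, base_speed = 3) {
  base_speed * pmin(pmax(1 - hearing_ability, 0.3), 1.7)
}

#' Stage a single pursuit to completion
#'
#' The daily pursuit kinematics used by the engine: within a day, pursuer
#' and prey move simultaneously along the chase line, so the gap changes at
#' the relative speed `pursuer speed - prey speed`. A strike fires at the
#' moment the gap reaches `capture_km` and kills with probability
#' `bite_ability`; a failed strike lets the prey escape. The chase ends
#' without a strike when the prey re-opens the gap beyond the pursuer's
#' binocular radius (sight lost) or after `max_days` unresolved days (the
#' pursuer gives up).
#'
#' @param distance starting gap, km.
#' @param hearing_ability,bite_ability pursuer abilities.
#' @param binocular_vision pursuer prey-detection radius, km.
#' @param speed pursuer speed, km/day.
#' @param capture_km strike radius, km.
#' @param max_days give-up horizon, days.
#' @return list with `outcome` (`"kill"`, `"escape"`, `"lost"` or
#'   `"abandoned"`) and `days` spent.
#' @export
pursue_and_attack <- function(distance, hearing_ability, bite_ability,
                              binocular_vision = 0.5, speed = 3,
                              capture_km = 0.1, max_days = 5L) {
  vp <- prey_flight_speed(hearing_ability, speed)
  closing <- speed - vp
  for (day in seq_len(max_days)) {
    if (closing > 0 && distance - closing <= capture_km) {
      kill <- stats::runif(1) < bite_ability
      return(list(outcome = if (kill) "kill" else "escape", days = day))
    }
    distance <- distance - closing
    if (distance > binocular_vision) {
      return(list(outcome = "lost", days = day))
    }
  }
  list(outcome = "abandoned", days = max_days)
}
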