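#' Landscape geometry and carcass lifecycle
#'
#' The landscape is a flat torus (70 x 70 km by default): both coordinates
#' wrap, distances use the minimal-image convention, and the maximum
#' separation between two points is `size/sqrt(2) * sqrt(2)` = 49.5 km.
#' Sauropod carcasses (10--25 t) appear only inside seasonal windows, decay
#' daily, can vanish at random, and are removed once eaten or rotted down to
#' 20% of their original mass.
#'
#' @name environment-module
NULL

#' Minimal-image distance on the torus
#'
#' @param p,q numeric length-2 positions `c(x, y)`, or 2-column matrices.
#' @param size torus edge length, km.
#' @return distance(s) in km.
#' @export
torus_distance <- function(p, q, size = 70) {
  p <- matrix(p, ncol = 2)
  q <- matrix(q, ncol = 2)
  d <- q - p
  d <- d - size * round(d / size)
  sqrt(rowSums(d^2))
}

wrap_position <- function(p, size = 70) {
  p <- p %% size
  p[p < 0] <- p[p < 0] + size
  p
}

#' One day of movement
#'
#' With a target, the agent walks along the minimal-image bearing by
#' `min(max_step, distance)`, landing exactly on the target when it is
#' within reach. Without a target it takes a full step on a uniform random
#' heading. The result is wrapped back onto the torus.
#'
#' @param pos numeric length-2 current position.
#' @param target numeric length-2 position, or `NULL` for a random walk.
#' @param max_step maximum displacement, km/day.
#' @param size torus edge length, km.
#' @return new position, length-2 numeric.
#' @export
move <- function(pos, target = NULL, max_step = 3, size = 70) {
  stopifnot(max_step > 0)
  if (is.null(target)) {
    theta <- stats::runif(1, 0, 2 * pi)
    return(wrap_position(pos + max_step * c(cos(theta), sin(theta)), size))
  }
  d <- target - pos
  d <- d - size * round(d / size)
  len <- sqrt(sum(d^2))
  if (len <= max_step) return(wrap_position(target, size))
  wrap_position(pos + d / len * max_step, size)
}

#' Seasonal carcass-generation window
#'
#' Sauropod carcasses appear only during the 1st quarter, the 3rd quarter,
#' and the final 45 days of the year (0-based day-of-year on a 365-day
#' calendar: days `[0,91) U [182,274) U [320,365)`), mimicking seasonal
#' mortality pulses of giant herbivores.
#'
#' @param day_of_year integer(s) in `0:364`.
#' @return logical.
#' @export
in_spawn_window <- function(day_of_year) {
  stopifnot(all(day_of_year >= 0), all(day_of_year <= 364))
  (day_of_year < 91) |
    (day_of_year >= 182 & day_of_year < 274) |
    (day_of_year >= 320)
}

#' One day of carcass decay, depletion and random removal
#'
#' `current' = current - consumed_today - decay_frac * initial`. The object
#' is removed when the updated mass falls strictly below
#' `residual_frac * initial` (bones and low-value remains), or -- whatever
#' its mass -- with an independent daily probability `removal_prob`, which
#' keeps carrion availability unpredictable.
#'
#' @param initial_mass,current_mass kg.
#' @param consumed_today kg eaten today; must not exceed `current_mass`.
#' @param decay_frac daily decay as a fraction of the *initial* mass.
#' @param residual_frac inedible residual fraction.
#' @param removal_prob daily random-removal probability.
#' @return list with `current_mass` (kg, `NA` if removed), `removed`
#'   (logical) and `reason` (`"depleted"`, `"random"` or `NA`).
#' @export
carcass_daily_update <- function(initial_mass, current_mass, consumed_today = 0,
                                 decay_frac = 0.005, residual_frac = 0.2,
                                 removal_prob = 0.02) {
  if (consumed_today < 0 || consumed_today > current_mass) {
    stop("consumed_today must lie in [0, current_mass]")
  }
  m <- current_mass - consumed_today - decay_frac * initial_mass
  if (m < residual_frac * initial_mass) {
    return(list(current_mass = NA_real_, removed = TRUE, reason = "depleted"))
  }
  if (stats::runif(1) < removal_prob) {
    return(list(current_mass = NA_real_, removed = TRUE, reason = "random"))
  }
  list(current_mass = m, removed = FALSE, reason = NA_character_)
}
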