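#' Simulated clock: nighttime predicate
#'
#' The simulation starts at 00:00 and runs at an hourly resolution.
#' Nighttime — the window in which pupal emergence, larval pupation,
#' oviposition and host seeking are permitted — is 6 P.M. to 6 A.M.,
#' i.e. hours-of-day in `[18, 24)` or `[0, 6)`.
#'
#' @param hour Integer vector of simulated hours since start (or hours of
#'   day; any value is reduced modulo 24).
#' @return Logical vector, `TRUE` for nighttime hours.
#' @export
#' @examples
#' is_nighttime(c(0, 5, 6, 12, 17, 18, 23))
is_nighttime <- function(hour) {
  hod <- hour %% 24
  hod >= 18 | hod < 6
}

#' Hatch-time curve
#'
#' Deterministic hatch-time transform of a uniform variate, in hours. Egg
#' and pupal stage durations are 24 hours plus a hatch-time term drawn as
#' `sample_hatch_time(runif(1))`. The transform is the five-branch piecewise
#' linear curve
#' \deqn{H_t(x) = 40x \; (x \le 0.5);\; 68.57x - 10.28 \; (x \le 0.85);\;
#'   480x - 360 \; (x \le 0.9);\; 600x - 468 \; (x \le 0.94);\;
#'   2400x - 2160 \; (x \le 1)}
#' so that most individuals hatch within two days while a small upper tail
#' takes much longer. The curve is continuous at 0.85, 0.9 and 0.94 and has
#' a small jump at 0.5 (20 vs 24.005 hours).
#'
#' @param x Numeric vector in `[0, 1]`.
#' @return Hatch times in hours, same length as `x`.
#' @seealso [rhatch_time()] for random draws.
#' @export
#' @examples
#' sample_hatch_time(c(0, 0.5, 0.85, 0.9, 0.94, 1))
sample_hatch_time <- function(x) {
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("hatch-time input must lie in [0, 1]")
  }
  ifelse(x <= 0.5, 40 * x,
  ifelse(x <= 0.85, 68.57 * x - 10.28,
  ifelse(x <= 0.9, 480 * x - 360,
  ifelse(x <= 0.94, 600 * x - 468, 2400 * x - 2160))))
}

#' Random hatch-time draws
#'
#' @param n Number of draws.
#' @return `n` hatch times in hours.
#' @export
rhatch_time <- function(n) sample_hatch_time(runif(n))

#' Age-dependent daily adult mortality rate
#'
#' Daily death probability of an adult aged `n` days,
#' \deqn{M_{adult}(n) = \frac{0.1\, e^{n/25}}{1 + 0.25\,(e^{n/25} - 1)},}
#' a logistic-in-hazard senescence curve rising strictly from 0.1 at age 0
#' towards an asymptote of 0.4.
#'
#' @param age_days Nonnegative numeric vector, age in days.
#' @return Daily mortality probabilities in `[0.1, 0.4)`.
#' @export
#' @examples
#' adult_mortality_rate(c(0, 10, 25, 100))
adult_mortality_rate <- function(age_days) {
  if (anyNA(age_days) || any(age_days < 0)) stop("age must be nonnegative")
  # algebraically identical form that is stable for extreme ages
  0.1 / (0.25 + 0.75 * exp(-age_days / 25))
}

#' Age-weighted larval biomass
#'
#' The biomass of the larval habitat is the age-weighted larva count
#' \deqn{L_{mass} = \sum_{n=1}^{10} n \cdot L_n} where `L_n` is the number
#' of `n`-day-old larvae (integer day-age). Larval growth is thereby
#' modelled as linear in age. Larvae with integer day-age below 1 contribute
#' nothing; larvae older than 10 days (possible while awaiting a nighttime
#' pupation hour) are clamped to weight 10.
#'
#' @param x Numeric vector of larval ages in days, or a population table
#'   (see [generate_fixture_population()]) from which larvae are selected.
#' @param hour Simulated hour at which ages are evaluated (population-table
#'   input only).
#' @return Scalar biomass.
#' @export
#' @examples
#' larval_biomass(c(1, 1, 1, 4, 4))  # 3*1 + 2*4 = 11
larval_biomass <- function(x, hour = 0L) {
  if (is.data.frame(x)) {
    larvae <- x$state == .states[["LARVA"]]
    x <- (hour - x$birth_hour[larvae]) / 24
  }
  if (length(x) == 0) return(0)
  nd <- floor(x)
  w <- pmin(nd, 10)
  w[nd < 1] <- 0
  sum(w)
}

#' Density-dependent daily larval mortality rate
#'
#' Daily death probability of a larva aged `n` days in a habitat with
#' biomass `L_mass` and carrying capacity `C`,
#' \deqn{M_{larva}(n) = 0.1\, e^{L_{mass} / (n\,C)},}
#' clamped to 1 where the expression exceeds a valid probability. Mortality
#' increases with crowding (`L_mass`) and decreases with age, so older
#' larvae are favoured. Integer day-age with a minimum of 1 is used, the
#' same convention as [larval_biomass()].
#'
#' @param age_days Larval age in days (numeric vector).
#' @param l_mass Habitat biomass, see [larval_biomass()].
#' @param carrying_capacity Positive habitat constant `C`.
#' @return Daily mortality probabilities in `[0.1, 1]`.
#' @export
#' @examples
#' larval_mortality_rate(1, 0, 100)     # uncrowded: 0.1
#' larval_mortality_rate(1, 100, 100)   # 0.1 * e
#' larval_mortality_rate(10, 100, 100)  # 0.1 * e^0.1
larval_mortality_rate <- function(age_days, l_mass, carrying_capacity) {
  if (length(carrying_capacity) != 1 || is.na(carrying_capacity) ||
      carrying_capacity <= 0) {
    stop("carrying capacity must be a positive scalar")
  }
  if (anyNA(age_days) || any(age_days < 0)) stop("age must be nonnegative")
  if (any(l_mass < 0)) stop("biomass must be nonnegative")
  n <- pmax(1, floor(age_days))
  pmin(1, 0.1 * exp(l_mass / (n * carrying_capacity)))
}
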