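#' Population tables
#'
#' A population is a plain data frame with one row per living agent and
#' columns:
#' \describe{
#'   \item{id}{unique integer}
#'   \item{sex}{0 = male, 1 = female}
#'   \item{zygosity}{lethal-allele count 0/1/2, see [zygosity()]}
#'   \item{competitiveness}{mating weight in `[0, 1]`}
#'   \item{state}{life state code, see [life_states()]}
#'   \item{birth_hour}{simulated hour of creation; age in days is
#'     `(hour - birth_hour) / 24`}
#'   \item{state_entry}{hour the current state was entered}
#'   \item{hatch_hours}{the active stage's hatch-time draw (egg/pupa)}
#'   \item{clutch}{eggs remaining to deposit (gravid females)}
#'   \item{sire_zygosity}{mated females only; -1 before mating}
#'   \item{sire_competitiveness}{mated females only; NA before mating}
#'   \item{fate}{0 unaffected, 1 blocked in egg, 2 blocked in pupa}
#' }
#'
#' @return `empty_population()` returns a zero-row population table.
#' @name population
NULL

.pop_cols <- c("id", "sex", "zygosity", "competitiveness", "state",
               "birth_hour", "state_entry", "hatch_hours", "clutch",
               "sire_zygosity", "sire_competitiveness", "fate")

#' @rdname population
#' @export
empty_population <- function() {
  data.frame(
    id = integer(), sex = integer(), zygosity = integer(),
    competitiveness = double(), state = integer(), birth_hour = integer(),
    state_entry = integer(), hatch_hours = double(), clutch = integer(),
    sire_zygosity = integer(), sire_competitiveness = double(),
    fate = integer()
  )
}

# row-builder used by fixtures, releases and tests
new_agents <- function(n, id, sex, zygosity, competitiveness, state,
                       birth_hour = 0L, state_entry = birth_hour,
                       hatch_hours = 0, clutch = 0L, sire_zygosity = -1L,
                       sire_competitiveness = NA_real_, fate = 0L) {
  data.frame(
    id = as.integer(rep_len(id, n)),
    sex = as.integer(rep_len(sex, n)),
    zygosity = as.integer(rep_len(zygosity, n)),
    competitiveness = rep_len(as.double(competitiveness), n),
    state = as.integer(rep_len(state, n)),
    birth_hour = as.integer(rep_len(birth_hour, n)),
    state_entry = as.integer(rep_len(state_entry, n)),
    hatch_hours = rep_len(as.double(hatch_hours), n),
    clutch = as.integer(rep_len(clutch, n)),
    sire_zygosity = as.integer(rep_len(sire_zygosity, n)),
    sire_competitiveness = rep_len(as.double(sire_competitiveness), n),
    fate = as.integer(rep_len(fate, n))
  )
}

validate_population <- function(pop) {
  if (!is.data.frame(pop) || !all(.pop_cols %in% names(pop))) {
    stop("not a population table; see ?population for the required columns")
  }
  stopifnot(!anyDuplicated(pop$id),
            all(pop$state %in% .states[.states != .states[["DEAD"]]]),
            all(pop$zygosity %in% 0:2),
            all(pop$competitiveness >= 0 & pop$competitiveness <= 1))
  invisible(pop)
}

#' Deterministic wild-type fixture population
#'
#' Builds a small all-wild-type adult population used both to seed burn-in
#' runs and as a unit-test fixture: exactly half males (mate seeking) and
#' half females (already mated to a wild-type male of full competitiveness,
#' mid gonotrophic cycle in the bloodmeal-seeking state), with adult ages
#' staggered over 13-19 days. The same `(n_adults, seed)` pair always
#' yields an identical table.
#'
#' @param n_adults Total number of adults (at least 2).
#' @param seed Optional integer seed set before construction, so the call
#'   is self-contained; with `NULL` the current RNG state is used.
#' @return A population table, females first.
#' @export
#' @examples
#' generate_fixture_population(6, seed = 1)
generate_fixture_population <- function(n_adults, seed = NULL) {
  if (n_adults < 2) stop("need at least 2 adults")
  if (!is.null(seed)) set.seed(seed)
  n_f <- n_adults %/% 2L
  n_m <- n_adults - n_f
  ages <- 13L + (seq_len(n_adults) %% 7L)  # staggered adult ages, days
  fem <- new_agents(n_f, id = seq_len(n_f), sex = .sexes[["female"]],
                    zygosity = 0L, competitiveness = 1,
                    state = .states[["BLOODMEAL_SEEKING"]],
                    birth_hour = -24L * ages[seq_len(n_f)],
                    state_entry = 0L, sire_zygosity = 0L,
                    sire_competitiveness = 1)
  mal <- new_agents(n_m, id = n_f + seq_len(n_m), sex = .sexes[["male"]],
                    zygosity = 0L, competitiveness = 1,
                    state = .states[["MATE_SEEKING"]],
                    birth_hour = -24L * ages[n_f + seq_len(n_m)],
                    state_entry = 0L)
  rbind(fem, mal)
}

# Demographically structured burn-in seed: the adult fixture plus an
# aquatic-stage ladder (standing egg bank, larval age ladder, pupae) in the
# per-female proportions of the model's own steady state. Seeding adults
# alone launches a synchronized first larval cohort whose boom-bust
# oscillation takes ~200 days to damp; seeding the pipeline near its
# equilibrium composition lets a six-month burn-in reach stationarity.
# Ratios are scale invariant (per adult female), so they serve any C.
.burn_in_population <- function(n_adults, clutch_size = 60L) {
  adults <- generate_fixture_population(n_adults, seed = NULL)
  nf <- n_adults %/% 2L
  next_id <- max(adults$id) + 1L
  mk_stage <- function(per_female, state, entry_off, hatch_fn) {
    ages <- as.integer(names(per_female))
    counts <- round(nf * as.numeric(per_female))
    total <- sum(counts)
    if (total == 0) return(empty_population())
    age <- rep(ages, counts)
    off <- sample.int(24, total, replace = TRUE) - 1L
    birth <- -(age * 24L + off)
    out <- new_agents(
      total, id = next_id + seq_len(total) - 1L,
      sex = as.integer(runif(total) < 0.5),
      zygosity = 0L, competitiveness = 1, state = .states[[state]],
      birth_hour = birth,
      state_entry = pmin(as.integer(birth + entry_off), 0L),
      hatch_hours = hatch_fn(age, total)
    )
    next_id <<- next_id + total
    out
  }
  eggs <- mk_stage(
    c(`0` = 13, `1` = 9, `2` = 4.5), "EGG", entry_off = 0,
    hatch_fn = function(age, n) pmax(0, age * 24 - 24 + runif(n, 0, 48))
  )
  larvae <- mk_stage(
    stats::setNames(c(1.0, 1.45, 2.5, 2.15, 1.85, 1.85, 1.35, 1.35, 1.05,
                      1.1, 0.9, 0.9, 0.65, 0.55), 1:14),
    "LARVA", entry_off = 44, hatch_fn = function(age, n) 0
  )
  pupae <- mk_stage(
    c(`14` = 0.45, `15` = 0.45), "PUPA", entry_off = 14 * 24 - 12,
    hatch_fn = function(age, n) runif(n, 0, 48)
  )
  rbind(adults, eggs, larvae, pupae)
}

#' Advance a population through simulated hours
#'
#' Runs the hourly engine with no release campaign: state transitions,
#' mating at 18:00, the daily noon mortality pass, oviposition and all
#' lifecycle logic, exactly as inside [run_replicate()]. Useful for
#' stepping small populations in tests and for inspecting dynamics.
#'
#' Stochastic draws come from R's RNG: call `set.seed()` beforehand for a
#' reproducible trajectory.
#'
#' @param pop Population table (see [population]).
#' @param hours Number of hours to simulate.
#' @param start_hour Simulated hour at which `pop` is given (default 0,
#'   i.e. midnight).
#' @param carrying_capacity Habitat constant `C` for larval mortality.
#' @param clutch_size Eggs deposited per gonotrophic cycle.
#' @param implementation Active SIT implementation governing offspring
#'   fates (default `"none"`).
#' @param log_events If `TRUE`, return the full state-transition event log
#'   (`id`, `hour`, `from`, `to`; deaths transition to the `DEAD` code).
#' @return List with `population` (the survivors at `start_hour + hours`),
#'   `measures` (daily 3 P.M. census rows, see [run_replicate()]) and,
#'   when requested, `events`.
#' @export
advance_population <- function(pop, hours, start_hour = 0L,
                               carrying_capacity = 24000,
                               clutch_size = 60L,
                               implementation = "none",
                               log_events = FALSE) {
  validate_population(pop)
  stopifnot(hours >= 0, start_hour >= 0)
  res <- .sim_engine(pop, as.integer(start_hour),
                     as.integer(start_hour + hours),
                     carrying_capacity, as.integer(clutch_size),
                     .as_impl_code(implementation),
                     -1L, 0L, 0, 1, -1L, 0L, 0L, log_events)
  out <- list(population = res$population,
              measures = as.data.frame(res$measures))
  if (log_events) out$events <- res$events
  out
}
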