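#' Campaign configuration
#'
#' Bundles every parameter of a simulated SIT experiment: the transgene
#' implementation, the daily release proportion and released-male
#' competitiveness, the burn-in and campaign durations, the habitat and
#' clutch parameters, and replication/seeding. Defaults follow the study
#' design: a six-month burn-in to a steady population, a 30-day baseline
#' male census at its end, one year of daily releases, and 30 stochastic
#' replicates.
#'
#' @param implementation `"none"`, `"ebs"`, `"efk"`, `"lbs"` or `"lfk"`.
#' @param release_proportion Daily released males as a fraction of the
#'   baseline average wild-type male population (nonnegative).
#' @param released_competitiveness Mating weight of released males in
#'   `[0, 1]` (1 = as competitive as wild types).
#' @param burn_in_days Days simulated before the first release.
#' @param baseline_window_days Consecutive daily male observations averaged
#'   for the release-number baseline; must fit inside the burn-in.
#' @param campaign_days Days of daily releases.
#' @param clutch_size Eggs per gonotrophic cycle.
#' @param carrying_capacity Habitat constant `C`. The default is calibrated
#'   so a no-intervention population equilibrates near 500 adult females.
#' @param replicates Stochastic replicates per arm.
#' @param init_adults Adults seeding the burn-in
#'   (see [generate_fixture_population()]).
#' @param master_seed Master seed from which per-replicate seeds derive.
#' @return An object of class `campaign_config` (a validated list).
#' @export
#' @examples
#' campaign_config("lbs", 0.3, 1.0, campaign_days = 60, replicates = 5)
campaign_config <- function(implementation = "none",
                            release_proportion = 0,
                            released_competitiveness = 1,
                            burn_in_days = 180L,
                            baseline_window_days = 30L,
                            campaign_days = 365L,
                            clutch_size = 60L,
                            carrying_capacity = 24000,
                            replicates = 30L,
                            init_adults = 400L,
                            master_seed = 1L) {
  cfg <- list(
    implementation = names(.impls)[match(.as_impl_code(implementation),
                                         .impls)],
    release_proportion = release_proportion,
    released_competitiveness = released_competitiveness,
    burn_in_days = as.integer(burn_in_days),
    baseline_window_days = as.integer(baseline_window_days),
    campaign_days = as.integer(campaign_days),
    clutch_size = as.integer(clutch_size),
    carrying_capacity = carrying_capacity,
    replicates = as.integer(replicates),
    init_adults = as.integer(init_adults),
    master_seed = as.integer(master_seed)
  )
  if (cfg$release_proportion < 0) stop("release proportion must be >= 0")
  if (cfg$released_competitiveness < 0 || cfg$released_competitiveness > 1) {
    stop("released competitiveness must lie in [0, 1]")
  }
  if (cfg$burn_in_days < 1 || cfg$campaign_days < 1 ||
      cfg$baseline_window_days < 1) {
    stop("all durations must be positive")
  }
  if (cfg$baseline_window_days > cfg$burn_in_days) {
    stop("the baseline window must lie inside the burn-in")
  }
  if (cfg$carrying_capacity <= 0) stop("carrying capacity must be positive")
  if (cfg$replicates < 1) stop("need at least one replicate")
  structure(cfg, class = "campaign_config")
}

#' @export
print.campaign_config <- function(x, ...) {
  cat("SIT campaign configuration\n")
  cat(sprintf("  implementation: %s\n", toupper(x$implementation)))
  cat(sprintf("  release proportion %.3g, released competitiveness %.3g\n",
              x$release_proportion, x$released_competitiveness))
  cat(sprintf("  burn-in %d d (baseline last %d d), campaign %d d\n",
              x$burn_in_days, x$baseline_window_days, x$campaign_days))
  cat(sprintf("  C = %g, clutch %d, %d replicates, master seed %d\n",
              x$carrying_capacity, x$clutch_size, x$replicates,
              x$master_seed))
  invisible(x)
}

#' Fixed daily release number
#'
#' The number of males released each day is the release proportion times
#' the baseline average wild-type male population, rounded to the nearest
#' whole number (halves away from zero). It stays fixed for the whole
#' campaign even as the wild population is suppressed.
#'
#' @param avg_male_pop Positive baseline average of daily wild-type adult
#'   male counts, see [baseline_male_average()].
#' @param proportion Nonnegative release proportion.
#' @return Nonnegative integer.
#' @export
#' @examples
#' compute_release_number(1000, 0.3)   # 300
#' compute_release_number(333.4, 0.3)  # 100
compute_release_number <- function(avg_male_pop, proportion) {
  if (length(proportion) != 1 || is.na(proportion) || proportion < 0) {
    stop("release proportion must be nonnegative")
  }
  if (length(avg_male_pop) != 1 || is.na(avg_male_pop) || avg_male_pop <= 0) {
    stop("baseline male average must be positive")
  }
  as.integer(floor(avg_male_pop * proportion + 0.5))
}

#' Baseline male population average
#'
#' Arithmetic mean of consecutive daily wild-type adult male counts taken
#' at the daily 3 P.M. census over the last weeks of the burn-in.
#'
#' @param census Numeric vector of daily counts.
#' @return Mean count.
#' @export
baseline_male_average <- function(census) {
  if (length(census) == 0) stop("empty baseline census")
  mean(census)
}

#' Construct released males
#'
#' Released males are homozygous for the cell-lethal transgene, enter the
#' simulation mate seeking, carry the configured released-male
#' competitiveness, and are aged 0 days at release.
#'
#' @param config A [campaign_config()] with a non-`"none"` implementation.
#' @param n Number of males.
#' @param hour Simulated release hour (sets `birth_hour`).
#' @param id_start First id to assign.
#' @return A population table of `n` males.
#' @export
make_released_male <- function(config, n = 1L, hour = 0L, id_start = 1L) {
  if (config$implementation == "none") {
    stop("no males are released without an SIT implementation")
  }
  fate <- .fates[[lethal_fate(2L, "male", config$implementation)]]
  new_agents(n, id = id_start + seq_len(n) - 1L, sex = .sexes[["male"]],
             zygosity = 2L,
             competitiveness = config$released_competitiveness,
             state = .states[["MATE_SEEKING"]], birth_hour = as.integer(hour),
             fate = fate)
}

#' Derive a replicate seed from a master seed
#'
#' Splittable, documented seed derivation: the master seed is combined with
#' an arm label (e.g. `"control"` or `"lfk_p0.3_c1"`) by a 31-ary
#' polynomial string hash modulo 2^31 - 1, then shifted affinely by the
#' replicate index. Arms are thereby independent streams, and any consumer
#' that uses the same `(master_seed, arm, replicate)` triple — for example
#' [run_sweep()] reusing the `"control"` arm of [run_experiment()] — gets
#' bit-identical runs.
#'
#' @param master_seed Integer master seed.
#' @param arm Arm label (any string).
#' @param replicate Replicate index (1-based).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, arm, replicate) {
  m <- 2147483647
  h <- abs(as.double(master_seed)) %% m
  for (ch in utf8ToInt(as.character(arm))) h <- (h * 31 + ch) %% m
  h <- (h * 69621 + 3889 * as.double(replicate)) %% (m - 1)
  as.integer(h + 1)
}

.arm_label <- function(config) {
  sprintf("%s_p%g_c%g", config$implementation, config$release_proportion,
          config$released_competitiveness)
}

# engine column -> measure-series column
.measure_map <- c(
  wt_adult_females = "i_wt_adult_females",
  wt_adult_males = "ii_wt_adult_males",
  hom_adult_males = "iii_hom_adult_males",
  het_adult_males = "iv_het_adult_males",
  fecundity_potential = "v_fecundity_potential",
  wt_larval_females = "vi_wt_larval_females",
  wt_larval_males = "vii_wt_larval_males",
  het_larval_females = "viii_het_larval_females",
  het_larval_males = "ix_het_larval_males",
  larval_mortality_factor = "x_larval_mortality_factor",
  hom_larval_females = "hom_larval_females",
  hom_larval_males = "hom_larval_males",
  eggs = "eggs", pupae = "pupae"
)

#' Run one simulated replicate
#'
#' Executes the full protocol for one stochastic replicate: seed the
#' population, burn in to a steady state, average the wild-type adult male
#' census over the baseline window, then release the fixed daily number of
#' homozygous males at 3 P.M. for the campaign duration. The population is
#' censused daily at 3 P.M. immediately *before* the release; the fecundity
#' potential is evaluated immediately *after* it.
#'
#' @param config A [campaign_config()].
#' @param seed Integer seed fixing the whole trajectory (same seed and
#'   config give a bit-identical series).
#' @param include_burn_in Keep the burn-in days in the returned series
#'   (negative `day`); by default only campaign days (day 0 = first
#'   release) are returned.
#' @param log_events Attach the full state-transition event log.
#' @return A `measure_series` data frame with `day` and the ten daily
#'   measures as `raw_`-prefixed columns (plus bookkeeping columns), and
#'   attributes `baseline_male_average`, `release_number`,
#'   `released_total`, `extinct_before_campaign`, `seed` and `config`.
#'   Extinction before the campaign marks a failed calibration in the
#'   attribute rather than an error.
#' @export
run_replicate <- function(config, seed, include_burn_in = FALSE,
                          log_events = FALSE) {
  stopifnot(inherits(config, "campaign_config"))
  set.seed(seed)
  pop <- .burn_in_population(config$init_adults, config$clutch_size)
  total_days <- config$burn_in_days + config$campaign_days
  res <- .sim_engine(
    pop, 0L, 24L * total_days,
    config$carrying_capacity, config$clutch_size,
    .as_impl_code(config$implementation),
    config$burn_in_days, config$campaign_days,
    config$release_proportion, config$released_competitiveness,
    config$burn_in_days - config$baseline_window_days,
    config$baseline_window_days,
    -1L, log_events
  )
  m <- as.data.frame(res$measures)
  out <- data.frame(day = as.integer(m$day) - config$burn_in_days)
  for (col in names(.measure_map)) {
    out[[paste0("raw_", .measure_map[[col]])]] <- m[[col]]
  }
  if (!include_burn_in) out <- out[out$day >= 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline_male_average") <- res$baseline_male_average
  attr(out, "release_number") <- res$release_number
  attr(out, "released_total") <- res$released_total
  attr(out, "extinct_before_campaign") <- res$extinct_before_campaign
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  if (log_events) attr(out, "events") <- res$events
  class(out) <- c("measure_series", class(out))
  out
}

# across-replicate per-day mean of a list of measure series
mean_series <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  days <- series_list[[1]]$day
  for (s in series_list) stopifnot(identical(s$day, days))
  cols <- setdiff(names(series_list[[1]]), "day")
  out <- data.frame(day = days)
  for (col in cols) {
    vals <- vapply(series_list, function(s) s[[col]], numeric(length(days)))
    out[[col]] <- rowMeans(matrix(vals, nrow = length(days)), na.rm = TRUE)
  }
  out
}

#' Run a full experiment: treated and control arms, replicate-averaged
#'
#' Runs `config$replicates` treated replicates and as many no-intervention
#' control replicates (the same configuration with implementation
#' `"none"`), with per-replicate seeds derived from the master seed via
#' [derive_seed()]. Daily measures are averaged across replicates within
#' each arm; the treated mean series is then normalized against the control
#' mean series ([normalize_measures()]) and summarized into a final-window
#' suppression factor ([suppression_factor()]).
#'
#' @param config A [campaign_config()] (its `implementation` defines the
#'   treated arm).
#' @param control Optional precomputed control result (the `control`
#'   element of a previous [run_experiment()] with identical
#'   non-intervention settings), reused instead of re-running the arm.
#' @param paired If `TRUE`, each control replicate reuses its treated
#'   counterpart's seed (common random numbers): both arms are then
#'   bit-identical through the burn-in and the normalized series starts at
#'   exactly 1 on the first release day, which sharpens estimates of small
#'   transient responses. The default keeps the arms on independent seed
#'   streams.
#' @return An object of class `sit_experiment`: list with `treated` and
#'   `control` (mean series), `normalized` (treated series with `norm_`
#'   columns), `suppression` ([suppression_factor()] summary),
#'   `treated_replicates` and `control_replicates` (per-replicate series)
#'   and `config`.
#' @export
run_experiment <- function(config, control = NULL, paired = FALSE) {
  stopifnot(inherits(config, "campaign_config"))
  arm <- .arm_label(config)
  treated <- lapply(seq_len(config$replicates), function(r) {
    run_replicate(config, derive_seed(config$master_seed, arm, r))
  })
  if (is.null(control)) {
    ccfg <- config
    ccfg$implementation <- "none"
    ccfg$release_proportion <- 0
    control_arm <- if (paired) arm else "control"
    control_reps <- lapply(seq_len(config$replicates), function(r) {
      run_replicate(ccfg, derive_seed(config$master_seed, control_arm, r))
    })
    control <- list(mean = mean_series(control_reps),
                    replicates = control_reps)
  }
  treated_mean <- mean_series(treated)
  normalized <- normalize_measures(treated_mean, control$mean)
  window <- min(30L, nrow(treated_mean))
  structure(list(
    treated = treated_mean,
    control = control$mean,
    normalized = normalized,
    suppression = suppression_factor(treated_mean, control$mean,
                                     window_days = window, config = config),
    treated_replicates = treated,
    control_replicates = control$replicates,
    config = config
  ), class = "sit_experiment")
}

#' @export
print.sit_experiment <- function(x, ...) {
  cat("SIT experiment:", toupper(x$config$implementation),
      sprintf("(proportion %.3g, competitiveness %.3g, %d replicates)\n",
              x$config$release_proportion,
              x$config$released_competitiveness, x$config$replicates))
  s <- x$suppression
  cat(sprintf("  final %d-day suppression factor: %.4f%s\n",
              s$final_window_days, s$suppression_factor,
              if (isTRUE(s$elimination_flag)) " (elimination)" else ""))
  invisible(x)
}
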