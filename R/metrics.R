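#' Canonical measure names
#'
#' The ten daily output measures, indexed i-x: wild-type adult females and
#' males, homozygous and heterozygous adult males, fecundity potential,
#' wild-type and heterozygous larvae by sex, and the density-dependent
#' larval mortality factor `L_mass / C`. Measure series hold them as
#' `raw_`-prefixed columns; [normalize_measures()] adds `norm_` variants.
#'
#' @return Character vector of the ten measure names.
#' @export
measure_names <- function() {
  c("i_wt_adult_females", "ii_wt_adult_males", "iii_hom_adult_males",
    "iv_het_adult_males", "v_fecundity_potential", "vi_wt_larval_females",
    "vii_wt_larval_males", "viii_het_larval_females", "ix_het_larval_males",
    "x_larval_mortality_factor")
}

# control column used to normalize each measure: populations are divided by
# the control's wild-type counterpart (controls carry no transgene)
.norm_map <- c(
  i_wt_adult_females = "i_wt_adult_females",
  ii_wt_adult_males = "ii_wt_adult_males",
  iii_hom_adult_males = "ii_wt_adult_males",
  iv_het_adult_males = "ii_wt_adult_males",
  v_fecundity_potential = "v_fecundity_potential",
  vi_wt_larval_females = "vi_wt_larval_females",
  vii_wt_larval_males = "vii_wt_larval_males",
  viii_het_larval_females = "vi_wt_larval_females",
  ix_het_larval_males = "vii_wt_larval_males",
  x_larval_mortality_factor = "x_larval_mortality_factor"
)

#' Fecundity potential of a male pool
#'
#' The probability-weighted potential that a wild-type female mating into
#' the pool produces wild-type female offspring:
#' \deqn{F = 1 - \frac{\sum m_i [0\,0\,1]\cdot x_i}{\sum m_i}
#'             - \frac{\sum m_i [0\,1\,0]\cdot x_i}{2 \sum m_i}}
#' where `m_i` is male `i`'s mating competitiveness and `x_i` his zygosity
#' indicator ([zygosity_indicator()]). Matings with homozygous males yield
#' no unaffected female line; only half the female progeny of heterozygous
#' males carry the transgene, hence the halved second term. `F` is 1 for an
#' all-wild pool, 0 for an all-homozygous pool, and undefined (`NA`) for an
#' empty or weightless pool.
#'
#' @param zyg Integer zygosity codes of the mate-seeking males.
#' @param competitiveness Their mating weights `m_i`.
#' @return Scalar in `[0, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' fecundity_potential(c(0, 2), c(1, 1))  # 0.5
fecundity_potential <- function(zyg, competitiveness) {
  zyg <- as.integer(zyg)
  stopifnot(all(zyg %in% 0:2), length(zyg) == length(competitiveness))
  s <- sum(competitiveness)
  if (length(zyg) == 0 || s <= 0) return(NA_real_)
  1 - sum(competitiveness[zyg == 2]) / s -
    sum(competitiveness[zyg == 1]) / (2 * s)
}

#' Density-dependent larval mortality factor
#'
#' The habitat crowding term `L_mass / C` reported as daily measure x; it
#' is proportional to the density-dependent mortality experienced by larvae
#' ([larval_mortality_rate()]).
#'
#' @param x Larval ages (days) or a population table, as in
#'   [larval_biomass()].
#' @param carrying_capacity Habitat constant `C`.
#' @param hour Census hour for population-table input.
#' @return Nonnegative scalar.
#' @export
larval_mortality_factor <- function(x, carrying_capacity, hour = 0L) {
  if (carrying_capacity <= 0) stop("carrying capacity must be positive")
  larval_biomass(x, hour = hour) / carrying_capacity
}

#' Normalize a measure series against a no-intervention control
#'
#' Divides each day's measures by the control's value for the same day.
#' Population measures are divided by the control's corresponding
#' *wild-type* series (a control run has no transgenic classes): the
#' homozygous and heterozygous adult male counts are normalized by control
#' wild-type adult males, and transgenic larval counts by the control
#' wild-type larvae of the same sex. Division by a zero control value
#' yields `NA` for that day.
#'
#' @param treated,control Measure series on the same day grid (typically
#'   across-replicate means, see [run_experiment()]).
#' @return `treated` with a `norm_` column added for every measure.
#' @export
normalize_measures <- function(treated, control) {
  if (!identical(treated$day, control$day)) {
    stop("treated and control series must share the same day grid")
  }
  out <- treated
  for (meas in measure_names()) {
    ctrl <- control[[paste0("raw_", .norm_map[[meas]])]]
    ctrl[!is.na(ctrl) & ctrl == 0] <- NA_real_
    out[[paste0("norm_", meas)]] <- treated[[paste0("raw_", meas)]] / ctrl
  }
  out
}

#' Final-window suppression factor
#'
#' Campaign effectiveness is summarized as the mean control-normalized
#' wild-type adult female count over the final `window_days` of the
#' campaign: 1 means no effect, 0.5 means the wild-type female population
#' was halved relative to no intervention, and 0 means elimination. The
#' elimination flag is set exactly when the *raw* treated mean over the
#' window is zero.
#'
#' @param treated,control Measure series covering the final window on the
#'   same day grid.
#' @param window_days Length of the final averaging window (default 30,
#'   the last month of the campaign).
#' @param config Optional [campaign_config()] recorded in the summary.
#' @return An object of class `suppression_summary`: list with
#'   `suppression_factor`, `elimination_flag`, `final_window_days` and the
#'   identifying campaign settings.
#' @export
suppression_factor <- function(treated, control, window_days = 30L,
                               config = NULL) {
  if (!identical(treated$day, control$day)) {
    stop("treated and control series must share the same day grid")
  }
  n <- nrow(treated)
  if (window_days > n) stop("window longer than the series")
  idx <- seq.int(n - window_days + 1L, n)
  tr <- treated$raw_i_wt_adult_females[idx]
  ct <- control$raw_i_wt_adult_females[idx]
  norm <- tr / ifelse(ct == 0, NA_real_, ct)
  structure(list(
    implementation = if (!is.null(config)) config$implementation else NA,
    release_proportion = if (!is.null(config)) config$release_proportion
                         else NA,
    released_competitiveness = if (!is.null(config))
      config$released_competitiveness else NA,
    suppression_factor = mean(norm, na.rm = TRUE),
    elimination_flag = mean(tr) == 0,
    final_window_days = as.integer(window_days)
  ), class = "suppression_summary")
}

#' @export
print.suppression_summary <- function(x, ...) {
  cat(sprintf(
    "suppression factor %.4f over final %d days%s\n",
    x$suppression_factor, x$final_window_days,
    if (isTRUE(x$elimination_flag)) " — elimination" else ""))
  invisible(x)
}
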