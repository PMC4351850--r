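#' Genotype zygosity at the cell-lethal locus
#'
#' Agents carry two alleles at a single locus, each either wild-type or the
#' dominant cell-lethal transgene. Zygosity is encoded as an integer count
#' of lethal alleles: 0 (wild type), 1 (heterozygous), 2 (homozygous).
#'
#' @param allele1,allele2 `"wild"` or `"lethal"` (vectors recycle).
#' @return Integer zygosity codes.
#' @export
#' @examples
#' zygosity(c("wild", "wild", "lethal"), c("wild", "lethal", "lethal"))
zygosity <- function(allele1, allele2) {
  ok <- c(wild = 0L, lethal = 1L)
  a1 <- ok[tolower(allele1)]
  a2 <- ok[tolower(allele2)]
  if (anyNA(a1) || anyNA(a2)) stop("alleles must be 'wild' or 'lethal'")
  unname(a1 + a2)
}

#' Indicator-vector encoding of zygosity
#'
#' Each male in the fecundity-potential statistic is encoded as an indicator
#' vector: wild type `[1 0 0]`, heterozygous `[0 1 0]`, homozygous
#' `[0 0 1]`.
#'
#' @param zyg Integer zygosity codes (0, 1, 2).
#' @return A `length(zyg)` x 3 indicator matrix with columns
#'   `wild_type`, `heterozygous`, `homozygous`.
#' @export
zygosity_indicator <- function(zyg) {
  zyg <- as.integer(zyg)
  stopifnot(all(zyg %in% 0:2))
  m <- matrix(0L, length(zyg), 3,
              dimnames = list(NULL, c("wild_type", "heterozygous",
                                      "homozygous")))
  m[cbind(seq_along(zyg), zyg + 1L)] <- 1L
  m
}

#' Properties of an SIT implementation
#'
#' The four transgenic implementations differ in where lethality manifests
#' (early acting: in the egg; late acting: in the pupa) and in which sexes
#' are affected (bisex: both; female-killing: females only).
#'
#' @param implementation One of `"none"`, `"ebs"`, `"efk"`, `"lbs"`,
#'   `"lfk"`.
#' @return List with `name`, `blocking_state` (`"EGG"`, `"PUPA"` or `NA`)
#'   and `affected_sexes` (`"both"`, `"female_only"` or `"none"`).
#' @export
#' @examples
#' sit_implementation("lfk")
sit_implementation <- function(implementation) {
  code <- .as_impl_code(implementation)
  stopifnot(length(code) == 1)
  name <- names(.impls)[match(code, .impls)]
  list(
    name = name,
    blocking_state = switch(name, ebs = , efk = "EGG",
                            lbs = , lfk = "PUPA", NA_character_),
    affected_sexes = switch(name, ebs = , lbs = "both",
                            efk = , lfk = "female_only", "none")
  )
}

#' Developmental fate of a genotype under an SIT implementation
#'
#' The cell-lethal transgene is dominant and fully penetrant: any carrier
#' (heterozygous or homozygous) of an affected sex ceases development in the
#' implementation's blocking state. Early-acting implementations block in
#' the egg; late-acting implementations block in the pupa, so that doomed
#' carriers still live out a full larval life and contribute to
#' density-dependent larval mortality. Female-killing implementations spare
#' male carriers, which develop as normal and can propagate the transgene.
#'
#' @param zyg Integer zygosity codes (0, 1, 2); vectors recycle against
#'   `sex`.
#' @param sex `"male"`/`"female"` (or codes 0/1).
#' @param implementation One of `"none"`, `"ebs"`, `"efk"`, `"lbs"`,
#'   `"lfk"`.
#' @return Character vector: `"unaffected"`, `"blocked_in_egg"` or
#'   `"blocked_in_pupa"`.
#' @export
#' @examples
#' lethal_fate(1, "female", "lfk")  # blocked_in_pupa
#' lethal_fate(1, "male", "efk")    # unaffected
lethal_fate <- function(zyg, sex, implementation) {
  zyg <- as.integer(zyg)
  stopifnot(all(zyg %in% 0:2))
  sex <- .as_sex_code(sex)
  impl <- sit_implementation(implementation)
  n <- max(length(zyg), length(sex))
  zyg <- rep_len(zyg, n)
  sex <- rep_len(sex, n)
  fate <- rep("unaffected", n)
  carrier <- zyg >= 1L
  affected <- switch(impl$affected_sexes,
                     both = rep(TRUE, n),
                     female_only = sex == .sexes[["female"]],
                     rep(FALSE, n))
  hit <- carrier & affected
  fate[hit] <- if (identical(impl$blocking_state, "EGG")) {
    "blocked_in_egg"
  } else {
    "blocked_in_pupa"
  }
  fate
}

#' Competitiveness-weighted mate choice
#'
#' A mate-seeking female is assigned a male drawn from the mate-seeking
#' male pool with probability proportional to his mating competitiveness
#' `m_i` (a male with `m = 0.5` is half as likely per capita to be chosen
#' as a wild-type male with `m = 1`). Female competitiveness plays no role
#' in mate choice. Males remain in the pool — they can mate repeatedly —
#' while a mated female never returns to it.
#'
#' @param competitiveness Numeric vector of male weights in `[0, 1]`.
#' @param n Number of independent choices to draw.
#' @return Integer indices into `competitiveness`, length `n`; `integer(0)`
#'   when the pool is empty or carries no weight (the females simply wait
#'   for the next mating hour).
#' @export
#' @examples
#' table(select_mate(c(1, 0.5), 1000))  # ~2:1
select_mate <- function(competitiveness, n = 1) {
  if (anyNA(competitiveness) || any(competitiveness < 0) ||
      any(competitiveness > 1)) {
    stop("competitiveness values must lie in [0, 1]")
  }
  if (length(competitiveness) == 0 || sum(competitiveness) == 0) {
    return(integer(0))
  }
  sample.int(length(competitiveness), n, replace = TRUE,
             prob = competitiveness)
}

#' Offspring generation
#'
#' Each egg independently receives a fair-coin sex, one allele drawn
#' uniformly from the mother's pair and one from the sire's pair, and a
#' mating competitiveness equal to the mean of its parents' values. The
#' developmental fate under the active implementation is evaluated once at
#' conception (it is deterministic given genotype and sex) and stored.
#'
#' @param mother_zygosity,sire_zygosity Integer zygosity codes (0, 1, 2).
#' @param mother_competitiveness,sire_competitiveness Parental weights in
#'   `[0, 1]`.
#' @param n Number of eggs.
#' @param implementation Active SIT implementation (default `"none"`).
#' @return Data frame with one row per egg: `sex`, `zygosity`,
#'   `competitiveness`, `fate`, `hatch_hours` (a fresh hatch-time draw).
#' @export
#' @examples
#' set.seed(1)
#' table(conceive_offspring(0, 1, 2, 1, 100)$zygosity)  # all heterozygous
conceive_offspring <- function(mother_zygosity, mother_competitiveness,
                               sire_zygosity, sire_competitiveness,
                               n, implementation = "none") {
  if (length(sire_zygosity) != 1 || is.na(sire_zygosity) ||
      sire_zygosity < 0) {
    stop("mother has no sire record; females conceive only after mating")
  }
  stopifnot(n >= 1, mother_zygosity %in% 0:2, sire_zygosity %in% 0:2)
  sex <- ifelse(runif(n) < 0.5, "male", "female")
  a <- as.integer(runif(n) < mother_zygosity / 2)
  b <- as.integer(runif(n) < sire_zygosity / 2)
  zyg <- a + b
  data.frame(
    sex = sex,
    zygosity = zyg,
    competitiveness = rep((mother_competitiveness + sire_competitiveness) / 2,
                          n),
    fate = lethal_fate(zyg, sex, implementation),
    hatch_hours = rhatch_time(n)
  )
}
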