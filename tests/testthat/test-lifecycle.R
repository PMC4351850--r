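# Engine-level checks of the Table-of-transitions logic, exercised through
# advance_population() on constructed cohorts. Where a noon mortality pass
# intervenes, assertions are made on the survivors.

test_that("eggs hatch after 24 h + hatch time, with no time-of-day gate", {
  # hatch 34 h: exit falls at hour 58 (10:00, daytime) and must not wait
  set.seed(1)
  before <- advance_population(cohort(300, "EGG", hatch = 34), hours = 58,
                               carrying_capacity = 1e6)
  expect_true(all(before$population$state == st[["EGG"]]))
  set.seed(1)
  after <- advance_population(cohort(300, "EGG", hatch = 34), hours = 59,
                              carrying_capacity = 1e6)
  expect_gt(nrow(after$population), 0)
  expect_true(all(after$population$state == st[["LARVA"]]))
})

test_that("pupal emergence waits for nighttime", {
  # duration 24 + 12 h is reached at hour 36 (noon); emergence waits for 18:00
  mk <- function() cohort(300, "PUPA", birth = -12 * 24L, hatch = 12)
  set.seed(2)
  day <- advance_population(mk(), hours = 42, carrying_capacity = 1e6)
  expect_true(all(day$population$state == st[["PUPA"]]))
  set.seed(2)
  night <- advance_population(mk(), hours = 43, carrying_capacity = 1e6)
  expect_true(all(night$population$state == st[["IMMATURE_ADULT"]]))
})

test_that("immature adults mature after 53 hours regardless of hour", {
  mk <- function() cohort(200, "IMMATURE_ADULT", sex = "male",
                          birth = -13 * 24L)
  set.seed(3)
  before <- advance_population(mk(), hours = 53, carrying_capacity = 1e6)
  expect_true(all(before$population$state == st[["IMMATURE_ADULT"]]))
  set.seed(3)
  after <- advance_population(mk(), hours = 54, carrying_capacity = 1e6)
  expect_true(all(after$population$state == st[["MATE_SEEKING"]]))
})

test_that("host seeking succeeds at 25% per nighttime hour only", {
  set.seed(4)
  fem <- cohort(4000, "BLOODMEAL_SEEKING", birth = -14 * 24L,
                entry = 18L, sire_zyg = 0L, sire_comp = 1)
  # one nighttime hour: ~25% succeed
  out <- advance_population(fem, hours = 1, start_hour = 18,
                            carrying_capacity = 1e6)
  frac <- mean(out$population$state == st[["BLOODMEAL_DIGESTING"]])
  expect_equal(frac, 0.25, tolerance = 0.08)
  # one daytime hour: none succeed
  set.seed(5)
  fem_day <- cohort(4000, "BLOODMEAL_SEEKING", birth = -14 * 24L,
                    entry = 8L, sire_zyg = 0L, sire_comp = 1)
  out_day <- advance_population(fem_day, hours = 1, start_hour = 8,
                                carrying_capacity = 1e6)
  expect_true(all(out_day$population$state == st[["BLOODMEAL_SEEKING"]]))
})

test_that("digestion takes 36 h, then the whole clutch is laid at night", {
  set.seed(6)
  fem <- cohort(400, "BLOODMEAL_DIGESTING", birth = -14 * 24L,
                sire_zyg = 2L, sire_comp = 0.5)
  # 36 h elapse at noon (hour 36): gravid wait until 18:00, lay at 19:00
  out <- advance_population(fem, hours = 44, carrying_capacity = 1e6,
                            clutch_size = 60L)
  pop <- out$population
  mothers <- pop[pop$state != st[["EGG"]], ]
  eggs <- pop[pop$state == st[["EGG"]], ]
  expect_true(all(mothers$state == st[["BLOODMEAL_SEEKING"]]))
  expect_equal(nrow(eggs), 60 * nrow(mothers))
  # wild-type mother x homozygous sire: every egg heterozygous, with the
  # mid-parent competitiveness
  expect_true(all(eggs$zygosity == 1L))
  expect_true(all(eggs$competitiveness == 0.75))
  expect_true(all(eggs$birth_hour == eggs$state_entry))
})

test_that("mating pairs every female at 18:00, weighted by male competitiveness", {
  set.seed(7)
  males <- rbind(
    cohort(1, "MATE_SEEKING", sex = "male", comp = 1, birth = -15 * 24L),
    cohort(1, "MATE_SEEKING", sex = "male", comp = 0.5, birth = -15 * 24L,
           id_start = 2L)
  )
  females <- cohort(3000, "MATE_SEEKING", comp = 1, birth = -15 * 24L,
                    id_start = 3L)
  out <- advance_population(rbind(males, females), hours = 2,
                            start_hour = 17, carrying_capacity = 1e6)
  pop <- out$population
  m <- pop[pop$sex == 0L, ]
  f <- pop[pop$sex == 1L, ]
  expect_true(all(m$state == st[["MATE_SEEKING"]]))  # males stay in the pool
  expect_true(all(f$state == st[["BLOODMEAL_SEEKING"]]))
  expect_true(all(f$sire_zygosity == 0L))
  # weight ratio 1 : 0.5 -> the m = 1 male sires ~2/3 of matings
  expect_equal(mean(f$sire_competitiveness == 1), 2 / 3, tolerance = 0.05)
  # with no males present, females simply wait for a later mating hour
  set.seed(8)
  alone <- advance_population(cohort(50, "MATE_SEEKING", birth = -15 * 24L),
                              hours = 2, start_hour = 17,
                              carrying_capacity = 1e6)
  expect_true(all(alone$population$state == st[["MATE_SEEKING"]]))
})

test_that("every observed transition is a lifecycle edge and DEAD absorbs", {
  cfg <- tiny_config("lfk", 0.5)
  s <- run_replicate(cfg, seed = 31, log_events = TRUE)
  ev <- attr(s, "events")
  expect_gt(nrow(ev), 1000)
  allowed <- rbind(
    c("EGG", "LARVA"), c("LARVA", "PUPA"), c("PUPA", "IMMATURE_ADULT"),
    c("IMMATURE_ADULT", "MATE_SEEKING"),
    c("MATE_SEEKING", "BLOODMEAL_SEEKING"),
    c("BLOODMEAL_SEEKING", "BLOODMEAL_DIGESTING"),
    c("BLOODMEAL_DIGESTING", "GRAVID"), c("GRAVID", "BLOODMEAL_SEEKING"),
    cbind(names(st)[1:8], "DEAD")
  )
  key <- paste(allowed[, 1], allowed[, 2])
  obs <- paste(names(st)[match(ev$from, st)], names(st)[match(ev$to, st)])
  expect_true(all(obs %in% key))
  # DEAD is absorbing: no agent has an event after its death
  dead_hours <- tapply(ev$hour[ev$to == st[["DEAD"]]],
                       ev$id[ev$to == st[["DEAD"]]], min)
  last_hours <- tapply(ev$hour, ev$id, max)
  died <- names(dead_hours)
  expect_true(all(last_hours[died] == dead_hours))
  # per-agent event chains are consistent: each transition leaves the state
  # the previous one entered
  by_id <- split(ev[order(ev$hour), c("from", "to")], ev$id[order(ev$hour)])
  chained <- vapply(by_id, function(e) {
    nrow(e) < 2 || all(e$from[-1] == e$to[-nrow(e)])
  }, logical(1))
  expect_true(all(chained))
})

test_that("agents never change id, sex or genotype; population only shrinks
           between oviposition and release events", {
  set.seed(9)
  init <- generate_fixture_population(100)
  out <- advance_population(init, hours = 24 * 30,
                            carrying_capacity = 2000)
  fin <- out$population
  expect_false(any(duplicated(fin$id)))
  shared <- intersect(init$id, fin$id)
  i0 <- init[match(shared, init$id), ]
  i1 <- fin[match(shared, fin$id), ]
  expect_identical(i0$sex, i1$sex)
  expect_identical(i0$zygosity, i1$zygosity)
  # a mated female's sire record never changes (females mate once)
  expect_identical(i0$sire_zygosity, i1$sire_zygosity)
  expect_identical(i0$sire_competitiveness, i1$sire_competitiveness)
})

test_that("same seed and configuration give a bit-identical trajectory", {
  cfg <- tiny_config("efk", 0.4)
  a <- run_replicate(cfg, seed = 77)
  b <- run_replicate(cfg, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "release_number"), attr(b, "release_number"))
  c2 <- run_replicate(cfg, seed = 78)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("the census row equals a from-scratch recount of the population", {
  cfg <- tiny_config("lfk", 0.5, burn_in = 30L, campaign = 10L)
  hours_to_census <- 24 * (cfg$burn_in_days + 5) + 15
  set.seed(55)
  pop0 <- generate_fixture_population(cfg$init_adults)
  set.seed(55)
  run_a <- advance_population(pop0, hours = hours_to_census,
                              carrying_capacity = cfg$carrying_capacity)
  set.seed(55)
  run_b <- advance_population(pop0, hours = hours_to_census + 1,
                              carrying_capacity = cfg$carrying_capacity)
  p <- run_a$population
  row <- run_b$measures[nrow(run_b$measures), ]
  adult <- p$state %in% sitabm:::.adult_states
  larva <- p$state == st[["LARVA"]]
  expect_equal(row$wt_adult_females, sum(adult & p$sex == 1 & p$zygosity == 0))
  expect_equal(row$wt_adult_males, sum(adult & p$sex == 0 & p$zygosity == 0))
  expect_equal(row$wt_larval_females, sum(larva & p$sex == 1 & p$zygosity == 0))
  expect_equal(row$wt_larval_males, sum(larva & p$sex == 0 & p$zygosity == 0))
  expect_equal(row$larval_mortality_factor,
               larval_mortality_factor(p, cfg$carrying_capacity,
                                       hour = hours_to_census))
})

test_that("a no-intervention population is stationary after burn-in", {
  cfg <- campaign_config("none", 0, 1, campaign_days = 1, replicates = 1)
  reps <- lapply(1:5, function(r) {
    run_replicate(cfg, seed = derive_seed(1, "control", r),
                  include_burn_in = TRUE)
  })
  window <- lapply(reps, function(s) {
    s$raw_i_wt_adult_females[s$day >= -60 & s$day < 0]
  })
  # calibrated desk scale: roughly 500 adult females
  expect_gt(mean(unlist(window)), 400)
  expect_lt(mean(unlist(window)), 600)
  # no drift shared across replicates over the last 60 burn-in days: the
  # per-replicate regression slopes are indistinguishable from zero at 5%
  # (daily counts are strongly autocorrelated, so slopes are tested across
  # independent replicates rather than against their own OLS errors)
  slopes <- vapply(window, function(f) {
    unname(stats::coef(stats::lm(f ~ seq_along(f)))[2])
  }, numeric(1))
  expect_gt(stats::t.test(slopes)$p.value, 0.05)
})
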