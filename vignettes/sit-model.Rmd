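---
title: "The sitabm simulation model: lifecycle, genetics and campaign design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sitabm simulation model: lifecycle, genetics and campaign design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sitabm` is an individual-based, hourly-resolution simulator of an
*Anopheles gambiae* population under transgenic sterile insect technique
(SIT) campaigns. Males homozygous for a dominant, fully penetrant
cell-lethal transgene are released daily; their matings with wild females
produce carrier offspring that die in a fixed aquatic stage. Four
implementations are compared: early-acting bisex (**EBS**, carriers die in
the egg), early-acting female-killing (**EFK**, carrier females die in the
egg, carrier males develop normally), late-acting bisex (**LBS**, carriers
die in the pupa) and late-acting female-killing (**LFK**, carrier females
die in the pupa). Late-acting genes are the interesting case: their doomed
carriers live out a full larval life and keep competing for the larval
habitat, so density-dependent mortality keeps bearing on the wild-type
cohort even as the population is suppressed.

# The lifecycle state machine

Agents move through `EGG -> LARVA -> PUPA -> IMMATURE_ADULT`, after which
males enter a permanent `MATE_SEEKING` state and females cycle through
`MATE_SEEKING -> BLOODMEAL_SEEKING -> BLOODMEAL_DIGESTING -> GRAVID ->
BLOODMEAL_SEEKING` (the gonotrophic cycle) until death. The simulation
starts at midnight and steps one hour at a time; *nighttime* is 18:00-06:00.
Transition rules:

* **Egg**: 24 h plus a hatch-time term `H_t`, no time-of-day gate.
  `H_t = sample_hatch_time(x)` with `x ~ U(0,1)` is a five-branch piecewise
  linear curve (breaks at 0.5, 0.85, 0.9, 0.94): half of all eggs hatch
  within 20 extra hours, while the top six percent take up to ten extra
  days. The curve is continuous at its upper three breaks and has a small
  printed jump at 0.5 (20 vs 24.005 h); it is implemented exactly as
  specified, jump included.
* **Larva**: exactly 12.0 days, then pupation at the first nighttime hour.
  The duration is made deterministic because no variance is specified.
* **Pupa**: 24 h plus a fresh, independent `H_t` draw, emergence only at
  night.
* **Immature adult**: 53 h.
* **Mating**: at each 18:00 hour every mate-seeking female is paired with
  one male drawn from the mate-seeking pool with probability proportional
  to his mating competitiveness `m_i`; mating is always successful, males
  remain in the pool, females mate once for life and store the sire's
  genotype and competitiveness. If no (weighted) male is available the
  female waits for the next evening.
* **Host seeking**: 25% success per nighttime hour; the bloodmeal completes
  within the hour.
* **Digestion**: 36 h, finishing at a nighttime hour.
* **Oviposition**: a gravid female deposits her whole clutch (default 60
  eggs) in the single larval habitat during her first full nighttime hour
  gravid, then resumes host seeking.

## Mortality

All mortality is applied once per simulated day, at noon, because every
rate in the model is a daily probability; noon avoids colliding with the
15:00 release, the 18:00 mating hour and the nighttime transitions. Eggs
and pupae die at a fixed 0.1 per day. Adults die at
$$M_{adult}(n) = \frac{0.1\,e^{n/25}}{1 + 0.25\,(e^{n/25}-1)},$$
rising from 0.1 at age 0 towards 0.4 (`n` is the agent's age in days,
counted from its creation as an egg; released males enter at age 0).
Larvae die at the density-dependent rate
$$M_{larva}(n) = 0.1\,e^{L_{mass}/(n\,C)},$$
clamped to 1, where `C` is the habitat's carrying capacity and
$$L_{mass} = \sum_{n=1}^{10} n\,L_n$$
is the age-weighted larva count, evaluated once at the start of each
mortality pass. Age enters both equations as the integer day-age with a
floor of 1; larvae older than 10 days (awaiting a nighttime pupation hour)
are clamped to biomass weight 10. Crowding therefore falls hardest on the
youngest larvae — the mechanism late-acting transgenes exploit.

# Genetics

One locus, two alleles (wild-type / cell-lethal), zygosity coded 0/1/2.
Each egg receives a fair-coin sex, one allele drawn uniformly from each
parent's pair, and a mating competitiveness equal to the mid-parent value.
Lethality is dominant and 100% penetrant; the developmental fate of a
genotype is evaluated once at conception. Blocked-in-egg carriers are
removed when their egg stage would have ended, so they never enter the
habitat; blocked-in-pupa carriers live as normal larvae, contribute fully
to `L_mass`, and are removed at their pupal-exit moment. Female
competitiveness never affects mate choice, only her progeny's inherited
values.

# Campaigns

A campaign experiment runs per replicate:

1. **Burn-in** (default 180 days) to a steady population.
2. **Baseline census**: the wild-type adult male count at the daily 15:00
   census, averaged over the last 30 burn-in days.
3. **Releases**: every day at 15:00 for the campaign duration (default one
   year), a fixed number of homozygous mate-seeking males — the release
   proportion times the baseline average, rounded half away from zero — is
   added, regardless of how far the wild population has fallen.

The daily census happens at 15:00 *before* the release; the fecundity
potential
$$F = 1 - \frac{\sum m_i [0\,0\,1]\cdot x_i}{\sum m_i}
        - \frac{\sum m_i [0\,1\,0]\cdot x_i}{2\sum m_i}$$
is evaluated over the mate-seeking male pool immediately *after* it. `F`
is the competitiveness-weighted chance that a wild female's mating yields
an unaffected female line: 1 in an untreated population, 0 when every
mating partner is homozygous, 0.5 in an all-heterozygous pool. Days with
an empty (or weightless) pool report `F` as missing rather than 0 or 1,
since the statistic is undefined there.

Ten measures are recorded daily: wild-type adult females and males,
homozygous and heterozygous adult males, `F`, wild-type and heterozygous
larvae by sex, and the crowding factor `L_mass/C`. Treated series are
normalized day-by-day against the across-replicate mean of a
no-intervention control arm; transgenic classes, which a control does not
contain, are divided by the control's wild-type counterpart. The headline
summary is the **suppression factor**: the mean normalized wild-type adult
female count over the last 30 campaign days (1 = no effect, 0 =
elimination; the elimination flag is set exactly when the raw treated mean
is zero).

## Seeding and replication

Every replicate is a deterministic function of one integer seed; all
stochastic draws flow through R's generator. Per-replicate seeds derive
from the master seed through a documented splittable scheme
(`derive_seed()`): a polynomial hash of an arm label plus an affine shift
in the replicate index. The no-intervention arm uses the fixed label
`"control"`, so sweeps can run it once and share it across cells while
remaining bit-identical to stand-alone experiments.

Control arms are unpaired by default. `run_experiment(paired = TRUE)`
instead reuses each treated replicate's seed for its control partner
(common random numbers): both arms are then identical through the burn-in
and the normalized series starts at exactly 1 on the first release day.
Pairing is pure variance reduction — it changes no model mechanism — and
is what the transient-response checks in the test suite use, because the
EBS transient (about +1% at this population scale) is smaller than the
between-arm burn-in noise of unpaired 10-replicate means.

## Burn-in initialization

Seeding the burn-in with adults alone launches one synchronized larval
mega-cohort whose boom-bust oscillation takes roughly 200 days to damp —
longer than the burn-in itself, leaving a systematic drift in the
pre-release window. `run_replicate()` therefore seeds a demographically
structured population: the balanced adult fixture (half mated females
mid-cycle, half mate-seeking males, staggered ages) plus a standing egg
bank, a larval age ladder and pupae in the per-adult-female proportions of
the model's own measured steady state. Those proportions are scale
invariant, so the same ladder serves any carrying capacity. With it, the
adult female count over the last 60 burn-in days shows no drift shared
across replicates (slope t-test, 5%).

# Calibration and desk scale

The model's population scale is set by the carrying capacity; nothing else
in the model fixes it. The package default, `C = 24000` with clutch size
60, was calibrated once so that a no-intervention population equilibrates
near 500 adult females (observed 495-515 across seeds, with
`L_mass/C ~ 2.5`), and is not adjusted per experiment. Clutch size 60 is a
mid-range *An. gambiae* value and is exposed as a config parameter, as is
the initial adult count (default 400).

All shipped tests and the reproduction script run at this desk scale.
Typical problem sizes: a full replicate simulates 180 + 60 to 365 days at
24 steps/day over a standing population of roughly 40,000 agents;
experiments average 5-10 replicates per arm, and the proportion sweep runs
five proportions by five replicates. These sizes were chosen so that the
dynamics of interest (onset lags, transients, orderings, dose response)
are resolved while a complete experiment stays in the minutes range on one
CPU.

# What desk scale does and does not show

The generator reproduces the mechanisms — overlapping generations,
density-dependent larval crowding, the heterozygous male reservoir under
female-killing genes, fixed-number releases against a shrinking population
— but not the (unstated) field-like population scale. Consequences worth
knowing:

* Onset lags are scale free and reproduce cleanly: heterozygous larvae
  appear ~4-5 days and heterozygous adult males ~17-19 days after the
  first female-killing release.
* The qualitative final-effect orderings reproduce: late-acting beats
  early-acting, LBS beats LFK, and EFK beats EBS. At ~500 females the late
  arms reach outright elimination by about day 150 at any proportion at or
  above 0.3, so ordering comparisons are made on 90-day campaigns, where
  the four arms are well separated (roughly 200 / 87 / 45 / 25 wild-type
  females for EBS / EFK / LFK / LBS at proportion 0.3).
* Demographic stochasticity at a few hundred females makes elimination
  *easier* than at a large population scale. In proportion sweeps the LFK
  suppression plateau (within 0.05 of the best value) begins already at
  proportion 0.3 here, whereas at field scale appreciable gains continue
  to about 0.7. This is a property of the small-population regime, not of
  the release mechanism; the package reports the desk-scale value it
  actually computes.
* The EBS wild-type transient (less larval competition after the first
  doomed clutches, hence a brief rise before suppression) peaks at about
  day 18-20 here but with an amplitude of only ~1%, so it is detected on
  paired, smoothed series as the last local maximum before sustained
  decline (first smoothed day below 0.9).

# Numerical and degenerate-input choices

* Eq-3 mortality can exceed 1 under heavy crowding; it is clamped, so a
  sufficiently overloaded habitat kills every young larva in one pass.
* Rounding of the release number is half away from zero.
* An empty mate-seeking pool leaves females waiting (not an error) and
  reports `F` as missing; downstream averages skip missing values.
* Population extinction before the campaign start is flagged as a failed
  calibration on the result rather than raised as an error.
* Hour-of-day bookkeeping uses a fixed start at 00:00; all "first
  nighttime hour" rules are evaluated on integer hours.
* Within an hour agents are updated batch-synchronously. No same-hour
  transition depends on another agent's same-hour transition (mate choice
  samples males with replacement; all eggs land in the single habitat), so
  the result is equivalent to updating agents in random order.

# Known limitations

No seasonality, temperature forcing, rainfall-driven carrying capacity,
spatial structure, migration, multiple habitats, larval instars, multiple
lethal loci, incomplete penetrance, female remating or accidental female
release — the model isolates the genetics-by-density-dependence
interaction at a single site. Adult age is counted from egg creation, so
wild adults emerge at an age where the senescence curve already exceeds
its floor, while released males enter at age 0; both follow the same
mortality curve thereafter.
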