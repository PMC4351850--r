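# small population builders for engine-level tests
agents <- function(...) sitabm:::new_agents(...)

st <- life_states()

# a cohort of identical agents in one state
cohort <- function(n, state, sex = "female", zyg = 0L, comp = 1,
                   birth = 0L, entry = 0L, hatch = 0, sire_zyg = -1L,
                   sire_comp = NA_real_, id_start = 1L) {
  agents(n, id = id_start + seq_len(n) - 1L,
         sex = if (sex == "female") 1L else 0L, zygosity = zyg,
         competitiveness = comp, state = st[[state]], birth_hour = birth,
         state_entry = entry, hatch_hours = hatch, sire_zygosity = sire_zyg,
         sire_competitiveness = sire_comp)
}

# a fast, small campaign configuration for plumbing tests (not calibrated
# to the desk-scale equilibrium; dynamics only need to be non-degenerate)
tiny_config <- function(implementation = "lfk", proportion = 0.5,
                        competitiveness = 1, burn_in = 40L, campaign = 20L,
                        replicates = 2L, master_seed = 5L, C = 2000) {
  campaign_config(implementation, proportion, competitiveness,
                  burn_in_days = burn_in, baseline_window_days = 10L,
                  campaign_days = campaign, carrying_capacity = C,
                  replicates = replicates, init_adults = 80L,
                  master_seed = master_seed)
}
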