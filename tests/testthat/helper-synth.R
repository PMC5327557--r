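# memoized synthetic cohorts shared across test files
.synth_cache <- new.env(parent = emptyenv())

shared_synth <- function(n = 20000, seed = 101) {
  key <- paste0("n", n, "s", seed)
  if (is.null(.synth_cache[[key]])) {
    .synth_cache[[key]] <- generate_cohort(cohort_config(n_persons = n,
                                                         seed = seed))
  }
  .synth_cache[[key]]
}

noiseless_config <- function(n = 4000, seed = 5) {
  quiet <- function(incidence) cancer_sim_params(
    incidence_month = incidence, p_code = 1, lag_pmf = c("0" = 1),
    prevalent_fraction = 0, p_recode = 0, miscode_month = 0,
    case_fatality_month = 0, p_prevalent_death = 0, p_death_cause = 0,
    p_secondary_miscode = 0, p_death_miscert = 0,
    bg_surgery = 0, bg_mbs_chemo = 0, bg_pbs_chemo = 0, bg_ed = 0)
  cohort_config(n_persons = n, seed = seed,
                cancers = list(colorectal = quiet(3e-4),
                               lung = quiet(1.5e-4)),
                border_fraction = 0, border_penalty = 1)
}
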