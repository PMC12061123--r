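# Shared fixtures, built in code.  Small channel subsets keep tests fast;
# the subsets always contain the electrodes the analyses key on.

CH_SMALL <- c("Fp1", "Fp2", "F3", "F4", "Cz", "CP5", "CP1", "P7", "P3",
              "Pz", "P4", "P8", "O1", "O2")

small_params <- function(...) {
  sim_params(channel_names = CH_SMALL, ...)
}

# Noiseless forward-priming epochs for exact round-trip checks.
noiseless_epochs <- function(n_trials = 20, experiment = "forward",
                             seed = 1) {
  p <- small_params(noise_sd = 0, blink_rate = 0, experiment = experiment)
  simulate_participant_epochs(make_schedule(experiment, n_trials, seed), p,
                              seed = seed)
}

# A small cohort of baseline-corrected epoch sets.
cohort_epochs <- function(n_participants, n_trials, params, seed = 1) {
  seeds <- primingEEG:::child_seeds(seed, 2L * n_participants)
  lapply(seq_len(n_participants), function(i) {
    sch <- make_schedule(params$experiment, n_trials, seed = seeds[2L * i - 1L])
    baseline_correct(simulate_participant_epochs(sch, params,
                                                 seed = seeds[2L * i]))
  })
}
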