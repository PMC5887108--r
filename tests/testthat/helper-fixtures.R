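# Small shared fixtures, built once per test run.

# short two-run navigation session
tiny_session <- function(seed = 1, n_runs = 2, run_duration = 240) {
  simulate_navigation_session(arena_config(), n_runs = n_runs,
                              run_duration = run_duration, seed = seed)
}

# orientation map with exactly the given orientations (via unit-norm
# quadrature betas, so estimate_orientations reproduces them)
map_with <- function(orientations, n_fold = 6) {
  th <- orientations * n_fold * pi / 180
  estimate_orientations(sin(th), cos(th), n_fold = n_fold)
}

# hand-written event table: one run, explicit translations
events_from <- function(onsets, durations, directions, run_duration,
                        kind = "translation") {
  make_event_table(
    data.frame(run_id = 1L, trial_id = seq_along(onsets), onset = onsets,
               duration = durations, kind = kind, direction = directions),
    c(`1` = run_duration))
}

the_paths <- default_path_set()
the_design <- build_session(the_paths)

# standardization records giving unit correction factors
unit_std <- function(modality = "body_based") {
  data.frame(modality = modality, std_distance = c(3, 3, 9, 9),
             response = c(3, 3, 9, 9))
}
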