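# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

gap_config <- function() synthetic_config()

# ground-truth dataset (noisy observations + noiseless trajectory)
gap_truth <- function() fixture("gap_truth", function() {
  ground_truth_dataset(gap_config())
})

# frozen-gradient companion run of the ground truth
gap_frozen <- function() fixture("gap_frozen", function() {
  gt <- gap_truth()
  simulate_circuit(gt$params, gap_config()$schedule, gt$profiles, gt$init,
                   mode = "frozen")
})

# a decoupled decay-only circuit on the standard rows
decay_params <- function(lambda = 2) {
  circuit_parameters(R = rep(0, 4), lambda = rep(lambda, 4),
                     W = matrix(0, 4, 4), E = matrix(0, 4, 4), h = rep(0, 4))
}

# zero-input profiles on the standard grid
null_profiles <- function(t_end = 70) {
  external_profiles(c(0, t_end), seq(35, 92), array(0, c(2, 58, 4)))
}

# profiles frozen in time (values of the synthetic set at t = 0)
constant_profiles <- function() fixture("constant_profiles", function() {
  prof <- make_profiles(gap_config())
  v <- prof$values
  for (k in seq_along(prof$times)) v[k, , ] <- prof$values[1, , ]
  external_profiles(prof$times, prof$positions, v, prof$species)
})

# toggle ramp experiment crossing the fold (saddle-node annihilation)
toggle_fold_ramp <- function() fixture("toggle_fold_ramp", function() {
  tg <- fixture_toggle2()
  prof <- ramp_profile(seq(0, 60, by = 5), c(0, 6))
  at <- seq(0, 60, by = 6)
  init <- matrix(c(0.0101, 0.9899), 1, 2)
  traj <- simulate_nuclei(tg, prof, init,
                          sort(unique(c(at, seq(0, 60, by = 1)))))
  series <- portrait_series(tg, prof, position = 50, times = at,
                            row = nucleus_row(50, 14L),
                            n_grid = 6, n_random = 120, seed = 1)
  list(params = tg, profiles = prof, times = at, traj = traj,
       series = series)
})

# sub-fold ramp moving the saddle across a loitering trajectory
toggle_subfold_ramp <- function() fixture("toggle_subfold_ramp", function() {
  tg <- fixture_toggle2()
  knots <- seq(0, 10, by = 0.5)
  vals <- c(seq(0, 3.9, length.out = 5), rep(3.9, 16))
  prof <- ramp_profile(knots, vals)
  at <- c(0, 1, 2, 4, 6, 10)
  init <- matrix(c(0.49, 0.56), 1, 2)
  traj <- simulate_nuclei(tg, prof, init,
                          sort(unique(c(at, seq(0, 10, by = 0.25)))))
  series <- portrait_series(tg, prof, position = 50, times = at,
                            row = nucleus_row(50, 14L),
                            n_grid = 6, n_random = 120, seed = 1)
  list(params = tg, profiles = prof, times = at, traj = traj,
       series = series)
})

expect_no_flags <- function(flags) expect_length(flags, 0)
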