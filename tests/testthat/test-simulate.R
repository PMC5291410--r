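# Hybrid integration: closed forms, conservation, frozen mode, and an
# independent solver cross-check.

test_that("decay-only dynamics match the exponential closed form", {
  sched <- stage_schedule()
  traj <- simulate_circuit(decay_params(lambda = 2), sched, null_profiles(),
                           matrix(1, 29, 4), sample_times = 1)
  g <- state_at(traj, 1)
  expect_lt(max(abs(g - exp(-2)) / exp(-2)), 1e-6)
})

test_that("pure diffusion conserves total concentration through the division", {
  sched <- stage_schedule()
  p <- circuit_parameters(R = rep(0, 4), lambda = rep(1e-12, 4),
                          W = matrix(0, 4, 4), E = matrix(0, 4, 4),
                          h = rep(0, 4), D_base = rep(0.3, 4))
  set.seed(42)
  init <- matrix(runif(29 * 4), 29, 4)
  traj <- simulate_circuit(p, sched, null_profiles(), init,
                           sample_times = c(16, 70))
  # zero-flux boundaries: the nucleus-summed concentration is conserved
  # (division duplicates nuclei, so compare per-cycle sums)
  expect_lt(abs(sum(state_at(traj, 16)) - sum(init)) / sum(init), 1e-9)
  expect_lt(abs(sum(state_at(traj, 70)) / 2 - sum(init)) / sum(init), 1e-9)
})

test_that("dynamic and frozen modes agree when inputs are constant in time", {
  gt <- gap_truth()
  sched <- gap_config()$schedule
  prof <- constant_profiles()
  a <- simulate_circuit(gt$params, sched, prof, gt$init,
                        sample_times = sched$analysis_times)
  b <- simulate_circuit(gt$params, sched, prof, gt$init, mode = "frozen",
                        clamp_time = 35, sample_times = sched$analysis_times)
  cmp <- compare_runs(a, b)
  expect_lt(max(abs(cmp$table$difference)), 1e-8)
})

test_that("trajectories agree with an independent lsoda integration", {
  skip_if_not_installed("deSolve")
  gt <- gap_truth()
  p <- gt$params
  prof <- gt$profiles
  sched <- gap_config()$schedule
  row <- default_rows()$C14A
  # post-division segment only (no hybrid event), so one lsoda call covers it
  t0 <- sched$division_time
  init <- state_at(gt$trajectory, t0)
  ts <- c(t0, sched$analysis_times[c("T2", "T5", "gast")])
  rhs_desolve <- function(t, y, parms) {
    st <- matrix(y, nrow = row$n_nuclei)
    # lsoda may probe slightly beyond the final time
    ext <- interpolate_external(prof, min(max(t, 0), sched$t_end), row)
    list(as.vector(circuit_rhs(st, ext, p, row, "interphase")))
  }
  sol <- deSolve::lsoda(as.vector(init), ts, rhs_desolve, NULL,
                        rtol = 1e-9, atol = 1e-11)
  ours <- simulate_circuit(p, sched, prof, unclass(init), t_start = t0,
                           sample_times = ts)
  for (k in 2:length(ts)) {
    ref <- matrix(sol[k, -1], nrow = row$n_nuclei)
    expect_lt(max(abs(state_at(ours, ts[k]) - ref)), 1e-4)
  }
})

test_that("halving the tolerances barely changes the final state", {
  gt <- gap_truth()
  sched <- gap_config()$schedule
  a <- simulate_circuit(gt$params, sched, gt$profiles, gt$init,
                        rtol = 1e-6, atol = 1e-8, sample_times = 70)
  b <- simulate_circuit(gt$params, sched, gt$profiles, gt$init,
                        rtol = 5e-7, atol = 5e-9, sample_times = 70)
  expect_lt(max(abs(state_at(a, 70) - state_at(b, 70))), 1e-3)
})

test_that("states stay non-negative and finite on the ground-truth run", {
  gt <- gap_truth()
  mins <- vapply(gt$trajectory$states, min, numeric(1))
  expect_true(all(is.finite(unlist(gt$trajectory$states))))
  expect_gte(min(mins), -1e-8)
  expect_false(gt$trajectory$unstable)
})

test_that("a frozen run restarted from an intermediate state reproduces the remainder", {
  gt <- gap_truth()
  sched <- gap_config()$schedule
  frz <- simulate_circuit(gt$params, sched, gt$profiles, gt$init,
                          mode = "frozen", clamp_time = 0,
                          sample_times = c(30, 50, 70))
  mid <- state_at(frz, 30)
  prof0 <- freeze_external_inputs(gt$profiles, 0)
  restart <- simulate_circuit(gt$params, sched, prof0, unclass(mid),
                              t_start = 30, sample_times = c(50, 70))
  expect_lt(max(abs(state_at(restart, 70) - state_at(frz, 70))), 1e-6)
})

test_that("compare_runs reports signed frozen-minus-dynamic differences", {
  gt <- gap_truth()
  frz <- gap_frozen()
  identical_cmp <- compare_runs(gt$trajectory, gt$trajectory)
  expect_equal(max(abs(identical_cmp$table$difference)), 0)
  cmp <- compare_runs(gt$trajectory, frz)
  sched <- gap_config()$schedule
  late <- cmp$summary[cmp$summary$time_class == "T8", ]
  early <- cmp$summary[cmp$summary$time_class == "T2", ]
  m <- merge(late, early, by = "species")
  # divergence grows late, as the gradients decay only from T3 onwards
  expect_true(all(m$max_abs_diff.x > m$max_abs_diff.y))
})

test_that("a constant offset between runs shows up as a constant difference table", {
  gt <- gap_truth()
  shifted <- gt$trajectory
  shifted$states <- lapply(shifted$states, function(s) s + 3)
  cmp <- compare_runs(gt$trajectory, shifted)
  expect_equal(max(abs(cmp$table$difference - 3)), 0, tolerance = 1e-9)
})
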