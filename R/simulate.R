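# Hybrid integration of the non-autonomous circuit over the stage schedule,
# with optional frozen-gradient (autonomous) mode.

#' Simulate a gap gene circuit over the stage schedule
#'
#' Integrates the hybrid ODE system with an adaptive embedded Runge-Kutta
#' (Cash-Karp 4/5) solver through each schedule phase in order: C13
#' interphase, C13 mitosis (production off), the instantaneous nuclear
#' division (state copied to daughters, integration restarted), and the C14A
#' time classes. In `mode = "frozen"` the external inputs are clamped to
#' their values at `clamp_time` (default: the earliest profile time), which
#' makes the system autonomous from the clamp onwards.
#'
#' @param params a `circuit_parameters` object.
#' @param schedule a `stage_schedule`.
#' @param profiles an `external_profiles` object spanning the schedule.
#' @param init_state nuclei x genes matrix on the starting row.
#' @param mode `"dynamic"` (time-variable inputs) or `"frozen"`.
#' @param clamp_time clamp time for frozen mode (min).
#' @param freeze_species regulators to freeze in frozen mode (default all).
#' @param rows list with `C13` and `C14A` nucleus rows (default
#'   [default_rows()]).
#' @param t_start start time (min); states before `t_start` are not computed.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param sample_dt spacing of the dense output grid (min); all schedule
#'   analysis times are always included.
#' @param sample_times optional explicit sample times overriding the dense
#'   grid (analysis times are still appended).
#' @param max_steps optional cap on solver steps per phase; exceeding it
#'   flags the run as numerically unstable (used to bound the cost of a
#'   single evaluation during model fitting).
#' @return an object of class `circuit_trajectory`: sample `times`, a list of
#'   per-sample state matrices `states`, per-sample row keys, the division
#'   record, and an `unstable` flag set on solver failure instead of an
#'   exception (used by model selection).
#' @export
simulate_circuit <- function(params, schedule, profiles, init_state,
                             mode = c("dynamic", "frozen"),
                             clamp_time = NULL,
                             freeze_species = NULL,
                             rows = default_rows(),
                             t_start = 0,
                             rtol = 1e-8, atol = 1e-10,
                             sample_dt = 0.5, sample_times = NULL,
                             max_steps = NULL) {
  mode <- match.arg(mode)
  validate_parameters(params)
  init_state <- as.matrix(init_state)
  if (mode == "frozen") {
    if (is.null(clamp_time)) clamp_time <- profiles$times[1]
    if (is.null(freeze_species)) freeze_species <- profiles$species
    profiles <- freeze_external_inputs(profiles, clamp_time, freeze_species)
  }
  if (is.null(sample_times)) {
    sample_times <- seq(t_start, schedule$t_end, by = sample_dt)
  }
  sample_times <- sort(unique(c(sample_times, schedule$analysis_times,
                                schedule$t_end)))
  sample_times <- sample_times[sample_times >= t_start - 1e-12 &
                               sample_times <= schedule$t_end + 1e-12]

  phases <- schedule$phases
  phases <- phases[phases$end > t_start + 1e-12, , drop = FALSE]
  phases$start <- pmax(phases$start, t_start)

  # starting row inferred from the start time
  pre_division <- t_start < schedule$division_time - 1e-12
  row <- if (pre_division) rows$C13 else rows$C14A
  if (nrow(init_state) != row$n_nuclei)
    stop("init_state has ", nrow(init_state), " rows; expected ",
         row$n_nuclei, " nuclei at t_start = ", t_start)

  state <- init_state
  times <- t_start
  states <- list(state)
  row_keys <- if (pre_division) "C13" else "C14A"
  unstable <- FALSE
  division <- NULL

  for (k in seq_len(nrow(phases))) {
    ph <- phases[k, ]
    if (ph$cycle == 14L && identical(row$cycle_index, rows$C13$cycle_index)) {
      division <- list(time = schedule$division_time, pre_state = state)
      div <- divide_nuclei(state, row)
      state <- div$state
      row <- div$row
      # the division instant itself is recorded as the post-division state
      if (any(abs(times - schedule$division_time) < 1e-9)) {
        i <- which(abs(times - schedule$division_time) < 1e-9)
        states[[i]] <- state
        row_keys[i] <- "C14A"
      }
    }
    ts <- sample_times[sample_times > ph$start + 1e-12 &
                       sample_times <= ph$end + 1e-12]
    ts <- sort(unique(c(ts, ph$end)))
    res <- .ck_integrate(
      state, ph$start, ts,
      params$R, diffusion_coefficient(params, row$cycle_index),
      params$lambda, params$W, params$E, params$h,
      profiles$times, profile_values_for_row(profiles, row),
      ph$production, rtol, atol, -1, -1,
      if (is.null(max_steps)) -1 else max_steps)
    if (!res$ok) unstable <- TRUE
    st <- res$states
    for (s in seq_along(ts)) {
      keep <- any(abs(sample_times - ts[s]) < 1e-9) || s == length(ts)
      if (!keep) next
      times <- c(times, ts[s])
      states[[length(states) + 1L]] <- matrix(st[, , s], nrow = row$n_nuclei)
      row_keys <- c(row_keys, if (row$cycle_index == rows$C13$cycle_index)
        "C13" else "C14A")
    }
    state <- matrix(st[, , length(ts)], nrow = row$n_nuclei)
    if (unstable) break
  }

  # drop duplicate times (phase ends shared with next phase starts)
  keep <- !duplicated(round(times, 9))
  structure(list(times = times[keep], states = states[keep],
                 row_keys = row_keys[keep], rows = rows,
                 schedule = schedule, mode = mode,
                 clamp_time = if (mode == "frozen") clamp_time else NULL,
                 division = division, unstable = unstable,
                 gene_names = params$gene_names),
            class = "circuit_trajectory")
}

#' Extract the state at a sampled time
#'
#' @param traj a `circuit_trajectory`.
#' @param t a sampled time (min) or analysis-time label.
#' @return nuclei x genes matrix with a `positions` attribute.
#' @export
state_at <- function(traj, t) {
  t <- resolve_time(t, traj$schedule)
  i <- which(abs(traj$times - t) < 1e-9)
  if (length(i) == 0) stop("time ", t, " was not sampled")
  st <- traj$states[[i[1]]]
  colnames(st) <- traj$gene_names
  attr(st, "positions") <- traj$rows[[traj$row_keys[i[1]]]]$positions
  st
}

#' Tidy data frame of a trajectory
#'
#' @param x a `circuit_trajectory`.
#' @param times times (or labels) to export; default all sampled times.
#' @param ... unused.
#' @return data frame with columns `time_min`, `position_pct`, `species`,
#'   `concentration`.
#' @export
as.data.frame.circuit_trajectory <- function(x, times = NULL, ...) {
  tt <- if (is.null(times)) x$times else resolve_time(times, x$schedule)
  out <- lapply(tt, function(t) {
    st <- state_at(x, t)
    pos <- attr(st, "positions")
    data.frame(time_min = t,
               position_pct = rep(pos, times = ncol(st)),
               species = rep(colnames(st), each = nrow(st)),
               concentration = as.vector(st),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare dynamic and frozen-gradient runs
#'
#' Signed per-time, per-nucleus, per-gene differences (frozen - dynamic)
#' aligned on shared sample times, with a per-gene, per-time-class summary of
#' the maximum absolute difference.
#'
#' @param traj_dynamic,traj_frozen `circuit_trajectory` objects on the same
#'   schedule and nucleus rows.
#' @return list with `table` (columns `time_min`, `position_pct`, `species`,
#'   `difference`) and `summary` (`species`, `time_class`, `max_abs_diff`).
#' @export
compare_runs <- function(traj_dynamic, traj_frozen) {
  shared <- intersect(round(traj_dynamic$times, 9), round(traj_frozen$times, 9))
  if (length(shared) == 0) stop("no shared sample times")
  rows_match <- identical(traj_dynamic$rows$C14A$positions,
                          traj_frozen$rows$C14A$positions)
  if (!rows_match) stop("mismatched nucleus rows")
  tabs <- lapply(shared, function(t) {
    a <- state_at(traj_dynamic, t)
    b <- state_at(traj_frozen, t)
    if (!identical(dim(a), dim(b))) stop("mismatched grids at t = ", t)
    pos <- attr(a, "positions")
    data.frame(time_min = t,
               position_pct = rep(pos, times = ncol(a)),
               species = rep(colnames(a), each = nrow(a)),
               difference = as.vector(b - a),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab$time_class <- time_class_label(tab$time_min, traj_dynamic$schedule)
  agg <- aggregate(abs(tab$difference),
                   by = list(species = tab$species,
                             time_class = tab$time_class),
                   FUN = max)
  names(agg)[3] <- "max_abs_diff"
  list(table = tab[, c("time_min", "position_pct", "species", "difference")],
       summary = agg)
}
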