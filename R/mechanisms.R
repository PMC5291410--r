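# Classification of non-autonomous patterning mechanisms: transitions,
# pursuits, geometrical captures, and topological captures.

#' Per-nucleus state series at analysis times
#'
#' Extracts the 4D trajectory of one nucleus at the given analysis times.
#' Before the division a nucleus at position p is represented by its parent,
#' the nearest row position at or anterior of p.
#'
#' @param traj a `circuit_trajectory`.
#' @param position nucleus position (% A-P) on the post-division row.
#' @param times analysis times (default: the schedule's).
#' @return matrix times x genes.
#' @export
nucleus_state_series <- function(traj, position, times = NULL) {
  if (is.null(times)) times <- traj$schedule$analysis_times
  out <- matrix(NA_real_, length(times), length(traj$gene_names),
                dimnames = list(NULL, traj$gene_names))
  for (k in seq_along(times)) {
    st <- state_at(traj, times[k])
    pos <- attr(st, "positions")
    i <- match(round(position, 6), round(pos, 6))
    if (is.na(i)) {
      cand <- which(pos <= position + 1e-9)
      if (length(cand) == 0) stop("position ", position, " anterior of row")
      i <- max(cand)
    }
    out[k, ] <- st[i, ]
  }
  out
}

#' Classify the non-autonomous mechanism acting on one nucleus
#'
#' At each analysis time the basin of the trajectory state is computed in
#' that time's instantaneous portrait. For each inter-analysis interval the
#' label is then: basin changed with a coincident bifurcation event ->
#' topological capture; basin changed without a bifurcation -> geometrical
#' capture; basin unchanged with the governing attractor displaced by more
#' than `movement_threshold` (relative to the box diagonal) -> pursuit;
#' basin unchanged with a static attractor -> transition (convergence).
#' Unresolved basins yield "unclassifiable" intervals.
#'
#' @param traj a `circuit_trajectory` sampled at the analysis times.
#' @param series a `portrait_series` for the same nucleus whose sets retain
#'   their `field` element.
#' @param movement_threshold attractor displacement threshold, relative to
#'   the box diagonal.
#' @param basin_eps convergence radius for [basin_of()].
#' @param basin_t_max integration horizon for [basin_of()]; the default (ten
#'   times the slowest decay time) can be too short right after a saddle-node
#'   event, where the ghost of the annihilated pair slows trajectories down.
#' @return an object of class `mechanism_call`: the nucleus position, the
#'   per-time basin ids (tracked stable ids), and an evidence table with one
#'   row per interval (`t_from`, `t_to`, `basin_from`, `basin_to`,
#'   `n_bifurcations`, `attractor_displacement`, `label`).
#' @export
classify_mechanism <- function(traj, series, movement_threshold = 0.05,
                               basin_eps = 1e-4, basin_t_max = NULL) {
  times <- series$times
  states <- nucleus_state_series(traj, series$position, times)
  basins <- rep(NA_integer_, length(times))
  for (k in seq_along(times)) {
    set <- series$sets[[k]]
    idx <- basin_of(pmax(states[k, ], 0), set$field, set, eps = basin_eps,
                    t_max = basin_t_max)
    basins[k] <- if (is.na(idx)) NA_integer_ else set$stable_id[idx]
  }
  n_int <- length(times) - 1L
  ev <- data.frame(t_from = times[-length(times)], t_to = times[-1L],
                   basin_from = basins[-length(basins)],
                   basin_to = basins[-1L],
                   n_bifurcations = 0L, attractor_displacement = NA_real_,
                   label = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(n_int)) {
    in_interval <- series$events$t_from >= times[k] - 1e-9 &
      series$events$t_to <= times[k + 1L] + 1e-9
    ev$n_bifurcations[k] <- sum(in_interval)
    b0 <- ev$basin_from[k]; b1 <- ev$basin_to[k]
    if (is.na(b0) || is.na(b1)) {
      ev$label[k] <- "unclassifiable"
      next
    }
    if (b0 != b1) {
      ev$label[k] <- if (ev$n_bifurcations[k] > 0)
        "topological capture" else "geometrical capture"
      next
    }
    loc0 <- state_location(series$sets[[k]], b0)
    loc1 <- state_location(series$sets[[k + 1L]], b1)
    disp <- if (is.null(loc0) || is.null(loc1)) NA_real_ else
      sqrt(sum((loc1 - loc0)^2))
    ev$attractor_displacement[k] <- disp
    ev$label[k] <- if (!is.na(disp) &&
                       disp > movement_threshold * series$box_diag)
      "pursuit" else "transition"
  }
  structure(list(position = series$position, basins = basins,
                 times = times, evidence = ev,
                 labels = ev$label),
            class = "mechanism_call")
}

state_location <- function(set, stable_id) {
  j <- match(stable_id, set$stable_id)
  if (is.na(j)) return(NULL)
  set$states[[j]]$location
}
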