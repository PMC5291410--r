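# Time- and space-indexed external regulator profiles (Bcd, Cad, Tll, Hkb)
# with piecewise-linear interpolation in time. These profiles are the
# time-dependent parameters that make the circuit non-autonomous.

#' External input profiles
#'
#' Concentration profiles of the external regulators, stored on a grid of
#' time knots x nucleus positions x species and interpolated piecewise
#' linearly in time. Values at a knot are reproduced exactly.
#'
#' @param times strictly increasing numeric vector of time knots (min).
#' @param positions numeric vector of % A-P positions (the finest nucleus
#'   row on which the profiles are defined).
#' @param values numeric array `length(times)` x `length(positions)` x
#'   `length(species)`, all values finite and non-negative.
#' @param species character vector of regulator names.
#' @return an object of class `external_profiles`.
#' @export
external_profiles <- function(times, positions, values,
                              species = EXTERNAL_REGULATORS) {
  times <- as.numeric(times)
  positions <- as.numeric(positions)
  if (is.unsorted(times, strictly = TRUE))
    stop("time knots must be strictly increasing")
  values <- array(values, dim = c(length(times), length(positions),
                                  length(species)))
  if (any(!is.finite(values))) stop("profile values must be finite")
  if (any(values < 0)) stop("profile values must be non-negative")
  dimnames(values) <- list(NULL, NULL, species)
  structure(list(times = times, positions = positions, values = values,
                 species = species),
            class = "external_profiles")
}

position_index <- function(profiles, positions) {
  idx <- match(round(positions, 6), round(profiles$positions, 6))
  if (any(is.na(idx)))
    stop("nucleus positions not covered by the profile grid: ",
         paste(positions[is.na(idx)], collapse = ", "))
  idx
}

#' Interpolate external inputs at a time point
#'
#' Piecewise-linear interpolation in time of all external regulator profiles,
#' sampled at the positions of a nucleus row. Values at knots are exact; a
#' coarser (e.g. C13) row samples the matching subset of profile positions.
#'
#' @param profiles an `external_profiles` object.
#' @param t time (min) within the profile span.
#' @param row a `nucleus_row` whose positions are a subset of the profile
#'   grid.
#' @return matrix nuclei x species.
#' @export
interpolate_external <- function(profiles, t, row) {
  if (t < profiles$times[1] - 1e-9 ||
      t > profiles$times[length(profiles$times)] + 1e-9)
    stop("time ", t, " outside the profile span")
  idx <- position_index(profiles, row$positions)
  K <- length(profiles$times)
  if (K == 1L) {
    out <- profiles$values[1, idx, , drop = FALSE]
    dim(out) <- c(length(idx), length(profiles$species))
  } else {
    k <- findInterval(t, profiles$times, rightmost.closed = TRUE,
                      all.inside = TRUE)
    t0 <- profiles$times[k]; t1 <- profiles$times[k + 1L]
    w <- if (t1 > t0) min(max((t - t0) / (t1 - t0), 0), 1) else 0
    v0 <- profiles$values[k, idx, , drop = FALSE]
    v1 <- profiles$values[k + 1L, idx, , drop = FALSE]
    out <- (1 - w) * v0 + w * v1
    dim(out) <- c(length(idx), length(profiles$species))
  }
  colnames(out) <- profiles$species
  out
}

#' Freeze external inputs at a clamp time
#'
#' Returns profiles whose value at every `t >= t_clamp` equals the value at
#' `t_clamp`, leaving earlier values unchanged. Used for the frozen-gradient
#' (autonomous) comparison runs; the default clamp in [simulate_circuit()] is
#' the earliest profile time, mimicking gradients fixed at their early
#' blastoderm levels.
#'
#' @param profiles an `external_profiles` object.
#' @param t_clamp clamp time (min) within the profile span.
#' @param species regulators to freeze (default: all).
#' @return an `external_profiles` object.
#' @export
freeze_external_inputs <- function(profiles, t_clamp,
                                   species = profiles$species) {
  tk <- profiles$times
  if (t_clamp < tk[1] - 1e-9 || t_clamp > tk[length(tk)] + 1e-9)
    stop("t_clamp outside the profile span")
  sp <- match(species, profiles$species)
  if (any(is.na(sp))) stop("unknown species in freeze request")
  # value at the clamp time on the full position grid
  full_row <- nucleus_row_any(profiles$positions)
  at_clamp <- interpolate_external(profiles, t_clamp, full_row)
  new_times <- sort(unique(c(tk[tk <= t_clamp], t_clamp, tk[tk > t_clamp])))
  K <- length(new_times)
  vals <- array(NA_real_, dim = c(K, length(profiles$positions),
                                  length(profiles$species)))
  for (k in seq_len(K)) {
    tt <- new_times[k]
    v <- interpolate_external(profiles, tt, full_row)
    if (tt >= t_clamp) v[, sp] <- at_clamp[, sp]
    vals[k, , ] <- v
  }
  external_profiles(new_times, profiles$positions, vals, profiles$species)
}

# nucleus_row without the equal-spacing requirement (profile grids are
# usually regular, but freeze/interp helpers must not depend on it)
nucleus_row_any <- function(positions) {
  structure(list(positions = as.numeric(positions),
                 n_nuclei = length(positions), cycle_index = NA_integer_,
                 spacing = NA_real_),
            class = "nucleus_row")
}

# K x n x M array of profile values restricted to a nucleus row, in the
# layout the compiled integrator expects.
profile_values_for_row <- function(profiles, row) {
  idx <- position_index(profiles, row$positions)
  v <- profiles$values[, idx, , drop = FALSE]
  array(v, dim = c(length(profiles$times), length(idx),
                   length(profiles$species)))
}

#' Tidy data frame of profile values
#'
#' @param x an `external_profiles` object.
#' @param ... unused.
#' @return data frame with columns `time_min`, `position_pct`, `species`,
#'   `concentration`.
#' @export
as.data.frame.external_profiles <- function(x, ...) {
  grid <- expand.grid(time_min = x$times, position_pct = x$positions,
                      species = x$species, stringsAsFactors = FALSE)
  grid$concentration <- as.vector(x$values)
  grid[order(grid$species, grid$time_min, grid$position_pct), ,
       drop = FALSE]
}
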