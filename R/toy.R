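# Schedule-free integration of small circuits (toy fixtures, single nuclei,
# frozen-field probes). Same solver and RHS as the full hybrid simulation,
# without mitosis or division.

#' Simulate a circuit without the blastoderm schedule
#'
#' Integrates the interphase dynamics on a fixed nucleus row from
#' `sample_times[1]` through the remaining sample times. Used for toy
#' fixtures (toggle/spiral), ramp experiments, and any run that does not
#' involve the mitotic schedule.
#'
#' @param params a `circuit_parameters`.
#' @param profiles an `external_profiles` covering the row positions and the
#'   sampled time span.
#' @param init_state nuclei x genes matrix, the state at `sample_times[1]`.
#' @param sample_times strictly increasing times; the first is the initial
#'   time.
#' @param row `nucleus_row`; defaults to a single nucleus at the first
#'   profile position.
#' @param production keep production on (TRUE) or simulate a mitotic phase.
#' @param rtol,atol solver tolerances.
#' @return a `circuit_trajectory` (with a `NULL` schedule).
#' @export
simulate_nuclei <- function(params, profiles, init_state, sample_times,
                            row = NULL, production = TRUE,
                            rtol = 1e-8, atol = 1e-10) {
  validate_parameters(params)
  init_state <- as.matrix(init_state)
  if (is.null(row)) {
    stopifnot(nrow(init_state) == 1)
    row <- nucleus_row_any(profiles$positions[1])
  }
  stopifnot(length(sample_times) >= 2,
            !is.unsorted(sample_times, strictly = TRUE))
  t0 <- sample_times[1]
  ts <- sample_times[-1]
  res <- .ck_integrate(init_state, t0, ts,
                       params$R, diffusion_coefficient(params, 14L),
                       params$lambda, params$W, params$E, params$h,
                       profiles$times, profile_values_for_row(profiles, row),
                       production, rtol, atol, -1, -1, -1)
  states <- c(list(init_state),
              lapply(seq_along(ts), function(s)
                matrix(res$states[, , s], nrow = row$n_nuclei)))
  structure(list(times = sample_times, states = states,
                 row_keys = rep("C14A", length(sample_times)),
                 rows = list(C14A = row), schedule = NULL, mode = "dynamic",
                 clamp_time = NULL, division = NULL,
                 unstable = !res$ok, gene_names = params$gene_names),
            class = "circuit_trajectory")
}

#' Ramp profile for a single external input
#'
#' Linear ramp of one external regulator over time, constant in space; a
#' convenience for bifurcation experiments on the toy fixtures.
#'
#' @param times time knots.
#' @param values ramp values at the knots (recycled linearly if length 2:
#'   interpreted as start/end).
#' @param positions spatial grid (default a single position at 50).
#' @param species regulator name.
#' @return an `external_profiles`.
#' @export
ramp_profile <- function(times, values, positions = 50, species = "bias") {
  if (length(values) == 2)
    values <- seq(values[1], values[2], length.out = length(times))
  stopifnot(length(values) == length(times))
  vals <- array(rep(values, times = length(positions)),
                dim = c(length(times), length(positions), 1))
  external_profiles(times, positions, vals, species)
}
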