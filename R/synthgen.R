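# Synthetic-data generator: dynamic maternal gradients (anterior exponential
# Bcd that decays late, posterior Cad that clears from the trunk), posterior
# terminal Tll/Hkb domains, a maternal Hb initial condition, and a
# ground-truth gap gene circuit whose posterior domains shift anteriorly.
# Functional forms are simple parametric stand-ins for measured profiles; all
# shape parameters are exposed through the config.

#' Synthetic data configuration
#'
#' Defaults define the study conditions of the whole pipeline: the trunk
#' spatial range, the stage schedule, the maternal gradient shapes and their
#' decay/clearing schedules, the terminal domains, the maternal Hb initial
#' condition, the ground-truth circuit, and the observation noise.
#'
#' @param ... overrides of the default entries (see the function body for
#'   names and units).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(...) {
  schedule <- stage_schedule()
  cfg <- list(
    schedule = schedule,
    positions = seq(35, 92, by = 1),        # C14A profile grid (% A-P)
    knot_dt = 2.5,                          # profile time knots (min)
    # Bcd: A(t) * exp(-x / length_scale); amplitude constant until the decay
    # onset, then linearly decreasing to fraction f at gastrulation
    bcd_amplitude = 100, bcd_length = 20,
    bcd_decay_onset = schedule$class_bounds[3], bcd_decay_fraction = 0.4,
    # Cad: posterior sigmoid plateau; the plateau decays and its anterior
    # edge retreats posteriorly over the late time classes
    cad_plateau = 110, cad_edge = 45, cad_steepness = 2.5, cad_tilt = 0.45,
    cad_clear_onset = schedule$class_bounds[3], cad_clear_fraction = 0.45,
    cad_edge_shift = 10,
    # terminal inputs: Gaussian posterior domains, constant in time
    tll_amplitude = 80, tll_center = 85, tll_width = 3,
    hkb_amplitude = 80, hkb_center = 92, hkb_width = 2.5,
    # maternal Hb initial condition: anterior step
    hb_maternal_amplitude = 60, hb_maternal_edge = 47,
    hb_maternal_steepness = 3,
    noise_sd = 0.02,                        # fraction of per-species max
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  class(cfg) <- "synthetic_config"
  cfg
}

bcd_amplitude_at <- function(cfg, t) {
  f <- cfg$bcd_decay_fraction
  t_on <- cfg$bcd_decay_onset
  t_end <- cfg$schedule$t_end
  ifelse(t <= t_on, 1,
         1 - (1 - f) * pmin((t - t_on) / (t_end - t_on), 1)) *
    cfg$bcd_amplitude
}

#' Anterior Bcd gradient
#'
#' \eqn{B(x, t) = A(t) e^{-x/\lambda_B}} with the amplitude constant until
#' the decay onset and then decreasing linearly to a fraction of its early
#' value at gastrulation.
#'
#' @param cfg a `synthetic_config`.
#' @param times,positions evaluation grid; default the config's.
#' @return matrix times x positions.
#' @export
make_bcd <- function(cfg, times = profile_knots(cfg),
                     positions = cfg$positions) {
  A <- bcd_amplitude_at(cfg, times)
  outer(A, exp(-positions / cfg$bcd_length))
}

#' Posterior Cad gradient with late clearing
#'
#' A posterior sigmoid plateau, tilted so concentration keeps increasing
#' gently towards the posterior across the trunk (`cad_tilt` is the fraction
#' of the posterior-most level missing at the anterior end). From the
#' clearing onset the plateau level decreases linearly and the anterior edge
#' retreats posteriorly, so the concentration is monotone non-increasing in
#' time at every position posterior of the initial edge.
#'
#' @inheritParams make_bcd
#' @return matrix times x positions.
#' @export
make_cad <- function(cfg, times = profile_knots(cfg),
                     positions = cfg$positions) {
  t_on <- cfg$cad_clear_onset
  t_end <- cfg$schedule$t_end
  prog <- pmin(pmax((times - t_on) / (t_end - t_on), 0), 1)
  plateau <- cfg$cad_plateau * (1 - (1 - cfg$cad_clear_fraction) * prog)
  edge <- cfg$cad_edge + cfg$cad_edge_shift * prog
  x0 <- min(positions); x1 <- max(positions)
  tilt <- (1 - cfg$cad_tilt) + cfg$cad_tilt * (positions - x0) / (x1 - x0)
  out <- matrix(NA_real_, length(times), length(positions))
  for (k in seq_along(times)) {
    out[k, ] <- plateau[k] * tilt /
      (1 + exp(-(positions - edge[k]) / cfg$cad_steepness))
  }
  out
}

#' Terminal Tll and Hkb domains
#'
#' Gaussian posterior bumps, negligible anterior of 75% A-P so that the
#' 35-71% phase-portrait analysis range stays free of terminal inputs.
#'
#' @inheritParams make_bcd
#' @return list with matrices `Tll` and `Hkb` (times x positions).
#' @export
make_terminal_inputs <- function(cfg, times = profile_knots(cfg),
                                 positions = cfg$positions) {
  gauss <- function(a, c0, w)
    matrix(rep(a * exp(-((positions - c0)^2) / (2 * w^2)),
               each = length(times)),
           nrow = length(times))
  list(Tll = gauss(cfg$tll_amplitude, cfg$tll_center, cfg$tll_width),
       Hkb = gauss(cfg$hkb_amplitude, cfg$hkb_center, cfg$hkb_width))
}

profile_knots <- function(cfg) {
  sort(unique(c(seq(0, cfg$schedule$t_end, by = cfg$knot_dt),
                cfg$schedule$t_end)))
}

#' Assemble the external input profiles
#'
#' @param cfg a `synthetic_config`.
#' @return an `external_profiles` with species Bcd, Cad, Tll, Hkb.
#' @export
make_profiles <- function(cfg) {
  times <- profile_knots(cfg)
  term <- make_terminal_inputs(cfg, times)
  vals <- array(NA_real_, c(length(times), length(cfg$positions), 4))
  vals[, , 1] <- make_bcd(cfg, times)
  vals[, , 2] <- make_cad(cfg, times)
  vals[, , 3] <- term$Tll
  vals[, , 4] <- term$Hkb
  external_profiles(times, cfg$positions, vals, EXTERNAL_REGULATORS)
}

#' Maternal initial condition
#'
#' Anterior Hb step (maternal Hb), zero for the zygotic-only genes, on the
#' C13 row.
#'
#' @param cfg a `synthetic_config`.
#' @param row the starting `nucleus_row` (default C13).
#' @return nuclei x 4 matrix (hb, Kr, gt, kni).
#' @export
initial_state <- function(cfg, row = default_rows()$C13) {
  hb <- cfg$hb_maternal_amplitude /
    (1 + exp((row$positions - cfg$hb_maternal_edge) /
               cfg$hb_maternal_steepness))
  cbind(hb = hb, Kr = 0, gt = 0, kni = 0)
}

#' Ground-truth gap gene circuit
#'
#' The diffusion-less four-gene circuit used to generate synthetic
#' expression data. Its sign structure follows the consensus trunk network:
#' activation by the maternal gradients, repression by the terminal genes,
#' self-activation, strong mutual repression between the mutually exclusive
#' pairs (hb/kni and Kr/gt), and asymmetric repression around the
#' hb -> Kr -> kni -> gt ring, which drives the damped temporal succession
#' of gap genes in posterior nuclei and hence the anterior domain shifts.
#'
#' @return a `circuit_parameters` object with its `sign_mask` set.
#' @export
ground_truth_params <- function() {
  genes <- GAP_GENES
  # rows = target, cols = regulator (hb, Kr, gt, kni)
  # strong repression of each gene by its posterior neighbour closes the
  # odd Kr -> kni -> gt repression cycle (a damped oscillator posteriorly);
  # hb/kni and Kr/gt are the mutually exclusive pairs
  W <- matrix(c(
    #  hb      Kr      gt      kni
    0.010, -0.015, -0.004, -0.040,   # -> hb
    -0.015,  0.004, -0.004, -0.035,  # -> Kr
    -0.040, -0.035,  0.004, -0.004,  # -> gt
    -0.040, -0.012, -0.035,  0.004   # -> kni
  ), nrow = 4, byrow = TRUE)
  # cols = Bcd, Cad, Tll, Hkb
  E <- matrix(c(
    0.120,  0.000,  0.025, -0.010,   # -> hb
    0.150,  0.025, -0.060, -0.060,   # -> Kr
    0.010,  0.030, -0.008, -0.050,   # -> gt
    0.008,  0.040, -0.050, -0.050    # -> kni
  ), nrow = 4, byrow = TRUE)
  h <- c(-1.8, -2.0, -2.5, -2.6)
  sign_mask <- list(W = sign(W), E = sign(E))
  circuit_parameters(R = rep(15, 4), lambda = rep(0.095, 4), W = W, E = E,
                     h = h, D_base = rep(0, 4), gene_names = genes,
                     sign_mask = sign_mask)
}

#' Two-gene toggle switch fixture
#'
#' Mutual repression with weights -10 and thresholds +5 (R = lambda = 1).
#' The symmetric state (0.5, 0.5) is an exact saddle with eigenvalues
#' \{+4, -6\}; two stable asymmetric states complete the bistable portrait.
#' One external input with weight (1, 0) on the first gene provides the bias
#' channel used in the ramp experiments.
#'
#' @return a `circuit_parameters` object.
#' @export
fixture_toggle2 <- function() {
  circuit_parameters(R = c(1, 1), lambda = c(1, 1),
                     W = matrix(c(0, -10, -10, 0), 2, 2, byrow = TRUE),
                     E = matrix(c(1, 0), 2, 1),
                     h = c(5, 5), gene_names = c("g1", "g2"),
                     external_names = "bias")
}

#' Two-gene spiral sink fixture
#'
#' Cross-activation/repression (+3 / -3) with thresholds (-1.5, +1.5);
#' the unique steady state is exactly (0.5, 0.5) with eigenvalues
#' \eqn{-1 \pm 1.5 i}: a spiral sink.
#'
#' @return a `circuit_parameters` object.
#' @export
fixture_spiral2 <- function() {
  circuit_parameters(R = c(1, 1), lambda = c(1, 1),
                     W = matrix(c(0, 3, -3, 0), 2, 2, byrow = TRUE),
                     E = matrix(numeric(0), 2, 0),
                     h = c(-1.5, 1.5), gene_names = c("g1", "g2"))
}

#' Generate the ground-truth synthetic dataset
#'
#' Simulates the ground-truth circuit on the generated inputs, samples at
#' the ten analysis times, and adds truncated-at-zero Gaussian noise (SD =
#' `noise_sd` of each species' maximum). Generation verifies that the
#' default pattern shows at least four distinguishable domains and that the
#' posterior kni and gt domains shift anterior-ward between T1 and T8; it
#' fails loudly otherwise.
#'
#' @param cfg a `synthetic_config`.
#' @param check verify the pattern contract (default TRUE).
#' @param rtol,atol solver tolerances.
#' @return list with `profiles`, `init` (C13 initial state), `params`,
#'   `trajectory` (noiseless dynamic run), `data` (tidy noisy observation
#'   table), and `manifest`.
#' @export
ground_truth_dataset <- function(cfg = synthetic_config(), check = TRUE,
                                 rtol = 1e-8, atol = 1e-10) {
  params <- ground_truth_params()
  profiles <- make_profiles(cfg)
  init <- initial_state(cfg)
  traj <- simulate_circuit(params, cfg$schedule, profiles, init,
                           rtol = rtol, atol = atol)
  if (traj$unstable) stop("ground-truth simulation unstable")
  data <- as.data.frame(traj, times = cfg$schedule$analysis_times)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    for (sp in unique(data$species)) {
      i <- data$species == sp
      sd_sp <- cfg$noise_sd * max(data$concentration[i])
      data$concentration[i] <-
        pmax(data$concentration[i] + rnorm(sum(i), sd = sd_sp), 0)
    }
  }
  if (check) check_ground_truth_pattern(traj, cfg)
  manifest <- list(seed = cfg$seed, noise_sd = cfg$noise_sd,
                   n_times = length(cfg$schedule$analysis_times),
                   genes = params$gene_names,
                   generated = "gapdyn::ground_truth_dataset")
  list(profiles = profiles, init = init, params = params, trajectory = traj,
       data = data, manifest = manifest)
}

check_ground_truth_pattern <- function(traj, cfg) {
  sched <- cfg$schedule
  t4 <- sched$analysis_times[["T4"]]
  n_domains <- 0L
  for (g in traj$gene_names) {
    st <- state_at(traj, t4)
    pos <- attr(st, "positions")
    doms <- extract_domains(pos, st[, g])
    n_domains <- n_domains + sum(doms$peak > 20)
  }
  if (n_domains < 4)
    stop("pattern check failed: only ", n_domains,
         " distinguishable domains at T4 (need >= 4)")
  t1 <- sched$analysis_times[["T1"]]
  t8 <- sched$analysis_times[["T8"]]
  for (g in c("kni", "gt")) {
    bt <- boundary_timecourse(traj, g, side = "anterior",
                              times = sched$analysis_times)
    # posterior-most linked domain present at both T1 and T8
    ok <- FALSE
    for (dom in unique(bt$domain)) {
      b <- bt[bt$domain == dom, ]
      p1 <- b$position[abs(b$time - t1) < 1e-9]
      p8 <- b$position[abs(b$time - t8) < 1e-9]
      if (length(p1) == 1 && length(p8) == 1 && p8 < p1 - 1) ok <- TRUE
    }
    if (!ok)
      stop("pattern check failed: posterior ", g,
           " domain does not shift anterior-ward between T1 and T8")
  }
  invisible(TRUE)
}
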