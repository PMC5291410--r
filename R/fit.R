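# Reverse-engineering harness: weighted least-squares cost, sign-constrained
# simulated annealing, RMS scoring, defect detection, and circuit selection.

#' Root-mean-square score of a model against data
#'
#' \eqn{\sqrt{\sum w (model - data)^2 / \sum w}} over all (time, position,
#' gene) triples present in the data; weights default to 1.
#'
#' @param model tidy data frame (`time_min`, `position_pct`, `species`,
#'   `concentration`) of model output, or a `circuit_trajectory`.
#' @param data tidy data frame of observations with the same columns.
#' @param weights optional per-observation weights aligned with `data`, or a
#'   `weight` column in `data`.
#' @return non-negative RMS score (au).
#' @export
rms_score <- function(model, data, weights = NULL) {
  res <- model_residuals(model, data, weights)
  sqrt(sum(res$w * res$r^2) / sum(res$w))
}

model_residuals <- function(model, data, weights = NULL) {
  if (inherits(model, "circuit_trajectory"))
    model <- as.data.frame(model, times = sort(unique(data$time_min)))
  if (is.null(weights))
    weights <- if ("weight" %in% names(data)) data$weight else
      rep(1, nrow(data))
  key <- function(d) paste(round(d$time_min, 6), round(d$position_pct, 6),
                           d$species)
  idx <- match(key(data), key(model))
  ok <- !is.na(idx)
  if (!any(ok)) stop("no overlap between model samples and data support")
  list(r = model$concentration[idx[ok]] - data$concentration[ok],
       w = weights[ok])
}

#' Weighted least-squares cost of a parameter set
#'
#' Simulates the circuit and returns \eqn{\sum w (model - data)^2}.
#' Numerically unstable simulations return a large sentinel cost instead of
#' raising an error, so the optimizer can move away from them.
#'
#' @param params a `circuit_parameters` object.
#' @param data tidy observation table.
#' @param profiles an `external_profiles`.
#' @param schedule a `stage_schedule`.
#' @param init_state initial state on the starting row.
#' @param weights optional per-observation weights.
#' @param unstable_cost sentinel cost for failed simulations.
#' @param ... passed to [simulate_circuit()] (tolerances etc.).
#' @return scalar cost.
#' @export
wls_cost <- function(params, data, profiles, schedule, init_state,
                     weights = NULL, unstable_cost = 1e30, ...) {
  traj <- tryCatch(
    simulate_circuit(params, schedule, profiles, init_state,
                     sample_times = sort(unique(data$time_min)), ...),
    error = function(e) NULL)
  if (is.null(traj) || traj$unstable) return(unstable_cost)
  res <- model_residuals(traj, data, weights)
  if (any(!is.finite(res$r))) return(unstable_cost)
  sum(res$w * res$r^2)
}

#' Sign-constrained simulated annealing
#'
#' Serial simulated annealing with geometric cooling. Proposals perturb one
#' coordinate at a time with a Gaussian step, reflecting at the box bounds
#' and at zero for sign-constrained coordinates, so no accepted state ever
#' violates the constraints. Step sizes adapt toward a target acceptance
#' rate during an initial adaptation phase. Deterministic given `seed`.
#'
#' @param cost function of a numeric parameter vector.
#' @param x0 initial parameter vector (must satisfy the constraints).
#' @param lower,upper box bounds (finite, recycled).
#' @param sign per-coordinate sign constraint: -1 (<= 0), +1 (>= 0) or 0
#'   (unconstrained); recycled.
#' @param seed RNG seed.
#' @param control list: `n_iter` (total proposals), `t0` (initial
#'   temperature; default set from initial cost), `cooling` (geometric factor
#'   per sweep), `step0` (initial step, fraction of each coordinate's range),
#'   `adapt_until` (fraction of iterations with step adaptation),
#'   `keep_trace` (record every proposal in `proposal_trace`).
#' @return an object of class `fit_result` with `par` (best-ever vector),
#'   `cost`, `n_eval`, `accept_rate`, `seed`, and `flags`.
#' @export
anneal <- function(cost, x0, lower, upper, sign = 0, seed = 1L,
                   control = list()) {
  d <- length(x0)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  sgn <- rep_len(sign, d)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower > upper)) stop("bounds must be finite with lower <= upper")
  lo <- ifelse(sgn > 0, pmax(lower, 0), lower)
  hi <- ifelse(sgn < 0, pmin(upper, 0), upper)
  if (any(lo > hi)) stop("infeasible sign/bounds combination")
  if (any(x0 < lo - 1e-12) || any(x0 > hi + 1e-12))
    stop("x0 violates the constraints")
  ctrl <- modifyList(list(n_iter = 5000L, t0 = NULL, cooling = 0.995,
                          sweep = max(d, 10L), step0 = 0.25,
                          adapt_until = 0.7, t_min = 1e-12,
                          keep_trace = FALSE), control)
  reflect <- function(x, l, u) {
    # reflect into [l, u]; handles multiple bounces
    if (u == l) return(l)
    span <- u - l
    y <- (x - l) %% (2 * span)
    if (y < 0) y <- y + 2 * span
    l + ifelse(y <= span, y, 2 * span - y)
  }
  set.seed(seed)
  x <- x0
  fx <- cost(x)
  n_eval <- 1L
  best <- x; fbest <- fx
  temp <- if (is.null(ctrl$t0)) max(abs(fx), 1) * 0.1 else ctrl$t0
  steps <- ctrl$step0 * (hi - lo)
  steps[steps <= 0] <- ctrl$step0
  acc <- integer(d); tries <- integer(d)
  n_accept <- 0L
  trace <- if (ctrl$keep_trace)
    matrix(NA_real_, ctrl$n_iter, d) else NULL
  for (it in seq_len(ctrl$n_iter)) {
    j <- ((it - 1L) %% d) + 1L
    xp <- x
    xp[j] <- reflect(x[j] + rnorm(1L, sd = steps[j]), lo[j], hi[j])
    if (ctrl$keep_trace) trace[it, ] <- xp
    fp <- cost(xp)
    n_eval <- n_eval + 1L
    tries[j] <- tries[j] + 1L
    if (fp <= fx || runif(1L) < exp(-(fp - fx) / temp)) {
      x <- xp; fx <- fp
      acc[j] <- acc[j] + 1L
      n_accept <- n_accept + 1L
      if (fx < fbest) { best <- x; fbest <- fx }
    }
    if (it %% ctrl$sweep == 0L) {
      temp <- max(temp * ctrl$cooling, ctrl$t_min)
      if (it < ctrl$adapt_until * ctrl$n_iter) {
        rate <- ifelse(tries > 0, acc / pmax(tries, 1L), 0.44)
        steps <- steps * exp((rate - 0.44))
        steps <- pmin(steps, (hi - lo) + 1e-12)
        steps <- pmax(steps, 1e-9 * (hi - lo + 1e-12))
        acc[] <- 0L; tries[] <- 0L
      }
    }
  }
  structure(list(par = best, cost = fbest, n_eval = n_eval,
                 accept_rate = n_accept / ctrl$n_iter,
                 seed = seed, temperature_final = temp,
                 proposal_trace = trace,
                 flags = character(0)),
            class = "fit_result")
}

# Precompiled WLS cost closure. The data is aligned to (time, nucleus, gene)
# indices and the per-phase integrator inputs (sample times, external-input
# arrays, diffusion rates) are built once, so each annealing step pays only
# for the integration itself.
make_wls_cost <- function(data, profiles, schedule, init_state,
                          weights = NULL, rows = default_rows(),
                          unstable_cost = 1e30, rtol = 1e-6, atol = 1e-8,
                          max_steps = 500) {
  times <- sort(unique(data$time_min))
  init_state <- as.matrix(init_state)
  stopifnot(nrow(init_state) == rows$C13$n_nuclei)
  if (is.null(weights))
    weights <- if ("weight" %in% names(data)) data$weight else
      rep(1, nrow(data))
  gene_index <- function(sp) match(sp, GAP_GENES)
  lookup <- vector("list", length(times))
  for (k in seq_along(times)) {
    sel <- which(abs(data$time_min - times[k]) < 1e-9)
    row <- if (times[k] < schedule$division_time - 1e-12) rows$C13 else
      rows$C14A
    i <- match(round(data$position_pct[sel], 6), round(row$positions, 6))
    if (any(is.na(i)))
      stop("data positions at t = ", times[k], " not on the nucleus row")
    lookup[[k]] <- list(idx = cbind(i, gene_index(data$species[sel])),
                        y = data$concentration[sel], w = weights[sel])
    if (any(is.na(lookup[[k]]$idx)))
      stop("unknown species in data")
  }
  # precompute per-phase integrator inputs
  phases <- schedule$phases
  plan <- vector("list", nrow(phases))
  for (k in seq_len(nrow(phases))) {
    ph <- phases[k, ]
    row <- if (ph$cycle == 13L) rows$C13 else rows$C14A
    ts <- times[times > ph$start + 1e-12 & times <= ph$end + 1e-12]
    plan[[k]] <- list(start = ph$start,
                      ts = sort(unique(c(ts, ph$end))),
                      data_at = match(round(ts, 9),
                                      round(sort(unique(c(ts, ph$end))), 9)),
                      time_idx = match(round(ts, 9), round(times, 9)),
                      production = ph$production,
                      cycle = ph$cycle,
                      ext = profile_values_for_row(profiles, row))
  }
  div13 <- rep(seq_len(rows$C13$n_nuclei), each = 2L)
  function(params) {
    state <- init_state
    total <- 0
    for (k in seq_along(plan)) {
      pl <- plan[[k]]
      if (pl$cycle == 14L && nrow(state) == rows$C13$n_nuclei)
        state <- state[div13, , drop = FALSE]
      cyc <- if (pl$cycle == 13L) 13L else 14L
      res <- .ck_integrate(state, pl$start, pl$ts,
                           params$R, diffusion_coefficient(params, cyc),
                           params$lambda, params$W, params$E, params$h,
                           profiles$times, pl$ext, pl$production,
                           rtol, atol, -1, -1, max_steps)
      if (!res$ok) return(unstable_cost)
      st <- res$states
      n <- nrow(state)
      for (s in seq_along(pl$data_at)) {
        lk <- lookup[[pl$time_idx[s]]]
        sm <- matrix(st[, , pl$data_at[s]], nrow = n)
        r <- sm[lk$idx] - lk$y
        if (any(!is.finite(r))) return(unstable_cost)
        total <- total + sum(lk$w * r * r)
      }
      state <- matrix(st[, , dim(st)[3]], nrow = n)
    }
    total
  }
}

#' Fit circuit weights to expression data
#'
#' Convenience harness around [anneal()]: the free parameters are the
#' entries of `W`, `E` and `h` (production, decay and diffusion rates are
#' kept at their values in `base_params`), sign constraints are taken from
#' `base_params$sign_mask`, and the cost is [wls_cost()] against `data`.
#'
#' @param data tidy observation table.
#' @param profiles an `external_profiles`.
#' @param schedule a `stage_schedule`.
#' @param init_state initial expression state.
#' @param base_params `circuit_parameters` providing fixed rates, the sign
#'   mask, and the parameter layout.
#' @param bounds list with `W`, `E`, `h` two-sided magnitude bounds
#'   (defaults: |w| <= 0.3, |e| <= 0.3, h in [-10, 10]).
#' @param seed RNG seed (controls the random start and the annealing chain).
#' @param control passed to [anneal()].
#' @param random_start draw the starting point uniformly within the
#'   constrained box (TRUE) or start from `base_params` (FALSE).
#' @param rtol,atol solver tolerances used inside the cost.
#' @param rows nucleus rows to fit on. For diffusion-less circuits the
#'   equations are spatially uncoupled, so fitting on a coarser row (see
#'   [coarse_rows()]) is exact and proportionally cheaper; `init_state` and
#'   `data` are subset to the row positions automatically.
#' @return a `fit_result` whose `params` element is the fitted
#'   `circuit_parameters`; also records the RMS score on `data`.
#' @export
fit_circuit <- function(data, profiles, schedule, init_state, base_params,
                        bounds = list(W = 0.3, E = 0.3, h = 10),
                        seed = 1L, control = list(), random_start = TRUE,
                        rtol = 1e-6, atol = 1e-8, rows = default_rows()) {
  G <- length(base_params$R)
  M <- ncol(base_params$E)
  mask <- base_params$sign_mask
  if (is.null(mask)) mask <- list(W = matrix(0, G, G), E = matrix(0, G, M))
  layout <- list(W = G * G, E = G * M, h = G)
  sgn <- c(as.vector(mask$W), as.vector(mask$E), rep(0, G))
  lower <- c(rep(-bounds$W, G * G), rep(-bounds$E, G * M), rep(-bounds$h, G))
  upper <- -lower
  unpack <- function(x) {
    p <- base_params
    p$W <- matrix(x[seq_len(G * G)], G, G)
    p$E <- matrix(x[G * G + seq_len(G * M)], G, M)
    p$h <- x[G * G + G * M + seq_len(G)]
    p
  }
  lo <- ifelse(sgn > 0, pmax(lower, 0), lower)
  hi <- ifelse(sgn < 0, pmin(upper, 0), upper)
  # subset data and the initial state to the fitting rows
  keep <- rep(FALSE, nrow(data))
  for (tt in unique(data$time_min)) {
    row <- if (tt < schedule$division_time - 1e-12) rows$C13 else rows$C14A
    keep <- keep | (abs(data$time_min - tt) < 1e-9 &
                      round(data$position_pct, 6) %in% round(row$positions, 6))
  }
  data <- data[keep, , drop = FALSE]
  i0 <- match(round(rows$C13$positions, 6),
              round(default_rows()$C13$positions, 6))
  if (nrow(init_state) != rows$C13$n_nuclei) {
    if (any(is.na(i0)))
      stop("fitting rows are not a subset of the default C13 row")
    init_state <- init_state[i0, , drop = FALSE]
  }
  set.seed(seed)
  x0 <- if (random_start) lo + runif(length(lo)) * (hi - lo) else
    c(as.vector(base_params$W), as.vector(base_params$E), base_params$h)
  wcost <- make_wls_cost(data, profiles, schedule, init_state, rows = rows,
                         rtol = rtol, atol = atol)
  cost <- function(x) wcost(unpack(x))
  res <- anneal(cost, x0, lower, upper, sgn, seed = seed, control = control)
  res$params <- unpack(res$par)
  traj <- simulate_circuit(res$params, schedule, profiles, init_state,
                           rows = rows,
                           sample_times = sort(unique(data$time_min)),
                           rtol = rtol, atol = atol)
  res$unstable <- traj$unstable
  res$rms <- if (traj$unstable) Inf else rms_score(traj, data)
  res$trajectory <- traj
  res$data <- data
  res
}

#' Multi-seed parameter-recovery experiment
#'
#' Runs [fit_circuit()] from several random starts against a synthetic
#' ground-truth dataset and summarises recovery: which runs pass the RMS
#' acceptance threshold, whether the accepted runs reproduce every
#' sign-constrained interaction sign of the ground truth, and the best run's
#' RMS against the noiseless trajectory, expressed relative to the data's
#' dynamic range. A scaled-down serial stand-in for large parallel
#' reverse-engineering protocols.
#'
#' @param gt output of [ground_truth_dataset()].
#' @param seeds integer vector of annealing seeds (one run per seed).
#' @param schedule the `stage_schedule` the data was generated on.
#' @param rows fitting rows (default [coarse_rows()] for speed; exact for
#'   diffusion-less circuits).
#' @param bounds,control passed to [fit_circuit()].
#' @param rms_max RMS acceptance threshold (default 20).
#' @return list with `results` (all `fit_result`s), `accepted` (logical),
#'   `signs_recovered` (logical per run: all masked W/E entries match the
#'   ground-truth signs), `best_rms_noiseless`, `dynamic_range`, and
#'   `best_rms_fraction` (best noiseless RMS / dynamic range).
#' @export
recovery_experiment <- function(gt, seeds = 1:10,
                                schedule = stage_schedule(),
                                rows = coarse_rows(2L),
                                bounds = list(W = 0.25, E = 0.25, h = 5),
                                control = list(n_iter = 16000,
                                               cooling = 0.982,
                                               adapt_until = 0.9),
                                rms_max = 20) {
  noiseless <- as.data.frame(gt$trajectory,
                             times = schedule$analysis_times)
  truth <- gt$params
  results <- list()
  rms_noiseless <- numeric(0)
  signs_ok <- logical(0)
  for (seed in seeds) {
    res <- fit_circuit(gt$data, gt$profiles, schedule, gt$init, truth,
                       bounds = bounds, seed = seed, control = control,
                       rows = rows)
    rn <- if (res$unstable) Inf else rms_score(res$trajectory, noiseless)
    ok <- TRUE
    for (nm in c("W", "E")) {
      mask <- truth$sign_mask[[nm]]
      fit <- res$params[[nm]]
      if (any(mask != 0 & sign(fit) != mask)) ok <- FALSE
    }
    res$rms_noiseless <- rn
    results[[length(results) + 1L]] <- res
    rms_noiseless <- c(rms_noiseless, rn)
    signs_ok <- c(signs_ok, ok)
  }
  accepted <- vapply(results, function(r)
    !isTRUE(r$unstable) && r$rms < rms_max, logical(1))
  rng <- diff(range(gt$data$concentration))
  list(results = results, accepted = accepted, signs_recovered = signs_ok,
       rms_noiseless = rms_noiseless,
       best_rms_noiseless = min(rms_noiseless),
       dynamic_range = rng,
       best_rms_fraction = min(rms_noiseless) / rng)
}

#' Coarser nucleus rows for fitting
#'
#' Sub-samples the default trunk rows by keeping every `step`-th C13 nucleus
#' (daughters follow). Exact for diffusion-less circuits, whose per-nucleus
#' equations are uncoupled.
#'
#' @param step keep every `step`-th C13 nucleus (default 2).
#' @return list with `C13` and `C14A` nucleus rows.
#' @export
coarse_rows <- function(step = 2L) {
  full <- default_rows()
  pos13 <- full$C13$positions[seq(1, full$C13$n_nuclei, by = step)]
  # drop parents whose second daughter would fall off the modelled range
  spacing <- diff(pos13)[1]
  pos13 <- pos13[pos13 + spacing / 2 <= max(full$C14A$positions)]
  row13 <- nucleus_row(pos13, 13L)
  list(C13 = row13, C14A = divide_nuclei(matrix(0, row13$n_nuclei, 1),
                                         row13)$row)
}

#' Detect gross patterning defects
#'
#' Automated stand-ins for visual defect screening, evaluated within
#' per-gene, per-time expected domain windows: a *missing domain* has model
#' maximum below 20% of the data maximum in the window; a *bimodal domain*
#' has two local maxima separated by a trough below 50% of the lower peak;
#' a *disconnected boundary* re-crosses the half-maximum level on a domain
#' flank (two or more separate above-half-max runs) without qualifying as
#' bimodal.
#'
#' @param model tidy model table or `circuit_trajectory`.
#' @param data tidy observation table.
#' @param windows data frame with columns `species`, `time_min`, `x_lo`,
#'   `x_hi` (% A-P) defining the expected domains.
#' @return character vector drawn from `missing_domain`, `bimodal_domain`,
#'   `disconnected_boundary` (empty when clean).
#' @export
detect_defects <- function(model, data, windows) {
  if (inherits(model, "circuit_trajectory"))
    model <- as.data.frame(model, times = sort(unique(windows$time_min)))
  flags <- character(0)
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    sel <- function(d) {
      d <- d[d$species == w$species & abs(d$time_min - w$time_min) < 1e-6 &
               d$position_pct >= w$x_lo & d$position_pct <= w$x_hi, ,
             drop = FALSE]
      d[order(d$position_pct), ]
    }
    m <- sel(model); d <- sel(data)
    if (nrow(m) < 3) next
    if (nrow(d) > 0 && max(m$concentration) < 0.2 * max(d$concentration)) {
      flags <- c(flags, "missing_domain")
      next
    }
    y <- m$concentration
    n <- length(y)
    peaks <- which(diff(sign(diff(y))) < 0) + 1L
    bimodal <- FALSE
    if (length(peaks) >= 2) {
      ord <- peaks[order(y[peaks], decreasing = TRUE)]
      p1 <- ord[1]; p2 <- ord[2]
      trough <- min(y[min(p1, p2):max(p1, p2)])
      if (trough < 0.5 * min(y[p1], y[p2])) bimodal <- TRUE
    }
    if (bimodal) flags <- c(flags, "bimodal_domain")
    half <- max(y) / 2
    runs <- rle(y >= half)
    n_runs <- sum(runs$values)
    if (n_runs >= 2 && !bimodal)
      flags <- c(flags, "disconnected_boundary")
  }
  unique(flags)
}

#' Filter and rank fitted circuits
#'
#' Applies the selection cascade: discard numerically unstable circuits,
#' discard solutions with RMS score >= 20.0, discard circuits with any
#' patterning defect flag, discard circuits whose posterior gap domains do
#' not shift anterior-ward by at least one inter-nucleus spacing between T1
#' and T8, and rank the survivors by RMS ascending.
#'
#' @param results list of `fit_result` objects (each carrying `params`,
#'   `rms`, `unstable`, and `trajectory`).
#' @param data tidy observation table (for defect windows).
#' @param windows defect windows for [detect_defects()]; `NULL` skips the
#'   defect filter.
#' @param shift_genes genes whose posterior domain must shift (default kni
#'   and gt).
#' @param rms_max RMS acceptance threshold (default 20).
#' @param min_shift minimum anterior-ward boundary movement (% A-P) between
#'   T1 and T8; default one C14A inter-nucleus spacing (1%).
#' @return the surviving `fit_result`s ordered by RMS, each annotated with
#'   its selection `flags`; dropped results are excluded.
#' @export
select_circuits <- function(results, data, windows = NULL,
                            shift_genes = c("kni", "gt"),
                            rms_max = 20, min_shift = 1) {
  keep <- list()
  for (res in results) {
    flags <- character(0)
    if (isTRUE(res$unstable)) flags <- c(flags, "numerically_unstable")
    if (!isTRUE(res$unstable) && res$rms >= rms_max)
      flags <- c(flags, "rms_above_threshold")
    if (length(flags) == 0 && !is.null(windows))
      flags <- c(flags, detect_defects(res$trajectory, data, windows))
    if (length(flags) == 0 && !is.null(res$trajectory)) {
      sched <- res$trajectory$schedule
      t1 <- sched$analysis_times[["T1"]]
      t8 <- sched$analysis_times[["T8"]]
      for (g in shift_genes) {
        bt <- boundary_timecourse(res$trajectory, g, side = "anterior",
                                  times = c(t1, t8))
        moved <- FALSE
        for (dom in unique(bt$domain)) {
          b <- bt[bt$domain == dom, ]
          if (nrow(b) == 2 && b$position[b$time == t8] <=
              b$position[b$time == t1] - min_shift) moved <- TRUE
        }
        if (!moved) flags <- c(flags, "no_posterior_shift")
      }
    }
    res$flags <- unique(flags)
    if (length(res$flags) == 0) keep[[length(keep) + 1L]] <- res
  }
  if (length(keep) == 0) return(list())
  keep[order(vapply(keep, `[[`, numeric(1), "rms"))]
}
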