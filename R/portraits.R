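# Instantaneous phase portraits of the diffusion-less per-nucleus system:
# frozen vector fields, Newton-Raphson steady-state search with analytic
# Jacobians, eigenvalue classification, tracking across analysis times, and
# saddle-node bifurcation detection.

#' Frozen autonomous vector field
#'
#' The autonomous field obtained by fixing the external regulator
#' concentrations at given values and setting diffusion to zero:
#' \eqn{f(g) = R \phi(W g + E g_m + h) - \lambda g}. Because
#' \eqn{0 < \phi < 1}, the box \eqn{[0, R^a/\lambda^a]} per gene is positively
#' invariant and contains every steady state.
#'
#' @param params a `circuit_parameters` object.
#' @param external numeric vector of external regulator concentrations
#'   (length = `ncol(params$E)`).
#' @return an object of class `frozen_field` with the field constants, the
#'   per-gene bounding box, and optional `position`/`time` metadata.
#' @export
frozen_field <- function(params, external = numeric(ncol(params$E))) {
  validate_parameters(params)
  if (length(external) != ncol(params$E))
    stop("external must have length ", ncol(params$E))
  bias <- params$h
  if (ncol(params$E) > 0) bias <- bias + drop(params$E %*% external)
  structure(list(R = params$R, lambda = params$lambda, W = params$W,
                 bias = bias, external = external,
                 gene_names = params$gene_names,
                 box_hi = params$R / params$lambda),
            class = "frozen_field")
}

#' Instantaneous field of a nucleus at a time point
#'
#' Builds the [frozen_field()] for one nucleus by clamping the time-dependent
#' external inputs at time `t` and excluding diffusion.
#'
#' @param params a `circuit_parameters` object.
#' @param profiles an `external_profiles` object.
#' @param position nucleus position (% A-P), must lie on the row grid.
#' @param t time (min) within the profile span.
#' @param row the `nucleus_row` to resolve `position` on.
#' @return a `frozen_field` with `position` and `time` metadata.
#' @export
instantaneous_field <- function(params, profiles, position, t,
                                row = default_rows()$C14A) {
  i <- match(round(position, 6), round(row$positions, 6))
  if (is.na(i)) stop("position ", position, " is not on the nucleus row")
  ext <- interpolate_external(profiles, t, row)[i, ]
  f <- frozen_field(params, ext)
  f$position <- position
  f$time <- t
  f
}

#' Evaluate a frozen field
#'
#' @param field a `frozen_field`.
#' @param g a state vector, or a matrix with one state per row.
#' @return the field value(s), same shape as `g`.
#' @export
field_eval <- function(field, g) {
  if (is.matrix(g)) {
    u <- g %*% t(field$W)
    u <- sweep(u, 2, field$bias, "+")
    sweep(regulation_expression(u), 2, field$R, "*") -
      sweep(g, 2, field$lambda, "*")
  } else {
    u <- drop(field$W %*% g) + field$bias
    field$R * regulation_expression(u) - field$lambda * g
  }
}

#' Analytic Jacobian of a frozen field
#'
#' Entry (a, b) is \eqn{R^a \phi'(u^a) W_{ab} - \lambda^a \delta_{ab}}.
#'
#' @param field a `frozen_field`.
#' @param point state vector.
#' @return a G x G matrix.
#' @export
field_jacobian <- function(field, point) {
  u <- drop(field$W %*% point) + field$bias
  J <- (field$R * regulation_expression_derivative(u)) * field$W
  diag(J) <- diag(J) - field$lambda
  J
}

#' Classify a steady state from its eigenvalues
#'
#' All real parts negative gives an attractor (a spiral sink when any
#' imaginary part exceeds the spiral threshold), all positive an unstable
#' node or spiral source, mixed signs a saddle or spiral saddle, and any real
#' part within `tol_real` of zero is marginal.
#'
#' @param eigenvalues complex eigenvalues of the Jacobian at the state.
#' @param tol_real marginality threshold on real parts; default
#'   `1e-6 * max(abs(Re))`.
#' @param tol_imag absolute threshold on imaginary parts for the spiral
#'   label.
#' @return one of "point attractor", "spiral sink", "saddle",
#'   "spiral saddle", "unstable node", "spiral source", "marginal".
#' @export
classify_steady_state <- function(eigenvalues, tol_real = NULL,
                                  tol_imag = 1e-8) {
  re <- Re(eigenvalues)
  im <- Im(eigenvalues)
  if (is.null(tol_real)) tol_real <- 1e-6 * max(abs(re), 1e-300)
  spiral <- any(abs(im) > tol_imag)
  if (any(abs(re) <= tol_real)) return("marginal")
  if (all(re < 0)) return(if (spiral) "spiral sink" else "point attractor")
  if (all(re > 0)) return(if (spiral) "spiral source" else "unstable node")
  if (spiral) "spiral saddle" else "saddle"
}

is_attractor <- function(class) class %in% c("point attractor", "spiral sink")
is_saddle <- function(class) class %in% c("saddle", "spiral saddle")

#' Find the steady states of a frozen field
#'
#' Newton-Raphson with the analytic Jacobian from a regular grid of starts
#' (`n_grid` points per axis) plus `n_random` seeded uniform starts inside
#' the bounding box. Converged roots are de-duplicated at a relative distance
#' of `dedup_tol` (relative to the box diagonal); roots outside the box by
#' more than a small tolerance are discarded, as are non-convergent starts.
#'
#' @param field a `frozen_field`.
#' @param n_grid grid starts per axis (default 5, i.e. 625 starts in 4D).
#' @param n_random number of random starts (default 500).
#' @param seed RNG seed for the random starts.
#' @param tol absolute tolerance on the max-norm of the field residual.
#' @param dedup_tol relative de-duplication distance.
#' @param max_iter Newton iteration cap per start.
#' @return an object of class `steady_state_set`: a list with `states` (each
#'   with `location`, `eigenvalues`, `class`, `residual`), the `field`, and
#'   search diagnostics.
#' @export
find_steady_states <- function(field, n_grid = 5L, n_random = 500L,
                               seed = 1L, tol = 1e-9, dedup_tol = 1e-5,
                               max_iter = 60L) {
  G <- length(field$R)
  hi <- field$box_hi
  diag_len <- max(sqrt(sum(hi^2)), sqrt(.Machine$double.eps))
  grid_axes <- lapply(hi, function(b) seq(0, b, length.out = n_grid))
  starts <- as.matrix(do.call(expand.grid, grid_axes))
  if (n_random > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    rnd <- matrix(runif(n_random * G), ncol = G)
    rnd <- sweep(rnd, 2, hi, "*")
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    starts <- rbind(starts, rnd)
  }
  max_step <- diag_len  # cap Newton steps to stay near the box
  roots <- list()
  n_fail <- 0L
  for (s in seq_len(nrow(starts))) {
    x <- starts[s, ]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      fx <- field_eval(field, x)
      if (max(abs(fx)) < tol) { converged <- TRUE; break }
      J <- field_jacobian(field, x)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) break
      sn <- sqrt(sum(step^2))
      if (!is.finite(sn)) break
      if (sn > max_step) step <- step * (max_step / sn)
      x <- x + step
      if (any(!is.finite(x)) || any(abs(x) > 100 * (diag_len + 1))) break
    }
    if (!converged) { n_fail <- n_fail + 1L; next }
    if (any(x < -1e-6 * diag_len) || any(x > hi + 1e-6 * diag_len)) next
    dup <- FALSE
    for (r in roots) {
      if (sqrt(sum((r - x)^2)) < dedup_tol * diag_len) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1L]] <- x
  }
  states <- lapply(roots, function(x) {
    ev <- eigen(field_jacobian(field, x), only.values = TRUE)$values
    list(location = setNames(as.numeric(x), field$gene_names),
         eigenvalues = ev,
         class = classify_steady_state(ev),
         residual = max(abs(field_eval(field, x))))
  })
  structure(list(states = states, field = field, n_failed = n_fail,
                 n_starts = nrow(starts), box_diag = diag_len),
            class = "steady_state_set")
}

#' Basin of attraction of a point
#'
#' Forward-integrates the frozen autonomous field from `point` until the
#' trajectory comes within `eps` (relative to the box diagonal) of a known
#' attractor, or until `t_max` (default ten times the slowest decay time).
#'
#' @param point state vector inside the box.
#' @param field a `frozen_field`.
#' @param states a `steady_state_set` for the field (computed if missing).
#' @param eps convergence radius, relative to the box diagonal.
#' @param t_max integration horizon (min).
#' @param ... passed to [find_steady_states()] when `states` is missing.
#' @return the index of the reached attractor within `states$states`, or
#'   `NA_integer_` when unresolved.
#' @export
basin_of <- function(point, field, states = NULL, eps = 1e-4,
                     t_max = NULL, ...) {
  if (is.null(states)) states <- find_steady_states(field, ...)
  if (is.null(t_max)) t_max <- 10 / min(field$lambda)
  eps_abs <- eps * states$box_diag
  att <- which(vapply(states$states, function(s) is_attractor(s$class),
                      logical(1)))
  if (length(att) == 0) return(NA_integer_)
  locs <- do.call(rbind, lapply(states$states[att], `[[`, "location"))
  near <- function(x) {
    d <- sqrt(rowSums(sweep(locs, 2, x)^2))
    if (min(d) < eps_abs) att[which.min(d)] else NA_integer_
  }
  hit <- near(point)
  if (!is.na(hit)) return(hit)
  G <- length(field$R)
  y <- matrix(point, nrow = 1)
  n_chunks <- 50L
  chunk <- t_max / n_chunks
  E0 <- matrix(0, G, 0)
  t <- 0
  for (k in seq_len(n_chunks)) {
    res <- .ck_integrate(y, t, t + chunk,
                         field$R, rep(0, G), field$lambda, field$W,
                         E0, field$bias,
                         0, numeric(0), TRUE, 1e-8, 1e-10, -1, -1, -1)
    if (!res$ok) return(NA_integer_)
    y <- matrix(res$states[, , 1], nrow = 1)
    t <- t + chunk
    hit <- near(drop(y))
    if (!is.na(hit)) return(hit)
  }
  NA_integer_
}

#' Phase-portrait series of one nucleus
#'
#' Generates instantaneous phase portraits at the given analysis times,
#' tracks steady states between consecutive times by greedy nearest-neighbour
#' matching, and emits bifurcation events where tracked states appear or
#' disappear. A simultaneous loss (gain) of a nearby attractor-saddle pair is
#' labelled a saddle-node annihilation (creation).
#'
#' @param params a `circuit_parameters` object.
#' @param profiles an `external_profiles`.
#' @param position nucleus position (% A-P).
#' @param times analysis times (min); default the schedule argument's
#'   `analysis_times`.
#' @param schedule optional `stage_schedule` supplying default times.
#' @param row `nucleus_row` on which `position` lives.
#' @param match_dist maximum matching distance, relative to the box diagonal.
#' @param ... passed to [find_steady_states()].
#' @return an object of class `portrait_series`: `times`, per-time `fields`
#'   and `sets` (steady states annotated with persistent `stable_id`s), the
#'   `events` table, and the box diagonal.
#' @export
portrait_series <- function(params, profiles, position, times = NULL,
                            schedule = NULL, row = default_rows()$C14A,
                            match_dist = 0.2, ...) {
  if (is.null(times)) {
    if (is.null(schedule)) stop("give either times or a schedule")
    times <- schedule$analysis_times
  }
  fields <- lapply(times, function(t)
    instantaneous_field(params, profiles, position, t, row))
  sets <- lapply(fields, find_steady_states, ...)
  track_steady_states(sets, times, match_dist = match_dist,
                      position = position)
}

#' Track steady states across a series of portraits
#'
#' @param sets list of `steady_state_set` objects at consecutive times.
#' @param times the analysis times the sets belong to.
#' @param match_dist maximum matching distance (relative to box diagonal).
#' @param position optional nucleus position metadata.
#' @return a `portrait_series` object (see [portrait_series()]).
#' @export
track_steady_states <- function(sets, times, match_dist = 0.2,
                                position = NULL) {
  stopifnot(length(sets) == length(times), length(sets) >= 1)
  box_diag <- sets[[1]]$box_diag
  maxd <- match_dist * box_diag
  next_id <- 0L
  for (k in seq_along(sets)) {
    ids <- rep(NA_integer_, length(sets[[k]]$states))
    sets[[k]]$stable_id <- ids
  }
  # initial ids
  n1 <- length(sets[[1]]$states)
  sets[[1]]$stable_id <- seq_len(n1)
  next_id <- n1
  events <- data.frame(t_from = numeric(0), t_to = numeric(0),
                       type = character(0), ids = character(0),
                       stringsAsFactors = FALSE)
  if (length(sets) >= 2) {
    for (k in seq_len(length(sets) - 1L)) {
      a <- sets[[k]]; b <- sets[[k + 1L]]
      na <- length(a$states); nb <- length(b$states)
      ids_b <- rep(NA_integer_, nb)
      if (na > 0 && nb > 0) {
        la <- do.call(rbind, lapply(a$states, `[[`, "location"))
        lb <- do.call(rbind, lapply(b$states, `[[`, "location"))
        dmat <- as.matrix(stats::dist(rbind(la, lb)))[seq_len(na),
                                                      na + seq_len(nb),
                                                      drop = FALSE]
        free_a <- rep(TRUE, na); free_b <- rep(TRUE, nb)
        repeat {
          dmat2 <- dmat
          dmat2[!free_a, ] <- Inf
          dmat2[, !free_b] <- Inf
          m <- which(dmat2 == min(dmat2), arr.ind = TRUE)
          if (!is.finite(min(dmat2)) || min(dmat2) > maxd) break
          i <- m[1, 1]; j <- m[1, 2]
          ids_b[j] <- a$stable_id[i]
          free_a[i] <- FALSE; free_b[j] <- FALSE
          if (!any(free_a) || !any(free_b)) break
        }
      } else {
        free_a <- rep(TRUE, na); free_b <- rep(TRUE, nb)
      }
      lost <- which(if (na > 0) free_a else logical(0))
      gained <- which(if (nb > 0) free_b else logical(0))
      ids_b[gained] <- next_id + seq_along(gained)
      next_id <- next_id + length(gained)
      sets[[k + 1L]]$stable_id <- ids_b
      ev <- pair_saddle_node(a, b, lost, gained, ids_b, maxd,
                             times[k], times[k + 1L])
      events <- rbind(events, ev)
    }
  }
  structure(list(times = times, sets = sets, events = events,
                 box_diag = box_diag, position = position),
            class = "portrait_series")
}

# Pair simultaneous attractor+saddle losses (gains) into saddle-node
# annihilation (creation) events; leftovers become plain (dis)appearances.
pair_saddle_node <- function(a, b, lost, gained, ids_b, maxd, t0, t1) {
  ev <- list()
  add <- function(type, ids) {
    ev[[length(ev) + 1L]] <<- data.frame(
      t_from = t0, t_to = t1, type = type,
      ids = paste(ids, collapse = "+"), stringsAsFactors = FALSE)
  }
  lost_att <- lost[vapply(a$states[lost],
                          function(s) is_attractor(s$class), logical(1))]
  lost_sad <- lost[vapply(a$states[lost],
                          function(s) is_saddle(s$class), logical(1))]
  used <- integer(0)
  for (i in lost_att) {
    cand <- setdiff(lost_sad, used)
    if (length(cand) == 0) next
    d <- vapply(cand, function(j)
      sqrt(sum((a$states[[i]]$location - a$states[[j]]$location)^2)),
      numeric(1))
    # the colliding pair approaches each other, so proximity is expected
    j <- cand[which.min(d)]
    if (min(d) <= 2 * maxd) {
      add("saddle_node_annihilation", a$stable_id[c(i, j)])
      used <- c(used, i, j)
    }
  }
  for (i in setdiff(lost, used)) add("disappearance", a$stable_id[i])
  gain_att <- gained[vapply(b$states[gained],
                            function(s) is_attractor(s$class), logical(1))]
  gain_sad <- gained[vapply(b$states[gained],
                            function(s) is_saddle(s$class), logical(1))]
  usedg <- integer(0)
  for (i in gain_att) {
    cand <- setdiff(gain_sad, usedg)
    if (length(cand) == 0) next
    d <- vapply(cand, function(j)
      sqrt(sum((b$states[[i]]$location - b$states[[j]]$location)^2)),
      numeric(1))
    j <- cand[which.min(d)]
    if (min(d) <= 2 * maxd) {
      add("saddle_node_creation", ids_b[c(i, j)])
      usedg <- c(usedg, i, j)
    }
  }
  for (i in setdiff(gained, usedg)) add("appearance", ids_b[i])
  if (length(ev) == 0)
    data.frame(t_from = numeric(0), t_to = numeric(0), type = character(0),
               ids = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, ev)
}

#' Steady-state report table
#'
#' @param series a `portrait_series`.
#' @return data frame with one row per steady state per time: position, time,
#'   stable id, location coordinates, eigenvalues, and class.
#' @export
portrait_table <- function(series) {
  rows <- list()
  for (k in seq_along(series$times)) {
    set <- series$sets[[k]]
    for (j in seq_along(set$states)) {
      s <- set$states[[j]]
      G <- length(s$location)
      loc <- as.list(s$location)
      names(loc) <- paste0("g_", names(s$location))
      ev <- s$eigenvalues
      evl <- c(as.list(Re(ev)), as.list(Im(ev)))
      names(evl) <- c(paste0("eig_re", seq_len(G)), paste0("eig_im", seq_len(G)))
      rows[[length(rows) + 1L]] <- data.frame(
        position = if (is.null(series$position)) NA_real_ else series$position,
        time = series$times[k], state_id = set$stable_id[j],
        as.data.frame(loc), as.data.frame(evl), class = s$class,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}
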