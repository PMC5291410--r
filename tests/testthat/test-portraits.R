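# Steady-state search, classification, and basins on fixtures with known
# exact answers, cross-checked against independent oracles.

test_that("toggle switch has exactly three steady states including the exact saddle", {
  tg <- fixture_toggle2()
  f <- frozen_field(tg, external = 0)
  ss <- find_steady_states(f, n_grid = 5, n_random = 200, seed = 1)
  expect_length(ss$states, 3)
  cls <- vapply(ss$states, `[[`, character(1), "class")
  expect_equal(sort(cls), c("point attractor", "point attractor", "saddle"))
  sad <- ss$states[[which(cls == "saddle")]]
  expect_equal(unname(sad$location), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(sort(Re(sad$eigenvalues)), c(-6, 4), tolerance = 1e-8)
  expect_equal(Im(sad$eigenvalues), c(0, 0))
  # every root satisfies the residual and box invariants
  for (s in ss$states) {
    expect_lt(s$residual, 1e-9)
    expect_true(all(s$location >= -1e-6 & s$location <= f$box_hi + 1e-6))
  }
})

test_that("toggle root set matches a forward-integration + bisection oracle", {
  skip_if_not_installed("deSolve")
  tg <- fixture_toggle2()
  f <- frozen_field(tg, external = 0)
  # oracle 1: forward-integrate a 50x50 grid of starts with lsoda and
  # cluster the endpoints -> the attractors
  grid <- as.matrix(expand.grid(seq(0, 1, length.out = 50),
                                seq(0, 1, length.out = 50)))
  rhs <- function(t, y, parms) {
    st <- matrix(y, ncol = 2)
    u <- st %*% t(tg$W) + rep(tg$h, each = nrow(st))
    list(as.vector(0.5 * (u / sqrt(u^2 + 1) + 1) - st))
  }
  sol <- deSolve::lsoda(as.vector(grid), c(0, 40), rhs, NULL,
                        rtol = 1e-8, atol = 1e-10)
  ends <- matrix(sol[2, -1], ncol = 2)
  # endpoint clusters: the two attractors, plus the saddle reached by the
  # starts lying exactly on the diagonal separatrix
  cl <- unique(round(ends, 4))
  # oracle 2: sign-change bisection along the diagonal pins down the saddle
  fdiag <- function(g) 0.5 * ((-10 * g + 5) / sqrt((-10 * g + 5)^2 + 1) + 1) - g
  saddle_g <- uniroot(fdiag, c(0.3, 0.7), tol = 1e-12)$root
  oracle <- unique(round(rbind(cl, c(saddle_g, saddle_g)), 4))
  expect_equal(nrow(oracle), 3)
  found <- do.call(rbind, lapply(find_steady_states(f, n_random = 200,
                                                    seed = 1)$states,
                                 `[[`, "location"))
  expect_equal(nrow(found), nrow(oracle))
  for (k in seq_len(nrow(oracle))) {
    d <- sqrt(rowSums(sweep(found, 2, oracle[k, ])^2))
    expect_lt(min(d), 1e-4)
  }
})

test_that("the spiral fixture has the exact root (0.5, 0.5) classified as a spiral sink", {
  sp <- fixture_spiral2()
  ss <- find_steady_states(frozen_field(sp), n_random = 100, seed = 1)
  expect_length(ss$states, 1)
  s <- ss$states[[1]]
  expect_equal(s$class, "spiral sink")
  expect_equal(unname(s$location), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sort(Im(s$eigenvalues)), c(-1.5, 1.5), tolerance = 1e-9)
  expect_equal(Re(s$eigenvalues), c(-1, -1), tolerance = 1e-9)
})

test_that("the analytic Jacobian matches finite differences at random points", {
  gt <- gap_truth()
  f <- instantaneous_field(gt$params, gt$profiles, 60,
                           gap_config()$schedule$analysis_times[["T4"]])
  set.seed(7)
  eps <- 1e-5
  for (rep in 1:10) {
    x <- runif(4) * f$box_hi
    J <- field_jacobian(f, x)
    Jfd <- matrix(0, 4, 4)
    for (b in 1:4) {
      e <- rep(0, 4); e[b] <- eps
      Jfd[, b] <- (field_eval(f, x + e) - field_eval(f, x - e)) / (2 * eps)
    }
    expect_equal(J, Jfd, tolerance = 1e-5)
  }
  # W = 0 gives the pure-decay Jacobian
  p0 <- decay_params(lambda = 2.5)
  J0 <- field_jacobian(frozen_field(p0, rep(0, 4)), rep(1, 4))
  expect_equal(J0, diag(-2.5, 4))
})

test_that("eigenvalue classification is exhaustive and mutually exclusive", {
  cases <- list(
    list(ev = c(-1, -2, -3, -4), class = "point attractor"),
    list(ev = c(-0.5 + 2i, -0.5 - 2i, -1 + 0i, -3 + 0i), class = "spiral sink"),
    list(ev = c(4, -6), class = "saddle"),
    list(ev = c(0.5 + 1i, 0.5 - 1i, -2 + 0i, -1 + 0i), class = "spiral saddle"),
    list(ev = c(1, 2, 3, 4), class = "unstable node"),
    list(ev = c(1 + 1i, 1 - 1i, 2 + 0i, 3 + 0i), class = "spiral source"),
    list(ev = c(0, -1, -2, -3), class = "marginal"))
  for (cs in cases) expect_equal(classify_steady_state(cs$ev), cs$class)
  # random sweeps always land in exactly one class
  set.seed(1)
  classes <- c("point attractor", "spiral sink", "saddle", "spiral saddle",
               "unstable node", "spiral source", "marginal")
  for (rep in 1:50) {
    ev <- complex(real = rnorm(4), imaginary = rnorm(4) *
                    sample(c(0, 1), 4, replace = TRUE))
    expect_true(classify_steady_state(ev) %in% classes)
  }
})

test_that("root search is insensitive to the number and seed of random starts", {
  tg <- fixture_toggle2()
  f <- frozen_field(tg, external = 1.5)
  ref <- find_steady_states(f, n_random = 200, seed = 1)
  alt <- find_steady_states(f, n_random = 400, seed = 99)
  expect_equal(length(ref$states), length(alt$states))
  locs_ref <- do.call(rbind, lapply(ref$states, `[[`, "location"))
  locs_alt <- do.call(rbind, lapply(alt$states, `[[`, "location"))
  for (k in seq_len(nrow(locs_ref))) {
    expect_lt(min(sqrt(rowSums(sweep(locs_alt, 2, locs_ref[k, ])^2))), 1e-5)
  }
})

test_that("decoupled and degenerate fields have the expected unique roots", {
  # single decoupled gene at R phi(0) / lambda
  p <- circuit_parameters(R = c(10, 0), lambda = c(2, 1),
                          W = matrix(0, 2, 2), E = matrix(0, 2, 0),
                          h = c(0, 0), gene_names = c("a", "b"))
  ss <- find_steady_states(frozen_field(p), n_random = 50, seed = 1)
  expect_length(ss$states, 1)
  expect_equal(unname(ss$states[[1]]$location[1]), 2.5, tolerance = 1e-9)
  # all production off: origin
  p0 <- decay_params()
  ss0 <- find_steady_states(frozen_field(p0, rep(0, 4)), n_grid = 2,
                            n_random = 10, seed = 1)
  expect_length(ss0$states, 1)
  expect_equal(max(abs(ss0$states[[1]]$location)), 0)
})

test_that("frozen fields depend only on the external values", {
  gt <- gap_truth()
  const <- constant_profiles()
  f1 <- instantaneous_field(gt$params, const, 55, 10)
  f2 <- instantaneous_field(gt$params, const, 55, 60)
  set.seed(3)
  for (rep in 1:10) {
    x <- runif(4) * f1$box_hi
    expect_equal(field_eval(f1, x), field_eval(f2, x))
  }
  # all weights and thresholds zero: unique root at R / (2 lambda)
  pz <- circuit_parameters(R = rep(6, 4), lambda = rep(2, 4),
                           W = matrix(0, 4, 4), E = matrix(0, 4, 4),
                           h = rep(0, 4))
  fz <- frozen_field(pz, rep(0, 4))
  ssz <- find_steady_states(fz, n_random = 20, seed = 1)
  expect_length(ssz$states, 1)
  expect_equal(unname(ssz$states[[1]]$location), rep(1.5, 4),
               tolerance = 1e-9)
})

test_that("basin assignment follows forward integration", {
  tg <- fixture_toggle2()
  f <- frozen_field(tg, external = 0)
  ss <- find_steady_states(f, n_random = 100, seed = 1)
  cls <- vapply(ss$states, `[[`, character(1), "class")
  att <- which(cls == "point attractor")
  hi_first <- att[which.max(vapply(ss$states[att],
                                   function(s) s$location[1], numeric(1)))]
  hi_second <- setdiff(att, hi_first)
  expect_equal(basin_of(c(0.9, 0.1), f, ss), hi_first)
  expect_equal(basin_of(c(0.1, 0.9), f, ss), hi_second)
  # a point at an attractor maps to that attractor
  expect_equal(basin_of(ss$states[[hi_first]]$location, f, ss), hi_first)
  # monostable field: every start reaches the unique attractor
  sp <- fixture_spiral2()
  fsp <- frozen_field(sp)
  sss <- find_steady_states(fsp, n_random = 50, seed = 1)
  set.seed(11)
  for (rep in 1:20) {
    expect_equal(basin_of(runif(2), fsp, sss), 1L)
  }
})
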