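# Regulation-expression kinetics, total input, RHS, division.

test_that("regulation-expression function matches its closed form", {
  expect_equal(regulation_expression(0), 0.5)
  expect_equal(regulation_expression(1), 0.5 * (1 / sqrt(2) + 1),
               tolerance = 1e-12)
  # odd-symmetry identity phi(u) + phi(-u) = 1, swept
  u <- c(1.7, seq(-50, 50, length.out = 101))
  expect_equal(regulation_expression(u) + regulation_expression(-u),
               rep(1, length(u)), tolerance = 1e-12)
  # bounded and strictly increasing
  u <- seq(-100, 100, length.out = 2001)
  v <- regulation_expression(u)
  expect_true(all(v > 0 & v < 1))
  expect_true(all(diff(v) > 0))
  expect_error(regulation_expression(NaN), "non-finite")
})

test_that("regulation-expression derivative is positive, peaked at 0, and matches finite differences", {
  expect_equal(regulation_expression_derivative(0), 0.5)
  expect_lt(regulation_expression_derivative(1e3), 1e-8)
  expect_lt(regulation_expression_derivative(-1e3), 1e-8)
  eps <- 1e-6
  for (u in c(0.3, -1.2, 4)) {
    fd <- (regulation_expression(u + eps) -
             regulation_expression(u - eps)) / (2 * eps)
    expect_equal(regulation_expression_derivative(u), fd, tolerance = 1e-6)
  }
  u <- seq(-10, 10, length.out = 101)
  d <- regulation_expression_derivative(u)
  expect_true(all(d > 0))
  expect_equal(u[which.max(d)], 0)
})

test_that("total input sums weighted regulators plus the threshold", {
  p <- circuit_parameters(R = rep(1, 4), lambda = rep(1, 4),
                          W = matrix(0, 4, 4), E = matrix(0, 4, 4),
                          h = rep(-2.5, 4))
  expect_equal(total_input(c(3, 1, 4, 1), c(2, 7, 1, 8), p),
               rep(-2.5, 4))
  expect_equal(total_input(rep(0, 4), rep(0, 4), p, target = 2), -2.5)
  # hand-computed dot product on one row
  p$W[1, ] <- c(0.5, -1, 0, 0)
  p$h <- c(1, rep(0, 3))
  expect_equal(total_input(c(1, 2, 0, 0), rep(0, 4), p, target = 1),
               0.5 - 2 + 1)
  expect_error(total_input(c(1, 2), rep(0, 4), p), "length")
})

test_that("the RHS reduces to decay, shuts production off in mitosis, and has a null Laplacian on uniform states", {
  rows <- default_rows()
  p <- decay_params(lambda = 3)
  st <- matrix(runif(29 * 4), 29, 4)
  ext <- matrix(0, 29, 4)
  expect_equal(circuit_rhs(st, ext, p, rows$C13, "interphase"), -3 * st)
  # mitosis with lambda ~ 0 and D = 0: derivative is zero everywhere
  p2 <- circuit_parameters(R = rep(7, 4), lambda = rep(1e-300, 4),
                           W = matrix(1, 4, 4), E = matrix(1, 4, 4),
                           h = rep(1, 4))
  expect_equal(max(abs(circuit_rhs(st, ext, p2, rows$C13, "mitosis"))), 0)
  # uniform state: diffusion contributes exactly zero for any D
  p3 <- circuit_parameters(R = rep(2, 4), lambda = rep(1, 4),
                           W = matrix(0, 4, 4), E = matrix(0, 4, 4),
                           h = rep(0, 4), D_base = rep(5, 4))
  uni <- matrix(rep(c(1, 2, 3, 4), each = 29), 29, 4)
  expect_equal(circuit_rhs(uni, ext, p3, rows$C14A, "interphase"),
               2 * regulation_expression(0) - uni)
  expect_error(circuit_rhs(-st, ext, p, rows$C13), "negative")
})

test_that("diffusion scales 4-fold per division", {
  p <- circuit_parameters(R = rep(1, 4), lambda = rep(1, 4),
                          W = matrix(0, 4, 4), E = matrix(0, 4, 4),
                          h = rep(0, 4), D_base = c(0.2, 0.3, 0, 0.1))
  expect_equal(diffusion_coefficient(p, 14L), p$D_base)
  expect_equal(diffusion_coefficient(p, 13L), p$D_base / 4)
  p$D_base <- rep(0, 4)
  expect_equal(diffusion_coefficient(p, 10L), rep(0, 4))
})

test_that("nuclear division copies concentrations, doubles the count, and halves the spacing", {
  rows <- default_rows()
  st <- matrix(seq_len(29 * 4), 29, 4)
  div <- divide_nuclei(st, rows$C13)
  expect_equal(div$row$n_nuclei, 58)
  expect_equal(div$row$spacing, rows$C13$spacing / 2)
  expect_equal(div$row$positions, rows$C14A$positions)
  # each daughter inherits the parent state; total concentration doubles
  expect_equal(div$state[seq(1, 57, by = 2), ], st, ignore_attr = TRUE)
  expect_equal(div$state[seq(2, 58, by = 2), ], st, ignore_attr = TRUE)
  expect_equal(sum(div$state), 2 * sum(st))
})

test_that("parameter validation enforces rate signs and the sign mask", {
  W <- matrix(c(0, -1, -1, 0), 2, 2)
  ok <- circuit_parameters(R = c(1, 1), lambda = c(1, 1), W = W,
                           E = matrix(0, 2, 0), h = c(0, 0),
                           sign_mask = list(W = sign(W),
                                            E = matrix(0, 2, 0)))
  expect_s3_class(ok, "circuit_parameters")
  expect_error(circuit_parameters(R = c(1, 1), lambda = c(1, 0), W = W,
                                  E = matrix(0, 2, 0), h = c(0, 0)),
               "lambda")
  expect_error(circuit_parameters(R = c(-1, 1), lambda = c(1, 1), W = W,
                                  E = matrix(0, 2, 0), h = c(0, 0)),
               "production")
  bad_mask <- list(W = -sign(W), E = matrix(0, 2, 0))
  bad_mask$W[1, 2] <- 1  # claims activation where W is repressive
  expect_error(circuit_parameters(R = c(1, 1), lambda = c(1, 1), W = W,
                                  E = matrix(0, 2, 0), h = c(0, 0),
                                  sign_mask = bad_mask),
               "sign constraint")
})

test_that("stage schedule partitions C14A into eight classes with ten analysis times", {
  sched <- stage_schedule()
  expect_length(sched$analysis_times, 10)
  expect_equal(names(sched$analysis_times)[c(1, 10)], c("C13", "gast"))
  cls <- diff(sched$class_bounds)
  expect_equal(cls, rep(cls[1], 8))
  # phases contiguous and non-overlapping
  expect_equal(sched$phases$start[-1], head(sched$phases$end, -1))
  expect_equal(time_class_label(c(5, 21, 69, 70), sched),
               c("C13", "T1", "T8", "gast"))
  expect_equal(resolve_time("T3", sched), sched$analysis_times[["T3"]])
  expect_error(resolve_time("T9", sched), "unknown")
})
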