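# RMS scoring, annealing, defect detection, and circuit selection.

toy_tidy <- function(values, gene = "hb", times = 1, pos = NULL) {
  if (is.null(pos)) pos <- seq_along(values)
  expand <- expand.grid(position_pct = pos, time_min = times)
  data.frame(time_min = expand$time_min, position_pct = expand$position_pct,
             species = gene, concentration = rep(values, length(times)))
}

test_that("rms_score matches hand-computed residuals", {
  d <- toy_tidy(c(1, 2, 3, 4))
  expect_equal(rms_score(d, d), 0)
  m <- d
  m$concentration <- d$concentration + 3
  expect_equal(rms_score(m, d), 3)
  m2 <- d
  m2$concentration <- d$concentration + c(1, -1, 2, -2)
  expect_equal(rms_score(m2, d), sqrt(10 / 4))
  expect_equal(round(rms_score(m2, d), 4), 1.5811)
  expect_error(rms_score(toy_tidy(1:3, gene = "zz"), d), "overlap")
})

test_that("wls_cost is linear in the weights and consistent with rms_score", {
  gt <- gap_truth()
  sched <- gap_config()$schedule
  noiseless <- as.data.frame(gt$trajectory, times = sched$analysis_times)
  c0 <- wls_cost(gt$params, noiseless, gt$profiles, sched, gt$init)
  expect_lt(c0, 1e-6)  # zero-residual synthetic pair
  c1 <- wls_cost(gt$params, gt$data, gt$profiles, sched, gt$init)
  c2 <- wls_cost(gt$params, gt$data, gt$profiles, sched, gt$init,
                 weights = rep(2, nrow(gt$data)))
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  r <- rms_score(simulate_circuit(gt$params, sched, gt$profiles, gt$init,
                                  sample_times = sched$analysis_times),
                 gt$data)
  expect_equal(c1, r^2 * nrow(gt$data), tolerance = 1e-6)
})

test_that("annealing recovers a convex optimum, is deterministic, and honours constraints", {
  target <- c(1.3, -0.7)
  cost <- function(x) sum((x - target)^2)
  r1 <- anneal(cost, c(0, 0), lower = -3, upper = 3, seed = 42,
               control = list(n_iter = 3000))
  expect_lt(max(abs(r1$par - target)), 1e-2)
  r2 <- anneal(cost, c(0, 0), lower = -3, upper = 3, seed = 42,
               control = list(n_iter = 3000))
  expect_identical(r1$par, r2$par)
  expect_identical(r1$cost, r2$cost)
  # sign constraint: every proposal for a negative-constrained coordinate <= 0
  r3 <- anneal(cost, c(-0.5, 0), lower = -3, upper = 3, sign = c(-1, 0),
               seed = 7, control = list(n_iter = 2000, keep_trace = TRUE))
  expect_true(all(r3$proposal_trace[, 1] <= 0))
  expect_true(all(r3$proposal_trace >= -3 - 1e-12 &
                    r3$proposal_trace <= 3 + 1e-12))
  expect_lte(r3$par[1], 0)
  expect_error(anneal(cost, c(1, 1), lower = 0.5, upper = 3,
                      sign = c(-1, 0), seed = 1),
               "infeasible")
})

test_that("defect detection flags exactly the constructed pathologies", {
  pos <- seq(35, 92)
  windows <- data.frame(species = "kni", time_min = 45, x_lo = 55, x_hi = 80)
  clean <- toy_tidy(pmax(0, 10 - abs(pos - 67) / 2), gene = "kni",
                    times = 45, pos = pos)
  expect_no_flags(detect_defects(clean, clean, windows))
  # missing: the model is flat where the data peaks at 200
  flat <- clean
  flat$concentration <- 0
  data_peak <- clean
  data_peak$concentration <- clean$concentration * 20
  expect_equal(detect_defects(flat, data_peak, windows), "missing_domain")
  # bimodal: peaks 10 and 8 with trough 2 < 0.5 * 8
  bim <- toy_tidy(approx(c(55, 60, 64, 70, 80), c(0, 10, 2, 8, 0), pos,
                         yleft = 0, yright = 0)$y,
                  gene = "kni", times = 45, pos = pos)
  expect_equal(detect_defects(bim, clean, windows), "bimodal_domain")
  # disconnected: flank re-crosses half-max but the trough stays shallow
  disc <- toy_tidy(approx(c(55, 60, 64, 70, 80), c(0, 10, 4.5, 5.6, 0), pos,
                          yleft = 0, yright = 0)$y,
                   gene = "kni", times = 45, pos = pos)
  expect_equal(detect_defects(disc, clean, windows), "disconnected_boundary")
})

test_that("selection drops high-RMS and unstable circuits and ranks by RMS", {
  gt <- gap_truth()
  sched <- gap_config()$schedule
  mk_res <- function(rms, unstable = FALSE) {
    structure(list(params = gt$params, rms = rms, unstable = unstable,
                   trajectory = gt$trajectory),
              class = "fit_result")
  }
  kept <- select_circuits(list(mk_res(12), mk_res(25), mk_res(9),
                               mk_res(5, unstable = TRUE)),
                          gt$data)
  expect_length(kept, 2)
  expect_equal(vapply(kept, `[[`, numeric(1), "rms"), c(9, 12))
  expect_length(select_circuits(list(mk_res(25)), gt$data), 0)
})

test_that("parameter files round-trip and reject invalid rates", {
  p <- ground_truth_params()
  path <- tempfile(fileext = ".txt")
  write_parameters(p, path)
  q <- read_parameters(path)
  for (f in c("R", "D_base", "lambda", "W", "E", "h"))
    expect_equal(q[[f]], p[[f]], tolerance = 1e-7)
  expect_equal(q$sign_mask$W, p$sign_mask$W)
  # lambda = 0 must fail validation
  bad <- readLines(path)
  bad[grep("^lambda:", bad)] <- "lambda: 0 0.095 0.095 0.095"
  path2 <- tempfile(fileext = ".txt")
  writeLines(bad, path2)
  expect_error(read_parameters(path2), "lambda")
})
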