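# Half-maximum domain extraction, boundary time courses, shift rates,
# and frozen-vs-dynamic overshoot.

test_that("rectangular and triangular profiles give interpolated half-max boundaries", {
  pos <- seq(35, 92)
  rect <- ifelse(pos >= 50 & pos <= 60, 10, 0)
  d <- extract_domains(pos, rect)
  expect_equal(nrow(d), 1)
  # crossings interpolated between the flanking nuclei (0 -> 10 across 1%)
  expect_equal(d$anterior, 49.5)
  expect_equal(d$posterior, 60.5)
  # triangular peak 0 -> 10 -> 0 over 40..60: half-max at 45 and 55
  tri <- pmax(0, 10 - abs(pos - 50))
  d2 <- extract_domains(pos, tri)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$anterior, 45)
  expect_equal(d2$posterior, 55)
  # two separated rectangles in anterior-to-posterior order
  two <- ifelse(pos >= 40 & pos <= 45, 8, 0) +
    ifelse(pos >= 70 & pos <= 80, 6, 0)
  d3 <- extract_domains(pos, two)
  expect_equal(nrow(d3), 2)
  expect_true(d3$posterior[1] < d3$anterior[2])
  expect_equal(nrow(extract_domains(pos, rep(0, length(pos)))), 0)
})

test_that("extraction is invariant under uniform rescaling and filters speckles", {
  pos <- seq(35, 92)
  prof <- pmax(0, 10 - abs(pos - 50)) + ifelse(pos == 80, 9, 0)
  a <- extract_domains(pos, prof)
  b <- extract_domains(pos, prof * 137.5)
  expect_equal(a$anterior, b$anterior)
  expect_equal(a$posterior, b$posterior)
  # the single-nucleus speckle at 80% is discarded (min width 2 nuclei)
  expect_equal(nrow(a), 1)
})

test_that("boundary time courses follow stationary and translated domains", {
  pos <- seq(35, 92)
  mk_df <- function(shift_per_class) {
    rows <- list()
    for (k in 0:7) {
      centre <- 70 + k * shift_per_class
      conc <- ifelse(pos >= centre - 5 & pos <= centre + 5, 10, 0)
      rows[[k + 1]] <- data.frame(time_min = 20 + k * 6.25,
                                  position_pct = pos, species = "kni",
                                  concentration = conc)
    }
    do.call(rbind, rows)
  }
  still <- boundary_timecourse(mk_df(0), "kni", side = "anterior")
  expect_equal(length(unique(still$domain)), 1)
  expect_equal(diff(range(still$position)), 0)
  moving <- boundary_timecourse(mk_df(-1), "kni", side = "anterior")
  expect_equal(unique(round(diff(moving$position), 9)), -1)
})

test_that("posterior kni boundary of the synthetic truth shifts anterior-ward while domains move", {
  gt <- gap_truth()
  at <- gap_config()$schedule$analysis_times
  bt <- boundary_timecourse(gt$trajectory, "kni", side = "posterior",
                            times = at)
  main <- as.integer(names(which.max(table(bt$domain))))
  b <- bt[bt$domain == main, ]
  expect_gte(nrow(b), 9)
  # non-increasing through the shifting period (C13-T5); afterwards the
  # domain fades and its half-max width blurs, so only the net displacement
  # from the start is constrained
  shift_phase <- b[b$time <= at[["T5"]] + 1e-9, ]
  expect_true(all(diff(shift_phase$position) <= 1e-6))
  expect_lte(b$position[nrow(b)], b$position[1])
})

test_that("shift rates report per-interval finite differences and the overall slope", {
  b <- data.frame(time = c(0, 6.25, 12.5), position = c(70, 70, 70))
  sr <- shift_rate(b)
  expect_equal(sr$intervals$rate, c(0, 0))
  expect_equal(sr$slope, 0)
  b2 <- data.frame(time = seq(0, 31.25, by = 6.25),
                   position = 70 - seq(0, 5, by = 1))
  sr2 <- shift_rate(b2)
  expect_equal(sr2$intervals$rate, rep(-0.16, 5))
  expect_equal(sr2$slope, -0.16)
  # decelerating steps -2, -1, -0.5: rates strictly increasing toward 0
  b3 <- data.frame(time = c(0, 1, 2, 3), position = cumsum(c(70, -2, -1, -0.5)))
  r3 <- shift_rate(b3)$intervals$rate
  expect_true(all(diff(r3) > 0))
  expect_false(shift_rate(b3[1, ])$defined)
})

test_that("overshoot is zero for identical runs and signed for shifted ones", {
  b <- data.frame(time = c(20, 45, 63.75), position = c(70, 68, 67),
                  domain = 1L)
  ov <- overshoot(b, b)
  expect_equal(ov$table$difference, rep(0, 3))
  expect_equal(ov$final, 0)
  b2 <- b
  b2$position[3] <- b$position[3] - 2  # frozen boundary 2% further anterior
  ov2 <- overshoot(b, b2)
  expect_equal(ov2$final, -2)
})
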