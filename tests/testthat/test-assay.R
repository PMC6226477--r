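logistic_melt <- function(tm, slope = 0.35, temps = melt_ramp()) {
  melt_curve(temps, 1 / (1 + exp(-slope * (temps - tm))))
}

test_that("melt normalization maps emission to [0, 1]", {
  c0 <- melt_curve(c(25, 50, 90), c(10, 55, 100))
  n0 <- normalize_melt(c0)
  expect_equal(range(n0$normalized), c(0, 1))
  expect_equal(n0$normalized[2], 0.5)
  expect_error(melt_curve(c(25, 25, 30), c(1, 2, 3)), "increasing")
  expect_error(normalize_melt(melt_curve(c(25, 30), c(1, 1))), "flat")
})

test_that("t_half reads the first upward 0.5 crossing with interpolation", {
  # normalized emission hits exactly 0.5 at a sampled 61 C point
  c1 <- melt_curve(c(59, 61, 63), c(0, 0.5, 1))
  expect_equal(t_half(c1), 61)
  # 0.4 at 60 C and 0.6 at 62 C -> 61 by linear interpolation
  c2 <- melt_curve(c(58, 60, 62, 64), c(0, 0.4, 0.6, 1))
  expect_equal(t_half(c2), 61)
  # a decreasing curve has no upward crossing
  dec <- melt_curve(c(25, 30, 35), c(1, 0.7, 0))
  expect_error(t_half(dec), "never crosses")
  # non-monotone curve: first of multiple crossings, with a warning
  c3 <- melt_curve(1:6, c(0, 0.6, 0.2, 0.8, 0.4, 1))
  expect_warning(th <- t_half(c3), "multiple")
  expect_lt(th, 2)  # first crossing is between 1 and 2
})

test_that("t_half is invariant under affine transforms of raw emission", {
  set.seed(88)
  for (i in 1:10) {
    tm <- runif(1, 40, 75)
    cur <- logistic_melt(tm)
    gain <- runif(1, 0.5, 50); offset <- runif(1, -10, 10)
    cur2 <- melt_curve(cur$temperature, gain * cur$emission + offset)
    expect_equal(t_half(cur2), t_half(cur), tolerance = 1e-12)
  }
})

test_that("t_half recovers a logistic midpoint sampled on the 25-90 C ramp", {
  for (tm in c(40.3, 55.0, 61.7, 74.9)) {
    expect_lt(abs(t_half(logistic_melt(tm)) - tm), 0.25)
  }
})

test_that("delta_t_half averages paired replicate differences", {
  a <- logistic_melt(60)
  expect_equal(delta_t_half(a, a), 0)
  b <- logistic_melt(65)
  expect_equal(delta_t_half(b, a), t_half(b) - t_half(a))
  # triplicates: average of pairwise shifts
  wl <- list(logistic_melt(64), logistic_melt(65), logistic_melt(66))
  wo <- list(logistic_melt(60), logistic_melt(60), logistic_melt(60))
  d <- delta_t_half(wl, wo)
  expect_equal(d, mean(vapply(1:3, function(i)
    t_half(wl[[i]]) - t_half(wo[[i]]), 0)))
  expect_error(delta_t_half(wl, wo[1:2]), "equal length")
})

test_that("melt_ramp reproduces the stepwise protocol", {
  r <- melt_ramp()
  expect_equal(r[1], 25)
  expect_equal(max(r), 90)
  expect_equal(length(r), 66L)  # start + 65 cycles
  expect_true(all(diff(r) == 1))
})

test_that("capture efficiency is the sample/control mean ratio", {
  expect_equal(capture_efficiency(c(5, 5), c(5, 5)), 1.0)
  expect_equal(capture_efficiency(c(2, 3, 4), c(1, 1, 1)), 3.0)
  expect_equal(capture_efficiency(20.7, 1), 20.7)
  # homogeneous of degree 0 under common scaling of all wells
  expect_equal(capture_efficiency(c(2, 3, 4) * 7, c(1, 1, 1) * 7), 3.0)
  expect_error(capture_efficiency(c(1, 2), c(0, 0)), "positive")
  expect_error(capture_efficiency(numeric(0), 1), "at least one")
})

test_that("qPCR fold change follows delta-delta-Ct with triplicate-mean Ct", {
  un <- qpcr_measurement("VEGFA", "untreated",
                         ct_pulldown = c(25, 25, 25),
                         ct_input = c(20, 20, 20))
  tr_same <- qpcr_measurement("VEGFA", "BRACO-19",
                              ct_pulldown = c(25, 25, 25),
                              ct_input = c(20, 20, 20))
  expect_equal(qpcr_fold_change(tr_same, un), 1)
  # ddCt = -1 with efficiency 2 -> fold 2
  tr2 <- qpcr_measurement("VEGFA", "BRACO-19",
                          ct_pulldown = c(24, 24, 24),
                          ct_input = c(20, 20, 20))
  expect_equal(qpcr_fold_change(tr2, un), 2)
  # triplicates are averaged on the Ct scale before differencing
  tr3 <- qpcr_measurement("VEGFA", "BRACO-19",
                          ct_pulldown = c(20.1, 20.0, 19.9),
                          ct_input = c(16, 16, 16))
  un3 <- qpcr_measurement("VEGFA", "untreated",
                          ct_pulldown = c(26, 25, 24),
                          ct_input = c(20, 20, 20))
  expect_equal(qpcr_fold_change(tr3, un3), 2^(5 - 4))
  expect_equal(qpcr_fold_change(tr3, un3, efficiency = 1.9), 1.9)
  expect_error(qpcr_measurement("x", "c", numeric(0), 20), "required")
  expect_error(qpcr_measurement("x", "c", -1, 20), "> 0")
})

test_that("ld_dose interpolates on log10 dose and refuses extrapolation", {
  # response exactly 0.85 at dose 5
  cur <- dose_response_curve(c(1, 5, 25), c(1, 0.85, 0.2),
                             normalize = FALSE)
  expect_equal(ld_dose(cur, 15), 5)
  # 0.9 at dose 1, 0.8 at dose 10 -> LD15 = 10^0.5
  cur2 <- dose_response_curve(c(0.1, 1, 10), c(1, 0.9, 0.8),
                              normalize = FALSE)
  expect_equal(ld_dose(cur2, 15), 10^0.5)
  expect_lt(ld_dose(cur2, 15), ld_dose(cur2, 18))  # monotone in x
  # curve never dropping below 0.95
  cur3 <- dose_response_curve(c(1, 10), c(1, 0.96), normalize = FALSE)
  expect_error(ld_dose(cur3, 15), "outside")
  expect_error(ld_dose(cur2, 0), "in \\(0, 100\\)")
  expect_error(dose_response_curve(c(1, 1), c(1, 0)), "increasing")
})

test_that("assay CSV readers build the right objects", {
  # melt curves
  mp <- withr::local_tempfile(fileext = ".csv")
  temps <- melt_ramp()
  d <- do.call(rbind, lapply(c("A1", "A2"), function(w)
    data.frame(temperature = temps,
               emission = 1 / (1 + exp(-0.35 * (temps - 60))),
               well = w, label = "F21T+ligand")))
  write.csv(d, mp, row.names = FALSE)
  curves <- read_melt_curves(mp)
  expect_length(curves, 2L)
  expect_lt(abs(t_half(curves[["A1"]]) - 60), 0.25)
  # qPCR
  qp <- withr::local_tempfile(fileext = ".csv")
  qd <- rbind(
    data.frame(target = "VEGFA", condition = "untreated",
               assay = "pulldown", ct = c(25, 25, 25)),
    data.frame(target = "VEGFA", condition = "untreated",
               assay = "input", ct = c(20, 20, 20)))
  write.csv(qd, qp, row.names = FALSE)
  q <- read_qpcr_table(qp)
  expect_length(q, 1L)
  expect_equal(mean(q[[1]]$ct_pulldown), 25)
  # dose-response with replicates averaged
  dp <- withr::local_tempfile(fileext = ".csv")
  dd <- data.frame(dose = rep(c(0.1, 1, 10), each = 2),
                   confluency = c(100, 100, 90, 88, 10, 12),
                   replicate = rep(1:2, 3))
  write.csv(dd, dp, row.names = FALSE)
  cur <- read_dose_response(dp)
  expect_equal(nrow(cur), 3L)
  expect_equal(cur$normalized[1], 1)
  expect_error(read_qpcr_table(dp), "missing columns")
})
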