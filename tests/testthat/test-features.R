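# ROI aggregation, analysis windows, per-sample features.

test_that("central ROI mean reduces to the central 5x5 block of a 9x9 grid", {
  expect_equal(central_roi_mean(matrix(3.7, 9, 9)), 3.7)
  ind <- matrix(0, 9, 9); ind[3:7, 3:7] <- 1
  expect_equal(central_roi_mean(ind), 1)
  set.seed(21)
  g <- matrix(rnorm(81), 9, 9)
  # brute-force enumeration oracle over 0-based rows/cols 2..6
  acc <- 0
  for (r in 2:6) for (cl in 2:6) acc <- acc + g[r + 1, cl + 1]
  expect_equal(central_roi_mean(g), acc / 25, tolerance = 1e-12)
  expect_error(central_roi_mean(matrix(0, 8, 8)), "even")
})

test_that("ROI mean tolerates isolated bad pixels but not widespread failure", {
  g <- matrix(2, 9, 9)
  g[5, 5] <- NaN; g[4, 4] <- NA # 2 of 25 = 8%
  expect_equal(central_roi_mean(g), 2)
  g[3:7, 3:5] <- NaN # 15 of 25
  expect_error(central_roi_mean(g), "20%")
})

test_that("ROI values may be permuted without changing the mean", {
  set.seed(8)
  g <- matrix(rnorm(81), 9, 9)
  g2 <- g
  g2[3:7, 3:7] <- matrix(sample(as.vector(g[3:7, 3:7])), 5, 5)
  expect_equal(central_roi_mean(g), central_roi_mean(g2), tolerance = 1e-12)
})

test_that("default protocol windows are (30,60], (270,300], (510,540]", {
  w <- period_windows(protocol_spec())
  expect_equal(w$start, c(30, 60))
  expect_equal(w$elev, c(270, 300))
  expect_equal(w$phys, c(510, 540))
  # enumeration of 4-min frames inside (270, 300]
  frames <- seq(0, 540, by = 4)
  inw <- frames[frames > 270 & frames <= 300]
  expect_equal(inw, c(272, 276, 280, 284, 288, 292, 296, 300))
  expect_length(inw, 8)
  expect_error(period_windows(protocol_spec(acclimation_min = 28,
                                            frame_interval_min = 4)),
               "shorter")
})

test_that("features are window means, immune to frames outside the windows", {
  prot <- protocol_spec()
  times <- frame_times(prot)
  base <- data.frame(t_min = times, iop_mmHg = protocol_iop(prot, times),
                     slope_ps = -2)
  class(base) <- c("slope_series", "data.frame")
  fv <- extract_features(base, prot)
  expect_equal(unname(fv), c(-2, -2, -2))

  # series equal to the frame index: each S_* is the mean of enumerated indices
  idx_series <- base
  idx_series$slope_ps <- seq_along(times) - 1
  fv2 <- extract_features(idx_series, prot)
  oracle <- vapply(list(c(30, 60), c(270, 300), c(510, 540)), function(w)
    mean(which(times > w[1] & times <= w[2]) - 1), numeric(1))
  expect_equal(unname(fv2), oracle)

  # perturbing out-of-window frames changes nothing
  pert <- idx_series
  outside <- !(times > 30 & times <= 60) & !(times > 270 & times <= 300) &
    !(times > 510 & times <= 540)
  pert$slope_ps[outside] <- 1e6
  expect_equal(extract_features(pert, prot), fv2)
})

test_that("empty analysis windows are reported", {
  prot <- protocol_spec()
  s <- data.frame(t_min = c(0, 4, 8), iop_mmHg = 15, slope_ps = -1)
  expect_error(extract_features(s, prot), "window")
})

test_that("slope_series collapses a per-pixel table to ROI means per frame", {
  co <- test_cohort(n = 1, seed = 4)
  st <- process_cohort(co)
  ss <- slope_series(st)
  expect_equal(nrow(ss), length(co$frame_times))
  expect_true(all(diff(ss$t_min) > 0))
  # grid is 3x3 in the test config: ROI covers the full grid
  first <- st[st$t_min == 0, ]
  expect_equal(ss$slope_ps[1], mean(first$slope_ps))
})
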