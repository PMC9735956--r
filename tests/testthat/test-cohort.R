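# Synthetic cohort generation: structure, determinism, physics consistency.

test_that("the default design yields 19 samples in groups of 7/6/6", {
  cfg <- default_config()
  expect_equal(unname(cfg$cohort$group_sizes), c(7L, 6L, 6L))
  co <- test_cohort(n = 3, seed = 1)
  expect_equal(nrow(co$samples), 3)
  expect_error(generate_cohort(group_sizes = c(7, 6, 6),
                               protocol = test_protocol(),
                               config = test_config()),
               "named")
})

test_that("cohort generation is bit-deterministic in the master seed", {
  a <- test_cohort(n = 2, seed = 5)
  b <- test_cohort(n = 2, seed = 5)
  d <- test_cohort(n = 2, seed = 6)
  expect_identical(a$samples, b$samples)
  expect_identical(a$hydration, b$hydration)
  expect_identical(synthesize_frame(a, 1, 3), synthesize_frame(b, 1, 3))
  expect_false(identical(a$samples$ecd_cells_per_mm2,
                         d$samples$ecd_cells_per_mm2))
  expect_false(identical(synthesize_frame(a, 1, 3), synthesize_frame(d, 1, 3)))
})

test_that("a perfectly pumping sample with no influx is static up to noise", {
  cfg <- test_config()
  cfg$hydration$k_in <- 0
  cfg$cohort$noise_sd <- 0
  co <- test_cohort(n = 1, seed = 9, config = cfg)
  co$samples$pump[1] <- 1
  expect_identical(synthesize_frame(co, 1, 1), synthesize_frame(co, 1, 10))
})

test_that("ECD mixture separates intact and damaged modes around 3000", {
  set.seed(31)
  mix <- draw_ecd(400)
  expect_gt(min(mix$ecd[mix$component == "intact"]), 3000)
  expect_lt(max(mix$ecd[mix$component == "damaged"]), 3000)
})

test_that("generated damaged samples show larger elevated-period slopes than intact", {
  # 50-sample cohort; S_Elev taken at the model level (band slope of |r(f)|
  # at the end-of-elevation hydration state), one-sided rank test
  cfg <- test_config()
  prot <- protocol_spec(elevated_iop = 45)
  co <- generate_cohort(group_sizes = c(`45` = 50L), protocol = prot,
                        config = cfg, seed = 17)
  times <- frame_times(prot)
  k_end <- max(which(times <= 300))
  s_elev <- vapply(seq_len(50), function(i) model_band_slope(co, i, k_end),
                   numeric(1))
  lab <- label_from_ecd(co$samples$ecd_cells_per_mm2)
  expect_gt(min(table(lab)), 5)
  wt <- wilcox.test(abs(s_elev)[lab == "damaged"], abs(s_elev)[lab == "intact"],
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("noiseless pipeline slopes match the model slope within 1 percent", {
  cfg <- test_config()
  cfg$cohort$noise_sd <- 0
  cfg$reference$n <- 2048L
  co <- test_cohort(n = 1, seed = 13, config = cfg)
  k <- length(co$frame_times) # end of recovery; hydrated state
  tr <- synthesize_frame(co, 1, k)
  pipe <- thzcornea:::frame_slopes(tr, co$reference)[1]
  model <- model_band_slope(co, 1, k)
  expect_lt(abs(pipe - model), 0.01 * abs(model))
})

test_that("noiseless damaged samples swell: |S_Elev| exceeds |S_Start|", {
  cfg <- test_config()
  cfg$cohort$noise_sd <- 0
  co <- test_cohort(n = 6, seed = 23, config = cfg)
  damaged <- which(co$samples$ecd_cells_per_mm2 <= 3000)
  expect_gt(length(damaged), 0)
  st <- process_cohort(co)
  ft <- feature_table(st, co)
  expect_true(all(abs(ft$S_Elev_ps[damaged]) > abs(ft$S_Start_ps[damaged])))
})
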