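test_that("activity normalisation reproduces the reference dose rates", {
  g <- cell_geometry()
  a_w <- total_activity(activity_scenario(c_rn = 1000, porosity = 100,
                                          geometry = g))
  expect_equal(dose_rate(11.2e4, 1e8, a_w[["rn222"]]), 2.8,
               tolerance = 0.02)
  a_d <- total_activity(activity_scenario(c_ra = 30, porosity = 0,
                                          geometry = g))
  expect_equal(dose_rate(10.3e4, 1e8, a_d[["ra226"]]), 92.4,
               tolerance = 0.02)
  expect_equal(dose_rate(5e4, 1e8, 0), 0)
  expect_error(dose_rate(1, 0, 1), "n_primaries")
})

test_that("dose rate is exactly linear in activity", {
  set.seed(5)
  a <- runif(20, 0, 1e-5)
  k <- runif(1, 0.5, 5)
  expect_equal(dose_rate(7e4, 1e8, k * a), k * dose_rate(7e4, 1e8, a),
               tolerance = 1e-12)
})

test_that("combining nuclides applies the ERICA screen", {
  both <- data.frame(nuclide = c("ra226", "rn222"),
                     dose_rate = c(8.3, 2.5), configuration = "benthic")
  r <- combine_dose_rates(both)
  expect_equal(r$total, 10.8)
  expect_true(r$exceeds_erica_threshold)
  frust <- data.frame(nuclide = c("ra226", "rn222"),
                      dose_rate = c(7.4, 2.3), configuration = "benthic-frustule")
  r2 <- combine_dose_rates(frust)
  expect_equal(r2$total, 9.7)
  expect_false(r2$exceeds_erica_threshold)
  zero <- combine_dose_rates(data.frame(nuclide = "rn222", dose_rate = 0))
  expect_equal(zero$total, 0)
  expect_false(zero$exceeds_erica_threshold)
  mixed <- data.frame(nuclide = c("a", "b"), dose_rate = c(1, 2),
                      configuration = c("x", "y"))
  expect_error(combine_dose_rates(mixed), "different configurations")
})

test_that("percent changes match the reported frustule and nuclide contrasts", {
  expect_equal(percent_change(10.8, 9.7), 10.185, tolerance = 1e-3)
  expect_equal(percent_change(7.3e4, 9.2e4, mode = "excess"), 26.03,
               tolerance = 1e-3)
  expect_equal(percent_change(3.7, 3.7), 0)
  expect_error(percent_change(0, 1), "positive")
})

test_that("linear rescaling to measured activities recovers spring 5", {
  ref <- c(rn222 = 2.3, ra226 = 7.4)
  expect_equal(scale_to_measured(ref, c(c_rn = 4594, c_ra = 31.4)), 18.3,
               tolerance = 0.002)
  # identity at the reference activities
  expect_equal(scale_to_measured(ref, c(c_rn = 1000, c_ra = 30)), 9.7)
  # linearity oracle on an arbitrary spring
  expect_equal(scale_to_measured(ref, c(c_rn = 13.7, c_ra = 30.8)),
               2.3 * 13.7 / 1000 + 7.4 * 30.8 / 30, tolerance = 1e-12)
})

test_that("dose_rate_table normalises simulated doses by scenario activity", {
  g <- cell_geometry()
  scn <- activity_scenario(c_rn = 1000, porosity = 100, geometry = g)
  m <- run_microdose(scn, 2e4, seed = 3)
  tab <- dose_rate_table(m)
  expect_equal(tab$nuclide, "rn222")
  expect_equal(tab$dose_rate,
               dose_rate(tab$absolute_dose_gy, tab$n_primaries,
                         tab$activity_bq))
})
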