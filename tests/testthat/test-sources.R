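test_that("built-in spectra carry the evaluated lines and sum to 100%", {
  sp <- builtin_spectra()
  expect_equal(sp$rn222$lines$energy[3], 5.490)
  expect_equal(sp$rn222$lines$intensity[3], 99.92)
  expect_equal(sp$ra226$lines$energy[5], 4.784)
  expect_equal(sp$ra226$lines$intensity[5], 93.84)
  expect_equal(nrow(sp$rn222$lines), 3)
  expect_equal(nrow(sp$ra226$lines), 5)
  for (s in sp) {
    expect_lt(abs(sum(s$lines$intensity) - 100), 0.1)
  }
})

test_that("spectrum construction enforces one alpha per decay", {
  expect_error(alpha_spectrum("X", c(4, 5), c(50, 30)), "sum")
  expect_error(alpha_spectrum("X", c(4, -5), c(50, 50)), "positive")
  expect_error(sample_decay(list(lines = NULL)), "empty")
})

test_that("custom spectra round-trip through the two-column text format", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# MeV  percent", "4.826 5.0e-4", "4.986 0.078",
               "5.490 99.92"), f)
  sp <- read_spectrum(f, "Rn-222")
  expect_equal(sp$lines$energy, builtin_spectra()$rn222$lines$energy)
  expect_equal(sp$lines$intensity, builtin_spectra()$rn222$lines$intensity)
})

test_that("decay sampling follows the line intensities", {
  single <- alpha_spectrum("mono", 5.0, 100)
  expect_equal(sample_decay(single, 5), rep(5.0, 5))
  set.seed(42)
  n <- 2e4
  e <- sample_decay(builtin_spectra()$rn222, n)
  p <- 0.9992
  expect_lt(abs(mean(e == 5.490) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("emission points are uniform in the source shell, directions isotropic", {
  g <- cell_geometry()
  set.seed(7)
  n <- 4e4
  em <- sample_emission(g, n)
  d <- sqrt(rowSums(em$position^2))
  expect_true(all(d > g$r_outer & d <= g$r_env))
  expect_equal(rowSums(em$direction^2), rep(1, n), tolerance = 1e-12)
  expect_true(all(em$weight == 1))
  # isotropy: each mean direction component within 3 sigma of zero
  expect_true(all(abs(colMeans(em$direction)) < 3 / sqrt(3 * n)))
  # uniform-in-volume radial law via Kolmogorov-Smirnov at alpha = 0.01
  cdf <- function(r) (r^3 - g$r_outer^3) / (g$r_env^3 - g$r_outer^3)
  ks <- suppressWarnings(ks.test(cdf(d), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("nucleus-aimed emissions stay in the cone and carry its weight", {
  g <- cell_geometry()
  set.seed(8)
  em <- sample_emission(g, 2000, toward_nucleus = TRUE)
  d <- sqrt(rowSums(em$position^2))
  b <- rowSums(em$position * em$direction)
  miss <- sqrt(pmax(rowSums(em$position^2) - b^2, 0))
  expect_true(all(miss <= g$r_nucleus + 1e-9))
  expect_true(all(b < 0))  # aimed inward
  expect_equal(em$weight, (1 - sqrt(1 - (g$r_nucleus / d)^2)) / 2,
               tolerance = 1e-12)
})

test_that("total activity matches the sphere-minus-sphere bookkeeping", {
  g <- cell_geometry()
  v_l <- (4 / 3) * pi * (g$r_env^3 - g$r_outer^3) * 1e-15
  water <- activity_scenario(c_rn = 1000, porosity = 100, geometry = g)
  expect_equal(total_activity(water)[["rn222"]], 1000 * v_l,
               tolerance = 1e-12)
  expect_equal(total_activity(water)[["rn222"]], 6.93e-7, tolerance = 0.01)
  dry <- activity_scenario(c_ra = 30, porosity = 0, geometry = g)
  expect_equal(total_activity(dry)[["ra226"]], 30 * 1.2 * v_l * 1e3,
               tolerance = 1e-12)
  expect_equal(total_activity(dry)[["ra226"]], 2.49e-5, tolerance = 0.01)
  none <- activity_scenario(0, 0, porosity = 50, geometry = g)
  expect_equal(unname(total_activity(none)), c(0, 0))
})

test_that("activity is linear in concentration and respects phase exclusivity", {
  g <- cell_geometry()
  a1 <- total_activity(activity_scenario(c_rn = 250, c_ra = 10,
                                         porosity = 90, geometry = g))
  a2 <- total_activity(activity_scenario(c_rn = 750, c_ra = 30,
                                         porosity = 90, geometry = g))
  expect_equal(3 * a1, a2, tolerance = 1e-12)
  # porosity 0: Ra only; porosity 100: Rn only
  expect_error(activity_scenario(c_rn = 1, porosity = 0), "water")
  expect_error(activity_scenario(c_ra = 1, porosity = 100), "sediment")
  d <- total_activity(activity_scenario(c_ra = 30, porosity = 0, geometry = g))
  expect_equal(d[["rn222"]], 0)
  w <- total_activity(activity_scenario(c_rn = 1000, porosity = 100,
                                        geometry = g))
  expect_equal(w[["ra226"]], 0)
})
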