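test_that("nucleosome targets fit inside the nucleus at the right packing", {
  set.seed(1)
  tg <- place_nucleosomes(30000)
  expect_equal(tg$n, 30000)
  expect_true(all(sqrt(rowSums(tg$center^2)) + tg$half_diag <= 500 + 1e-9))
  expect_equal(rowSums(tg$axis^2), rep(1, tg$n), tolerance = 1e-12)
  vol_frac <- tg$n * pi * tg$radius^2 * tg$height / ((4 / 3) * pi * 500^3)
  expect_equal(vol_frac, 0.0225, tolerance = 0.001)
  single <- place_nucleosomes(1)
  expect_equal(nrow(single$center), 1)
  expect_error(place_nucleosomes(1, nucleus_radius = 4), "fit")
})

test_that("specific energy converts eV to Gy through the cylinder mass", {
  expect_equal(specific_energy(1), 408, tolerance = 0.001)
  expect_equal(specific_energy(0), 0)
  expect_equal(specific_energy(100), 4.08e4, tolerance = 0.001)
  expect_equal(specific_energy(c(2, 4)), 2 * specific_energy(c(1, 2)))
  expect_error(specific_energy(-1), ">= 0")
})

test_that("transfer points are empty for degenerate tracks", {
  expect_equal(nrow(generate_transfer_points(2.0, c(0, 0, 0), c(0, 0, 1), 0)),
               0)
  expect_equal(nrow(generate_transfer_points(0, c(0, 0, 0), c(0, 0, 1), 500)),
               0)
})

test_that("site energies sum to the CSDA loss and counts are Poisson", {
  ts <- ts_params()
  set.seed(12)
  n <- 2000
  len <- 100  # nm
  e0 <- 2.5
  de_ev <- (e0 - residual_energy(e0, len / 1000)) * 1e6
  counts <- numeric(n); sums <- numeric(n)
  for (i in seq_len(n)) {
    p <- generate_transfer_points(e0, c(0, 0, 0), c(0, 0, 1), len, ts)
    counts[i] <- nrow(p)
    sums[i] <- sum(p$energy_ev)
  }
  expect_lt(abs(mean(sums) / de_ev - 1), 0.05)
  # dispersion index of a Poisson count is 1
  disp <- var(counts) / mean(counts)
  expect_lt(abs(disp - 1), 3 * sqrt(2 / (n - 1)))
})

test_that("electron sites are displaced off the track core, alpha sites are not", {
  ts <- ts_params(electron_fraction = 0.5, displacement_mean = 2)
  set.seed(13)
  p <- generate_transfer_points(3, c(0, 0, 0), c(0, 0, 1), 800, ts)
  off <- sqrt(p$x^2 + p$y^2)
  is_el <- grepl("^electron", p$process)
  expect_true(all(off[!is_el] < 1e-9))
  expect_true(all(off[is_el] > 0))
  expect_equal(mean(is_el), 0.5, tolerance = 0.1)
  # isotropic exponential displacement: mean perpendicular offset is
  # E[disp] * E[sin(theta)] = displacement_mean * pi/4
  expect_equal(mean(off[is_el]), 2 * pi / 4, tolerance = 0.15)
})

test_that("process attribution picks the largest contribution with a fixed tie-break", {
  expect_equal(attribute_process(30, "electron-solvation"),
               "electron-solvation")
  expect_equal(attribute_process(c(30, 10),
                                 c("alpha-ionisation", "electron-ionisation")),
               "alpha-ionisation")
  expect_equal(attribute_process(c(10, 30, 5),
                                 c("alpha-excitation", "electron-ionisation",
                                   "electron-solvation")),
               "electron-ionisation")
  # exact tie: first label in the fixed process order wins
  expect_equal(attribute_process(c(20, 20),
                                 c("electron-solvation", "alpha-excitation")),
               "alpha-excitation")
  expect_true(is.na(attribute_process(numeric(0), character(0))))
})

test_that("mean specific energy over uniform targets equals the nucleus dose", {
  g <- cell_geometry()
  phsp <- monoenergetic_phase_space(3, 150, g)
  nano <- run_nanodose(phsp, g, n_primaries = 150, n_targets = 20000,
                       seed = 14)
  # uniformly placed targets sample the dose: the two estimators agree
  expect_equal(nano$mean_z_per_primary, nano$nucleus_dose_per_primary,
               tolerance = 0.1)
  expect_gt(nrow(nano$events), 0)
})

test_that("per-process sub-spectra sum to the total spectrum", {
  g <- cell_geometry()
  set.seed(15)
  phsp <- monoenergetic_phase_space(2.5, 80, g)
  nano <- run_nanodose(phsp, g, n_primaries = 80, n_targets = 10000, seed = 16)
  sp <- se_spectrum(nano, n_bins = 25)
  tot <- sp[sp$process == "total", ]
  expect_equal(sum(tot$probability), 1, tolerance = 1e-12)
  parts <- sp[sp$process != "total", ]
  by_bin <- tapply(parts$probability, parts$z_gy, sum)
  expect_equal(as.numeric(by_bin[as.character(tot$z_gy)]), tot$probability,
               tolerance = 1e-12)
})

test_that("specific-energy rates are linear in activity", {
  g <- cell_geometry()
  phsp <- monoenergetic_phase_space(2.5, 40, g)
  nano <- run_nanodose(phsp, g, n_primaries = 40, n_targets = 5000, seed = 17)
  expect_equal(se_rate(nano, 2e-6), 2 * se_rate(nano, 1e-6))
  expect_equal(se_rate(nano, 0), 0)
})

test_that("monoenergetic chords start on the nucleus sphere pointing inward", {
  g <- cell_geometry()
  set.seed(18)
  ph <- monoenergetic_phase_space(4, 500, g)
  r <- sqrt(ph$x_um^2 + ph$y_um^2 + ph$z_um^2)
  expect_equal(r, rep(g$r_nucleus, 500), tolerance = 1e-12)
  b <- ph$x_um * ph$dx + ph$y_um * ph$dy + ph$z_um * ph$dz
  expect_true(all(b < 0))
  # uniform-chord law: mean chord of a sphere is 4R/3
  chord <- -2 * b
  expect_equal(mean(chord), 4 * g$r_nucleus / 3, tolerance = 0.05)
})
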