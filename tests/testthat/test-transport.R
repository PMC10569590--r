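test_that("energy is conserved track by track in layered geometries", {
  for (frustule in c(0, 2)) {
    g <- cell_geometry(frustule_thickness = frustule,
                       environment_material = mixture_material(90))
    set.seed(11 + frustule)
    n <- 2e4
    e0 <- sample_decay(builtin_spectra()$rn222, n)
    em <- sample_emission(g, n)
    tr <- trace_alpha(e0, em$position, em$direction, g)
    total <- tr$dep_environment + tr$dep_frustule + tr$dep_microorganism
    expect_lt(max(abs(total / e0 - 1)), 1e-6)
    expect_true(all(tr$dep_nucleus <= tr$dep_microorganism + 1e-12))
    if (frustule == 0) expect_true(all(tr$dep_frustule == 0))
  }
})

test_that("tracks pointing away or out of range never reach the diatom", {
  g <- cell_geometry()
  away <- trace_alpha(5.49, c(0, 0, 20), c(0, 0, 1), g)
  expect_equal(away$dep_microorganism, 0)
  expect_false(away$entered_microorganism)
  # emission farther than the range from the surface: no crossing possible
  d <- 10 + csda_range(5.49) + 0.5
  toward <- trace_alpha(5.49, c(0, 0, d), c(0, 0, -1), g)
  expect_false(toward$entered_microorganism)
  expect_error(trace_alpha(5.49, c(0, 0, 5), c(0, 0, 1), g), "outside")
})

test_that("monoenergetic entry fractions match the solid-angle quadrature oracle", {
  g <- cell_geometry()
  set.seed(21)
  n <- 2e5
  for (e in c(5.490, 4.784)) {
    em <- sample_emission(g, n)
    tr <- trace_alpha(rep(e, n), em$position, em$direction, g)
    f_sim <- mean(tr$entered_microorganism)
    f_oracle <- entry_fraction_quadrature(g, e)
    expect_lt(abs(f_sim - f_oracle),
              3 * sqrt(f_oracle * (1 - f_oracle) / n))
  }
})

test_that("the quadrature oracle also predicts the nucleus-aimed weighted fraction", {
  g <- cell_geometry()
  set.seed(22)
  n <- 3e4
  em <- sample_emission(g, n, toward_nucleus = TRUE)
  tr <- trace_alpha(rep(5.49, n), em$position, em$direction, g)
  f_sim <- sum(em$weight * tr$entered_nucleus) / n
  f_oracle <- entry_fraction_quadrature(g, 5.49, target = "nucleus")
  expect_lt(abs(f_sim / f_oracle - 1), 0.05)
})

test_that("run_microdose is reproducible and scores sensible entry energies", {
  g <- cell_geometry(environment_material = mixture_material(90))
  scn <- activity_scenario(c_rn = 1000, c_ra = 30, porosity = 90,
                           geometry = g)
  m1 <- run_microdose(scn, 4e4, seed = 31)
  m2 <- run_microdose(scn, 4e4, seed = 31)
  expect_equal(m1$per_nuclide$rn222$dose_gy, m2$per_nuclide$rn222$dose_gy)
  expect_equal(m1$per_nuclide$ra226$mean_entry_energy,
               m2$per_nuclide$ra226$mean_entry_energy)
  r <- m1$per_nuclide$rn222
  expect_lt(r$max_entry_energy, 5.4901)
  expect_gt(r$mean_entry_energy, r$max_entry_energy / 2)
  expect_gt(m1$per_nuclide$rn222$mean_entry_energy,
            m1$per_nuclide$ra226$mean_entry_energy)
})

test_that("the frustule lowers both entrant counts and entry energies", {
  cfg <- default_config()
  scn0 <- scenario_from_config(cfg, "benthic_mixture")
  scn2 <- scenario_from_config(cfg, "benthic_mixture_frustule")
  m0 <- run_microdose(scn0, 1.5e5, seed = 33,
                      keep_microorganism_phase_space = FALSE)
  m2 <- run_microdose(scn2, 1.5e5, seed = 33,
                      keep_microorganism_phase_space = FALSE)
  for (nuc in c("rn222", "ra226")) {
    expect_lt(m2$per_nuclide[[nuc]]$mean_entry_energy,
              m0$per_nuclide[[nuc]]$mean_entry_energy)
    expect_lt(m2$per_nuclide[[nuc]]$fraction_entering_microorganism,
              m0$per_nuclide[[nuc]]$fraction_entering_microorganism)
  }
  # entry energies in the printed range: Rn ~3.3 (2.9 with frustule)
  expect_equal(m0$per_nuclide$rn222$mean_entry_energy, 3.3, tolerance = 0.2 / 3.3)
  expect_equal(m2$per_nuclide$rn222$mean_entry_energy, 2.9, tolerance = 0.2 / 2.9)
  expect_equal(m0$per_nuclide$ra226$mean_entry_energy, 2.8, tolerance = 0.2 / 2.8)
  expect_equal(m2$per_nuclide$ra226$mean_entry_energy, 2.5, tolerance = 0.2 / 2.5)
})

test_that("phase spaces sit on their surfaces and round-trip through CSV", {
  g <- cell_geometry()
  scn <- activity_scenario(c_rn = 1000, porosity = 100, geometry = g)
  m <- run_microdose(scn, 3e4, seed = 35)
  ph <- m$per_nuclide$rn222$phase_space_microorganism
  expect_gt(nrow(ph), 0)
  r <- sqrt(ph$x_um^2 + ph$y_um^2 + ph$z_um^2)
  expect_equal(r, rep(g$r_microorganism, nrow(ph)), tolerance = 1e-9)
  expect_true(all(ph$E_MeV > 0 & ph$E_MeV <= 5.49))
  f <- withr::local_tempfile(fileext = ".csv")
  write_phase_space(ph, f)
  expect_identical(readLines(f, n = 1),
                   "particle,E_MeV,x_um,y_um,z_um,dx,dy,dz,surface,nuclide,primary_id,weight")
  back <- read_phase_space(f)
  expect_equal(back$E_MeV, ph$E_MeV, tolerance = 1e-12)
  expect_equal(back$surface, ph$surface)
})
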