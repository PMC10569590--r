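test_that("the SSB damage ramp is exact at its knots", {
  expect_equal(ssb_probability(5), 0)
  expect_equal(ssb_probability(37.5), 1)
  expect_equal(ssb_probability(21.25), 0.5)
  expect_equal(ssb_probability(0), 0)
  expect_equal(ssb_probability(500), 1)
  # linear in between
  e <- seq(5, 37.5, length.out = 14)
  expect_equal(ssb_probability(e), (e - 5) / 32.5, tolerance = 1e-12)
  expect_error(ssb_probability(-1), ">= 0")
})

test_that("SSB selection is binomial with probability s * ramp", {
  pts <- data.frame(x = 0, y = 0, z = 0, energy_ev = rep(50, 1e4))
  expect_equal(nrow(select_ssb_points(pts, dbscan_params(s_point_prob = 0))),
               0)
  expect_equal(nrow(select_ssb_points(pts, dbscan_params(s_point_prob = 1))),
               1e4)
  set.seed(61)
  n <- nrow(select_ssb_points(pts, dbscan_params(s_point_prob = 0.08)))
  expect_lt(abs(n - 800), 3 * sqrt(1e4 * 0.08 * 0.92))
})

test_that("expected SSB count is linear in the sensitive-point probability", {
  pts <- data.frame(x = 0, y = 0, z = 0,
                    energy_ev = rexp(2e4, 1 / 100))
  set.seed(62)
  n1 <- nrow(select_ssb_points(pts, dbscan_params(s_point_prob = 0.08)))
  n2 <- nrow(select_ssb_points(pts, dbscan_params(s_point_prob = 0.16)))
  se <- 3 * sqrt(n1 + n2 / 2)
  expect_lt(abs(n2 - 2 * n1), 2 * se)
})

test_that("two SSBs within 3.3 nm form one DSB, farther apart none", {
  close_pair <- rbind(c(0, 0, 0), c(0, 0, 2))
  lab <- dbscan_cluster(close_pair, eps = 3.3)
  expect_equal(lab, c(1, 1))
  expect_equal(count_dsb(lab), 1)
  far_pair <- rbind(c(0, 0, 0), c(0, 0, 4))
  lab2 <- dbscan_cluster(far_pair, eps = 3.3)
  expect_equal(lab2, c(0, 0))
  expect_equal(count_dsb(lab2), 0)
  # chain reachability: consecutive 3 nm steps merge into one cluster
  chain <- cbind(0, 0, seq(0, 12, by = 3))
  expect_equal(count_dsb(dbscan_cluster(chain, 3.3)), 1)
})

test_that("DBSCAN matches the brute-force reachability oracle on random instances", {
  set.seed(63)
  for (i in 1:100) {
    n <- sample(5:120, 1)
    x <- matrix(runif(3 * n, 0, 30), ncol = 3)
    eps <- runif(1, 1, 6)
    expect_true(same_partition(dbscan_cluster(x, eps),
                               brute_force_dbscan(x, eps)))
  }
  # with a stricter core condition (min_pts > 2) a border point adjacent to
  # two clusters may validly join either; compare the core-point partition
  # exactly and require every border assignment to name a core neighbour
  for (i in 1:20) {
    n <- sample(10:80, 1)
    x <- matrix(runif(3 * n, 0, 15), ncol = 3)
    a <- dbscan_cluster(x, 3, min_pts = 4)
    b <- brute_force_dbscan(x, 3, min_pts = 4)
    nb <- as.matrix(dist(x))^2 <= 9
    core <- rowSums(nb) >= 4
    expect_true(same_partition(ifelse(core, a, 0L), ifelse(core, b, 0L)))
    expect_identical(a == 0, b == 0)
    for (j in which(!core & a != 0)) {
      expect_true(a[j] %in% a[core & nb[j, ]])
    }
  }
})

test_that("yield normalisation is a pure ratio and rejects zero dose", {
  expect_equal(yields_per_gy_mbp(270, 10, 27), 1)
  expect_equal(yields_per_gy_mbp(0, 5), 0)
  expect_error(yields_per_gy_mbp(1, 0), "positive")
  # invariant under run length: doubling counts and dose together
  expect_equal(yields_per_gy_mbp(34, 7.3), yields_per_gy_mbp(68, 14.6))
})

test_that("per-day normalisation combines per-nuclide yields and dose rates", {
  expect_equal(per_day(c(rn222 = 0.08), c(rn222 = 2.8)),
               0.08 * 2.8 * 24e-6 * 27)
  expect_equal(per_day(c(rn222 = 0.08), c(rn222 = 2.8)), 1.48e-4,
               tolerance = 0.03)
  expect_equal(per_day(c(ra226 = 0.02), c(ra226 = 92.4)), 1.06e-3,
               tolerance = 0.15)
  expect_equal(per_day(c(rn222 = 0.1, ra226 = 0.2),
                       c(ra226 = 5, rn222 = 1)),
               (0.1 * 1 + 0.2 * 5) * 24e-6 * 27)
  expect_equal(per_day(c(rn222 = 0.08), c(rn222 = 0)), 0)
  expect_error(per_day(c(0.08), c(rn222 = 2.8)), "names")
})

test_that("the sensitive-point sweep is strictly ordered and superlinear for DSBs", {
  sw <- spointprob_sweep(energies = c(2, 6), n_tracks = 50, seed = 64)
  for (e in unique(sw$energy)) {
    sub <- sw[sw$energy == e, ]
    sub <- sub[order(sub$s_point_prob), ]
    expect_true(all(diff(sub$dsb_per_gy_mbp) > 0))
    expect_true(all(diff(sub$ssb_per_gy_mbp) > 0))
    # SSBs linear in s (common random numbers make this tight)
    expect_equal(sub$ssb_per_gy_mbp[3] / sub$ssb_per_gy_mbp[1], 2,
                 tolerance = 0.05)
    # DSB growth is superlinear at these densities
    expect_gt(sub$dsb_per_gy_mbp[4] / sub$dsb_per_gy_mbp[1], 2.5)
  }
})
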