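test_that("logistic increment evaluates the growth law and guards its domain", {
  expect_equal(logistic_increment(0, 0.7), 0)
  expect_equal(logistic_increment(100, 5), 0)
  expect_equal(logistic_increment(50, 0.4), 10)
  # vectorized, never negative on the valid domain
  x <- seq(0, 100, by = 0.5)
  expect_true(all(logistic_increment(x, 0.9) >= 0))
  expect_error(logistic_increment(-1, 0.4), "within")
  expect_error(logistic_increment(101, 0.4), "within")
  expect_error(logistic_increment(50, -0.1), ">= 0")
})

test_that("kernel cell mass is normalized, decaying, and diffuse in the limit", {
  kp <- kernel_params()  # mu = log(1200), sigma = 1
  # global tiling: 100 m cells to 60 km; sum ~ integral of the radial density
  side <- 100
  ctr <- seq(-6e4 + side / 2, 6e4 - side / 2, by = side)
  g <- expand.grid(x = ctr, y = ctr)
  d <- sqrt(g$x^2 + g$y^2)
  d <- d[d > 0]
  total <- sum(kernel_cell_mass(d, side, kp))
  # oracle: numerical integration of the lognormal radial density
  oracle <- stats::integrate(function(r) dlnorm(r, kp$mu, kp$sigma),
                             0, 6e4)$value
  expect_lt(abs(total - oracle), 0.01)
  expect_lt(abs(total - 1), 0.01)

  expect_lt(kernel_cell_mass(15000, 4927, kp),
            kernel_cell_mass(5000, 4927, kp))
  # diffuse limit: growing sigma spreads mass to nothing anywhere
  masses <- vapply(c(5, 50, 5000), function(s) {
    kernel_cell_mass(5000, 4927, kernel_params(sigma = s))
  }, numeric(1))
  expect_true(all(diff(masses) < 0))
  expect_lt(masses[3], 1e-4)
  expect_error(kernel_cell_mass(0, 4927, kp), "> 0")
  expect_error(kernel_params(sigma = 0), "sigma")
  expect_error(kernel_params(local_fraction = 1.5), "local_fraction")
})

test_that("maturation delay: colonized cells export nothing for 3 years", {
  # source colonized in year 0; recipient invaded so inflow is deterministic
  ls <- make_two_cell(occ1 = 40, colonized1 = 0L)
  ls$cells$occupancy_pct[2] <- 20
  ls$cells$colonized_year[2] <- -3L
  kp <- kernel_params(local_fraction = 0.5)
  state <- spread_state(ls, year = 0L)
  # recipient is mature, so it retains local_fraction of its own increment;
  # with no inflow its trajectory is the damped map below
  damped <- numeric(5); damped[1] <- 20
  for (t in 1:4) {
    damped[t + 1] <- damped[t] +
      kp$local_fraction * 0.4 * damped[t] * (1 - damped[t] / 100)
  }
  for (step in 1:4) {
    state <- step_year(state, ls, kp)
    if (step <= 2) {
      # years 1, 2: the year-0 colonist exports nothing
      expect_equal(state$occupancy[2], damped[step + 1])
    }
  }
  # year 3 onward the source (age 3) exports: recipient is ahead of the map
  expect_gt(state$occupancy[2], damped[5])
})

test_that("dispersal-off equivalence: local_fraction = 1 is the logistic map", {
  set.seed(11)
  n <- 30
  occ0 <- ifelse(runif(n) < 0.4, runif(n, 0, 100), 0)
  ls <- make_grid_landscape(5, 6, r = round(runif(n), 3), occupancy = occ0)
  ls <- build_neighbor_index(ls, 30000)
  kp <- kernel_params(local_fraction = 1)
  state <- spread_state(ls)
  for (t in 1:10) state <- step_year(state, ls, kp)
  expected <- occ0
  for (t in 1:10) {
    expected <- expected + ls$cells$max_spread_rate * expected *
      (1 - expected / 100)
  }
  expect_identical(state$occupancy, expected)
})

test_that("occupancy stays bounded and nothing appears from nothing", {
  set.seed(99)
  kp <- kernel_params(local_fraction = 0.7)
  # 10 random landscapes x 20 years x 5 cells each: > 1,000 cell-steps
  for (rep in 1:10) {
    occ0 <- ifelse(runif(25) < 0.5, runif(25, 0, 100), 0)
    ls <- make_grid_landscape(5, 5, r = runif(25, 0, 2), occupancy = occ0,
                              forested = runif(25) < 0.9 | occ0 > 0)
    ls$cells$occupancy_pct[!ls$cells$forested] <- 0
    ls <- landscape(ls$cells)  # revalidate after masking
    ls <- build_neighbor_index(ls, 15000)
    state <- spread_state(ls)
    for (t in 1:20) {
      state <- step_year(state, ls, kp)
      expect_true(all(state$occupancy >= 0 & state$occupancy <= 100))
      expect_true(all(state$occupancy[!ls$cells$forested] == 0))
    }
  }
  # no spontaneous generation: an empty landscape stays empty forever
  ls0 <- build_neighbor_index(make_grid_landscape(4, 4, occupancy = 0), 30000)
  state <- spread_state(ls0)
  for (t in 1:50) state <- step_year(state, ls0, kp)
  expect_identical(state$occupancy, rep(0, 16))
})

test_that("identical seeds give identical trajectories", {
  ls <- paper_like_landscape()
  cfg <- run_config(years = 8, replicates = 1, seed = 5,
                    snapshot_years = NULL)
  t1 <- run_replicate(ls, cfg, seed = 123)
  t2 <- run_replicate(ls, cfg, seed = 123)
  expect_identical(t1, t2)
  t3 <- run_replicate(ls, cfg, seed = 124)
  expect_false(identical(t1$invaded_ha, t3$invaded_ha))
})

test_that("colonization frequency matches the exact binomial probability", {
  ls <- make_two_cell(occ1 = 50)
  kp <- kernel_params()
  # exact oracle: exported increment times kernel mass, clamped
  export1 <- (1 - kp$local_fraction) * logistic_increment(50, 0.4)
  p12 <- min(1, export1 * kernel_cell_mass(4927, sqrt(2428 * 1e4), kp))
  W <- kernel_matrix(ls, kp)
  n <- 10000
  hits <- 0L
  state0 <- spread_state(ls)
  for (i in seq_len(n)) {
    set.seed(derive_seed(314159, i))
    s <- step_year(state0, ls, kp, W = W)
    if (s$occupancy[2] > 0) hits <- hits + 1L
  }
  se <- sqrt(p12 * (1 - p12) / n)
  expect_lt(abs(hits / n - p12), 3 * se)
})

test_that("invasion front advances monotonically, faster for longer kernels", {
  # homogeneous 1-row lattice, leftmost cell at peak-increment occupancy
  n_cells <- 60; years <- 20; reps <- 50
  ls <- make_grid_landscape(1, n_cells, r = 0.6,
                            occupancy = c(50, rep(0, n_cells - 1)))
  ls <- build_neighbor_index(ls, 30000)
  final_front <- sapply(c(600, 1200, 2400), function(med) {
    kp <- kernel_params(mu = log(med), local_fraction = 0.9)
    W <- kernel_matrix(ls, kp)
    front <- matrix(0, reps, years)
    for (r in seq_len(reps)) {
      state <- spread_state(ls)
      for (t in seq_len(years)) {
        set.seed(derive_seed(med, r, t))
        state <- step_year(state, ls, kp, W = W)
        front[r, t] <- max(which(state$occupancy > 0))
      }
    }
    mean_front <- colMeans(front)
    expect_true(all(diff(mean_front) >= 0))
    mean_front[years]
  })
  expect_true(all(diff(final_front) > 0))
})

test_that("control resets the maturation clock: re-colonized cells wait again", {
  ls <- make_two_cell(occ1 = 40, colonized1 = -3L)
  kp <- kernel_params(local_fraction = 0.5)
  state <- spread_state(ls)
  state$occupancy[2] <- 20; state$colonized_year[2] <- -3L
  ac <- apply_control(state, ls, control_policy("custom", threshold = 10),
                      cost_params())
  state <- ac$state
  expect_equal(state$occupancy, c(0, 0))
  expect_true(all(is.na(state$colonized_year)))
  # re-colonize cell 1 manually at year 5: no export until year 8
  state$occupancy[1] <- 5; state$colonized_year[1] <- 5L
  state$year <- 5L
  pure <- logistic_map(5, 0.4, 3)
  for (step in 1:2) {
    state <- step_year(state, ls, kp)
    expect_equal(state$occupancy[1], pure[step + 1])  # all growth retained
  }
  state <- step_year(state, ls, kp)  # year 8: mature, exports 50% of growth
  expect_lt(state$occupancy[1], pure[4])
})
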