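test_that("weighted market price is the share-weighted stumpage average", {
  # independent oracle: explicit sum over the five embedded classes
  tc <- timber_tables()$timber_classes
  oracle <- sum(tc$share_pct * tc$stumpage_price) / sum(tc$share_pct)
  expect_equal(weighted_market_price(digits = 8), round(oracle, 8))
  expect_equal(oracle, 0.02333756, tolerance = 1e-9)

  # degenerate cases
  tt <- timber_tables()
  tt$timber_classes <- data.frame(class = "only", share_pct = 100,
                                  stumpage_price = 0.019)
  expect_equal(weighted_market_price(tt), 0.019)
  tt$timber_classes <- data.frame(class = c("a", "b"), share_pct = c(50, 50),
                                  stumpage_price = c(0.01, 0.03))
  expect_equal(weighted_market_price(tt), 0.02)
  tt$timber_classes$share_pct <- c(50, 49)
  expect_error(weighted_market_price(tt), "sum to 100")
})

test_that("embedded productivity table carries the seven published constants", {
  expect_equal(unname(timber_tables()$productivity),
               c(5536.98, 4102.30, 2981.45, 2152.03, 1412.27, 739.76, 201.75))
})

test_that("damage cost is linear in invaded area and anchored correctly", {
  expect_equal(damage_cost(0, 5536.98, 0.0234), 0)
  # full occupancy, top productivity class: direct arithmetic
  expect_equal(damage_cost(100, 5536.98, 0.0234, area_ha = 2428),
               2428 * 5536.98 * 0.0234)
  expect_equal(damage_cost(100, 5536.98, 0.0234) / 1000, 314.6,
               tolerance = 1e-3)  # ~ $314.6k/yr
  # halving occupancy halves damage
  occ <- c(80, 40, 20, 10)
  d <- damage_cost(occ, 2152.03, 0.0234)
  expect_equal(d[-1] / d[-4], rep(0.5, 3))
  expect_error(damage_cost(120, 2152.03, 0.0234), "0, 100")
})

test_that("search cost: full-sweep anchor, kink continuity, decay forms", {
  cp <- cost_params()
  expect_equal(search_cost(0.5, cp), 48000)
  expect_equal(search_cost(1, cp), 48000)
  expect_equal(search_cost(50, cp), 960)
  expect_equal(search_cost(2, cp), 24000)
  expect_error(search_cost(0, cp), "> 0")
  grid <- seq(0.1, 100, by = 0.1)
  for (form in c("inverse", "linear", "exponential")) {
    cpf <- cost_params(search_form = form)
    s <- search_cost(grid, cpf)
    expect_true(all(diff(s) <= 0), label = paste(form, "non-increasing"))
    expect_equal(search_cost(1, cpf), 48000)
    # continuity at the kink
    expect_equal(search_cost(1 + 1e-9, cpf), 48000, tolerance = 1e-6)
  }
  # configurable floor
  cpfl <- cost_params(search_floor = 2000)
  expect_equal(search_cost(100, cpfl), 2000)
})

test_that("control curve fit matches the closed-form regression oracle", {
  br <- timber_tables()$control_brackets
  # simple-regression oracle on the log points, no lm
  xb <- mean(br$percent); yb <- mean(log(br$cost_per_ha))
  b_hat <- sum((br$percent - xb) * (log(br$cost_per_ha) - yb)) /
    sum((br$percent - xb)^2)
  a_hat <- exp(yb - b_hat * xb)
  fit <- fit_control_curve(br)
  expect_equal(fit$a, a_hat, tolerance = 1e-10)
  expect_equal(fit$b, b_hat, tolerance = 1e-10)
  expect_equal(fit$a, 107, tolerance = 0.01)
  expect_equal(fit$b, 0.0256, tolerance = 0.01)
  # fitted curve at 1% within the quoted bracket envelope
  at1 <- fit$a * exp(fit$b * 1)
  expect_gt(at1, 111 * 0.8)
  expect_lt(at1, 210 * 1.2)
  # flat two-point calibration
  flat <- fit_control_curve(data.frame(percent = c(0, 100),
                                       cost_per_ha = c(75, 75)))
  expect_equal(flat$a, 75)
  expect_equal(flat$b, 0)
  expect_error(fit_control_curve(data.frame(percent = 1, cost_per_ha = 111)),
               "at least 2")
})

test_that("control cost scales exponentially per hectare on invaded area", {
  cp <- cost_params()
  # bracket extremes reproduced within fit tolerance
  unit <- function(x) cp$control_a * exp(cp$control_b * x)
  expect_equal(unit(100) / unit(1), 1446 / 111, tolerance = 0.05)
  # strictly increasing total cost on a grid
  grid <- seq(0.5, 100, by = 0.5)
  expect_true(all(diff(control_cost(grid, cp)) > 0))
  # area factor dominates the limit
  expect_lt(control_cost(1e-6, cp), 0.01)
  expect_error(control_cost(0, cp), "> 0")
})

test_that("present value matches a brute-force term-by-term oracle", {
  expect_equal(present_value(c(10, 20, 30), 0), 60)
  expect_equal(present_value(c(0, 100), 0.05), 100 / 1.05)
  set.seed(2)
  stream <- runif(20, 0, 1e6)
  brute <- 0
  for (t in 0:19) brute <- brute + stream[t + 1] / (1 + 0.07)^t
  expect_equal(present_value(stream, 0.07), brute, tolerance = 1e-9)
  # monotone: higher rate never increases PV of a nonnegative stream
  rates <- c(0.01, 0.03, 0.05, 0.07, 0.09)
  pvs <- vapply(rates, function(r) present_value(stream, r), numeric(1))
  expect_true(all(diff(pvs) < 0))
  expect_error(present_value(stream, 1), "rate")
})

test_that("ledger identities: components sum exactly, PV recomputable", {
  set.seed(3)
  led <- cost_ledger(6, 0:10)
  led$damage[] <- runif(66, 0, 1e4)
  led$search[] <- runif(66, 0, 1e3)
  led$control[] <- runif(66, 0, 1e5)
  tt <- ledger_totals(led, 0.05)
  expect_equal(tt$damage + tt$search + tt$control, tt$total)
  expect_true(all(tt$total >= 0))
  expect_equal(tt$pv_total, tt$total * tt$discount_factor)
  expect_equal(tt$cum_pv_total[11], present_value(tt$total, 0.05))
  # expected_total_cost over replicate ledgers
  etc <- expected_total_cost(list(led, led), 0.05)
  expect_equal(etc$mean, sum(tt$pv_total))
  expect_equal(etc$se, 0)
  # tidy export round-trips
  f <- withr::local_tempfile(fileext = ".csv")
  write_ledger(led, cell_id = 1:6, rate = 0.05, path = f)
  back <- read.csv(f)
  expect_equal(nrow(back), 66)
  expect_equal(sum(back$damage), sum(led$damage))
  expect_equal(names(back), c("cell_id", "year", "damage", "search",
                              "control", "discount_factor"))
})
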