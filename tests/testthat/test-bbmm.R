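test_that("sigma2_m is recovered from simulated bridges and matches a grid oracle", {
  set.seed(61)
  s2_true <- 0.5
  segs <- lapply(1:60, function(i) make_bb_segment(5, 18000, s2_true))
  s2 <- as.numeric(estimate_sigma2m(segs, delta = 0))
  expect_lt(abs(s2 / s2_true - 1), 0.15)

  # brute-force grid search over sigma2_m using an independent likelihood
  grid <- exp(seq(log(0.05), log(5), length.out = 1500))
  ll <- vapply(grid, function(s) {
    tot <- 0
    for (seg in segs) {
      tt <- as.numeric(seg$t); n <- nrow(seg); i <- seq(2, n - 1, by = 2)
      a <- (tt[i] - tt[i - 1]) / (tt[i + 1] - tt[i - 1])
      v <- (tt[i + 1] - tt[i - 1]) * a * (1 - a) * s
      mx <- (1 - a) * seg$x[i - 1] + a * seg$x[i + 1]
      my <- (1 - a) * seg$y[i - 1] + a * seg$y[i + 1]
      tot <- tot + sum(dnorm(seg$x[i], mx, sqrt(v), log = TRUE) +
                       dnorm(seg$y[i], my, sqrt(v), log = TRUE))
    }
    tot
  }, 0)
  oracle <- grid[which.max(ll)]
  expect_lt(abs(s2 - oracle) / oracle, 0.01)

  # no movement: the estimate collapses to the lower bound
  still <- data.frame(animal_id = "Z",
                      t = utc("2003-05-01") + (0:8) * 18000,
                      x = rep(0, 9), y = rep(0, 9))
  expect_lt(as.numeric(estimate_sigma2m(still, delta = 30)), 1e-4)
  expect_error(estimate_sigma2m(still[1:2, ], delta = 30), ">= 3 fixes")
})

test_that("bridge UD matches a Monte-Carlo oracle on a two-fix segment", {
  T <- 40000; s2 <- 16; delta <- 150
  fx <- data.frame(animal_id = "M", t = utc("2003-05-01") + c(0, T),
                   x = c(0, 4000), y = c(0, 1000))
  ud <- bbmm_ud(fx, bbmm_params(s2, delta = delta, cell_size = 100,
                                alpha_steps = 200))
  expect_equal(sum(ud$p), 1, tolerance = 1e-9)

  set.seed(62)
  M <- 2e5
  a <- runif(M)
  sdv <- sqrt(T * a * (1 - a) * s2 + ((1 - a)^2 + a^2) * delta^2)
  px <- a * 4000 + rnorm(M, 0, sdv)
  py <- a * 1000 + rnorm(M, 0, sdv)
  rc <- migroutes:::cell_of(ud, px, py)
  ok <- !is.na(rc$row)
  cnt <- matrix(0, ud$n_rows, ud$n_cols)
  tb <- table((rc$col[ok] - 1) * ud$n_rows + rc$row[ok])
  cnt[as.integer(names(tb))] <- tb
  phat <- cnt / M
  se <- sqrt(pmax(ud$p, 1e-9) * (1 - ud$p) / M)
  big <- ud$p >= 2.5e-4          # cells with expected count >= 50
  expect_gt(sum(ud$p[big]), 0.8)
  z <- abs(ud$p - phat) / se
  expect_lt(max(z[big]), 5)                     # no gross disagreement
  expect_gt(mean(z[big] <= 3), 0.995)           # 3-SE agreement en masse
  expect_lt(sum(abs(ud$p - phat)) / 2, 0.03)    # total variation at noise level
})

test_that("a degenerate bridge concentrates mass on the straight line", {
  fx <- data.frame(animal_id = "D", t = utc("2003-05-01") + c(0, 40000),
                   x = c(0, 4000), y = c(0, 1000))
  ud <- suppressWarnings(
    bbmm_ud(fx, bbmm_params(1e-12, delta = 0, cell_size = 100,
                            alpha_steps = 50)))
  cx <- ud$x0 + (seq_len(ud$n_cols) - 0.5) * 100
  cy <- ud$y0 + (seq_len(ud$n_rows) - 0.5) * 100
  dline <- outer(cy, cx, function(Y, X) abs(1000 * X - 4000 * Y) /
                                        sqrt(1000^2 + 4000^2))
  expect_gt(sum(ud$p[dline <= 150]), 0.99)
})

test_that("long gaps are excluded from bridging", {
  fx <- data.frame(animal_id = "G",
                   t = utc("2003-05-01") + c(0, 5, 10, 100, 105) * 3600,
                   x = c(0, 1000, 2000, 50000, 51000),
                   y = c(0, 0, 0, 0, 0))
  ud <- bbmm_ud(fx, bbmm_params(1, delta = 30, cell_size = 250,
                                alpha_steps = 10, max_gap_h = 40))
  # no mass in the skipped 2 km -> 50 km stretch
  cx <- ud$x0 + (seq_len(ud$n_cols) - 0.5) * 250
  mid <- cx > 10000 & cx < 40000
  expect_lt(sum(ud$p[, mid]), 1e-6)
  expect_error(bbmm_ud(fx[3:4, ], bbmm_params(1, max_gap_h = 40)),
               "max_gap_h")
})

test_that("population routes average individuals and count years of use", {
  fx1 <- data.frame(animal_id = "P1", t = utc("2003-05-01") + c(0, 40000),
                    x = c(0, 4000), y = c(0, 0))
  fx2 <- data.frame(animal_id = "P2", t = utc("2003-05-01") + c(0, 40000),
                    x = c(0, 4000), y = c(20000, 20000))
  par <- bbmm_params(4, delta = 100, cell_size = 500, alpha_steps = 20)
  g <- make_grid(c(-3000, 7000), c(-5000, 25000), 500, margin = 3000)
  u1 <- bbmm_ud(fx1, par, grid = g)
  u2 <- bbmm_ud(fx2, par, grid = g)

  # mean of identical UDs is that UD; permutation invariance
  expect_equal(population_route(list(u1, u1))$p, u1$p, tolerance = 1e-12)
  expect_equal(population_route(list(u1, u2))$p,
               population_route(list(u2, u1))$p)

  # two disjoint unit-mass routes contribute half the mass each
  pop <- population_route(list(u1, u2))
  south <- (seq_len(pop$n_rows) - 0.5) * 500 + pop$y0 < 10000
  expect_equal(sum(pop$p[south, ]), 0.5, tolerance = 1e-6)
  expect_equal(sum(pop$p), 1, tolerance = 1e-9)
  expect_error(population_route(list()), "no individual")

  # identical routes in all 4 years: every route cell counts 4
  yo <- route_years_of_use(list(`2003` = u1, `2004` = u1, `2005` = u1,
                                `2006` = u1), level = 0.95)
  iso <- isopleth(u1, 0.95)
  expect_true(all(yo$counts[iso$cells] == 4))
  expect_true(all(yo$counts %in% c(0, 4)))

  # constructed partial intersection agrees with a per-cell membership oracle
  yo2 <- route_years_of_use(list(`2003` = u1, `2004` = u2), level = 0.95)
  i1 <- isopleth(u1, 0.95); i2 <- isopleth(u2, 0.95)
  cxs <- yo2$x0 + (seq_len(yo2$n_cols) - 0.5) * 500
  cys <- yo2$y0 + (seq_len(yo2$n_rows) - 0.5) * 500
  for (r in seq(1, yo2$n_rows, by = 7)) for (c in seq(1, yo2$n_cols, by = 7)) {
    expected <- point_in_isopleth(i1, cxs[c], cys[r]) +
                point_in_isopleth(i2, cxs[c], cys[r])
    expect_equal(unname(yo2$counts[r, c]), unname(expected))
  }
})

test_that("migrants sharing a corridor put their high-use core inside it", {
  # five individuals bridging through the same 2-km-wide corridor
  set.seed(63)
  par <- bbmm_params(2, delta = 100, cell_size = 500, alpha_steps = 20)
  g <- make_grid(c(-5000, 5000), c(-5000, 45000), 500, margin = 5000)
  uds <- lapply(1:5, function(i) {
    xoff <- runif(1, -800, 800)
    fx <- data.frame(animal_id = paste0("W", i),
                     t = utc("2003-05-01") + seq(0, 8) * 18000,
                     x = xoff + rnorm(9, 0, 300),
                     y = seq(0, 40000, length.out = 9) + rnorm(9, 0, 300))
    bbmm_ud(fx, par, grid = g)
  })
  pop <- population_route(uds, season = "spring", year = "2003")
  core <- isopleth(pop, 0.25)
  expect_gte(core$mass, 0.25)
  # every core cell lies within the corridor band |x| <= 2 km
  cxs <- core$x0 + (seq_len(core$n_cols) - 0.5) * 500
  expect_true(all(abs(cxs[which(core$cells, arr.ind = TRUE)[, 2]]) <= 2000))
})
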