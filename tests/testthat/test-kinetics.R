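test_that("parameter and state validation rejects unusable inputs", {
  expect_error(rate_parameters(-1e-9, 7e-7), "non-negative")
  expect_error(rate_parameters(7e-9, 0), "strictly positive")
  expect_error(rate_parameters(7e-9, 7e-7, nc = 2.5), "positive integer")
  expect_error(rate_parameters(NaN, 7e-7), "finite")
  expect_error(initial_state(0), "> 0")
  expect_error(initial_state(1e-6, P0 = 0, M0 = 1e-8), "M0")
  # a consistent decomposition is accepted, an inconsistent one is not:
  # lambda = k_n * k_plus * m0^nc, so k_n = 7e-9 / (1e4 * 1e-12) = 0.7
  p <- rate_parameters(7e-9, 7e-7, nc = 2, k_plus = 1e4, k_n = 0.7,
                       k_off = 7e-3, m_ref = 1e-6)
  expect_equal(p$lambda, 7e-9)
  expect_error(rate_parameters(7e-9, 7e-7, nc = 2, k_plus = 1e4, k_n = 1e-15,
                               k_off = 7e-3, m_ref = 1e-6), "inconsistent")
})

test_that("degenerate dynamics behave analytically", {
  tg <- hours_grid(24, 50)
  # no nucleation, no seeds: nothing happens
  still <- simulate_aggregation(rate_parameters(0, 7e-7),
                                initial_state(1e-6), tg)
  expect_equal(still$monomer, rep(1e-6, 50), tolerance = 1e-12)
  expect_equal(still$mass, rep(0, 50), tolerance = 1e-18)
  # starting at the solubility is a fixed point even when seeded
  fp <- simulate_aggregation(wt_params(), initial_state(7e-7, P0 = 1e-4), tg)
  expect_equal(fp$monomer, rep(7e-7, 50), tolerance = 1e-9)
})

test_that("terminal monomer reaches the solubility fixed point", {
  tg <- hours_grid(72, 60)
  for (p in list(wt_params(), mut_params())) {
    tr <- simulate_aggregation(p, initial_state(1e-6), tg)
    expect_equal(tail(tr$monomer, 1), steady_state_monomer(p),
                 tolerance = 0.01)
    expect_true(all(diff(tr$monomer) <= 1e-15))        # non-increasing
    expect_true(all(tr$monomer >= p$solubility * (1 - 1e-6)))
    expect_true(all(diff(tr$number) >= -1e-15))        # P non-decreasing
  }
  # fixed point across lambda and nc
  for (lam in c(7e-9, 2e-8)) for (nc in 1:3) {
    tr <- simulate_aggregation(rate_parameters(lam, 7e-7, nc),
                               initial_state(1e-6), tg)
    expect_equal(tail(tr$monomer, 1), 7e-7, tolerance = 0.01)
  }
})

test_that("mass conservation holds at every output time", {
  tg <- hours_grid(72, 80)
  inits <- list(initial_state(1e-6),
                initial_state(1e-6, P0 = 1e-5, M0 = 2e-8),
                initial_state(5e-7, P0 = 3e-6, M0 = 1e-8))
  for (init in inits) {
    tr <- simulate_aggregation(mut_params(), init, tg)
    total <- init$m0 + init$M0
    expect_lt(max(abs(tr$monomer + tr$mass - total)) / total, 1e-6)
    expect_true(all(tr$mass >= -1e-18))
  }
})

test_that("adaptive integration matches a fine-step explicit Euler oracle", {
  euler_oracle <- function(lambda, sol, nc, m0, q0, t_end, dt,
                           checkpoints) {
    x <- 1; q <- q0; s <- sol / m0
    n <- ceiling(t_end / dt)
    out <- numeric(length(checkpoints)); ci <- 1L
    t <- 0
    for (i in seq_len(n)) {
      dx <- -2 * (x - s) * q
      dq <- lambda * x^nc
      x <- x + dt * dx; q <- q + dt * dq
      t <- t + dt
      while (ci <= length(checkpoints) && t >= checkpoints[ci] - dt / 2) {
        out[ci] <- x * m0; ci <- ci + 1L
      }
    }
    out
  }
  t_end <- 12 * 3600
  checkpoints <- seq(t_end / 10, t_end, length.out = 10)
  set.seed(42)
  draws <- data.frame(lambda = 10^runif(5, -8, -7.3),
                      sol = 10^runif(5, -7.2, -6.6))
  for (i in seq_len(nrow(draws))) {
    lam <- draws$lambda[i]; sol <- draws$sol[i]
    ora <- euler_oracle(lam, sol, 2, 1e-6, 0, t_end, 0.1, checkpoints)
    tr <- simulate_aggregation(rate_parameters(lam, sol, 2),
                               initial_state(1e-6), c(0, checkpoints))
    expect_lt(max(abs(tr$monomer[-1] - ora) / ora), 1e-3)
  }
})

test_that("trajectories depend only on the combined rate, not its split", {
  tg <- hours_grid(48, 60)
  # two decompositions with equal products lambda = kn*k+*m0^nc
  p1 <- rate_parameters(7e-9, 7e-7, 2, k_plus = 1e4, k_n = 0.7,
                        k_off = 7e-3, m_ref = 1e-6)
  p2 <- rate_parameters(7e-9, 7e-7, 2, k_plus = 1e6, k_n = 7e-3,
                        k_off = 7e-1, m_ref = 1e-6)
  tr1 <- simulate_aggregation(p1, initial_state(1e-6), tg)
  tr2 <- simulate_aggregation(p2, initial_state(1e-6), tg)
  expect_equal(tr1$mass, tr2$mass, tolerance = 1e-10)
})

test_that("mass curves are monotone in the combined rate and in seeds", {
  tg <- hours_grid(48, 100)
  set.seed(11)
  for (i in 1:5) {
    lam <- 10^runif(1, -8.5, -7.5); sol <- 10^runif(1, -7.2, -6.3)
    lo <- simulate_aggregation(rate_parameters(lam, sol), initial_state(1e-6), tg)
    hi <- simulate_aggregation(rate_parameters(2 * lam, sol), initial_state(1e-6), tg)
    expect_true(all(hi$mass - lo$mass >= -1e-6 * 1e-6))
    seeded <- seeded_simulate(rate_parameters(lam, sol),
                              initial_state(1e-6, P0 = 1e-5), tg)
    expect_true(all(seeded$mass - lo$mass >= -1e-6 * 1e-6))
  }
})

test_that("seeding gives a non-zero initial growth rate and P0=0 reduces to unseeded", {
  tg <- early_grid(24, 200)  # first output point at t = 10 s
  un <- simulate_aggregation(wt_params(), initial_state(1e-6), tg)
  se <- seeded_simulate(wt_params(), initial_state(1e-6, P0 = 1e-4), tg)
  dt <- tg[2]
  # unseeded initial slope ~ 0 (t^2 growth); seeded slope = 2*Q0*(m0 - sol)
  expect_lt(un$mass[2] / dt, 1e-3 * se$mass[2] / dt)
  expect_equal(se$mass[2] / dt, 2 * 1e-4 * (1e-6 - 7e-7), tolerance = 0.05)
  # P0 = 0 path is exactly the unseeded model
  expect_error(seeded_simulate(wt_params(), initial_state(1e-6), tg), "P0")
  again <- simulate_aggregation(wt_params(), initial_state(1e-6, P0 = 0), tg)
  expect_identical(un$mass, again$mass)
})

test_that("nucleation rate is blind to injected aggregate mass", {
  # doubling M0 (mass held in seeds) without touching Q0 must leave the
  # number trajectory unchanged: dP/dt depends only on m
  tg <- hours_grid(24, 50)
  a <- simulate_aggregation(wt_params(), initial_state(1e-6, P0 = 1e-5,
                                                       M0 = 1e-8), tg)
  b <- simulate_aggregation(wt_params(), initial_state(1e-6, P0 = 1e-5,
                                                       M0 = 2e-8), tg)
  expect_identical(a$number, b$number)
  expect_equal(b$mass - a$mass, rep(1e-8, 50), tolerance = 1e-9)
})

test_that("early-time log-log slope discriminates nucleated growth", {
  tr <- simulate_aggregation(wt_params(), initial_state(1e-6), early_grid())
  expect_equal(early_time_exponent(tr, window = 0.02), 2.0, tolerance = 0.05)
  # strongly seeded: linear early growth (slope ~1 over the early window)
  se <- seeded_simulate(wt_params(), initial_state(1e-6, P0 = 1e-3),
                        early_grid())
  expect_equal(early_time_exponent(se, window = 0.1), 1.0, tolerance = 0.1)
  # precursor-limited first-order curve M = A(1 - exp(-kt)): slope ~ 1
  tt <- early_grid(72, 200)
  fo <- data.frame(time = tt, mass = 3e-7 * (1 - exp(-tt / 5e4)))
  expect_equal(early_time_exponent(fo, window = 0.1), 1.0, tolerance = 0.1)
  expect_error(early_time_exponent(tr[c(1, 50, 100), ], window = 0.001),
               "points")
})
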