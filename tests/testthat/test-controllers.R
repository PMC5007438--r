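test_that("the positional PI law evaluates as stated", {
  cfg <- pi_config(K_P = 80, K_I = 8)
  st <- pi_state(cfg)
  # zero error from rest: input clipped at the lower limit
  r0 <- pi_step(cfg, st, y_ref = 1, y = 1)
  expect_equal(r0$u, 0)
  expect_equal(r0$state$u_I, 0)
  # e = 0.5 with the published gains: u_I' = 4, u = 80*0.5 + 4 = 44
  r1 <- pi_step(cfg, st, y_ref = 1.5, y = 1)
  expect_equal(r1$state$u_I, 4)
  expect_equal(r1$u, 44)
  # saturation at the upper limit
  r2 <- pi_step(cfg, st, y_ref = 5, y = 1)
  expect_equal(r2$u, 100)
})

test_that("a measurement failure reuses the previous measurement", {
  cfg <- pi_config(K_P = 80, K_I = 8)
  st <- pi_state(cfg)
  r1 <- pi_step(cfg, st, y_ref = 1.5, y = 1)
  r2 <- pi_step(cfg, r1$state, y_ref = 1.5, y = NA)
  # same error as before: integral keeps accumulating deterministically
  expect_equal(r2$state$last_y, 1)
  expect_equal(r2$state$u_I, 8)
})

test_that("PI achieves zero steady-state error and rejects constant input disturbances", {
  p <- nominal_model_params()
  m <- discretize(p)
  cfg <- pi_config(K_P = 80, K_I = 8)
  b0 <- 0.14  # measured-fluorescence units per fold change
  sim <- function(d_in) {
    st <- pi_state(cfg)
    x <- c(1, 1, 1)
    u_prev <- 0
    e_last <- NA
    for (k in 1:150) {
      stp <- pi_step(cfg, st, y_ref = b0 * 2, y = b0 * x[3])
      st <- stp$state
      dr <- dose_response()
      u_fold <- dose_response_eval(dr, u_prev)  # one-step input delay
      x <- dm_step(m, x, u_fold, d_in)
      u_prev <- stp$u
      e_last <- 2 - x[3]
    }
    e_last
  }
  expect_lt(abs(sim(0)) / 2, 0.01)
  expect_lt(abs(sim(-0.3)) / 2, 0.01)  # constant additive input disturbance
})

test_that("gain scheduling switches once, carries the integral, and is bumpless at zero error", {
  cfg <- pi_config(80, 8, schedule = list(list(K_P = 160, K_I = 20,
                                               at_time = 240)))
  st <- pi_state(cfg)
  st$u_I <- 12
  st2 <- schedule_tick(cfg, st, t = 239, in_band = FALSE)
  expect_equal(st2$K_P, 80)
  st3 <- schedule_tick(cfg, st2, t = 240, in_band = FALSE)
  expect_equal(st3$K_P, 160)
  expect_equal(st3$K_I, 20)
  expect_equal(st3$u_I, 12)  # bumpless transfer
  # at most once
  st4 <- schedule_tick(cfg, st3, t = 500, in_band = FALSE)
  expect_equal(st4$stage, 1L)
  # with e = 0 the applied input is continuous across the switch
  u_before <- pi_step(pi_config(80, 8), st, 1, 1)$u
  u_after <- pi_step(pi_config(160, 20), st3, 1, 1)$u
  expect_equal(u_before, u_after)
})

test_that("the in-band trigger fires after sustained band entry", {
  cfg <- pi_config(80, 8, schedule = list(list(K_P = 160, K_I = 20,
                                               in_band_samples = 3)))
  st <- pi_state(cfg)
  st <- schedule_tick(cfg, st, 0, TRUE)
  st <- schedule_tick(cfg, st, 10, TRUE)
  expect_equal(st$K_P, 80)
  st <- schedule_tick(cfg, st, 20, TRUE)
  expect_equal(st$K_P, 160)
  # without a trigger the gains stay put for the whole run
  cfg0 <- pi_config(80, 8)
  st0 <- pi_state(cfg0)
  for (t in seq(0, 600, 10)) st0 <- schedule_tick(cfg0, st0, t, TRUE)
  expect_equal(st0$K_P, 80)
})

test_that("the growth PI couples complementary green and red channels", {
  cfg <- growth_pi_config(K_P = 6000, K_I = 45)
  st <- pi_state(cfg)
  # proportional term vanishes at zero error
  st$u_I <- 30
  r0 <- growth_pi_step(cfg, st, mu_ref = 0.008, mu_filtered = 0.008)
  expect_equal(r0$u_green, 30)
  expect_equal(r0$u_red, 70)
  # published gains on a 0.001 1/min error: u_I' = 0.045, u_g = 6.045
  st1 <- pi_state(cfg)
  r1 <- growth_pi_step(cfg, st1, mu_ref = 0.009, mu_filtered = 0.008)
  expect_equal(r1$state$u_I, 0.045)
  expect_equal(r1$u_green, 6.045)
  # persistent negative error: integral clamps at 0, never negative
  st2 <- pi_state(cfg)
  for (i in 1:50) {
    r <- growth_pi_step(cfg, st2, mu_ref = 0.004, mu_filtered = 0.012)
    st2 <- r$state
    expect_gte(st2$u_I, 0)
  }
  expect_equal(st2$u_I, 0)
})

test_that("quantized MPC matches a naive brute-force enumeration", {
  p <- nominal_model_params()
  m <- discretize(p)
  dr <- dose_response()
  levels <- c(0, 15, 30, 45, 60)
  cfg <- mpc_config(horizon = 3, input_levels = levels)
  est <- list(x = c(1.2, 1.3, 1.25), d = 0.05)
  ref <- c(1.5, 1.6, 1.7, 1.8)
  sol <- mpc_step(cfg, m, est, pending = 0.4, ref = ref, dr = dr,
                  last_u = 0.4)
  # independent oracle: plain nested loops, per-step state propagation
  lev_u <- dose_response_eval(dr, levels)
  best <- Inf
  for (a in lev_u) for (b in lev_u) for (cc in lev_u) {
    x <- est$x
    us <- c(0.4, a, b, cc)
    G <- numeric(4)
    for (j in 1:4) {
      x <- as.numeric(m$Ad %*% (x - 1)) + m$Bd * (us[j] + est$d) + 1
      G[j] <- x[3]
    }
    cost <- sum((G[2:4] - ref[2:4])^2) +
      1e-3 * sum(diff(c(0.4, a, b, cc))^2)
    best <- min(best, cost)
  }
  expect_equal(sol$cost, best, tolerance = 1e-6)
})

test_that("MPC respects the intensity cap and is deterministic", {
  p <- nominal_model_params()
  m <- discretize(p)
  dr <- dose_response()
  cfg <- mpc_config(horizon = 6, U_cap = 60)
  set.seed(31)
  for (i in 1:10) {
    est <- list(x = runif(3, 0.5, 3), d = runif(1, -0.5, 0.5))
    ref <- runif(7, 1, 3)
    sol <- mpc_step(cfg, m, est, pending = runif(1, 0, 2), ref = ref,
                    dr = dr, last_u = 0.5)
    expect_lte(sol$U, 60)
    expect_gte(sol$U, 0)
    sol2 <- mpc_step(cfg, m, est, pending = sol$u * 0 + 0.3, ref = ref,
                     dr = dr, last_u = 0.5)
    sol3 <- mpc_step(cfg, m, est, pending = 0.3, ref = ref, dr = dr,
                     last_u = 0.5)
    expect_identical(sol2, sol3)
  }
})

test_that("at a reachable equilibrium MPC keeps the prediction on the reference", {
  p <- nominal_model_params()
  m <- discretize(p)
  dr <- dose_response()
  cfg <- mpc_config(horizon = 6)
  u_eq <- (2 - 1) / (p$b_r / p$d_r)
  est <- list(x = fold_change_steady_state(p, u_eq), d = 0)
  sol <- mpc_step(cfg, m, est, pending = u_eq, ref = rep(2, 7), dr = dr,
                  last_u = u_eq)
  expect_equal(sol$u, u_eq, tolerance = 0.02)
  # predicted output stays inside the 5% band over the horizon
  x <- est$x
  for (j in 1:6) {
    x <- dm_step(m, x, if (j == 1) u_eq else sol$u_seq[j - 1])
    expect_lt(abs(x[3] - 2) / 2, 0.05)
  }
})

test_that("the optimal MPC cost grows with horizon length (nested windows)", {
  p <- nominal_model_params()
  m <- discretize(p)
  dr <- dose_response()
  est <- list(x = c(1.1, 1.1, 1.1), d = 0)
  ref <- rep(2.5, 12)
  costs <- vapply(3:8, function(N) {
    mpc_step(mpc_config(horizon = N, du_weight = 0), m, est,
             pending = 0, ref = ref, dr = dr, last_u = 0)$cost
  }, numeric(1))
  expect_true(all(diff(costs) >= -1e-9))
})
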