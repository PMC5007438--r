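test_that("constant input u=1 doubles steady-state expression", {
  p <- nominal_model_params()
  tr <- simulate_fold_change(p, input = 1, horizon = 3000, dt_out = 10)
  expect_equal(tail(tr$G, 1), 2, tolerance = 0.02)
  # analytic law: G_ss = 1 + (b_r/d_r) u
  expect_equal(tail(tr$G, 1), 1 + p$b_r / p$d_r, tolerance = 1e-4)
  ss <- fold_change_steady_state(p, 1)
  expect_true(ss[["G"]] >= 1.99 && ss[["G"]] <= 2.03)
})

test_that("the un-induced rest state is an exact equilibrium", {
  p <- nominal_model_params()
  tr <- simulate_fold_change(p, input = 0, horizon = 500, dt_out = 50)
  expect_equal(tr$R, rep(1, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$P, rep(1, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$G, rep(1, nrow(tr)), tolerance = 1e-9)
})

test_that("step response matches the closed-form LTI solution", {
  p <- nominal_model_params()
  times <- seq(0, 600, by = 50)
  tr <- simulate_fold_change(p, input = 1, horizon = 600, dt_out = 50)
  oracle <- step_response_oracle(p, 1, times)
  expect_equal(as.matrix(tr[, c("R", "P", "G")]), oracle,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("ODE solver agrees with the matrix-exponential oracle on random draws", {
  set.seed(11)
  for (i in 1:20) {
    p <- suppressWarnings(random_params())
    tr <- simulate_fold_change(p, input = 0.8, horizon = 300, dt_out = 100)
    oracle <- step_response_oracle(p, 0.8, c(0, 100, 200, 300))
    expect_equal(as.matrix(tr[, c("R", "P", "G")]), oracle,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("raw and fold-change coordinates are consistent", {
  p <- nominal_model_params()
  raw <- as_raw_params(p)
  dr <- dose_response()
  U <- as.numeric(dose_response_invert(dr, 1))
  ss0 <- raw_steady_state(raw)
  trr <- simulate_raw(raw, U, dr, horizon = 800, dt_out = 40)
  trf <- simulate_fold_change(p, 1, horizon = 800, dt_out = 40)
  expect_equal(trr$r / ss0[["r"]], trf$R, tolerance = 1e-6)
  expect_equal(trr$p / ss0[["p"]], trf$P, tolerance = 1e-6)
  expect_equal(trr$g / ss0[["g"]], trf$G, tolerance = 1e-6)
  # constant trajectory from the un-induced steady state
  tr0 <- simulate_raw(raw, 0, dr, horizon = 300, dt_out = 100)
  expect_equal(tr0$g, rep(ss0[["g"]], nrow(tr0)), tolerance = 1e-8)
  # steady-state fold change of g is 1 + f(U) b_r/d_r
  trc <- simulate_raw(raw, 35, dr, horizon = 3000, dt_out = 500)
  expect_equal(tail(trc$g, 1) / ss0[["g"]],
               1 + dose_response_eval(dr, 35) * p$b_r / p$d_r,
               tolerance = 1e-4)
})

test_that("basal production sets the concentration scale but not fold changes", {
  p <- nominal_model_params()
  r1 <- as_raw_params(p, b_r0 = 2)
  r2 <- as_raw_params(p, b_r0 = 4)
  expect_equal(raw_steady_state(r2), 2 * raw_steady_state(r1))
  expect_equal(raw_steady_state(r2, u = 1) / raw_steady_state(r2)[["g"]] *
                 raw_steady_state(r1)[["g"]],
               raw_steady_state(r1, u = 1))
})

test_that("superposition holds for deviations from rest", {
  p <- nominal_model_params()
  a <- 0.3
  resp <- function(u) {
    tr <- simulate_fold_change(p, u, horizon = 400, dt_out = 40)
    as.matrix(tr[, c("R", "P", "G")]) - 1
  }
  mix <- resp(a * 1.5 + (1 - a) * 0.4)
  combo <- a * resp(1.5) + (1 - a) * resp(0.4)
  expect_equal(mix, combo, tolerance = 1e-8)
})

test_that("states stay non-negative for admissible inputs", {
  p <- nominal_model_params()
  prof <- data.frame(time = c(0, 100, 200, 300), u = c(2, 0, 1.5, 0))
  tr <- simulate_fold_change(p, prof, horizon = 400,
                             initial = c(0, 0, 0), dt_out = 5)
  expect_true(all(tr$R >= 0 & tr$P >= 0 & tr$G >= 0))
})

test_that("invalid parameters and inputs are rejected", {
  expect_error(model_params(-0.1, 0.02, 0.1, 0.01), "positive")
  p <- nominal_model_params()
  expect_error(simulate_fold_change(p, input = -1, horizon = 100), ">= 0")
  expect_error(simulate_fold_change(p, input = NaN, horizon = 100))
  expect_error(simulate_fold_change(p, input = 1, horizon = -5), "> 0")
})

test_that("dose-response map passes through the origin and saturates", {
  dr <- dose_response()
  expect_identical(dose_response_eval(dr, 0), 0)
  f100 <- dose_response_eval(dr, 100)
  f60 <- dose_response_eval(dr, 60)
  expect_lte(f100 - f60, 0.05 * f100)
  # monotone non-decreasing on [0, 100]
  U <- seq(0, 100, by = 1)
  expect_true(all(diff(dose_response_eval(dr, U)) >= 0))
})

test_that("dose-response inversion is exact on the increasing region", {
  dr <- dose_response()
  U <- c(5, 17, 37, 55, 80)
  expect_equal(as.numeric(dose_response_invert(dr, dose_response_eval(dr, U))),
               U, tolerance = 1e-6)
  over <- dose_response_invert(dr, dose_response_eval(dr, 100) + 0.5)
  expect_equal(as.numeric(over), 100)
  expect_true(attr(over, "saturated"))
})

test_that("dose-response fit recovers a known Hill curve", {
  true_dr <- suppressWarnings(dose_response(u_sat = 2.5, K = 25, n = 2.5))
  U <- c(2, 5, 10, 20, 35, 50, 75, 100)
  G_ss <- 1 + dose_response_eval(true_dr, U)
  fit <- suppressWarnings(fit_dose_response(U, G_ss))
  expect_equal(fit$u_sat, 2.5, tolerance = 0.05)
  expect_equal(fit$K, 25, tolerance = 0.05)
  expect_equal(fit$n, 2.5, tolerance = 0.05)
})

test_that("medium shift replaces the dilution rate from the new doubling time", {
  plant <- gene_plant(
    raw_model_params(b_r0 = 2, b_r_gain = 2, d_r = 0.0956, b_p = 1,
                     d_p = log(2) / 38, k_m = 0.0116))
  plant <- apply_disturbance(plant,
                             disturbance_event("medium_shift", onset = 300,
                                               new_doubling_time = 25))
  expect_equal(plant_rates_at(plant, 299)$d_p, log(2) / 38)
  expect_equal(plant_rates_at(plant, 300)$d_p, log(2) / 25)
})

test_that("temperature shift slows all rates and lowers expression", {
  plant <- gene_plant(as_raw_params())
  plant <- apply_disturbance(plant,
                             disturbance_event("temperature_shift",
                                               onset = 100, scale = 0.5,
                                               production_scale = 0.8,
                                               ramp = 30))
  before <- plant_rates_at(plant, 99)
  after <- plant_rates_at(plant, 130)  # ramp complete
  expect_equal(after$d_p, before$d_p * 0.5)
  expect_equal(after$d_r, before$d_r * 0.5)
  # post-shift doubling time beyond an hour
  expect_gt(log(2) / after$d_p, 60)
  # steady-state output drops by the production factor
  expect_equal(raw_steady_state(after)[["g"]] /
                 raw_steady_state(before)[["g"]], 0.8, tolerance = 1e-9)
  # mid-ramp is between the two
  mid <- plant_rates_at(plant, 115)
  expect_true(mid$d_p < before$d_p && mid$d_p > after$d_p)
})

test_that("input offsets subtract a fraction of the onset input", {
  plant <- gene_plant(as_raw_params(),
                      disturbances = list(
                        disturbance_event("input_offset", onset = 300,
                                          fraction = 0.5)))
  base <- list("1" = 40)
  expect_equal(effective_intensity(plant, 299, 40, base), 40)
  expect_equal(effective_intensity(plant, 300, 40, base), 20)
  expect_equal(effective_intensity(plant, 400, 10, base), 0)  # floored
})

test_that("a zero-magnitude event leaves the closed-loop run bit-identical", {
  s1 <- preset_scenario("setpoints_pi", seed = 3)
  s2 <- s1
  s2$plant <- apply_disturbance(s2$plant,
                                disturbance_event("additive_output",
                                                  onset = 100, offset = 0))
  expect_identical(run_scenario(s1)$G_true, run_scenario(s2)$G_true)
})

test_that("unknown disturbance kinds are rejected", {
  expect_error(disturbance_event("sonication", onset = 10))
  expect_error(apply_disturbance(gene_plant(), list(kind = "medium_shift")),
               "unknown")
})

test_that("day-to-day variability perturbs rates multiplicatively", {
  set.seed(4)
  raw <- as_raw_params()
  pert <- perturb_day(raw, sigma = 0.15)
  ratios <- unlist(pert) / unlist(raw)
  expect_true(all(ratios > 0.5 & ratios < 2))
  expect_true(any(abs(log(ratios)) > 0.01))
})
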