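## Discrete-time feedback laws: positional PI with integral clamping and
## gain scheduling, the growth-rate PI with complementary green/red
## channels, and finite-horizon MPC over the ZOH model.

#' PI controller configuration
#'
#' Positional discrete PI: at each measurement the integral term is
#' updated first, `u_I <- clip(u_I + K_I e, clamp)`, then the applied
#' input is `u = clip(K_P e + u_I, [u_min, u_max])`.  An optional gain
#' schedule lists further gain stages switched in by a trigger (a fixed
#' time, or the output staying inside the tolerance band for a number of
#' consecutive samples); switching carries the integral term over
#' unchanged (bumpless transfer).
#'
#' @param K_P proportional gain (input units per output unit).
#' @param K_I integral gain (input units per output unit per step).
#' @param u_min,u_max saturation limits of the applied input (% LED).
#' @param clamp two-element clamp interval for the integral term.
#' @param schedule optional list of stages, each a list with `K_P`, `K_I`
#'   and either `at_time` (min) or `in_band_samples` (consecutive
#'   in-band samples required).
#' @return An object of class `pi_config`.
#' @export
pi_config <- function(K_P, K_I, u_min = 0, u_max = 100,
                      clamp = c(0, 100), schedule = NULL) {
  stopifnot(is.finite(K_P), is.finite(K_I), u_min < u_max,
            length(clamp) == 2, clamp[1] < clamp[2])
  if (!is.null(schedule)) {
    for (st in schedule) {
      stopifnot(is.finite(st$K_P), is.finite(st$K_I))
      if (is.null(st$at_time) && is.null(st$in_band_samples)) {
        stop("each schedule stage needs a trigger: at_time or ",
             "in_band_samples", call. = FALSE)
      }
    }
  }
  structure(list(K_P = K_P, K_I = K_I, u_min = u_min, u_max = u_max,
                 clamp = clamp, schedule = schedule),
            class = "pi_config")
}

#' Fresh PI controller state
#'
#' The integral term starts at 0; gains start at the base stage.
#'
#' @param cfg a [pi_config()].
#' @return An object of class `pi_state`.
#' @export
pi_state <- function(cfg) {
  structure(list(u_I = 0, K_P = cfg$K_P, K_I = cfg$K_I,
                 last_error = NA_real_, last_input = NA_real_,
                 last_y = NA_real_, stage = 0L, in_band_run = 0L),
            class = "pi_state")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' One PI update
#'
#' Computes the input to apply until the next measurement.  On a
#' measurement failure (`y = NA`) the previous measurement is reused, so
#' the controller output is held rather than jumping.
#'
#' @param cfg a [pi_config()].
#' @param state a [pi_state()].
#' @param y_ref reference output at this sample.
#' @param y measured output (or `NA` on measurement failure).
#' @return List with `u` (applied input) and the updated `state`.
#' @export
pi_step <- function(cfg, state, y_ref, y) {
  if (is.na(y)) y <- state$last_y
  if (is.na(y)) y <- y_ref  # no measurement ever seen: act as zero error
  e <- y_ref - y
  u_I <- clip(state$u_I + state$K_I * e, cfg$clamp[1], cfg$clamp[2])
  u <- clip(state$K_P * e + u_I, cfg$u_min, cfg$u_max)
  state$u_I <- u_I
  state$last_error <- e
  state$last_input <- u
  state$last_y <- y
  list(u = u, state = state)
}

#' Switch the PI gains to a scheduled stage
#'
#' Swaps in the gains of schedule stage `stage`, leaving the integral
#' term untouched (bumpless transfer).  Each stage is entered at most
#' once; asking for the current or an earlier stage is a no-op.
#'
#' @param cfg a [pi_config()] with a `schedule`.
#' @param state a [pi_state()].
#' @param stage index into `cfg$schedule` to activate.
#' @return The updated `pi_state`.
#' @export
apply_gain_schedule <- function(cfg, state, stage) {
  stopifnot(inherits(state, "pi_state"))
  stage <- as.integer(stage)
  if (is.null(cfg$schedule) || stage < 1 || stage > length(cfg$schedule) ||
      stage <= state$stage) {
    return(state)
  }
  st <- cfg$schedule[[stage]]
  state$K_P <- st$K_P
  state$K_I <- st$K_I
  state$stage <- stage
  state
}

# evaluate schedule triggers given time and in-band status; returns the
# (possibly updated) state
schedule_tick <- function(cfg, state, t, in_band) {
  if (is.null(cfg$schedule)) return(state)
  state$in_band_run <- if (isTRUE(in_band)) state$in_band_run + 1L else 0L
  nxt <- state$stage + 1L
  if (nxt > length(cfg$schedule)) return(state)
  st <- cfg$schedule[[nxt]]
  fire <- (!is.null(st$at_time) && t >= st$at_time) ||
    (!is.null(st$in_band_samples) && state$in_band_run >= st$in_band_samples)
  if (fire) state <- apply_gain_schedule(cfg, state, nxt)
  state
}

#' One growth-rate PI update
#'
#' The outer growth loop runs every minute on a filtered growth-rate
#' measurement.  The green channel follows the PI law with the integral
#' term clamped to `[0, 60]` (preventing accumulation of large positive
#' or negative errors); the red channel complements it so that the sum of
#' green and red intensities, normalized to their maxima, stays constant:
#' `u_r = 100 - u_g`.
#'
#' @param cfg a [pi_config()]; growth defaults use `clamp = c(0, 60)`.
#' @param state a [pi_state()].
#' @param mu_ref target growth rate (1/min).
#' @param mu_filtered filtered growth-rate measurement (1/min), `>= 0`.
#' @return List with `u_green`, `u_red` (% of maxima) and `state`.
#' @export
growth_pi_step <- function(cfg, state, mu_ref, mu_filtered) {
  stopifnot(mu_filtered >= 0)
  e <- mu_ref - mu_filtered
  u_I <- clip(state$u_I + state$K_I * e, cfg$clamp[1], cfg$clamp[2])
  u_g <- clip(state$K_P * e + u_I, 0, 100)
  state$u_I <- u_I
  state$last_error <- e
  state$last_input <- u_g
  list(u_green = u_g, u_red = 100 - u_g, state = state)
}

#' Default growth-loop PI configuration
#'
#' Gains from the growth-tracking experiments (`K_P` in the thousands
#' because the error is a rate in 1/min, of order 1e-3), integral clamp
#' `[0, 60]`.
#'
#' @param K_P,K_I gains.
#' @return A [pi_config()].
#' @export
growth_pi_config <- function(K_P = 6000, K_I = 45) {
  pi_config(K_P = K_P, K_I = K_I, u_min = 0, u_max = 100, clamp = c(0, 60))
}

#' MPC configuration
#'
#' @param horizon prediction horizon `N` in sampling periods (>= 2;
#'   default 6, i.e. one hour at 10-min sampling).
#' @param U_cap maximum allowable LED intensity (%); default 60 since the
#'   dose-response curve is almost flat above that level.
#' @param du_weight quadratic penalty weight on input increments.
#' @param input_levels optional vector of quantized intensity levels (%);
#'   when given the optimizer searches level sequences exhaustively.
#' @return An object of class `mpc_config`.
#' @export
mpc_config <- function(horizon = 6, U_cap = 60, du_weight = 1e-3,
                       input_levels = NULL) {
  stopifnot(horizon >= 2, U_cap <= 100, U_cap > 0, du_weight >= 0)
  structure(list(horizon = as.integer(horizon), U_cap = U_cap,
                 du_weight = du_weight, input_levels = input_levels),
            class = "mpc_config")
}

# batch-propagate deviation states for a matrix of input sequences
# (nseq x H); returns matrix of predicted G deviations (nseq x H)
mpc_predict_batch <- function(model, x_dev, useq, d) {
  nseq <- nrow(useq)
  H <- ncol(useq)
  X <- matrix(rep(x_dev, each = nseq), nseq, 3)
  G <- matrix(NA_real_, nseq, H)
  Ad <- model$Ad; Bd <- model$Bd
  for (j in seq_len(H)) {
    uin <- useq[, j] + d
    X <- cbind(Ad[1, 1] * X[, 1] + Bd[1] * uin,
               Ad[2, 1] * X[, 1] + Ad[2, 2] * X[, 2] + Bd[2] * uin,
               Ad[3, 1] * X[, 1] + Ad[3, 2] * X[, 2] + Ad[3, 3] * X[, 3] +
                 Bd[3] * uin)
    G[, j] <- X[, 3]
  }
  G
}

#' One MPC update
#'
#' Given the current state estimate, pending delayed inputs and the
#' disturbance estimate, computes the fold-change input sequence over the
#' horizon minimizing the sum of squared output-tracking errors plus a
#' small input-increment penalty, subject to the intensity cap mapped
#' through the dose-response curve.  Only the first input is applied; it
#' is returned both in fold-change units and as an intensity via
#' [dose_response_invert()].  The solver is warm-started from the shifted
#' previous solution, and a solver failure falls back to the previous
#' input with a warning.
#'
#' @param cfg an [mpc_config()].
#' @param model a [discretize()]d model (typically rebuilt each step from
#'   the particle filter's parameter estimates).
#' @param est list with state estimate `x` (fold units) and disturbance
#'   `d` (as from [pf_estimates()]).
#' @param pending fold-change inputs already commanded but not yet
#'   effective (length = model delay; oldest first).
#' @param ref reference fold changes at the next `delay + horizon`
#'   sampling instants (recycled if shorter).
#' @param dr [dose_response()] used to invert the first input.
#' @param last_u previously commanded fold-change input (for the
#'   increment penalty and the fallback).
#' @param warm optional warm-start sequence.
#' @return List with `U` (intensity %, `<= U_cap`), `u` (fold input),
#'   `cost`, and the optimized sequence `u_seq`.
#' @export
mpc_step <- function(cfg, model, est, pending, ref, dr = dose_response(),
                     last_u = 0, warm = NULL) {
  N <- cfg$horizon
  delay <- length(pending)
  H <- delay + N
  ref <- rep_len(ref, H)
  ref_dev <- ref - 1
  x_dev <- est$x - 1
  d <- est$d
  u_cap <- dose_response_eval(dr, cfg$U_cap)
  cost_of <- function(u) {
    useq <- matrix(c(pending, u), 1, H)
    G <- mpc_predict_batch(model, x_dev, useq, d)
    err <- G[1, (delay + 1):H] - ref_dev[(delay + 1):H]
    sum(err^2) + cfg$du_weight * sum(diff(c(last_u, u))^2)
  }
  if (!is.null(cfg$input_levels)) {
    lev <- dose_response_eval(dr, pmin(cfg$input_levels, cfg$U_cap))
    grid <- as.matrix(expand.grid(rep(list(lev), N)))
    useq <- cbind(matrix(rep(pending, each = nrow(grid)),
                         nrow(grid), delay), grid)
    G <- mpc_predict_batch(model, x_dev, useq, d)
    err <- G[, (delay + 1):H, drop = FALSE] -
      rep(ref_dev[(delay + 1):H], each = nrow(grid))
    dU <- cbind(grid[, 1] - last_u,
                grid[, -1, drop = FALSE] - grid[, -N, drop = FALSE])
    cost <- rowSums(err^2) + cfg$du_weight * rowSums(dU^2)
    i <- which.min(cost)
    u_opt <- grid[i, ]
    val <- cost[i]
  } else {
    start <- if (!is.null(warm)) clip(warm, 0, u_cap) else
      rep(clip(last_u, 0, u_cap), N)
    fit <- tryCatch(
      stats::optim(start, cost_of, method = "L-BFGS-B",
                   lower = 0, upper = u_cap),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("MPC optimizer failed; reusing previous input")
      u_opt <- rep(clip(last_u, 0, u_cap), N)
      val <- cost_of(u_opt)
    } else {
      u_opt <- fit$par
      val <- fit$value
    }
  }
  u_opt <- clip(u_opt, 0, u_cap)  # guard against solver round-off at bounds
  U <- as.numeric(dose_response_invert(dr, u_opt[1]))
  list(U = min(U, cfg$U_cap), u = u_opt[1], cost = val, u_seq = u_opt)
}
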