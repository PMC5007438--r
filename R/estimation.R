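## Discrete-time model construction and joint state/parameter estimation.
##
## The continuous fold-change system is linear and lower-triangular, so
## its zero-order-hold discretization has a closed form in the three
## eigenvalues -d_r, -(d_p+k_m), -d_p.  The closed form is vectorized
## over parameter draws, which makes per-particle propagation in the
## particle filter cheap.

# ZOH factors of exp(A T_s) and int_0^Ts exp(A s) ds B for (possibly
# vectorized) parameter draws; returns the 6 nonzero entries of Ad and
# the 3 entries of Bd.
zoh_factors <- function(d_r, d_p, b_r, k_m, T_s) {
  l1 <- -d_r
  l2 <- -(d_p + k_m)
  l3 <- -d_p
  # separate near-coincident eigenvalues (the closed form divides by the
  # differences); a 1e-9 relative nudge is far below solver tolerances
  eps <- 1e-9 * pmax(abs(l1), abs(l2), abs(l3))
  l1 <- ifelse(abs(l1 - l2) < eps | abs(l1 - l3) < eps, l1 * (1 + 1e-7) - eps,
               l1)
  l2 <- ifelse(abs(l2 - l3) < eps, l2 * (1 + 1e-7) - eps, l2)
  E1 <- exp(l1 * T_s); E2 <- exp(l2 * T_s); E3 <- exp(l3 * T_s)
  I1 <- (E1 - 1) / l1; I2 <- (E2 - 1) / l2; I3 <- (E3 - 1) / l3
  a21 <- d_p + k_m
  a32 <- d_p
  d12 <- l1 - l2; d13 <- l1 - l3; d23 <- l2 - l3
  S  <- E1 / (d12 * d13) - E2 / (d12 * d23) + E3 / (d13 * d23)
  IS <- I1 / (d12 * d13) - I2 / (d12 * d23) + I3 / (d13 * d23)
  list(A11 = E1, A21 = a21 * (E1 - E2) / d12, A22 = E2,
       A31 = a21 * a32 * S, A32 = a32 * (E2 - E3) / d23, A33 = E3,
       B1 = b_r * I1, B2 = b_r * a21 * (I1 - I2) / d12,
       B3 = b_r * a21 * a32 * IS)
}

#' Exact zero-order-hold discretization of the fold-change model
#'
#' Converts the continuous fold-change model into the equivalent
#' discrete-time system at the sampling period `T_s`: deviations from the
#' rest state `(1,1,1)` evolve as `x[k+1] = Ad x[k] + Bd (u[k] + d)`,
#' where `u` enters with `input_delay_steps` sampling periods of delay
#' and `d` is an additive disturbance input on the same channel (zero in
#' the nominal system; estimated online to detect perturbations).  Only
#' the last state, fluorescent protein `G`, is measured.
#'
#' @param params a [model_params()] object.
#' @return An object of class `discrete_model` with fields `Ad` (3x3
#'   transition matrix), `Bd` (input column), `C` (output selector),
#'   `T_s` and `delay`.
#' @export
discretize <- function(params) {
  stopifnot(inherits(params, "model_params"))
  discretize_rates(params$d_r, params$d_p, params$b_r, params$k_m,
                   params$T_s, params$input_delay_steps)
}

# same construction from bare rates (no range validation); used when the
# model is rebuilt every step from online parameter estimates
discretize_rates <- function(d_r, d_p, b_r, k_m, T_s, delay) {
  z <- zoh_factors(d_r, d_p, b_r, k_m, T_s)
  Ad <- matrix(c(z$A11, 0, 0,
                 z$A21, z$A22, 0,
                 z$A31, z$A32, z$A33), 3, 3, byrow = TRUE)
  Bd <- c(z$B1, z$B2, z$B3)
  structure(list(Ad = Ad, Bd = Bd, C = c(0, 0, 1),
                 T_s = T_s, delay = as.integer(delay)),
            class = "discrete_model")
}

#' One-step propagation of the discrete model
#'
#' @param model a [discretize()]d model.
#' @param x state `(R, P, G)` in fold-change units.
#' @param u fold-change input effective during the step (delay is the
#'   caller's bookkeeping: pass the input commanded `delay` steps ago).
#' @param d additive input disturbance.
#' @return Next state `(R, P, G)`.
#' @export
dm_step <- function(model, x, u, d = 0) {
  as.numeric(model$Ad %*% (x - 1)) + model$Bd * (u + d) + 1
}

#' Simulate the discrete model over a command sequence
#'
#' Propagates the ZOH model from an initial state under a sequence of
#' commanded fold-change inputs, honouring the model's input delay
#' (commands issued before the start default to `u_pre`).
#'
#' @param params a [model_params()] object.
#' @param u_seq commanded inputs `u[1..K]` (command `k` issued at time
#'   `(k-1) T_s`).
#' @param x0 initial state.
#' @param d additive disturbance (scalar or length-`K`).
#' @param u_pre input held before the experiment (default 0).
#' @return `data.frame(k, time, R, P, G)` for `k = 0..K`.
#' @export
simulate_discrete <- function(params, u_seq, x0 = c(1, 1, 1), d = 0,
                              u_pre = 0) {
  model <- discretize(params)
  K <- length(u_seq)
  d <- rep_len(d, K)
  out <- matrix(NA_real_, K + 1, 3)
  out[1, ] <- x0
  x <- x0
  for (k in seq_len(K)) {
    idx <- k - model$delay
    ueff <- if (idx >= 1) u_seq[idx] else u_pre
    x <- dm_step(model, x, ueff, d[k])
    out[k + 1, ] <- x
  }
  data.frame(k = 0:K, time = (0:K) * params$T_s,
             R = out[, 1], P = out[, 2], G = out[, 3])
}

#' Initialize a particle ensemble for joint state/parameter estimation
#'
#' Particles carry a fold-change state, the four rate parameters, and the
#' additive disturbance `d`.  Parameters are initialized log-normally
#' around the nominal fit; the disturbance starts at 0.
#'
#' @param n number of particles (default 2000).
#' @param params nominal [model_params()] centring the parameter prior.
#' @param x0 initial state (default rest).
#' @param spread prior standard deviation of log-parameters.
#' @return An object of class `particle_ensemble`.
#' @export
particle_ensemble <- function(n = 2000, params = nominal_model_params(),
                              x0 = c(1, 1, 1), spread = 0.15) {
  th0 <- log(c(params$d_r, params$d_p, params$b_r, params$k_m))
  lth <- matrix(stats::rnorm(n * 4, mean = rep(th0, each = n), sd = spread),
                n, 4)
  colnames(lth) <- c("d_r", "d_p", "b_r", "k_m")
  structure(list(X = matrix(rep(x0, each = n), n, 3),
                 log_theta = lth,
                 d = numeric(n),
                 w = rep(1 / n, n),
                 n = n, T_s = params$T_s,
                 ess = n),
            class = "particle_ensemble")
}

#' Particle-filter tuning constants
#'
#' @param sigma_y measurement noise, relative to the predicted output
#'   (Gaussian, default 3% of signal).
#' @param shrinkage Liu-West kernel shrinkage factor on log-parameters.
#' @param sigma_d random-walk standard deviation of the disturbance `d`
#'   per step.
#' @param d_bounds bounds of the disturbance random walk.
#' @param ess_frac resampling is triggered when the effective sample size
#'   drops below `ess_frac * n`.
#' @return A list of class `pf_config`.
#' @export
pf_config <- function(sigma_y = 0.03, shrinkage = 0.98, sigma_d = 0.01,
                      d_bounds = c(-2, 2), ess_frac = 0.5) {
  structure(list(sigma_y = sigma_y, shrinkage = shrinkage, sigma_d = sigma_d,
                 d_bounds = d_bounds, ess_frac = ess_frac),
            class = "pf_config")
}

systematic_resample <- function(w, n) {
  u <- (stats::runif(1) + 0:(n - 1)) / n
  findInterval(u, cumsum(w)) + 1L
}

#' One particle-filter update (propagate, weight, resample)
#'
#' Bootstrap filter step for the joint state/parameter/disturbance
#' posterior: parameters evolve by Liu-West kernel shrinkage on the log
#' scale, the disturbance by a bounded random walk, states by each
#' particle's own ZOH-discretized model, and weights by the Gaussian
#' measurement likelihood on the fluorescent-protein output.  Systematic
#' resampling is applied when the effective sample size falls below its
#' threshold.  A missing measurement (`NA`) propagates without
#' reweighting, so the controller can coast over a failed sample.
#'
#' @param ens a [particle_ensemble()].
#' @param u_applied fold-change input effective during the elapsed
#'   sampling period (after delay bookkeeping).
#' @param y measured fold-change output, or `NA` if the measurement
#'   failed.
#' @param cfg a [pf_config()].
#' @return The updated ensemble; point estimates via [pf_estimates()].
#' @export
pf_update <- function(ens, u_applied, y, cfg = pf_config()) {
  stopifnot(inherits(ens, "particle_ensemble"))
  n <- ens$n
  a <- cfg$shrinkage
  # Liu-West: shrink towards the weighted mean, jitter with h^2 * V
  m <- colSums(ens$log_theta * ens$w)
  V <- colSums((ens$log_theta - rep(m, each = n))^2 * ens$w)
  h <- sqrt(1 - a^2)
  lth <- a * ens$log_theta + (1 - a) * rep(m, each = n) +
    matrix(stats::rnorm(n * 4), n, 4) * rep(h * sqrt(pmax(V, 1e-12)),
                                            each = n)
  th <- exp(lth)
  d <- ens$d + stats::rnorm(n, 0, cfg$sigma_d)
  d <- pmin(pmax(d, cfg$d_bounds[1]), cfg$d_bounds[2])
  z <- zoh_factors(th[, 1], th[, 2], th[, 3], th[, 4], ens$T_s)
  x1 <- ens$X[, 1] - 1; x2 <- ens$X[, 2] - 1; x3 <- ens$X[, 3] - 1
  uin <- u_applied + d
  X <- cbind(z$A11 * x1 + z$B1 * uin,
             z$A21 * x1 + z$A22 * x2 + z$B2 * uin,
             z$A31 * x1 + z$A32 * x2 + z$A33 * x3 + z$B3 * uin) + 1
  w <- ens$w
  if (!is.na(y)) {
    sd_y <- cfg$sigma_y * pmax(abs(X[, 3]), 0.1)
    lik <- stats::dnorm(y, mean = X[, 3], sd = sd_y)
    w <- w * lik
    tot <- sum(w)
    if (!is.finite(tot) || tot <= 0) {
      warning("degenerate likelihood: reinitializing weights uniformly")
      w <- rep(1 / n, n)
    } else {
      w <- w / tot
    }
  }
  ess <- 1 / sum(w^2)
  if (ess < cfg$ess_frac * n) {
    idx <- systematic_resample(w, n)
    X <- X[idx, , drop = FALSE]
    lth <- lth[idx, , drop = FALSE]
    d <- d[idx]
    w <- rep(1 / n, n)
    ess <- n
  }
  ens$X <- X
  ens$log_theta <- lth
  ens$d <- d
  ens$w <- w
  ens$ess <- ess
  ens
}

#' Point estimates from a particle ensemble
#'
#' @param ens a [particle_ensemble()].
#' @return List with weighted-mean state `x`, rate estimates `theta`
#'   (named, natural scale), disturbance `d`, its posterior standard
#'   deviation `d_sd`, and the effective sample size `ess`.
#' @export
pf_estimates <- function(ens) {
  x <- colSums(ens$X * ens$w)
  th <- exp(colSums(ens$log_theta * ens$w))
  names(th) <- c("d_r", "d_p", "b_r", "k_m")
  dbar <- sum(ens$d * ens$w)
  dsd <- sqrt(max(sum((ens$d - dbar)^2 * ens$w), 0))
  list(x = x, theta = th, d = dbar, d_sd = dsd, ess = ens$ess)
}

#' Maximum-likelihood calibration from characterization traces
#'
#' Fits the four rate constants of the fold-change model to one or more
#' characterization traces (columns `time_min`, `U_pct`, `G_fold`;
#' typically a step response plus a few PI closed-loop responses) by
#' maximizing the Gaussian measurement likelihood under the deterministic
#' ZOH model, i.e. nonlinear least squares on the predicted output, with
#' a multistart over log-parameter perturbations to escape local optima.
#'
#' @param traces a `data.frame` or list of `data.frame`s with columns
#'   `time_min` (at `T_s` spacing from 0), `U_pct`, `G_fold`.
#' @param dr [dose_response()] map converting `U_pct` to input units.
#' @param params0 starting [model_params()] (also fixes `T_s` and delay).
#' @param n_starts number of multistart points (first is unperturbed).
#' @param spread log-scale standard deviation of the start perturbations.
#' @return List of class `ml_fit`: `params`, residual `rss`, noise
#'   estimate `sigma`, `logLik`, per-start objective values.
#' @export
fit_model_ml <- function(traces, dr = dose_response(),
                         params0 = nominal_model_params(),
                         n_starts = 5, spread = 0.3) {
  if (is.data.frame(traces)) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  n_obs <- sum(vapply(traces, nrow, integer(1)))
  if (n_obs < 10) stop("need at least 10 samples to fit", call. = FALSE)
  T_s <- params0$T_s
  delay <- params0$input_delay_steps
  pre <- lapply(traces, function(tr) {
    stopifnot(all(c("time_min", "U_pct", "G_fold") %in% names(tr)))
    tr <- tr[order(tr$time_min), ]
    if (any(abs(diff(tr$time_min) - T_s) > 1e-6)) {
      stop("trace timestamps must be strictly increasing at T_s spacing",
           call. = FALSE)
    }
    list(u = dose_response_eval(dr, tr$U_pct), y = tr$G_fold)
  })
  if (all(vapply(pre, function(p) length(unique(round(p$u, 10))) == 1,
                 logical(1)))) {
    warning("constant-input traces: parameters are weakly identifiable; ",
            "expect wide confidence intervals")
  }
  sse <- function(lth) {
    th <- exp(lth)
    z <- zoh_factors(th[1], th[2], th[3], th[4], T_s)
    s <- 0
    for (p in pre) {
      K <- length(p$u)
      x1 <- 0; x2 <- 0; x3 <- 0
      g <- numeric(K)
      g[1] <- 1
      for (k in seq_len(K - 1)) {
        idx <- k - delay
        ueff <- if (idx >= 1) p$u[idx] else 0
        n1 <- z$A11 * x1 + z$B1 * ueff
        n2 <- z$A21 * x1 + z$A22 * x2 + z$B2 * ueff
        n3 <- z$A31 * x1 + z$A32 * x2 + z$A33 * x3 + z$B3 * ueff
        x1 <- n1; x2 <- n2; x3 <- n3
        g[k + 1] <- x3 + 1
      }
      s <- s + sum((g - p$y)^2)
    }
    s
  }
  th0 <- log(c(params0$d_r, params0$d_p, params0$b_r, params0$k_m))
  best <- NULL
  values <- numeric(n_starts)
  for (i in seq_len(n_starts)) {
    start <- if (i == 1) th0 else th0 + stats::rnorm(4, 0, spread)
    fit <- stats::optim(start, sse, method = "L-BFGS-B",
                        lower = log(1e-4), upper = log(1),
                        control = list(maxit = 500))
    values[i] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th <- exp(best$par)
  sigma <- sqrt(best$value / n_obs)
  structure(list(
    params = model_params(d_r = th[1], d_p = th[2], b_r = th[3], k_m = th[4],
                          T_s = T_s, input_delay_steps = delay),
    rss = best$value, sigma = sigma,
    logLik = -n_obs / 2 * (log(2 * pi * sigma^2) + 1),
    start_values = values, convergence = best$convergence),
    class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("Maximum-likelihood model fit\n")
  print(x$params)
  cat(sprintf("  rss = %.4g, sigma = %.4g, logLik = %.4g\n",
              x$rss, x$sigma, x$logLik))
  invisible(x)
}
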