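# Shared oracles: dense matrix-exponential reference for the ZOH
# discretization, naive brute-force computations, and trace builders.

# continuous-time system matrix of the fold-change model (deviations
# from the rest state)
fold_A <- function(p) {
  matrix(c(-p$d_r, 0, 0,
           p$d_p + p$k_m, -(p$d_p + p$k_m), 0,
           0, p$d_p, -p$d_p), 3, 3, byrow = TRUE)
}

fold_B <- function(p) c(p$b_r, 0, 0)

# dense matrix-exponential ZOH oracle (independent of the package's
# closed form)
zoh_oracle <- function(p, T_s = p$T_s) {
  A <- fold_A(p)
  Ad <- as.matrix(Matrix::expm(A * T_s))
  Bd <- solve(A, (Ad - diag(3)) %*% fold_B(p))
  list(Ad = Ad, Bd = as.numeric(Bd))
}

# closed-form LTI step response from rest: x(t) = 1 + A^-1(e^{At}-I) B u
step_response_oracle <- function(p, u, times) {
  A <- fold_A(p)
  B <- fold_B(p)
  t(vapply(times, function(t) {
    if (t == 0) return(c(1, 1, 1))
    E <- as.matrix(Matrix::expm(A * t))
    1 + as.numeric(solve(A, (E - diag(3)) %*% B)) * u
  }, numeric(3)))
}

# random plausible model parameters (positive rates; distinct timescales)
random_params <- function() {
  model_params(d_r = exp(stats::runif(1, log(0.03), log(0.3))),
               d_p = exp(stats::runif(1, log(0.008), log(0.05))),
               b_r = exp(stats::runif(1, log(0.03), log(0.3))),
               k_m = exp(stats::runif(1, log(0.004), log(0.05))),
               T_s = 10)
}

# simulate a characterization trace from the discrete nominal model
make_characterization_trace <- function(U_seq, noise_sd = 0,
                                        p = nominal_model_params(),
                                        dr = dose_response()) {
  u <- dose_response_eval(dr, U_seq)
  s <- simulate_discrete(p, u)
  K <- length(U_seq)
  g <- s$G[1:K]
  if (noise_sd > 0) g <- g * (1 + stats::rnorm(K, 0, noise_sd))
  data.frame(time_min = s$time[1:K], U_pct = U_seq, G_fold = g)
}

nominal_rates <- c(d_r = 0.0956, d_p = 0.0214, b_r = 0.0965, k_m = 0.0116)
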