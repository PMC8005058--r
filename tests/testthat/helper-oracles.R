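# Shared helpers: synthetic interferograms and independent oracles.

wrap_pi <- function(x) atan2(sin(x), cos(x))

# Synthetic interferogram with an integer number of fringes k and phase
# phi_c at the centre sample (the package's sweep-centre phase convention).
synth_cosine <- function(phi_c, k, n = 1000, dc = 0.6, amp = 0.5) {
  i <- seq_len(n) - 1
  ic <- (n - 1) / 2
  dc + amp * cos(phi_c - 2 * pi * k * (i - ic) / n)
}

# Independent oracle: nonlinear least-squares cosine fit of the centre phase,
# model x_i = C + a*cos(phi - w*(i - ic)). Gauss-Newton with the analytic
# Jacobian from a coarse-grid start; quadratic convergence takes it to
# machine precision even on zero-residual data, where off-the-shelf nls
# drivers stop at their ftol.
fit_cosine_phase <- function(x, k) {
  n <- length(x)
  i <- seq_len(n) - 1
  ic <- (n - 1) / 2
  w <- 2 * pi * k / n
  a0 <- diff(range(x)) / 2
  grid <- seq(-pi, pi, length.out = 73)
  sse <- vapply(grid, function(p) {
    sum((x - mean(x) - a0 * cos(p - w * (i - ic)))^2)
  }, numeric(1))
  beta <- c(C = mean(x), a = a0, phi = grid[which.min(sse)])
  for (iter in 1:100) {
    co <- cos(beta[3] - w * (i - ic))
    si <- sin(beta[3] - w * (i - ic))
    r <- x - beta[1] - beta[2] * co
    J <- cbind(1, co, -beta[2] * si)
    delta <- solve(crossprod(J), crossprod(J, r))
    beta <- beta + as.vector(delta)
    if (max(abs(delta)) < 1e-14) break
  }
  wrap_pi(beta[[3]])
}

# Analyte state with an arbitrary imposed wavelength-shift trajectory (pm)
# on channel 1 and zero elsewhere; for closed-loop demodulation tests.
state_with_trajectory <- function(shift_pm_fun, duration_s, dt_s = 0.1) {
  st <- run_assay_program(list(flow_step("buffer", duration_s)), dt_s = dt_s)
  st$surface_shift_pm[, 1] <- shift_pm_fun(st$time_s)
  st
}
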