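# Independent oracles used across the suite.  Deliberately written
# against the model equations directly, not against package internals.

# Pure-R classical RK4 for dtheta/dt = (b - A cos(Om t)) + (1 + A cos(Om t)) cos(theta)
rk4_steady_oracle <- function(b, A, Om, theta0, dt, nstep) {
  rhs <- function(t, th) (b - A * cos(Om * t)) + (1 + A * cos(Om * t)) * cos(th)
  th <- numeric(nstep + 1)
  th[1] <- theta0
  for (k in seq_len(nstep)) {
    t <- (k - 1) * dt
    k1 <- rhs(t, th[k])
    k2 <- rhs(t + dt / 2, th[k] + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, th[k] + dt / 2 * k2)
    k4 <- rhs(t + dt, th[k] + dt * k3)
    th[k + 1] <- th[k] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  th
}

# Pure-R RK4 for the constant-a half-width relaxation dw/dt = a (sqrt(D) - w)
rk4_width_oracle <- function(w0, a, D, dt, nstep) {
  rhs <- function(w) a * (sqrt(D) - w)
  w <- numeric(nstep + 1)
  w[1] <- w0
  for (k in seq_len(nstep)) {
    k1 <- rhs(w[k])
    k2 <- rhs(w[k] + dt / 2 * k1)
    k3 <- rhs(w[k] + dt / 2 * k2)
    k4 <- rhs(w[k] + dt * k3)
    w[k + 1] <- w[k] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  w
}

# build a trajectory-shaped data frame from a constructed phase series
constructed_traj <- function(t, theta) data.frame(t = t, theta = theta)

default_set <- default_tanh_params()
roper_set <- roper_linear_params()
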