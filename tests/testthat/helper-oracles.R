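# Independent RK4 on the dimensional four-constant kinetics
# dy/dt = k0 s(t) - k1 y + k2 y^n / (k3^n + y^n); used as a dual-simulation
# oracle against the reduced form, so it deliberately shares no code with
# the package integrator.
rk4_dimensional <- function(k0, k1, k2, k3, n, s_fun, y0, t_end, dt) {
  f <- function(t, y) {
    y <- max(y, 0)
    k0 * s_fun(t) - k1 * y + k2 * y^n / (k3^n + y^n)
  }
  nt <- round(t_end / dt)
  tt <- numeric(nt + 1)
  yy <- numeric(nt + 1)
  yy[1] <- y0
  for (k in seq_len(nt)) {
    t <- (k - 1) * dt
    y <- yy[k]
    a1 <- f(t, y)
    a2 <- f(t + dt / 2, y + dt / 2 * a1)
    a3 <- f(t + dt / 2, y + dt / 2 * a2)
    a4 <- f(t + dt, y + dt * a3)
    yy[k + 1] <- max(0, y + dt / 6 * (a1 + 2 * a2 + 2 * a3 + a4))
    tt[k + 1] <- t + dt
  }
  list(t = tt, y = yy)
}

# brute-force count of non-negative roots of c - r x + x^2/(1+x^2) via the
# equivalent cubic, independent of the package's root finder
count_roots_n2 <- function(c, r) {
  z <- polyroot(c(c, -r, c + 1, -r))
  x <- Re(z[abs(Im(z)) < 1e-7])
  sum(x > -1e-9)
}

expect_within <- function(object, target, tol) {
  expect_lte(abs(object - target), tol)
}
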