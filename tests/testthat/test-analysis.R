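test_that("the convergence expression matches its closed forms", {
  # n = 2 factorization
  u <- c(0.2, 0.7, 1.3)
  x <- c(1.1, 0.1, 2.4)
  expect_equal(p_uniqueness(u, x, 2),
               (u + x) / ((1 + u^2) * (1 + x^2)), tolerance = 1e-12)
  expect_equal(p_uniqueness(1, 1, 2), 0.5)
  # diagonal limit equals the Hill-term derivative, and p is continuous there
  for (n in c(1.3, 2, 2.7)) {
    xs <- c(0.3, 0.8, 1.5)
    expect_equal(p_uniqueness(xs, xs, n), n * xs^(n - 1) / (1 + xs^n)^2,
                 tolerance = 1e-12)
    expect_equal(p_uniqueness(xs + 1e-10, xs, n), p_uniqueness(xs, xs, n),
                 tolerance = 1e-6)
    expect_equal(p_uniqueness(xs + 1e-7, xs, n), p_uniqueness(xs, xs, n),
                 tolerance = 1e-5)
  }
  # symmetry
  expect_equal(p_uniqueness(0.4, 1.9, 1.7), p_uniqueness(1.9, 0.4, 1.7))
  expect_error(p_uniqueness(-1, 1, 2), "> 0")
})

test_that("max_p agrees with dense-grid oracles and analytic values", {
  # n = 2: analytic 3*sqrt(3)/8 at 1/sqrt(3)
  m2 <- max_p(2)
  expect_lt(abs(m2$value - 3 * sqrt(3) / 8), 1e-12)
  expect_lt(abs(m2$x_at_max - 1 / sqrt(3)), 1e-6)
  # 2-D grid oracle confirms the diagonal carries the global maximum
  g <- exp(seq(log(1e-3), log(30), length.out = 400))
  for (n in c(1.6, 2, 3)) {
    grid2d <- max(outer(g, g, function(u, x) p_uniqueness(u, x, n)))
    expect_lte(grid2d, max_p(n)$value + 1e-6)
  }
  # 1-D dense grid oracle for the diagonal itself
  gd <- exp(seq(log(1e-3), log(50), length.out = 20000))
  for (n in c(1.6, 2, 3, 4)) {
    expect_within(max_p(n)$value, max(n * gd^(n - 1) / (1 + gd^n)^2), 1e-6)
  }
  expect_equal(max_p(1.6)$value, 0.60948, tolerance = 1e-4)
  # boundary cases: supremum at the origin for n <= 1
  m1 <- max_p(1)
  expect_true(m1$boundary)
  expect_equal(m1$value, 1)
  expect_true(is.infinite(max_p(0.5)$value))
})

test_that("the optimal exponent minimizes the convergence threshold", {
  res <- argmin_max_p(0.1, 4)
  # interior minimum near 1.54; the coarse printed value is 1.55
  expect_within(res$n_star, 1.55, 0.0100001)
  expect_false(res$boundary)
  # independent grid-scan oracle
  ns <- seq(1.05, 4, by = 0.005)
  vals <- vapply(ns, function(n) max_p(n)$value, numeric(1))
  expect_within(res$n_star_raw, ns[which.min(vals)], 0.005)
  # local-minimum structure around the printed value
  expect_lt(max_p(1.55)$value, max_p(1.5)$value)
  expect_lt(max_p(1.55)$value, max_p(1.6)$value)
  # boundary search interval
  expect_equal(argmin_max_p(2, 4)$n_star, 2)
  expect_true(argmin_max_p(2, 4)$boundary)
})

test_that("the exponential bound holds for the reference initial conditions", {
  p <- switch_params(r = 0.7, c0 = 0.04, T = 0.01)
  sig <- sinusoidal_input(0.04, 0.02, 2, duration = 1)
  u <- simulate_switch(p, sig, x0 = 1.7)
  x <- simulate_switch(p, sig, x0 = 0.1)
  gc <- gronwall_check(u, x, p)
  expect_gt(min(gc$margin), -1e-6)
  expect_equal(attr(gc, "rate"), (0.7 - 3 * sqrt(3) / 8) / 0.01, tolerance = 1e-9)
  # identical starts keep a zero gap
  g0 <- gronwall_check(x, x, p)
  expect_true(all(g0$gap == 0))
  expect_error(gronwall_check(u, x[1:50, ], p), "grid")
})

test_that("slower switches converge later", {
  tconv <- vapply(c(0.005, 0.01, 0.02, 0.05), function(Tval) {
    p <- switch_params(r = 0.7, c0 = 0.04, T = Tval)
    sig <- sinusoidal_input(0.04, 0.02, 2, duration = 2)
    u <- simulate_switch(p, sig, x0 = 1.7)
    x <- simulate_switch(p, sig, x0 = 0.1)
    u$t[which(abs(u$x - x$x) < 0.01)[1]]
  }, numeric(1))
  expect_false(is.unsorted(tconv, strictly = TRUE))
})

test_that("interval increments count and sign out correctly", {
  tr <- regular_pulse_train(2, 6, duration = 3.5)
  sig <- pulses_to_calcium(tr, delta_c = 0.2, c0 = 0.04)
  p <- switch_params(r = 0.61, c0 = 0.04, n = 1.6, T = 0.01)
  traj <- simulate_switch(p, sig)
  d <- interval_deltas(traj, tr)
  expect_equal(nrow(d), nrow(tr) - 1)     # one delta per inter-pulse interval
  expect_true(all(d$delta > 0))           # each pulse evokes a rise
  # at equilibrium with no pulses the increments vanish
  flat <- sinusoidal_input(0.04, 0, 2, duration = 3.5)
  eqtraj <- simulate_switch(p, flat)
  d0 <- interval_deltas(eqtraj, tr)
  expect_true(all(abs(d0$delta) < 1e-6))
  # fewer than 2 pulses: empty result
  one <- regular_pulse_train(1, 1, duration = 2)
  expect_equal(nrow(interval_deltas(traj[traj$t <= 2, ], one)), 0)
})

test_that("identical baselines give vanishing paired discrepancy", {
  d <- discrepancy_experiment(0.59, trials = 2, duration = 5,
                              c0_ref = 0.04, c0_alt = 0.04, seed = 7)
  expect_lt(d$discrepancy, 1e-12)
})

test_that("paired trains reduce discrepancy variance versus independent ones", {
  # sharing the pulse train across arms removes train-to-train variance
  paired <- vapply(1:6, function(s)
    discrepancy_experiment(0.59, trials = 1, duration = 10, seed = s)$discrepancy,
    numeric(1))
  indep <- vapply(1:6, function(s) {
    t1 <- poisson_pulse_train(8, 10, seed = 100 + s)
    t2 <- poisson_pulse_train(8, 10, seed = 200 + s)
    s1 <- pulses_to_calcium(t1, delta_c = 0.5, c0 = 0.02)
    s2 <- pulses_to_calcium(t2, delta_c = 0.5, c0 = 0.04)
    p1 <- switch_params(r = 0.59, c0 = 0.02)
    p2 <- switch_params(r = 0.59, c0 = 0.04)
    dx <- interval_deltas(simulate_switch(p1, s1), t1)$delta
    du <- interval_deltas(simulate_switch(p2, s2), t2)$delta
    k <- min(length(dx), length(du))
    mean(abs(du[seq_len(k)] - dx[seq_len(k)]))
  }, numeric(1))
  expect_lt(stats::var(paired), stats::var(indep))
})

test_that("spectral gain is exact for identity and scales with power", {
  sig <- sinusoidal_input(0.04, 0.02, 2, duration = 20)
  traj <- structure(tibble::tibble(t = sig$t, x = sig$c),
                    class = c("switch_trajectory", class(tibble::tibble())))
  expect_within(spectral_gain(traj, sig, 2), 1, 1e-10)
  traj2 <- traj
  traj2$x <- 0.04 + 2 * (sig$c - 0.04)   # doubled amplitude at the probe bin
  expect_within(spectral_gain(traj2, sig, 2), 4, 1e-9)
  expect_error(spectral_gain(traj, sig, 600), "Nyquist")
})

test_that("the noisy switch oscillates at the drive frequency", {
  p <- switch_params(r = 0.61, c0 = 0.04, n = 1.6, T = 0.01)
  sig <- sinusoidal_input(0.04, 0.02, 2, duration = 60)
  tr <- simulate_switch_noisy(p, sig, sigma = 0.09, seed = 21)
  pg <- switchdyn:::periodogram_power(tr$x, 0.001)
  nontrivial <- pg$freq > 0.2  # skip the slow drift / DC leakage band
  fpeak <- pg$freq[nontrivial][which.max(pg$power[nontrivial])]
  expect_within(fpeak, 2, 0.05)
})

test_that("activation histograms detect uni- and bimodal regimes", {
  p <- switch_params(r = 0.61, c0 = 0.04, n = 1.6, T = 0.01)
  # deterministic equilibrium: a single occupied mode
  flat <- simulate_switch(p, sinusoidal_input(0.04, 0, duration = 30))
  h0 <- activation_histogram(flat, burn_in = 5)
  expect_equal(h0$modality, 1L)
  sig <- sinusoidal_input(0.04, 0.02, 2, duration = 100)
  h_lo <- activation_histogram(simulate_switch_noisy(p, sig, 0.01, seed = 101),
                               burn_in = 10)
  expect_equal(h_lo$modality, 2L)
  h_hi <- activation_histogram(simulate_switch_noisy(p, sig, 0.035, seed = 101),
                               burn_in = 10)
  expect_equal(h_hi$modality, 1L)
  expect_equal(sum(h_lo$counts), h_lo$n)  # counts account for every sample
})

test_that("burst detection flips on closely spaced pulses only", {
  # two pulses at 5 Hz spacing with zero baseline: no hysteresis, stays low
  b1 <- burst_detection_protocol(c(0.5, 0.7), tibble::tibble(time = 0, c0 = 0),
                                 duration = 2)
  expect_true(all(b1$state == "low"))
  # 10 Hz inter-pulse interval with augmented baseline: flips high and stays
  b2 <- burst_detection_protocol(c(0.5, 0.6), tibble::tibble(time = 0, c0 = 0.04),
                                 duration = 2)
  expect_equal(tail(b2$state, 1), "high")
  expect_true(all(b2$state[b2$t > 0.8] == "high"))
  # the static augmented baseline alone cannot generate the up state
  b3 <- burst_detection_protocol(numeric(0) + 1.5,
                                 tibble::tibble(time = 0, c0 = 0.04),
                                 delta_c = 0, duration = 2)
  expect_true(all(b3$state == "low"))
  # a single pulse cannot cross the separatrix at the calibrated amplitude
  b4 <- burst_detection_protocol(0.5, tibble::tibble(time = 0, c0 = 0.04),
                                 duration = 2)
  expect_equal(tail(b4$state, 1), "low")
})

test_that("trace alignment recovers offsets exactly", {
  a <- sin(seq(0, 10, by = 0.01))
  expect_equal(align_offset(a, a), 0)
  expect_equal(align_offset(a, a - 3), 3, tolerance = 1e-12)
  # closed form matches a numeric scan
  b <- a + 0.92 + stats::rnorm(length(a), sd = 0.05)
  off <- align_offset(b, a)
  scan <- seq(off - 0.1, off + 0.1, by = 1e-4)
  sse <- vapply(scan, function(o) sum((b - (a + o))^2), numeric(1))
  expect_within(off, scan[which.min(sse)], 1e-4)
  expect_error(align_offset(a, a[-1]), "length")
})

test_that("tidiers summarize result objects", {
  eq <- fixed_points(0.04, 0.52)
  td <- tidy(eq)
  expect_true(all(c("x", "stability", "c", "r", "n") %in% names(td)))
  gl <- glance(eq)
  expect_equal(gl$n_fixed, 3)
  expect_equal(gl$regime, "bistable")
})
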