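test_that("Poisson trains are reproducible with exponential gaps", {
  expect_equal(nrow(poisson_pulse_train(0, 10, seed = 1)), 0)
  a <- poisson_pulse_train(8, 50, seed = 42)
  b <- poisson_pulse_train(8, 50, seed = 42)
  expect_equal(a$time, b$time)
  expect_false(is.unsorted(a$time, strictly = TRUE))
  expect_true(all(a$time >= 0 & a$time <= 50))
  # gap distribution: KS against exponential(8) across pooled seeds
  gaps <- unlist(lapply(1:20, function(s) diff(poisson_pulse_train(8, 50, seed = s)$time)))
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", 8))
  expect_gt(ks$p.value, 0.01)
})

test_that("pulse-count distribution is Poisson(rate * duration)", {
  counts <- vapply(1:1000, function(s) nrow(poisson_pulse_train(5, 4, seed = s)),
                   numeric(1))
  lam <- 20
  edges <- c(-Inf, 12, 15, 18, 21, 24, 27, Inf)
  obs <- table(cut(counts, edges))
  pr <- diff(stats::ppois(c(-1, 12, 15, 18, 21, 24, 27, Inf), lam))
  gof <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("alpha-kernel calcium honours peak timing, normalization and causality", {
  tr <- poisson_pulse_train(8, 2, seed = 3)
  sig <- pulses_to_calcium(tr, tau_c = 0.03, delta_c = 0.5, c0 = 0.04)
  expect_equal(max(sig$c), 0.54, tolerance = 1e-12)  # max(c) - c0 = delta_c exactly
  expect_true(all(sig$c >= 0.04 - 1e-12))
  # single isolated pulse peaks at t0 + tau_c with value c0 + delta_c
  one <- tibble::tibble(time = 0.5)
  attr(one, "duration") <- 2
  class(one) <- c("pulse_train", class(one))
  s1 <- pulses_to_calcium(one, tau_c = 0.03, delta_c = 0.5, c0 = 0.04)
  expect_equal(s1$t[which.max(s1$c)], 0.53, tolerance = 1e-9)
  expect_equal(max(s1$c), 0.54, tolerance = 1e-12)
  # causality: adding a later pulse leaves earlier samples untouched (up to
  # the shared normalization, which equal peak heights preserve)
  two <- tibble::tibble(time = c(0.5, 1.6))
  attr(two, "duration") <- 2
  class(two) <- c("pulse_train", class(two))
  s2 <- pulses_to_calcium(two, tau_c = 0.03, delta_c = 0.5, c0 = 0.04)
  upto <- s1$t <= 1.4
  expect_equal(s2$c[upto], s1$c[upto], tolerance = 1e-9)
  # empty train: flat baseline
  s0 <- pulses_to_calcium(poisson_pulse_train(0, 1, seed = 1), c0 = 0.04,
                          duration = 1)
  expect_true(all(s0$c == 0.04))
})

test_that("sinusoidal input has exact range, mean and constraint warning", {
  sig <- sinusoidal_input(0.04, 0.02, 2, duration = 3)
  expect_equal(min(sig$c), 0.02, tolerance = 1e-12)
  expect_equal(max(sig$c), 0.06, tolerance = 1e-12)
  whole <- sig$t < 3  # integer number of periods at 2 Hz
  expect_equal(mean(sig$c[whole]), 0.04, tolerance = 1e-12)
  flat <- sinusoidal_input(0.04, 0, 2, duration = 1)
  expect_true(all(flat$c == 0.04))
  expect_warning(sinusoidal_input(0.01, 0.02, 2, duration = 1), "floored")
})

test_that("exponential-decay calcium superposes per-pulse decays", {
  one <- regular_pulse_train(1, 1, duration = 1)
  s1 <- exp_decay_calcium(one, tau = 0.2, delta_c = 0.5, c0 = 0)
  expect_equal(max(s1$c), 0.5, tolerance = 1e-12)   # jump by delta_c at the pulse
  k <- round(0.4 / 0.001)
  expect_equal(s1$c[1 + k], 0.5 * exp(-0.4 / 0.2), tolerance = 1e-9)
  # 1 Hz steady state: pre-pulse residual tends to delta_c e^-5 / (1 - e^-5)
  tr <- regular_pulse_train(1, 25, duration = 25)
  s <- exp_decay_calcium(tr, tau = 0.2, delta_c = 0.5, c0 = 0)
  pre <- s$c[1 + round(19.999 / 0.001)]   # just before the pulse at t = 20
  expect_equal(pre, 0.5 * exp(-0.999 / 0.2) / (1 - exp(-5)), tolerance = 1e-6)
  expect_within(pre, 0.5 * exp(-5) / (1 - exp(-5)), 2e-5)
})

test_that("OU paths decay deterministically, reproduce, and hit their variance", {
  # sigma = 0: pure relaxation at the discrete rate (1 - dt/tau)^k
  ou0 <- ou_noise_path(0, 0.01, duration = 0.05, eta0 = 1)
  k <- seq_len(nrow(ou0)) - 1
  expect_equal(ou0$eta, (1 - 0.1)^k, tolerance = 1e-12)
  expect_within(ou0$eta[31], exp(-0.03 / 0.01), 0.01)
  a <- ou_noise_path(0.3, 0.01, duration = 5, seed = 9)
  b <- ou_noise_path(0.3, 0.01, duration = 5, seed = 9)
  expect_equal(a$eta, b$eta)
  # stationary variance of the discrete chain: sigma^2 (dt/tau) / (1 - a^2),
  # which tends to sigma^2/2 as dt -> 0
  long <- ou_noise_path(0.3, 0.01, duration = 1000, seed = 5)
  v_exact <- 0.3^2 * 0.1 / (1 - 0.9^2)
  expect_within(stats::var(long$eta) / v_exact, 1, 0.05)
  expect_error(ou_noise_path(0.1, 0.001, duration = 1, dt = 0.001), "unstable")
})

test_that("OU autocorrelation decays by about e^-1 over one correlation time", {
  long <- ou_noise_path(0.5, 0.01, duration = 1000, seed = 7)
  lag <- 10  # tau_eta / dt
  e <- long$eta
  rho <- stats::cor(e[seq_len(length(e) - lag)], e[-seq_len(lag)])
  expect_within(rho / exp(-1), 1, 0.1)
})
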