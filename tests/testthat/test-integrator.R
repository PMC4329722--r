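test_that("a Heun step leaves an equilibrium fixed under zero noise", {
  eq <- upper_equilibrium(90)
  net <- jr_network(N = 1, K = 0, p_const = 90)
  out <- heun_step(matrix(eq, 6, 1), 0, 0, 1e-3, canon, net,
                   ou_config(D = 0, tau = 0.15))
  expect_equal(as.numeric(out$columns), eq, tolerance = 1e-12)
  expect_equal(out$noise, 0)
})

test_that("deterministic trajectories match a high-accuracy reference", {
  skip_if_not_installed("deSolve")
  f <- function(t, y, parms) list(column_derivatives(y, 100, canon))
  ref <- deSolve::ode(rep(0, 6), c(0, 5), f, NULL, method = "ode45",
                      atol = 1e-12, rtol = 1e-12)
  ts <- det_run(100, duration = 5, transient = 0)
  expect_lt(abs((ref[2, 3] - ref[2, 4]) - tail(ts$average, 1)), 1e-3)
})

test_that("deterministic global error scales like h^2", {
  skip_if_not_installed("deSolve")
  f <- function(t, y, parms) list(column_derivatives(y, 100, canon))
  ref <- deSolve::ode(rep(0, 6), seq(0, 2, by = 1e-3), f, NULL,
                      method = "ode45", atol = 1e-12, rtol = 1e-12)
  vref <- ref[, 3] - ref[, 4]
  err <- vapply(c(1e-3, 5e-4), function(h) {
    ts <- simulate_network(
      jr_network(N = 1, K = 0, p_const = 100), ou = ou_config(D = 0),
      sim = sim_config(h = h, duration = 2, transient = 0, seed = 1,
                       record_stride = round(1e-3 / h)))
    max(abs(ts$average - vref))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 6)
})

test_that("below the first Hopf point the column settles onto the fixed point", {
  ts <- det_run(80, duration = 50, transient = 0)
  d <- column_derivatives(ts$final_state$columns[, 1], 80, canon)
  expect_lt(sqrt(sum(d^2)), 1e-6)
})

test_that("inside the alpha window the column sustains an 8-13 Hz cycle", {
  init <- upper_equilibrium(100)
  init[2] <- init[2] + 2
  ts <- det_run(100, init = init, duration = 50, transient = 10)
  cls <- classify_attractor(ts$average, ts$fs)
  expect_equal(cls$label, "alpha_cycle")
  expect_gt(cls$dominant_frequency, 8)
  expect_lt(cls$dominant_frequency, 13)
})

test_that("identical seeds give bit-identical stochastic runs", {
  args <- list(net = jr_network(N = 2, K = 15, p_const = 75),
               sim = sim_config(duration = 5, transient = 1, seed = 77))
  a <- do.call(simulate_network, args)
  b <- do.call(simulate_network, args)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$final_state, b$final_state)
})

test_that("compiled and plain-R engines agree", {
  for (D in c(0, 350)) {
    a <- simulate_network(jr_network(N = 2, K = 15, p_const = 75),
                          ou = ou_config(D = D, tau = 0.15),
                          sim = sim_config(duration = 0.5, transient = 0,
                                           seed = 5),
                          engine = "cpp")
    b <- simulate_network(jr_network(N = 2, K = 15, p_const = 75),
                          ou = ou_config(D = D, tau = 0.15),
                          sim = sim_config(duration = 0.5, transient = 0,
                                           seed = 5),
                          engine = "r")
    expect_equal(a$eeg, b$eeg, tolerance = 1e-12)
    expect_equal(a$final_state$noise, b$final_state$noise,
                 tolerance = 1e-12)
  }
})

test_that("a shared noise stream keeps identical columns identical", {
  ts <- simulate_network(jr_network(N = 4, K = 15, p_const = 75),
                         sim = sim_config(duration = 5, transient = 0,
                                          seed = 3),
                         shared_noise = TRUE)
  for (i in 2:4) expect_identical(ts$eeg[, i], ts$eeg[, 1])
})

test_that("per-column noise substreams do not depend on network size", {
  w2 <- white_noise_matrix(100, 2, seed = 5)
  w4 <- white_noise_matrix(100, 4, seed = 5)
  expect_identical(w2, w4[, 1:2])
})

test_that("transient removal respects the boundary convention", {
  ts <- simulate_network(jr_network(N = 1, K = 0, p_const = 80),
                         ou = ou_config(D = 0),
                         sim = sim_config(duration = 30, transient = 0,
                                          seed = 1))
  expect_identical(discard_transient(ts, 0), ts)
  cut <- discard_transient(ts, 10)
  expect_equal(length(cut$average), 20000 + 1)
  # a cut between samples keeps the first sample with t >= t_cut
  cut2 <- discard_transient(ts, 10.0005)
  expect_equal(length(cut2$average), 20000)
  expect_error(discard_transient(ts, 40), "duration")
})

test_that("time series round-trip through plain text bit-exactly", {
  ts <- simulate_network(jr_network(N = 2, K = 15, p_const = 75),
                         sim = sim_config(duration = 2, transient = 0,
                                          seed = 13),
                         record_coupling = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_timeseries(ts, path)
  back <- read_timeseries(path)
  expect_identical(back$eeg, ts$eeg)
  expect_identical(back$average, ts$average)
  expect_identical(back$coupling, ts$coupling)
  expect_identical(back$time, ts$time)
  expect_identical(back$fs, ts$fs)
  unlink(path)
})

test_that("simulation configuration validates its invariants", {
  expect_error(sim_config(h = 0), "h")
  expect_error(sim_config(duration = 5, transient = 5), "transient")
  expect_error(sim_config(record_stride = 0), "record_stride")
})
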