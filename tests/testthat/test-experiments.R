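test_that("with zero coupling the mean effective input is the constant input", {
  ts <- simulate_network(jr_network(N = 4, K = 0, p_const = 75),
                         sim = sim_config(duration = 5, transient = 1,
                                          seed = 2),
                         record_coupling = TRUE)
  mi <- mean_effective_input(ts)
  expect_equal(mi$mean_total, 75)
  expect_equal(mi$coupling_mean, 0)
})

test_that("effective-input statistics require a coupled, recorded run", {
  ts1 <- simulate_network(jr_network(N = 1, K = 0, p_const = 90),
                          sim = sim_config(duration = 2, transient = 0,
                                           seed = 1))
  expect_error(mean_effective_input(ts1), "N >= 2")
  ts4 <- simulate_network(jr_network(N = 4, K = 15, p_const = 75),
                          sim = sim_config(duration = 2, transient = 0,
                                           seed = 1))
  expect_error(mean_effective_input(ts4), "record_coupling")
})

test_that("mean coupling input grows linearly with coupling strength", {
  Ks <- c(5, 10, 15, 20)
  cm <- vapply(Ks, function(K) {
    ts <- simulate_network(jr_network(N = 4, K = K, p_const = 90 - K),
                           sim = sim_config(duration = 110, transient = 10,
                                            seed = 6),
                           record_coupling = TRUE)
    mean_effective_input(ts)$coupling_mean
  }, numeric(1))
  fit <- summary(lm(cm ~ Ks))
  expect_gt(fit$r.squared, 0.99)
  expect_gt(coef(fit)[2, 1], 0)
})

test_that("column averaging attenuates individual spikes", {
  ts <- simulate_network(jr_network(N = 4, K = 15, p_const = 75),
                         sim = sim_config(duration = 110, transient = 10,
                                          seed = 9))
  expect_lt(max(abs(ts$average)), max(abs(ts$eeg)))
})

test_that("stationary pipelines return a trace and its spectrum", {
  rs <- run_stationary("single_column", duration = 50, seed = 4)
  expect_s3_class(rs$ts, "jr_timeseries")
  expect_s3_class(rs$psd, "jr_psd")
  expect_equal(rs$ts$config$net$p_const, 90)
  rc <- run_stationary("coupled_stationary", duration = 50, seed = 4)
  expect_equal(rc$ts$config$net$p_const, 75)
  expect_equal(ncol(rc$ts$eeg), 4)
  expect_false(is.null(rc$ts$coupling))
})

test_that("response maps have matching axes and finite cells", {
  m <- run_response_map("frequency", values = c(0.25, 1), duration = 50,
                        seed = 3)
  expect_equal(dim(m$db), c(2, length(m$freq)))
  expect_true(all(is.finite(m$db[, m$freq > 0])))
  a <- map_band_db(m, 8, 12)
  expect_length(a, 2)
  msize <- run_response_map("size", values = c(2, 4), duration = 50,
                            seed = 3)
  expect_equal(dim(msize$db)[1], 2)
})

test_that("driven pipeline returns matched stationary, sine and composed PSDs", {
  rd <- run_driven(duration = 50, transient = 5, seed = 2,
                   n_realizations = 2)
  expect_equal(rd$amplitude_composed,
               calibrate_composed_amplitude(45, 0.05, 4, 0.05))
  expect_identical(rd$psd_stationary$freq, rd$psd_sine$freq)
  expect_identical(rd$psd_stationary$freq, rd$psd_composed$freq)
  expect_true(all(rd$composed_stats$sd >= 0))
  # the sine drive line is visible at the driving frequency
  line <- band_power(rd$psd_sine, 0.2, 0.3)
  base <- band_power(rd$psd_stationary, 0.2, 0.3)
  expect_gt(line / base, 10)
})

test_that("configurations round-trip through YAML", {
  drv <- drive_spec("composed", amplitude = 45, phase_seed = 7)
  path <- tempfile(fileext = ".yml")
  write_model_config(path, net = jr_network(N = 4, K = 15, p_const = 75),
                     params = jr_params(), ou = ou_config(350, 0.15),
                     drive = drv,
                     sim = sim_config(duration = 110, transient = 10,
                                      seed = 12),
                     experiment = list(scenario = "coupled_stationary"))
  cfg <- read_model_config(path)
  expect_equal(cfg$net$N, 4)
  expect_equal(cfg$net$K[2, 1], 15)
  expect_equal(cfg$net$p_const, 75)
  expect_equal(cfg$ou$D, 350)
  expect_equal(cfg$sim$duration, 110)
  expect_equal(cfg$drive$mode, "composed")
  expect_equal(cfg$drive$phases, drv$phases, tolerance = 1e-12)
  expect_equal(cfg$drive$amplitude_composed, drv$amplitude_composed,
               tolerance = 1e-12)
  expect_equal(cfg$experiment$scenario, "coupled_stationary")
  unlink(path)
})

test_that("the experiment dispatcher runs a configured scenario", {
  cfg <- list(net = jr_network(N = 1, K = 0, p_const = 90),
              params = jr_params(), ou = ou_config(),
              drive = drive_spec("none"),
              sim = sim_config(duration = 40, transient = 5, seed = 3),
              experiment = list(scenario = "single_column"))
  out <- run_experiment(cfg)
  expect_s3_class(out$psd, "jr_psd")
  cfg$experiment$scenario <- "unknown_thing"
  expect_error(run_experiment(cfg), "unknown scenario")
})
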