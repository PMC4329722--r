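test_that("sigmoid hits its anchor points and stays bounded and monotone", {
  expect_equal(sigmoid(canon$v0, canon), canon$e0)
  expect_equal(sigmoid(0, canon), sigm0, tolerance = 1e-12)
  expect_equal(sigmoid(1e3, canon), 2 * canon$e0)
  grid <- seq(-100, 100, length.out = 4001)
  s <- sigmoid(grid, canon)
  expect_true(all(s > 0 & s <= 2 * canon$e0))
  expect_true(all(diff(s) >= 0))
  inner <- sigmoid(seq(-40, 40, length.out = 2001), canon)
  expect_true(all(diff(inner) > 0))
  expect_error(sigmoid(NaN, canon), "finite")
})

test_that("sigmoid derivative matches a central finite difference", {
  ys <- c(-10, -1, 0, 3, 6, 12, 30)
  h <- 1e-6
  fd <- (sigmoid(ys + h, canon) - sigmoid(ys - h, canon)) / (2 * h)
  expect_equal(sigmoid_deriv(ys, canon), fd, tolerance = 1e-7)
})

test_that("column derivatives reproduce hand-evaluated values", {
  d <- column_derivatives(rep(0, 6), 90, canon)
  expect_equal(d[5], 3.25 * 100 * (90 + 108 * sigm0), tolerance = 1e-12)
  d0 <- column_derivatives(rep(0, 6), 0, canon)
  expect_equal(d0[6], 22 * 50 * 33.75 * sigm0, tolerance = 1e-12)
  # first three components are the stored derivatives themselves
  st <- c(1, 2, 3, 4, 5, 6)
  expect_equal(column_derivatives(st, 10, canon)[1:3], c(4, 5, 6))
  expect_error(column_derivatives(rep(0, 5), 90, canon), "6")
  expect_error(column_derivatives(rep(0, 6), Inf, canon), "finite")
})

test_that("derivatives vanish at solved equilibria", {
  for (p in c(0, 50, 90, 200, 400)) {
    for (eq in fixed_points(p, canon)) {
      d <- column_derivatives(eq$state, p, canon)
      expect_lt(max(abs(d)) / 3.5e4, 1e-9)
    }
  }
})

test_that("coupling inputs follow the normalized homogeneous form", {
  # zero coupling matrix
  net0 <- jr_network(N = 3, K = 0, p_const = 75)
  st <- matrix(rnorm(18), 6, 3)
  expect_equal(coupling_inputs(st, net0, canon), rep(0, 3))

  # homogeneous network, all columns at y1 - y2 = v0: normalization cancels
  net <- jr_network(N = 4, K = 15, p_const = 75)
  st <- matrix(0, 6, 4)
  st[2, ] <- canon$v0
  expect_equal(coupling_inputs(st, net, canon), rep(15 * canon$e0, 4))

  # N = 2 with a single directed weight
  K <- matrix(0, 2, 2)
  K[2, 1] <- 10
  net2 <- jr_network(N = 2, K = K, p_const = 75)
  st2 <- matrix(0, 6, 2)
  got <- coupling_inputs(st2, net2, canon)
  expect_equal(got[1], 10 * sigm0, tolerance = 1e-12)
  expect_equal(got[2], 0)

  # single column: no coupling
  expect_equal(coupling_inputs(matrix(0, 6, 1),
                               jr_network(N = 1, K = 0, p_const = 90),
                               canon), 0)
  expect_error(coupling_inputs(matrix(0, 6, 3), net, canon), "N")
})

test_that("coupling is permutation-equivariant and N-independent when homogeneous", {
  set.seed(42)
  net <- jr_network(N = 5, K = 7, p_const = 75)
  st <- matrix(rnorm(30, sd = 4), 6, 5)
  base <- coupling_inputs(st, net, canon)
  perm <- sample(5)
  expect_equal(coupling_inputs(st[, perm], net, canon), base[perm])

  # identical columns: input K * Sigm(y1 - y2) for any N
  for (N in c(2, 4, 8)) {
    sti <- matrix(rep(c(0.5, 3, 1, 0, 0, 0), N), 6, N)
    neti <- jr_network(N = N, K = 7, p_const = 75)
    expect_equal(coupling_inputs(sti, neti, canon),
                 rep(7 * sigmoid(2, canon), N))
  }
})

test_that("total pyramidal input sums its four components", {
  # isolated column: constant input only
  s1 <- jr_state(matrix(0, 6, 1), 0)
  net1 <- jr_network(N = 1, K = 0, p_const = 90)
  expect_equal(total_pyramidal_input(0, 1, s1, net1), 90)
  # sine contributes zero at t = 0
  drv <- drive_spec("sine", amplitude = 45, frequency = 0.25)
  expect_equal(total_pyramidal_input(0, 1, s1, net1, drv), 90)
  # full sum: constant + coupling + sine peak + noise
  st <- matrix(0, 6, 4)
  st[2, ] <- canon$v0
  s4 <- jr_state(st, rep(-3.1, 4))
  net4 <- jr_network(N = 4, K = 15, p_const = 75)
  expect_equal(total_pyramidal_input(1, 2, s4, net4, drv),
               75 + 37.5 + 45 - 3.1)
})

test_that("EEG observable is y1 - y2 and its column average", {
  st <- matrix(0, 6, 1)
  st[2] <- 5; st[3] <- 2
  expect_equal(eeg_observable(st)$average, 3)
  st2 <- matrix(0, 6, 2)
  st2[2, ] <- c(3, -3)
  expect_equal(eeg_observable(st2)$average, 0)
  st4 <- matrix(0, 6, 4)
  st4[2, ] <- 1:4
  obs <- eeg_observable(st4)
  expect_equal(obs$per_column, c(1, 2, 3, 4))
  expect_equal(obs$average, 2.5)
})

test_that("parameter and network constructors validate their invariants", {
  expect_error(jr_params(A = -1), "positive")
  expect_warning(jr_params(C2 = 200), "C2")
  expect_warning(jr_params(C3 = 30, C4 = 35), "C3")
  expect_error(jr_network(N = 0), "N")
  expect_error(jr_network(N = 2, K = -3), "nonnegative")
  net <- jr_network(N = 3, K = 12)
  expect_equal(diag(net$K), rep(0, 3))
  expect_error(jr_network(N = 2, K = 5, p_const = -1), "p_const")
})
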