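test_that("detect_events matches the local-maximum definition", {
  # flat, monotone, and too-short inputs
  expect_length(detect_events(rep(1, 100)), 0)
  expect_length(detect_events(seq_len(100)), 0)
  expect_error(detect_events(rnorm(15), M = 10), "too short")

  # single clean bump is found at its center
  x <- bump_signal(1000, 500)
  expect_equal(as.integer(detect_events(x)), 500L)

  # brute-force scan of the definition over random signals
  set.seed(41)
  for (rep in 1:20) {
    x <- rnorm(400, sd = 40)
    M <- sample(c(3, 5, 10), 1)
    h <- sample(c(0, 10, 30), 1)
    L <- length(x)
    expected <- integer(0)
    for (t in (M + 1):(L - M)) {
      lower <- all(x[t] > x[t + setdiff(-(M - 1):(M - 1), 0)])
      margin <- x[t] > x[t + M] + h && x[t] > x[t - M] + h
      if (lower && margin) expected <- c(expected, t)
    }
    expect_equal(as.integer(detect_events(x, M = M, h = h)), expected)
  }
})

test_that("events are interior and separated by at least M", {
  set.seed(7)
  for (rep in 1:10) {
    x <- bump_signal(2000, sort(sample(100:1900, 8)), halfwidth = 3) +
      rnorm(2000, sd = 3)
    ev <- detect_events(x)
    if (length(ev)) {
      expect_true(all(ev > 10 & ev <= 1990))
      if (length(ev) > 1) expect_true(all(diff(ev) >= 10))
    }
  }
})

test_that("delay scale follows the adjacent-pair half-minimum rule", {
  # regular identical spacing: tau is half the spacing
  a <- seq(100, 4000, by = 100)
  expect_equal(delay_scale(a, a + 3), 50)
  expect_equal(delay_scale(a, a), 50)

  # irregular trains match the exhaustive oracle
  t1 <- c(0, 10, 1000)
  t2 <- c(5, 500, 990)
  expect_equal(delay_scale(t1, t2), o_delay_scale(t1, t2))
  expect_equal(delay_scale(t1, t2), 5)

  set.seed(11)
  for (rep in 1:30) {
    a <- r_train(sample(3:20, 1), 5000)
    b <- r_train(sample(3:20, 1), 5000)
    expect_equal(delay_scale(a, b), o_delay_scale(a, b))
  }

  # two-event trains fall back to half the minimum adjacent interval
  expect_equal(delay_scale(c(10, 110), c(50, 90)), 20)
  expect_error(delay_scale(5, c(1, 2)), "insufficient")
})

test_that("pair counts match the double-loop oracle", {
  # identical trains: coincidences only, half each
  a <- seq(50, 950, by = 100)
  pc <- pair_counts(a, a, tau = 10)
  expect_equal(pc$e12, length(a) / 2)
  expect_equal(pc$e21, length(a) / 2)

  # perfectly lagged pairing: only the follower-side count
  b <- a + 7
  pc <- pair_counts(a, b, tau = 10)
  expect_equal(pc$e12, 0)
  expect_equal(pc$e21, length(a))

  set.seed(12)
  for (rep in 1:40) {
    t1 <- r_train(sample(5:30, 1), 10000)
    t2 <- r_train(sample(5:30, 1), 10000)
    tau <- sample(c(3, 10, 40, 200), 1)
    pc <- pair_counts(t1, t2, tau)
    oc <- o_pair_counts(t1, t2, tau)
    expect_equal(pc$e12, oc$e12)
    expect_equal(pc$e21, oc$e21)
  }
})

test_that("synchronization index hits its printed extremes", {
  # all events coincide: Q = 1 under the square-root normalization
  a <- seq(100, 2000, by = 100)
  sc <- sync_causality(pair_counts(a, a, tau = 10))
  expect_equal(sc$Q, 1)
  expect_equal(sc$q, 0)

  # one-to-one lagged pairing inside tau: q = 1 driver-to-follower
  es <- event_sync(a, a + 30)
  expect_equal(es$tau, 50)
  expect_equal(es$q, 1)
  expect_equal(es$Q, 1)

  # far-separated trains: zero counts
  es0 <- event_sync(c(100, 200, 300), c(5000, 5100, 5200))
  expect_equal(es0$Q, 0)
  expect_equal(es0$q, 0)
})

test_that("Q is symmetric and q antisymmetric, both within bounds", {
  set.seed(13)
  for (rep in 1:40) {
    a <- r_train(sample(5:40, 1), 20000)
    b <- r_train(sample(5:40, 1), 20000)
    ab <- event_sync(a, b)
    ba <- event_sync(b, a)
    expect_equal(ab$Q, ba$Q)
    expect_equal(ab$q, -ba$q)
    expect_gte(ab$Q, 0)
    expect_lte(ab$Q, 1)
    expect_lte(abs(ab$q), 1)
    expect_lte(ab$Q + abs(ab$q), 2 * ab$Q + 1e-12)  # |q| <= Q
  }
})

test_that("cumulative counts step at event times and close the total", {
  a <- seq(200, 8000, by = 200)
  b <- a + 30
  tau <- delay_scale(a, b)
  cum <- cumulative_counts(a, b, tau)

  # nothing before the first event; full total beyond the last
  at0 <- eval_cumulative(cum, 0)
  expect_equal(at0$Qn, 0)
  expect_equal(at0$qn, 0)
  pc <- pair_counts(a, b, tau)
  atL <- eval_cumulative(cum, 10000)
  expect_equal(atL$Qn, pc$e12 + pc$e21)

  # mid-series values match the truncated brute force
  for (n in c(1, 350, 1000, 4321, 8031)) {
    oc <- o_cumulative(a, b, tau, n)
    got <- eval_cumulative(cum, n)
    expect_equal(got$Qn, oc$Qn)
    expect_equal(got$qn, oc$qn)
  }

  set.seed(14)
  for (rep in 1:20) {
    t1 <- r_train(sample(5:25, 1), 9000)
    t2 <- r_train(sample(5:25, 1), 9000)
    tau <- sample(c(5, 25, 120), 1)
    cum <- cumulative_counts(t1, t2, tau)
    n <- sort(sample.int(9500, 5))
    got <- eval_cumulative(cum, n)
    for (k in seq_along(n)) {
      oc <- o_cumulative(t1, t2, tau, n[k])
      expect_equal(got$Qn[k], oc$Qn)
      expect_equal(got$qn[k], oc$qn)
    }
    # monotone nondecreasing synchronization
    dense <- eval_cumulative(cum, seq(0, 9500, by = 250))
    expect_true(all(diff(dense$Qn) >= 0))
  }
})

test_that("windowed rates match the per-window oracle and guard zeros", {
  a <- seq(200, 9800, by = 200)
  b <- a + 30
  tau <- delay_scale(a, b)
  rs <- rate_series(a, b, tau, window = 2000, stride = 500, L = 10000)
  expect_true(all(rs$dQ >= 0))
  expect_true(all(rs$dq > 0))  # stationary driver-follower fixture
  for (k in seq_len(nrow(rs))) {
    oc <- o_rate(a, b, tau, rs$n[k], 2000)
    expect_equal(rs$dQ[k], oc$dQ)
    expect_equal(rs$dq[k], oc$dq)
  }

  # empty window: defined as zero
  rs0 <- rate_series(c(9000, 9100), c(9050, 9150), tau = 20,
                     window = 1000, stride = 1000, L = 9500)
  expect_equal(rs0$dQ[1:8], rep(0, 8))
  expect_equal(rs0$dq[1:8], rep(0, 8))

  set.seed(15)
  for (rep in 1:15) {
    t1 <- r_train(sample(5:25, 1), 9000)
    t2 <- r_train(sample(5:25, 1), 9000)
    tau <- sample(c(10, 60), 1)
    rs <- rate_series(t1, t2, tau, window = 3000, stride = 1500, L = 9000)
    expect_true(all(rs$dQ >= 0))
    for (k in seq_len(nrow(rs))) {
      oc <- o_rate(t1, t2, tau, rs$n[k], 3000)
      expect_equal(rs$dQ[k], oc$dQ)
      expect_equal(rs$dq[k], oc$dq)
    }
  }
})

test_that("edge weights follow the one-sided amplified product", {
  expect_equal(adjacency_weight(-0.3, 0.5), 0)
  expect_equal(adjacency_weight(0, 0.5), 0)
  expect_equal(adjacency_weight(0.002, 0.004, gamma = 1000), 0.008)
  expect_equal(adjacency_weight(c(-1, 0.1), c(1, 0.1)), c(0, 10))
})

test_that("build_network yields zero diagonals, nonnegative weights, and
           recovers a planted direction", {
  cfg <- synth_config(n_channels = 2, duration = 40, event_rate = 1,
                      coupling_edges = tibble::tibble(
                        source = 1, target = 2, prob = 1, lag = 8),
                      seed = 99)
  sim <- simulate_recording(cfg)
  net <- build_network(sim$recording, delta_n = 5120, stride = 5120)
  expect_true(all(net$W >= 0))
  for (t in seq_along(net$times)) {
    expect_equal(diag(net$W[, , t]), c(0, 0))
  }
  # driver channel 1 acts on follower channel 2
  expect_gt(mean(net$W[1, 2, ]), mean(net$W[2, 1, ]))

  # deterministic: identical recording, identical network
  net2 <- build_network(sim$recording, delta_n = 5120, stride = 5120)
  expect_identical(net$W, net2$W)

  # eventless input warns and returns zeros
  flat <- new_recording(matrix(0, 2, 6000), fs = 512)
  expect_warning(net0 <- build_network(flat, delta_n = 5120), "eventless")
  expect_true(all(net0$W == 0))
})

test_that("event_table reports per-channel trains with labels", {
  cfg <- synth_config(n_channels = 3, duration = 10, event_rate = 1,
                      noise_sd = 0, seed = 5)
  sim <- simulate_recording(cfg)
  tab <- event_table(sim$recording)
  expect_named(tab, c("channel", "time"))
  expect_setequal(unique(tab$channel), sim$recording$channel_names)
})
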