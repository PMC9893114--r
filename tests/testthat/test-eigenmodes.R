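test_that("complex spectrum is sorted, unit-normalized, and matches a
           polynomial-root oracle", {
  # zero matrix: empty spectrum
  sp0 <- complex_spectrum(matrix(0, 3, 3))
  expect_equal(sp0$moduli, rep(0, 3))

  # rotation-like matrix: conjugate pair on the unit circle
  R <- matrix(c(0, 1, -1, 0), 2, 2)
  sp <- complex_spectrum(R)
  expect_equal(sp$moduli, c(1, 1))
  expect_equal(sort(sp$angles), c(-pi / 2, pi / 2))

  expect_error(complex_spectrum(matrix(1, 2, 3)), "square")
  expect_error(complex_spectrum(matrix(c(1, NA, 0, 1), 2, 2)), "finite")

  # eigenvalue moduli equal the characteristic-polynomial root moduli
  skip_if_not_installed("pracma")
  set.seed(21)
  for (rep in 1:10) {
    A <- r_adjacency(4, density = 0.9)
    # keep a cycle so the spectrum is genuinely nonzero
    A[1, 2] <- 1; A[2, 1] <- 0.5
    sp <- complex_spectrum(A)
    roots <- polyroot(rev(pracma::charpoly(A)))
    expect_equal(sp$moduli, sort(Mod(roots), decreasing = TRUE),
                 tolerance = 1e-8)
    expect_true(all(diff(sp$moduli) <= 1e-12))
    expect_equal(colSums(sp$comp_moduli^2), rep(1, 4))
  }
})

test_that("conjugate eigenvector pairs share component moduli", {
  set.seed(22)
  for (rep in 1:10) {
    A <- r_adjacency(6, density = 0.7)
    sp <- complex_spectrum(A)
    vals <- sp$values
    for (i in seq_along(vals)) {
      if (abs(Im(vals[i])) < 1e-12) next
      j <- which(abs(vals - Conj(vals[i])) < 1e-9)
      expect_length(j, 1)
      expect_equal(sp$comp_moduli[, i], sp$comp_moduli[, j],
                   tolerance = 1e-9)
    }
  }
})

test_that("nilpotent (acyclic) matrices get an exactly zero spectrum", {
  # a Jordan-like chain: LAPACK alone would report moduli ~ eps^(1/N)
  N <- 8
  A <- matrix(0, N, N)
  A[cbind(1:(N - 1), 2:N)] <- 0.5
  sp <- complex_spectrum(A)
  expect_equal(sp$moduli, rep(0, N))
  idx <- oscillation_indices(A)
  expect_equal(idx$H_in, 0)
  expect_equal(idx$H_se, 0)
  expect_equal(idx$H_sb_norm, 0)
})

test_that("band partition reproduces the hand rule", {
  # degenerate spread: everything weak, no heterogeneity
  part <- partition_layer(rep(0.25, 8), 2)
  expect_equal(part$M, 1)
  expect_equal(part$p, 0)
  expect_true(all(part$labels == "weak"))

  # hand-computed case: mean 0.375, sd 0.3841...
  cm <- c(0.1, 0.1, 0.5, 0.9)
  part <- partition_layer(cm, 3)
  avg <- mean(cm); s <- sd(cm)
  expect_equal(as.character(part$labels),
               c("weak", "weak", "weak", "balance"))
  expect_equal(part$M, 2)
  expect_equal(part$module_sizes, c(3L, 1L))
  expect_equal(part$p, (abs(3 - 2) + abs(1 - 2)) / 4)

  expect_error(partition_layer(cm, 1), "layer_index")
  expect_error(partition_layer(numeric(0), 2), "empty")

  # conservation: module sizes always sum to N, p stays in [0, 1]
  set.seed(23)
  for (rep in 1:50) {
    cm <- runif(sample(3:12, 1))
    part <- partition_layer(cm, 2)
    expect_equal(sum(part$module_sizes), length(cm))
    expect_gte(part$p, 0)
    expect_lte(part$p, 1)
  }
})

test_that("layer measure applies the modulus-module weighting", {
  expect_equal(layer_measure(0, 2, 0.3, 5), 0)
  expect_equal(layer_measure(2, 1, 0, 4), 0.25)
  expect_equal(layer_measure(1.5, 2, 0.5, 3), 1.5^2 * 2 * 0.5 / 9)
})

test_that("oscillation indices match an independent straight-line
           implementation", {
  # degenerate and boundary cases
  z <- oscillation_indices(matrix(0, 4, 4))
  expect_equal(z$H_sb_norm, 0)
  d <- oscillation_indices(diag(c(1, 0)))
  expect_equal(d$H_in, 0.25)
  expect_equal(d$H_se, 0)
  expect_equal(d$H_sb_norm, 1)

  set.seed(24)
  for (rep in 1:25) {
    N <- sample(4:8, 1)
    A <- r_adjacency(N, density = runif(1, 0.3, 0.9))
    got <- oscillation_indices(A)
    want <- o_indices(A)
    expect_equal(got$H_in, want$H_in, tolerance = 1e-10)
    expect_equal(got$H_se, want$H_se, tolerance = 1e-10)
    expect_equal(got$H_sb_norm, want$H_sb_norm, tolerance = 1e-10)
    expect_lte(abs(got$H_sb_norm), 1)
    expect_gte(got$H_in, 0)
    expect_gte(got$H_se, 0)
  }
})

test_that("indices are invariant under node permutation and follow the
           c^2 scale law", {
  set.seed(25)
  for (rep in 1:10) {
    N <- sample(5:9, 1)
    A <- r_adjacency(N, density = 0.6)
    base <- oscillation_indices(A)

    perm <- sample(N)
    got <- oscillation_indices(A[perm, perm])
    expect_equal(got$H_in, base$H_in, tolerance = 1e-9)
    expect_equal(got$H_se, base$H_se, tolerance = 1e-9)
    expect_equal(got$H_sb_norm, base$H_sb_norm, tolerance = 1e-9)

    c0 <- runif(1, 0.1, 5)
    scaled <- oscillation_indices(c0 * A)
    expect_equal(scaled$H_in, c0^2 * base$H_in, tolerance = 1e-9)
    expect_equal(scaled$H_se, c0^2 * base$H_se, tolerance = 1e-9)
    expect_equal(scaled$H_sb_norm, base$H_sb_norm, tolerance = 1e-9)
  }
})

test_that("a pure re-entrant ring plunges the balance index to its floor", {
  # directed k-cycle: k equal-modulus layers, each undiscounted
  k <- 8
  A <- matrix(0, k, k)
  A[cbind(1:k, c(2:k, 1))] <- 0.4
  idx <- oscillation_indices(A)
  expect_equal(idx$H_sb_norm, (2 - k) / k, tolerance = 1e-9)
})

test_that("index time course maps snapshots in order and is
           label-permutation invariant", {
  zero_net <- structure(
    list(W = array(0, c(3, 3, 4)), times = c(10, 20, 30, 40),
         channels = c("a", "b", "c"),
         params = list(delta_n = 10, stride = 10), annotations = NULL),
    class = "effective_network")
  idx <- index_time_course(zero_net)
  expect_equal(idx$time, c(10, 20, 30, 40))
  expect_equal(idx$H_sb_norm, rep(0, 4))

  set.seed(26)
  W <- array(runif(5 * 5 * 3), c(5, 5, 3))
  for (t in 1:3) diag(W[, , t]) <- 0
  net <- structure(
    list(W = W, times = 1:3, channels = letters[1:5],
         params = list(delta_n = 1, stride = 1), annotations = NULL),
    class = "effective_network")
  perm <- sample(5)
  net_p <- net
  net_p$W <- W[perm, perm, , drop = FALSE]
  net_p$channels <- net$channels[perm]
  expect_equal(index_time_course(net)$H_sb_norm,
               index_time_course(net_p)$H_sb_norm, tolerance = 1e-9)

  # max-abs alternative normalization is sign-preserving and bounded
  idx2 <- index_time_course(net, hsb_normalization = "max_abs")
  expect_true(all(abs(idx2$H_sb_norm) <= 1))
  expect_equal(sign(idx2$H_sb_norm),
               sign(index_time_course(net)$H_sb_raw))
})
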