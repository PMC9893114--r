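# Brute-force reference implementations used as independent oracles.
# These deliberately use plain double loops over the printed definitions,
# not the package's vectorized counting paths.

# directed pair counts: E[r,s] = 1 if 0 < t1[r]-t2[s] <= tau, 1/2 on ties
o_pair_counts <- function(t1, t2, tau) {
  e12 <- 0; e21 <- 0
  for (r in seq_along(t1)) {
    for (s in seq_along(t2)) {
      d <- t1[r] - t2[s]
      if (d == 0) {
        e12 <- e12 + 0.5; e21 <- e21 + 0.5
      } else if (d > 0 && d <= tau) {
        e12 <- e12 + 1
      } else if (d < 0 && -d <= tau) {
        e21 <- e21 + 1
      }
    }
  }
  list(e12 = e12, e21 = e21)
}

# local delay rule: interior events paired with nearest interior partner
o_delay_scale <- function(t1, t2) {
  taus <- c()
  one_side <- function(a, b) {
    out <- c()
    if (length(a) < 3 || length(b) < 3) return(out)
    for (r in 2:(length(a) - 1)) {
      s <- which.min(abs(a[r] - b))
      if (s == 1 || s == length(b)) next
      out <- c(out, 0.5 * min(a[r + 1] - a[r], a[r] - a[r - 1],
                              b[s + 1] - b[s], b[s] - b[s - 1]))
    }
    out
  }
  taus <- c(one_side(t1, t2), one_side(t2, t1))
  if (!length(taus)) return(0.5 * min(c(diff(t1), diff(t2))))
  min(taus)
}

# cumulative counts at a single time point n (step function: t < n)
o_cumulative <- function(t1, t2, tau, n) {
  e12 <- 0; e21 <- 0
  for (r in seq_along(t1)) {
    for (s in seq_along(t2)) {
      d <- t1[r] - t2[s]
      w <- if (d == 0) 0.5 else if (abs(d) <= tau) 1 else 0
      if (w == 0) next
      if (d >= 0 && t1[r] < n) e12 <- e12 + w
      if (d <= 0 && t2[s] < n) e21 <- e21 + w
    }
  }
  list(Qn = e12 + e21, qn = e21 - e12)
}

# windowed rates at one evaluation point
o_rate <- function(t1, t2, tau, n, window) {
  hi <- o_cumulative(t1, t2, tau, n)
  lo <- o_cumulative(t1, t2, tau, n - window)
  dn1 <- sum(t1 >= n - window & t1 <= n)
  dn2 <- sum(t2 >= n - window & t2 <= n)
  if (dn1 * dn2 == 0) return(list(dQ = 0, dq = 0))
  list(dQ = (hi$Qn - lo$Qn) / (dn1 * dn2),
       dq = (hi$qn - lo$qn) / (dn1 * dn2))
}

# straight-line reimplementation of the oscillation indices
o_indices <- function(A) {
  N <- nrow(A)
  ev <- eigen(A)
  mod <- Mod(ev$values)
  ord <- order(-mod, Arg(as.complex(ev$values)))
  mod <- mod[ord]
  V <- ev$vectors[, ord, drop = FALSE]
  H_in <- mod[1]^2 / N^2
  H_se <- 0
  for (i in 2:N) {
    cm <- Mod(V[, i])
    cm <- cm / sqrt(sum(cm^2))
    avg <- mean(cm); s <- stats::sd(cm)
    tol <- 1e-9 * (1 + max(cm))
    lab <- ifelse(cm > avg + 2 * s + tol, 3L,
                  ifelse(cm > avg + s + tol, 2L, 1L))
    sizes <- as.numeric(table(lab))
    M <- length(sizes)
    p <- min(sum(abs(sizes - N / M)) / N, 1)
    H_se <- H_se + mod[i]^2 * M * (1 - p) / N^2
  }
  total <- H_in + H_se
  list(H_in = H_in, H_se = H_se,
       H_sb_norm = if (total == 0) 0 else (H_in - H_se) / total)
}

# random event train of m events in [1, L] with minimum spacing
r_train <- function(m, L, min_gap = 10) {
  t <- sort(sample.int(L, m * 3, replace = FALSE))
  keep <- c(TRUE, diff(t) >= min_gap)
  while (!all(keep)) {
    t <- t[keep]
    keep <- c(TRUE, diff(t) >= min_gap)
  }
  head(t, m)
}

# random nonnegative zero-diagonal matrix
r_adjacency <- function(N, density = 0.5, wmax = 1) {
  A <- matrix(stats::runif(N * N, 0, wmax) *
                (stats::runif(N * N) < density), N, N)
  diag(A) <- 0
  A
}

# single-bump test signal
bump_signal <- function(L, centers, amplitude = 100, halfwidth = 5) {
  x <- numeric(L)
  for (c0 in centers) {
    at <- pmax(1, c0 - 4 * halfwidth):pmin(L, c0 + 4 * halfwidth)
    x[at] <- x[at] + amplitude * exp(-0.5 * ((at - c0) / halfwidth)^2)
  }
  x
}
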