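#' Detect events (sharp local maxima) in a single-channel signal
#'
#' An event is a sample that is a strict local maximum over the window of
#' `M - 1` samples on each side and additionally exceeds both samples exactly
#' `M` away by at least the margin `h`. Samples within `M` of either end of
#' the series are never events, and two events on one channel are therefore
#' always at least `M` samples apart.
#'
#' @param x Numeric vector, one channel of the recording.
#' @param M Half-window in samples shaping the event (default 10).
#' @param h Amplitude margin in signal units (default 30).
#' @return Integer vector of event sample indices (1-based), strictly
#'   increasing. The series length is attached as attribute `"L"`.
#' @examples
#' x <- numeric(1000)
#' x[480:520] <- 100 * exp(-0.5 * ((480:520 - 500) / 5)^2)
#' detect_events(x)
#' @export
detect_events <- function(x, M = 10, h = 30) {
  stopifnot(is.numeric(x), M >= 2, h >= 0)
  L <- length(x)
  if (L < 2 * M + 1) {
    stop("series too short: need at least 2*M + 1 = ", 2 * M + 1, " samples")
  }
  idx <- (M + 1):(L - M)
  ok <- rep(TRUE, length(idx))
  for (m in seq_len(M - 1)) {
    ok <- ok & x[idx] > x[idx + m] & x[idx] > x[idx - m]
  }
  ok <- ok & x[idx] > x[idx + M] + h & x[idx] > x[idx - M] + h
  out <- idx[ok]
  attr(out, "L") <- L
  out
}

#' Tabulate events for every channel of a recording
#'
#' @param recording A `recording` object (see [simulate_recording()] or
#'   [read_recording()]).
#' @inheritParams detect_events
#' @return A tibble with columns `channel` (label) and `time` (sample index).
#' @export
event_table <- function(recording, M = 10, h = 30) {
  stopifnot(inherits(recording, "recording"))
  trains <- lapply(seq_len(nrow(recording$data)), function(ch) {
    detect_events(recording$data[ch, ], M = M, h = h)
  })
  tibble::tibble(
    channel = rep(recording$channel_names, lengths(trains)),
    time = as.integer(unlist(trains, use.names = FALSE))
  )
}

#' Pair-adaptive delay scale tau for two event trains
#'
#' For each interior event of one train paired with its temporally nearest
#' interior event of the other, the local delay is half the smallest of the
#' four adjacent inter-event intervals around the pair; tau is the minimum
#' local delay over all such pairs. It bounds the lag at which two events can
#' still be attributed to one another, and guarantees that within tau the
#' matching between the two trains is one-to-one.
#'
#' When neither train has an interior event with an interior nearest
#' neighbour (e.g. two-event trains), tau falls back to half the smallest
#' adjacent inter-event interval over both trains.
#'
#' @param a,b Integer vectors of strictly increasing event times.
#' @param details If `TRUE`, also return the table of local delays.
#' @return The delay scale tau (double, > 0), or, with `details = TRUE`, a
#'   list with elements `tau` and `local_taus` (a tibble).
#' @export
delay_scale <- function(a, b, details = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient events: both trains need at least 2 events")
  }
  stopifnot(all(diff(a) > 0), all(diff(b) > 0))
  local_one_side <- function(t1, t2) {
    # interior events of t1 paired with nearest interior event of t2
    m1 <- length(t1); m2 <- length(t2)
    if (m1 < 3 || m2 < 3) return(NULL)
    rows <- list()
    for (r in 2:(m1 - 1)) {
      s <- which.min(abs(t1[r] - t2))
      if (s == 1 || s == m2) next
      tau_rs <- 0.5 * min(t1[r + 1] - t1[r], t1[r] - t1[r - 1],
                          t2[s + 1] - t2[s], t2[s] - t2[s - 1])
      rows[[length(rows) + 1L]] <- c(r = r, s = s, tau = tau_rs)
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }
  side_a <- local_one_side(a, b)
  side_b <- local_one_side(b, a)
  if (!is.null(side_b)) {
    side_b <- side_b[, c("s", "r", "tau"), drop = FALSE]
    colnames(side_b) <- c("r", "s", "tau")
  }
  loc <- rbind(side_a, side_b)
  if (is.null(loc) || !nrow(loc)) {
    tau <- 0.5 * min(c(diff(a), diff(b)))
    loc <- matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("r", "s", "tau")))
  } else {
    tau <- min(loc[, "tau"])
  }
  stopifnot(tau > 0)
  if (!details) return(tau)
  list(tau = tau,
       local_taus = tibble::as_tibble(as.data.frame(loc)))
}

# per-event forward counts: for each t1[r], the number of t2 events in
# [t1[r] - tau, t1[r]), plus 1/2 per exact coincidence. t2 must be sorted.
event_contrib <- function(t1, t2, tau) {
  if (!length(t1) || !length(t2)) return(numeric(length(t1)))
  n_lt <- findInterval(t1 - 1e-9, t2)        # t2 <  t1
  n_lo <- findInterval(t1 - tau - 1e-9, t2)  # t2 <  t1 - tau
  n_eq <- findInterval(t1, t2) - n_lt        # t2 == t1
  (n_lt - n_lo) + 0.5 * n_eq
}

#' Directed event counts within the delay scale
#'
#' `e12` counts, over all event pairs, occurrences of a `b` event at most
#' `tau` samples before an `a` event (the drive of `b` onto `a`); `e21` is the
#' symmetric count (drive of `a` onto `b`). Exact coincidences contribute one
#' half to each count so that they are not double counted.
#'
#' @inheritParams delay_scale
#' @param tau Delay scale in samples (> 0), normally from [delay_scale()].
#' @return A one-row tibble with columns `e12`, `e21`, `m1`, `m2`.
#' @export
pair_counts <- function(a, b, tau) {
  stopifnot(tau > 0)
  a <- as.numeric(a); b <- as.numeric(b)
  tibble::tibble(
    e12 = sum(event_contrib(a, b, tau)),
    e21 = sum(event_contrib(b, a, tau)),
    m1 = length(a),
    m2 = length(b)
  )
}

#' Event synchronization and directionality indices
#'
#' `Q` is the normalized total of quasi-coincident event pairs and `q` the
#' normalized asymmetry of the two directed counts. Under the default
#' square-root normalization (denominator `sqrt(m1 * m2)`) the printed bounds
#' hold: `0 <= Q <= 1` with `Q = 1` exactly when all events of both trains
#' coincide, and `-1 <= q <= 1` with `q = 1` for a perfect one-to-one lagged
#' pairing from driver to follower. The `product_mm` mode divides by
#' `m1 * m2` instead.
#'
#' Sign convention: `q > 0` means the first train drives the second.
#'
#' @param counts One-row data frame from [pair_counts()].
#' @param mode Normalization, `"sqrt_mm"` (default) or `"product_mm"`.
#' @return One-row tibble with columns `Q`, `q`, `mode`.
#' @export
sync_causality <- function(counts, mode = c("sqrt_mm", "product_mm")) {
  mode <- match.arg(mode)
  m1 <- counts$m1; m2 <- counts$m2
  if (m1 < 1 || m2 < 1) {
    return(tibble::tibble(Q = 0, q = 0, mode = mode))
  }
  D <- if (mode == "sqrt_mm") sqrt(m1 * m2) else m1 * m2
  tibble::tibble(
    Q = (counts$e21 + counts$e12) / D,
    q = (counts$e21 - counts$e12) / D,
    mode = mode
  )
}

#' One-call synchronization summary for two event trains
#'
#' Convenience wrapper: computes tau, the directed counts, and the
#' normalized indices in one step.
#'
#' @inheritParams delay_scale
#' @inheritParams sync_causality
#' @return One-row tibble `tau, m1, m2, e12, e21, Q, q`.
#' @export
event_sync <- function(a, b, mode = c("sqrt_mm", "product_mm")) {
  mode <- match.arg(mode)
  if (length(a) < 2 || length(b) < 2) {
    return(tibble::tibble(tau = NA_real_, m1 = length(a), m2 = length(b),
                          e12 = 0, e21 = 0, Q = 0, q = 0))
  }
  tau <- delay_scale(a, b)
  pc <- pair_counts(a, b, tau)
  sc <- sync_causality(pc, mode)
  tibble::tibble(tau = tau, m1 = pc$m1, m2 = pc$m2, e12 = pc$e12,
                 e21 = pc$e21, Q = sc$Q, q = sc$q)
}

#' Cumulative synchronization and causal-balance counts
#'
#' Step sequences over time: each directed event pair is attributed to the
#' time of its later (effect-side) event through the step function, so
#' `Qn(n)` is the number of quasi-coincident pairs whose effect event
#' occurred strictly before sample `n`, and `qn(n)` the signed balance of
#' the two directions.
#'
#' @inheritParams pair_counts
#' @return An object of class `cum_counts`; evaluate it at time points with
#'   [eval_cumulative()].
#' @export
cumulative_counts <- function(a, b, tau) {
  stopifnot(tau > 0)
  a <- as.numeric(a); b <- as.numeric(b)
  structure(
    list(t1 = a, c1 = event_contrib(a, b, tau),   # pairs counted in e(x1|x2)
         t2 = b, c2 = event_contrib(b, a, tau),   # pairs counted in e(x2|x1)
         tau = tau),
    class = "cum_counts"
  )
}

#' Evaluate cumulative counts at given time points
#'
#' @param cum A `cum_counts` object from [cumulative_counts()].
#' @param n Numeric vector of time points (samples).
#' @return Tibble with columns `n`, `Qn`, `qn`.
#' @export
eval_cumulative <- function(cum, n) {
  stopifnot(inherits(cum, "cum_counts"))
  cs1 <- cumsum(cum$c1); cs2 <- cumsum(cum$c2)
  at <- function(t, cs, n) {
    k <- findInterval(n - 1e-9, t)  # events with t < n
    c(0, cs)[k + 1L]
  }
  e12 <- at(cum$t1, cs1, n)
  e21 <- at(cum$t2, cs2, n)
  tibble::tibble(n = n, Qn = e21 + e12, qn = e21 - e12)
}

#' @export
print.cum_counts <- function(x, ...) {
  cat("<cum_counts> tau =", x$tau, "; events:", length(x$t1), "x",
      length(x$t2), "; total Q =", sum(x$c1) + sum(x$c2), "\n")
  invisible(x)
}

#' Windowed rates of synchronization and causality growth
#'
#' At each evaluation point `n`, the change of the cumulative counts over
#' the trailing window of `window` samples is divided by the product of the
#' two trains' event counts inside the closed band `[n - window, n]`;
#' windows containing no events on either side yield 0.
#'
#' @inheritParams pair_counts
#' @param window Window length in samples (default 5120).
#' @param stride Spacing of evaluation points (default `window`).
#' @param L Series length in samples; evaluation points are
#'   `window, window + stride, ..., <= L`.
#' @return Tibble with columns `n`, `dQ`, `dq`, `dn1`, `dn2`.
#' @export
rate_series <- function(a, b, tau, window = 5120, stride = window, L) {
  stopifnot(window >= 1, stride >= 1, L >= window)
  cum <- cumulative_counts(a, b, tau)
  n <- seq(window, L, by = stride)
  hi <- eval_cumulative(cum, n)
  lo <- eval_cumulative(cum, n - window)
  count_in <- function(t, n) {
    findInterval(n, t) - findInterval(n - window - 1e-9, t)
  }
  dn1 <- count_in(cum$t1, n)
  dn2 <- count_in(cum$t2, n)
  denom <- dn1 * dn2
  dQ <- ifelse(denom > 0, (hi$Qn - lo$Qn) / denom, 0)
  dq <- ifelse(denom > 0, (hi$qn - lo$qn) / denom, 0)
  tibble::tibble(n = n, dQ = dQ, dq = dq, dn1 = dn1, dn2 = dn2)
}

#' Directed edge weight from windowed rates
#'
#' The weight is the amplified product of the causality and synchronization
#' rates when the causality rate is positive, and 0 otherwise, so at most
#' one direction of a channel pair carries weight at any time.
#'
#' @param dq,dQ Numeric vectors of windowed rates (recycled).
#' @param gamma Amplification factor (default 1000).
#' @return Numeric vector of nonnegative weights.
#' @export
adjacency_weight <- function(dq, dQ, gamma = 1000) {
  ifelse(dq > 0, gamma * dq * dQ, 0)
}
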