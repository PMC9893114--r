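#' Recording container
#'
#' Multichannel signal matrix (channels x samples) with sampling rate,
#' channel labels, and optional phase annotations.
#'
#' @param data Numeric matrix, one row per channel; no missing values.
#' @param fs Sampling rate in samples per second.
#' @param channel_names Character labels, one per row.
#' @param annotations Optional tibble `label, start_sample, end_sample`.
#' @return An object of class `recording`.
#' @export
new_recording <- function(data, fs, channel_names = NULL, annotations = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), !anyNA(data), fs > 0)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  stopifnot(length(channel_names) == nrow(data))
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         annotations = annotations),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 1), " s)\n",
      sep = "")
  if (!is.null(x$annotations)) {
    cat("  phases:", paste(x$annotations$label, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build the time-resolved effective network of a recording
#'
#' For every ordered channel pair, events are detected, the pair delay scale
#' computed over the full recording, and windowed synchronization/causality
#' rates evaluated at the stride points `n = delta_n, delta_n + stride, ...`;
#' the directed weight of channel `i` on channel `j` at time `n` is the
#' amplified product of the positive causality rate and the synchronization
#' rate. Channels with fewer than 2 events contribute all-zero rows and
#' columns; the diagonal is identically zero.
#'
#' @param recording A `recording` object.
#' @inheritParams detect_events
#' @param delta_n Rate window in samples (default 5120, i.e. 10 s at 512 Hz).
#' @param stride Spacing of the snapshot times (default `delta_n`).
#' @param gamma Amplification factor for the edge weights (default 1000).
#' @param mode Normalization mode recorded for downstream summaries (the
#'   adjacency itself uses the raw windowed counts).
#' @return An object of class `effective_network`: weight array
#'   `W[i, j, t]`, snapshot times, channel labels, and the parameters used.
#' @seealso [tidy.effective_network()], [index_time_course()]
#' @export
build_network <- function(recording, M = 10, h = 30, delta_n = 5120,
                          stride = delta_n, gamma = 1000,
                          mode = c("sqrt_mm", "product_mm")) {
  stopifnot(inherits(recording, "recording"))
  mode <- match.arg(mode)
  N <- nrow(recording$data)
  if (N < 2) stop("need at least 2 channels")
  L <- ncol(recording$data)
  stopifnot(L >= delta_n)
  trains <- lapply(seq_len(nrow(recording$data)), function(ch) {
    detect_events(recording$data[ch, ], M = M, h = h)
  })
  if (all(lengths(trains) == 0)) {
    warning("all channels are eventless; returning all-zero snapshots")
  }
  times <- seq(delta_n, L, by = stride)
  W <- array(0, dim = c(N, N, length(times)))
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      a <- trains[[i]]; b <- trains[[j]]
      if (length(a) < 2 || length(b) < 2) next
      tau <- delay_scale(a, b)
      rs <- rate_series(a, b, tau, window = delta_n, stride = stride, L = L)
      # q > 0: channel i drives channel j
      W[i, j, ] <- adjacency_weight(rs$dq, rs$dQ, gamma)
      W[j, i, ] <- adjacency_weight(-rs$dq, rs$dQ, gamma)
    }
  }
  structure(
    list(W = W, times = times, channels = recording$channel_names,
         params = list(M = M, h = h, delta_n = delta_n, stride = stride,
                       gamma = gamma, mode = mode, fs = recording$fs),
         annotations = recording$annotations),
    class = "effective_network"
  )
}

#' @export
print.effective_network <- function(x, ...) {
  cat("<effective_network> ", length(x$channels), " nodes, ",
      length(x$times), " snapshots (delta_n = ", x$params$delta_n,
      ", stride = ", x$params$stride, ", gamma = ", x$params$gamma, ")\n",
      sep = "")
  invisible(x)
}

#' Extract one adjacency snapshot
#'
#' @param network An `effective_network`.
#' @param t Snapshot index (1-based position in `network$times`).
#' @return Numeric weight matrix with channel dimnames.
#' @export
snapshot_matrix <- function(network, t) {
  stopifnot(inherits(network, "effective_network"),
            t >= 1, t <= length(network$times))
  A <- network$W[, , t]
  dimnames(A) <- list(network$channels, network$channels)
  A
}

#' Tidy an effective network into a long edge table
#'
#' @param x An `effective_network`.
#' @param ... Unused.
#' @return Tibble `time, from, to, weight` (off-diagonal entries only).
#' @export
tidy.effective_network <- function(x, ...) {
  N <- length(x$channels)
  grid <- expand.grid(from = seq_len(N), to = seq_len(N),
                      t = seq_along(x$times))
  grid <- grid[grid$from != grid$to, ]
  tibble::tibble(
    time = x$times[grid$t],
    from = x$channels[grid$from],
    to = x$channels[grid$to],
    weight = x$W[cbind(grid$from, grid$to, grid$t)]
  )
}

#' Summarise an effective network
#'
#' @param x An `effective_network`.
#' @param ... Unused.
#' @return One-row tibble with node/snapshot counts and weight summaries.
#' @export
glance.effective_network <- function(x, ...) {
  N <- length(x$channels)
  off <- x$W[rep(c(!diag(N)) > 0, length(x$times))]
  tibble::tibble(
    n_nodes = length(x$channels),
    n_snapshots = length(x$times),
    mean_weight = mean(off),
    max_weight = max(off),
    density = mean(off > 0)
  )
}
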