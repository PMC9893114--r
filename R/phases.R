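phase_vocabulary <- c("interictal", "preictal", "ictal", "postictal")

#' Validate and order a phase segmentation
#'
#' @param annotations Data frame with columns `label`, `start_sample`,
#'   `end_sample` (inclusive sample windows). Labels must be one of
#'   interictal, preictal, ictal, postictal; windows must not overlap.
#' @return Tibble ordered by `start_sample`.
#' @export
segment_phases <- function(annotations) {
  ann <- tibble::as_tibble(annotations)
  stopifnot(all(c("label", "start_sample", "end_sample") %in% names(ann)))
  bad <- setdiff(unique(ann$label), phase_vocabulary)
  if (length(bad)) {
    stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  }
  ann <- dplyr::arrange(ann, .data$start_sample)
  if (any(ann$end_sample < ann$start_sample)) {
    stop("phase window with end before start")
  }
  if (nrow(ann) > 1 &&
      any(ann$start_sample[-1] <= ann$end_sample[-nrow(ann)])) {
    stop("overlapping phase windows")
  }
  ann
}

#' Split a segmentation into analysis intervals
#'
#' Each phase window is split into `n_sub` equal sub-intervals, mirroring
#' the per-phase interval scheme used for peak tracking (two interictal
#' intervals plus two sub-intervals per seizure phase by default).
#'
#' @param segmentation Tibble from [segment_phases()].
#' @param n_sub Sub-intervals per phase window (default 2).
#' @return Tibble `interval, phase, start_sample, end_sample`.
#' @export
phase_intervals <- function(segmentation, n_sub = 2) {
  stopifnot(n_sub >= 1)
  seg <- segment_phases(segmentation)
  rows <- purrr::pmap_dfr(seg, function(label, start_sample, end_sample, ...) {
    cuts <- round(seq(start_sample, end_sample + 1, length.out = n_sub + 1))
    tibble::tibble(
      phase = label,
      start_sample = cuts[-length(cuts)],
      end_sample = cuts[-1] - 1
    )
  })
  tibble::add_column(rows, interval = seq_len(nrow(rows)), .before = 1)
}

#' Kernel-density summary of balance-index values
#'
#' Gaussian-kernel density of `H_sb` values on a fixed grid over
#' `[-1, 1]`, renormalized to unit trapezoidal integral on the grid.
#' Bandwidth follows Silverman's rule of thumb; degenerate samples (all
#' values equal) fall back to a fixed bandwidth of 0.01. Modes are local
#' maxima whose topographic prominence is at least `prominence` times the
#' peak density.
#'
#' @param values Numeric vector of balance-index values (at least 2).
#' @param bw Bandwidth: `"nrd0"` (Silverman, default) or a positive number.
#' @param grid_n Grid size (default 512).
#' @param prominence Mode-counting prominence floor as a fraction of the
#'   peak density (default 0.05).
#' @return An object of class `hsb_density`: tibble `grid, density` plus
#'   `bandwidth`, `peak_x`, `peak_density`, `n_modes`, `n`.
#' @export
kde_hsb <- function(values, bw = "nrd0", grid_n = 512, prominence = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("insufficient samples: need at least 2 values")
  bwv <- if (is.numeric(bw)) bw else stats::bw.nrd0(values)
  if (!is.finite(bwv) || bwv <= 0) bwv <- 0.01
  d <- stats::density(values, bw = bwv, kernel = "gaussian",
                      from = -1, to = 1, n = grid_n)
  dens <- d$y
  area <- trapz(d$x, dens)
  if (area > 0) dens <- dens / area
  peaks <- find_modes(d$x, dens, prominence)
  i_max <- which.max(dens)
  structure(
    list(curve = tibble::tibble(grid = d$x, density = dens),
         bandwidth = bwv, peak_x = d$x[i_max], peak_density = dens[i_max],
         n_modes = nrow(peaks), modes = peaks, n = length(values)),
    class = "hsb_density"
  )
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

# local maxima of y with topographic prominence >= floor * max(y)
find_modes <- function(x, y, prominence) {
  n <- length(y)
  is_pk <- c(y[1] > y[2],
             y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
             y[n] > y[n - 1])
  pk <- which(is_pk)
  if (!length(pk)) {
    return(tibble::tibble(x = numeric(0), density = numeric(0),
                          prominence = numeric(0)))
  }
  prom <- vapply(pk, function(p) {
    left <- y[seq_len(p)]
    right <- y[p:n]
    higher_l <- which(left > y[p])
    higher_r <- which(right > y[p]) + p - 1L
    ref_l <- if (length(higher_l)) min(y[max(higher_l):p]) else min(left)
    ref_r <- if (length(higher_r)) min(y[p:min(higher_r)]) else min(right)
    y[p] - max(ref_l, ref_r)
  }, numeric(1))
  keep <- prom >= prominence * max(y)
  tibble::tibble(x = x[pk[keep]], density = y[pk[keep]],
                 prominence = prom[keep])
}

#' @export
print.hsb_density <- function(x, ...) {
  cat("<hsb_density> n = ", x$n, ", bw = ", signif(x$bandwidth, 3),
      ", peak at ", signif(x$peak_x, 3), " (density ",
      signif(x$peak_density, 3), "), ", x$n_modes, " mode(s)\n", sep = "")
  invisible(x)
}

#' @export
glance.hsb_density <- function(x, ...) {
  tibble::tibble(n = x$n, bandwidth = x$bandwidth, peak_x = x$peak_x,
                 peak_density = x$peak_density, n_modes = x$n_modes)
}

#' @export
tidy.hsb_density <- function(x, ...) x$curve

#' Per-interval density peaks of a balance-index time course
#'
#' @param indices Tibble with columns `time` and `H_sb_norm`
#'   (e.g. from [index_time_course()]).
#' @param intervals Tibble from [phase_intervals()].
#' @param min_points Minimum snapshots per interval (default 2); intervals
#'   with fewer are dropped.
#' @param ... Passed to [kde_hsb()].
#' @return Tibble `interval, phase, n, peak_x, peak_density, n_modes`.
#' @export
interval_peaks <- function(indices, intervals, min_points = 2, ...) {
  purrr::pmap_dfr(intervals, function(interval, phase, start_sample,
                                      end_sample, ...) {
    v <- indices$H_sb_norm[indices$time >= start_sample &
                             indices$time <= end_sample]
    if (length(v) < min_points) return(NULL)
    g <- glance(kde_hsb(v))
    tibble::tibble(interval = interval, phase = phase, n = length(v),
                   peak_x = g$peak_x, peak_density = g$peak_density,
                   n_modes = g$n_modes)
  })
}

#' Plunge statistics of a peak-location series
#'
#' A plunge episode is a strict drop of the density-peak location by more
#' than `threshold` below the running pre-drop level, followed by a rebound
#' to within `threshold / 2` of that level. The plunge interval spans the
#' observed extremes of the peak locations.
#'
#' @param peaks Tibble from [interval_peaks()] (needs `interval`, `peak_x`),
#'   or a bare numeric vector of peak locations.
#' @param threshold Drop threshold in normalized balance units (default 0.3).
#' @return An object of class `plunge_stats` with the episode table, the
#'   plunge interval `(min, max, length)`, the episode count, and the
#'   interval ids of the episode minima (`plunge_times`).
#' @export
peak_track <- function(peaks, threshold = 0.3) {
  if (is.numeric(peaks)) {
    peaks <- tibble::tibble(interval = seq_along(peaks), peak_x = peaks)
  }
  stopifnot(all(c("interval", "peak_x") %in% names(peaks)))
  if (nrow(peaks) < 3) stop("need at least 3 intervals to track peaks")
  x <- peaks$peak_x
  ids <- peaks$interval
  episodes <- list()
  ref <- x[1]
  in_plunge <- FALSE
  start_id <- min_id <- NA_integer_
  min_x <- Inf
  for (k in seq_along(x)[-1]) {
    if (!in_plunge) {
      if (x[k] < ref - threshold) {
        in_plunge <- TRUE
        start_id <- ids[k]; min_id <- ids[k]; min_x <- x[k]
      } else {
        ref <- max(ref, x[k])
      }
    } else {
      if (x[k] < min_x) { min_x <- x[k]; min_id <- ids[k] }
      if (x[k] >= ref - threshold / 2) {
        episodes[[length(episodes) + 1L]] <- tibble::tibble(
          start = start_id, minimum = min_id, rebound = ids[k],
          depth = ref - min_x)
        in_plunge <- FALSE
        ref <- x[k]
        min_x <- Inf
      }
    }
  }
  episodes <- if (length(episodes)) dplyr::bind_rows(episodes) else
    tibble::tibble(start = integer(0), minimum = integer(0),
                   rebound = integer(0), depth = numeric(0))
  structure(
    list(peaks = peaks, threshold = threshold, episodes = episodes,
         plunge_count = nrow(episodes), plunge_times = episodes$minimum,
         plunge_interval = c(min = min(x), max = max(x),
                             length = max(x) - min(x))),
    class = "plunge_stats"
  )
}

#' @export
print.plunge_stats <- function(x, ...) {
  cat("<plunge_stats> ", x$plunge_count, " episode(s); peak_x range [",
      signif(x$plunge_interval["min"], 3), ", ",
      signif(x$plunge_interval["max"], 3), "] (length ",
      signif(x$plunge_interval["length"], 3), "), threshold ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.plunge_stats <- function(x, ...) x$episodes

#' @export
glance.plunge_stats <- function(x, ...) {
  tibble::tibble(plunge_count = x$plunge_count,
                 interval_min = unname(x$plunge_interval["min"]),
                 interval_max = unname(x$plunge_interval["max"]),
                 interval_length = unname(x$plunge_interval["length"]),
                 threshold = x$threshold)
}

#' Run the full pipeline on channel sub-networks
#'
#' Re-runs event detection, network construction, eigenmode indices, and
#' peak/plunge statistics on each channel subset (e.g. global vs. local
#' epileptogenic vs. local non-epileptogenic scopes), aligned on the same
#' snapshot times for cross-scope comparison.
#'
#' @param recording A `recording` with phase annotations.
#' @param scopes Named list of channel-label vectors, or a data frame with
#'   columns `scope` and `channel`.
#' @param M,h,delta_n,stride,gamma See [build_network()].
#' @param n_sub Sub-intervals per phase for the peak table (default 2).
#' @param threshold Plunge threshold (default 0.3).
#' @return An object of class `scoped_analysis`: tibbles `indices` (with a
#'   `scope` column) and `peaks`, plus a named list `plunges`.
#' @export
scoped_analysis <- function(recording, scopes, M = 10, h = 30,
                            delta_n = 5120, stride = delta_n, gamma = 1000,
                            n_sub = 2, threshold = 0.3) {
  stopifnot(inherits(recording, "recording"),
            !is.null(recording$annotations))
  if (is.data.frame(scopes)) {
    scopes <- split(scopes$channel, scopes$scope)
  }
  stopifnot(length(names(scopes)) == length(scopes))
  missing_ch <- setdiff(unlist(scopes), recording$channel_names)
  if (length(missing_ch)) {
    stop("scope channel(s) missing from recording: ",
         paste(missing_ch, collapse = ", "))
  }
  intervals <- phase_intervals(recording$annotations, n_sub = n_sub)
  res <- purrr::imap(scopes, function(chans, name) {
    keep <- match(chans, recording$channel_names)
    sub <- new_recording(recording$data[keep, , drop = FALSE], recording$fs,
                         recording$channel_names[keep],
                         recording$annotations)
    net <- build_network(sub, M = M, h = h, delta_n = delta_n,
                         stride = stride, gamma = gamma)
    idx <- index_time_course(net)
    pk <- interval_peaks(idx, intervals)
    list(indices = tibble::add_column(tibble::as_tibble(idx), scope = name,
                                      .before = 1),
         peaks = tibble::add_column(pk, scope = name, .before = 1),
         plunges = peak_track(pk, threshold = threshold))
  })
  structure(
    list(indices = dplyr::bind_rows(purrr::map(res, "indices")),
         peaks = dplyr::bind_rows(purrr::map(res, "peaks")),
         plunges = purrr::map(res, "plunges"),
         intervals = intervals),
    class = "scoped_analysis"
  )
}

#' @export
print.scoped_analysis <- function(x, ...) {
  scopes <- unique(x$indices$scope)
  cat("<scoped_analysis> scopes:", paste(scopes, collapse = ", "), "\n")
  for (s in scopes) {
    cat("  ", s, ": ", x$plunges[[s]]$plunge_count, " plunge episode(s)\n",
        sep = "")
  }
  invisible(x)
}
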