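#' Configuration for the synthetic SEEG generator
#'
#' Defines a multichannel recording with background transient events,
#' directed pairwise couplings, re-entrant cascade circuits, and a seizure
#' phase plan. All randomness is governed by `seed`; identical
#' configurations generate bit-identical recordings and ground truth.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate in samples/s (default 512).
#' @param duration Recording length in seconds.
#' @param event_rate Background event rate per channel, events/s (default
#'   0.5, emulating sparse high-amplitude transients).
#' @param event_amplitude Event bump amplitude in signal units (default 100;
#'   must comfortably exceed the detection margin `h`).
#' @param event_halfwidth Gaussian bump scale in samples (default 5).
#' @param noise_sd Background noise standard deviation (default 5).
#' @param refractory Minimum spacing of events on one channel, in samples
#'   (default 20 = 2 M for the default detector; closer planted events are
#'   thinned, keeping the earliest).
#' @param coupling_edges Optional tibble `source, target, prob, lag`:
#'   each source-channel event propagates to the target channel at
#'   `lag >= 1` samples with the given probability.
#' @param cascades Optional list of re-entrant cascade circuits, each a list
#'   with `channels` (ordered member channels), `lag` (hop lag, samples),
#'   `interval` (samples between cascade onsets), `n_loops` (full traversals
#'   per onset), `phase_prob` (named vector: hop probability per phase
#'   label; phases not named get 0, i.e. the circuit is silent), and an
#'   optional `offset` (samples added to the first onset, to interleave
#'   circuits). Cascades are the coupling-regime override: one generator,
#'   phases switch their activation.
#' @param phase_plan Tibble `label, start_sample, end_sample` covering
#'   `[1, duration * fs]` with disjoint windows; optional columns
#'   `rate_scale` and `edge_prob_scale` override the background event rate
#'   and edge probabilities per phase (default 1). Default: one interictal
#'   window.
#' @param focus_channels Channel indices of the epileptogenic focus
#'   (annotation only; circuits reference channels directly).
#' @param seed Integer seed.
#' @param warn_h Detection margin used for the amplitude sanity warning
#'   (default 30).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_channels, duration, fs = 512, event_rate = 0.5,
                         event_amplitude = 100, event_halfwidth = 5,
                         noise_sd = 5, refractory = 20,
                         coupling_edges = NULL, cascades = NULL,
                         phase_plan = NULL, focus_channels = integer(0),
                         seed = 1, warn_h = 30) {
  stopifnot(n_channels >= 1, fs > 0, duration > 0, event_rate >= 0,
            event_halfwidth >= 1, noise_sd >= 0, refractory >= 1)
  L <- as.integer(round(duration * fs))
  if (is.null(phase_plan)) {
    phase_plan <- tibble::tibble(label = "interictal", start_sample = 1L,
                                 end_sample = L)
  }
  phase_plan <- segment_phases(phase_plan)
  if (!"rate_scale" %in% names(phase_plan)) phase_plan$rate_scale <- 1
  if (!"edge_prob_scale" %in% names(phase_plan)) {
    phase_plan$edge_prob_scale <- 1
  }
  if (phase_plan$start_sample[1] != 1L ||
      phase_plan$end_sample[nrow(phase_plan)] != L ||
      (nrow(phase_plan) > 1 &&
       any(phase_plan$start_sample[-1] !=
           phase_plan$end_sample[-nrow(phase_plan)] + 1L))) {
    stop("phase plan must cover [1, duration * fs] without gaps")
  }
  if (!is.null(coupling_edges)) {
    coupling_edges <- tibble::as_tibble(coupling_edges)
    stopifnot(all(c("source", "target", "prob", "lag") %in%
                    names(coupling_edges)),
              all(coupling_edges$prob >= 0 & coupling_edges$prob <= 1),
              all(coupling_edges$lag >= 1),
              all(c(coupling_edges$source, coupling_edges$target) %in%
                    seq_len(n_channels)))
  }
  if (!is.null(cascades)) {
    for (cs in cascades) {
      stopifnot(all(cs$channels %in% seq_len(n_channels)),
                cs$lag >= 1, cs$interval >= 1, cs$n_loops >= 1,
                all(cs$phase_prob >= 0 & cs$phase_prob <= 1))
    }
  }
  stopifnot(all(focus_channels %in% seq_len(n_channels)))
  if (event_rate > 0 && event_amplitude <= warn_h) {
    warning("event_amplitude <= detection margin h = ", warn_h,
            ": the detector will miss planted events")
  }
  structure(
    list(n_channels = as.integer(n_channels), fs = fs, duration = duration,
         L = L, event_rate = event_rate, event_amplitude = event_amplitude,
         event_halfwidth = event_halfwidth, noise_sd = noise_sd,
         refractory = refractory, coupling_edges = coupling_edges,
         cascades = cascades, phase_plan = phase_plan,
         focus_channels = as.integer(focus_channels),
         seed = as.integer(seed), warn_h = warn_h),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_channels, " channels x ", x$duration,
      " s @ ", x$fs, " Hz; background ", x$event_rate,
      " ev/s; seed ", x$seed, "\n", sep = "")
  cat("  phases:", paste(x$phase_plan$label, collapse = " -> "), "\n")
  invisible(x)
}

# thin a sorted time vector to a minimum spacing, keeping the earliest
thin_times <- function(t, min_gap) {
  t <- sort(unique(t))
  if (length(t) < 2) return(t)
  keep <- logical(length(t))
  last <- -Inf
  for (k in seq_along(t)) {
    if (t[k] - last >= min_gap) {
      keep[k] <- TRUE
      last <- t[k]
    }
  }
  t[keep]
}

#' Generate a synthetic recording with ground truth
#'
#' Background: zero-mean Gaussian noise plus smooth Gaussian bumps at
#' planted event times. Events arise from (a) per-channel Poisson
#' background, (b) directed couplings propagating source events to target
#' channels at a fixed lag with given probability, and (c) re-entrant
#' cascade circuits active in selected phases. Events on one channel closer
#' than the refractory spacing are thinned (earliest kept), so the planted
#' trains are always detectable as distinct local maxima.
#'
#' @param config A `synth_config`.
#' @return List with elements `recording` (a [new_recording()] object with
#'   phase annotations) and `truth` (list: `events` tibble
#'   `channel, time`; `couplings` tibble
#'   `source, source_time, target, target_time`; `phase_labels`
#'   per-sample factor).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, simulate_recording_impl(config))
}

simulate_recording_impl <- function(cfg) {
  L <- cfg$L
  N <- cfg$n_channels
  planted <- vector("list", N)

  # (a) background Poisson events, per phase (rate_scale override)
  for (ph in seq_len(nrow(cfg$phase_plan))) {
    s0 <- cfg$phase_plan$start_sample[ph]
    s1 <- cfg$phase_plan$end_sample[ph]
    rate <- cfg$event_rate * cfg$phase_plan$rate_scale[ph]
    len_s <- (s1 - s0 + 1) / cfg$fs
    for (ch in seq_len(N)) {
      k <- stats::rpois(1, rate * len_s)
      if (k > 0) {
        planted[[ch]] <- c(planted[[ch]],
                           sort(sample(s0:s1, min(k, s1 - s0 + 1))))
      }
    }
  }

  # (b) directed couplings: propagate background events
  coup <- list()
  if (!is.null(cfg$coupling_edges)) {
    for (e in seq_len(nrow(cfg$coupling_edges))) {
      src <- cfg$coupling_edges$source[e]
      tgt <- cfg$coupling_edges$target[e]
      lag <- cfg$coupling_edges$lag[e]
      src_t <- sort(planted[[src]])
      if (!length(src_t)) next
      scale <- cfg$phase_plan$edge_prob_scale[
        findInterval(src_t, cfg$phase_plan$start_sample)]
      fired <- stats::runif(length(src_t)) <
        cfg$coupling_edges$prob[e] * scale
      tgt_t <- src_t[fired] + lag
      tgt_t <- tgt_t[tgt_t <= L]
      if (length(tgt_t)) {
        planted[[tgt]] <- c(planted[[tgt]], tgt_t)
        coup[[length(coup) + 1L]] <- tibble::tibble(
          source = src, source_time = tgt_t - lag,
          target = tgt, target_time = tgt_t)
      }
    }
  }

  # (c) re-entrant cascades, activated per phase
  if (!is.null(cfg$cascades)) {
    for (cs in cfg$cascades) {
      k <- length(cs$channels)
      for (ph in seq_len(nrow(cfg$phase_plan))) {
        prob <- cs$phase_prob[cfg$phase_plan$label[ph]]
        if (is.na(prob) || prob <= 0) next
        s0 <- cfg$phase_plan$start_sample[ph]
        s1 <- cfg$phase_plan$end_sample[ph]
        off <- if (is.null(cs$offset)) 0 else cs$offset
        span <- k * cs$lag * cs$n_loops
        if (s1 - span < s0 + off) next
        onsets <- seq(s0 + off, s1 - span, by = cs$interval)
        for (onset in onsets) {
          hops <- seq_len(k * cs$n_loops) - 1L
          t_hop <- onset + hops * cs$lag
          ch_hop <- cs$channels[hops %% k + 1L]
          fired <- stats::runif(length(hops)) < prob
          for (ch in unique(ch_hop[fired])) {
            planted[[ch]] <- c(planted[[ch]], t_hop[fired & ch_hop == ch])
          }
          # realized hop links among consecutive fired hops one lag apart
          fr <- which(fired)
          adj <- fr[which(diff(fr) == 1L)]
          if (length(adj)) {
            coup[[length(coup) + 1L]] <- tibble::tibble(
              source = ch_hop[adj], source_time = t_hop[adj],
              target = ch_hop[adj + 1L], target_time = t_hop[adj + 1L])
          }
        }
      }
    }
  }

  planted <- lapply(planted, thin_times, min_gap = cfg$refractory)
  # keep bumps clear of the series ends so every planted event is a
  # complete, detectable local maximum
  margin <- 4 * cfg$event_halfwidth
  planted <- lapply(planted, function(t) {
    as.integer(t[t > margin & t <= L - margin])
  })

  # keep only realized couplings whose both endpoints survived thinning
  couplings <- if (length(coup)) dplyr::bind_rows(coup) else
    tibble::tibble(source = integer(0), source_time = integer(0),
                   target = integer(0), target_time = integer(0))
  if (nrow(couplings)) {
    ok <- vapply(seq_len(nrow(couplings)), function(r) {
      couplings$source_time[r] %in% planted[[couplings$source[r]]] &&
        couplings$target_time[r] %in% planted[[couplings$target[r]]]
    }, logical(1))
    couplings <- couplings[ok, ]
  }

  data <- matrix(if (cfg$noise_sd > 0) stats::rnorm(N * L, 0, cfg$noise_sd)
                 else 0, nrow = N, ncol = L)
  hw <- cfg$event_halfwidth
  support <- -(4 * hw):(4 * hw)
  bump <- cfg$event_amplitude * exp(-0.5 * (support / hw)^2)
  for (ch in seq_len(N)) {
    for (t0 in planted[[ch]]) {
      at <- t0 + support
      ok <- at >= 1 & at <= L
      data[ch, at[ok]] <- data[ch, at[ok]] + bump[ok]
    }
  }

  ann <- cfg$phase_plan[, c("label", "start_sample", "end_sample")]
  phase_labels <- factor(phase_at(ann, seq_len(L)),
                         levels = phase_vocabulary)
  truth <- list(
    events = tibble::tibble(
      channel = rep(seq_len(N), lengths(planted)),
      time = unlist(planted, use.names = FALSE)),
    couplings = couplings,
    phase_labels = phase_labels
  )
  rec <- new_recording(data, cfg$fs, annotations = ann)
  list(recording = rec, truth = truth)
}

#' Canonical synthetic patient scenario
#'
#' A 16-channel, 160 s recording with interictal (60 s), preictal (30 s),
#' ictal (40 s) and postictal (30 s) phases. Channels 1-8 form the
#' epileptogenic focus: during the ictal phase they sustain a continuous
#' 8-channel re-entrant cascade (hop lag 8 samples), the hypersynchronous
#' strong-local regime.
#' Channels 9-11 additionally carry a slower, strong re-entrant loop
#' during the seizure and background spiking is elevated across the whole
#' montage. Within the focus scope the circuit's eigenmodes are
#' homogeneous and the balance index plunges towards its ring floor;
#' globally the relay loop contributes a dominant integrative mode, so
#' the global plunge is genuinely shallower.
#'
#' @param seed Integer seed.
#' @param duration Total length in seconds (default 160; phases scale
#'   proportionally).
#' @param ictal_hop_prob Hop probability of the focus circuit during the
#'   ictal phase (default 0.95).
#' @return A `synth_config`.
#' @export
synth_patient_config <- function(seed = 1, duration = 160,
                                 ictal_hop_prob = 0.95) {
  fs <- 512
  L <- duration * fs
  cuts <- round(L * c(0, 0.375, 0.5625, 0.8125, 1))
  plan <- tibble::tibble(
    label = c("interictal", "preictal", "ictal", "postictal"),
    start_sample = cuts[1:4] + 1L,
    end_sample = cuts[2:5],
    # background spiking is elevated across the whole montage during the
    # seizure and settles through the post-ictal phase
    rate_scale = c(1, 1, 4, 1)
  )
  synth_config(
    n_channels = 16, duration = duration, fs = fs,
    focus_channels = 1:8, phase_plan = plan, seed = seed,
    cascades = list(
      # focus re-entry: continuous ictally, intermittent pre-ictally
      list(channels = 1:8, lag = 8, interval = 64, n_loops = 1,
           phase_prob = c(ictal = ictal_hop_prob)),
      # slow, strong re-entrant loop through remote relay contacts during
      # the seizure: a dominant integrative mode at the global scope
      list(channels = 9:11, lag = 8, interval = 160, n_loops = 2,
           offset = 24, phase_prob = c(ictal = 0.9))
    )
  )
}

#' Canonical synthetic control scenario
#'
#' Same channel count, duration, and background event statistics as the
#' patient scenario but without any planted coupling structure: channels
#' are independent, so the balance index fluctuates around 0.
#'
#' @param seed Integer seed.
#' @param duration Total length in seconds (default 160).
#' @return A `synth_config`.
#' @export
synth_control_config <- function(seed = 1, duration = 160) {
  synth_config(n_channels = 16, duration = duration, fs = 512, seed = seed)
}
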