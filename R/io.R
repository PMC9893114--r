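#' Write a recording and its ground truth as plain-text fixture files
#'
#' Writes `data.txt` (tab-delimited channels x samples matrix),
#' `annotations.csv` (`label,start_sample,end_sample`), `truth.csv`
#' (`channel,event_sample`), and `meta.yml` (fs, channel names). The files
#' round-trip bit-exactly through [read_recording()] for integer sample
#' indices.
#'
#' @param recording A `recording`.
#' @param truth Ground-truth list from [simulate_recording()], or `NULL`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_fixture <- function(recording, truth = NULL, dir) {
  stopifnot(inherits(recording, "recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(recording$data, file.path(dir, "data.txt"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(fs = recording$fs,
                        channel_names = recording$channel_names),
                   file.path(dir, "meta.yml"))
  ann <- recording$annotations
  if (is.null(ann)) {
    ann <- tibble::tibble(label = character(0), start_sample = integer(0),
                          end_sample = integer(0))
  }
  utils::write.csv(ann, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  ev <- if (is.null(truth)) {
    tibble::tibble(channel = integer(0), event_sample = integer(0))
  } else {
    tibble::tibble(channel = truth$events$channel,
                   event_sample = truth$events$time)
  }
  utils::write.csv(ev, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a multichannel recording
#'
#' Delimited format: one channel per row, whitespace/tab separated; the
#' sampling rate comes from a `meta.yml` sidecar in the same directory or
#' from the `fs` argument. EDF format: a minimal reader for continuous
#' EDF/EDF+C files with identical sampling rates across signals.
#'
#' @param path Path to the data file (`data.txt`-style matrix or `.edf`).
#' @param format `"delimited"` or `"edf"` (default guessed from the
#'   extension).
#' @param fs Sampling rate override for delimited input without a sidecar.
#' @return A `recording`; phase annotations are attached when an
#'   `annotations.csv` sidecar exists.
#' @export
read_recording <- function(path, format = NULL, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
    else "delimited"
  }
  format <- match.arg(format, c("delimited", "edf"))
  if (format == "edf") return(read_edf(path))
  if (file.size(path) == 0) stop("empty file: ", path)
  data <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(data) <- NULL
  meta_path <- file.path(dirname(path), "meta.yml")
  channel_names <- NULL
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (is.null(fs)) fs <- meta$fs
    channel_names <- meta$channel_names
  }
  if (is.null(fs)) {
    stop("fs missing: provide `fs` or a meta.yml sidecar")
  }
  ann_path <- file.path(dirname(path), "annotations.csv")
  ann <- NULL
  if (file.exists(ann_path)) {
    ann <- read_annotations(ann_path)
    if (!nrow(ann)) ann <- NULL
  }
  new_recording(data, fs, channel_names, ann)
}

#' Read a phase-annotation file
#'
#' @param path CSV with columns `label,start_sample,end_sample`.
#' @return Validated, ordered tibble (see [segment_phases()]).
#' @export
read_annotations <- function(path) {
  ann <- tibble::as_tibble(utils::read.csv(path))
  if (!nrow(ann)) return(ann)
  segment_phases(ann)
}

#' Read a ground-truth event file
#'
#' @param path CSV with columns `channel,event_sample`.
#' @return Tibble `channel, time`, ordered by channel then time.
#' @export
read_truth <- function(path) {
  tr <- tibble::as_tibble(utils::read.csv(path))
  tibble::tibble(channel = as.integer(tr$channel),
                 time = as.integer(tr$event_sample))
}

# --- minimal EDF (16-bit, continuous, equal fs) ---------------------------

edf_pad <- function(x, width) {
  formatC(substr(as.character(x), 1, width), width = width, flag = "-")
}

#' Write a recording as a minimal EDF file
#'
#' Continuous EDF with one data record per second and identical sampling
#' rate on all signals. Physical and digital ranges are mapped over the
#' observed amplitude range; like any EDF writer this quantizes amplitudes
#' to 16 bits.
#'
#' @param recording A `recording`; `fs` must be a whole number and the
#'   length a whole number of seconds.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "recording"))
  data <- recording$data
  ns <- nrow(data)
  fs <- as.integer(recording$fs)
  stopifnot(recording$fs == fs, ncol(data) %% fs == 0)
  n_rec <- ncol(data) %/% fs
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  pmax_[pmax_ <= pmin_] <- pmin_[pmax_ <= pmin_] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) {
    writeChar(paste(edf_pad(x, width), collapse = ""), con,
              eos = NULL, useBytes = TRUE)
  }
  wr("0", 8)                                  # version
  wr("X X X X", 80); wr("Startdate X", 80)    # patient / recording ids
  wr("01.01.00", 8); wr("00.00.00", 8)        # date, time
  wr(as.character(256 * (1 + ns)), 8)         # header bytes
  wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8)      # records, duration (s)
  wr(as.character(ns), 4)
  wr(recording$channel_names, 16)
  wr(rep("", ns), 80)                         # transducer
  wr(rep("uV", ns), 8)
  wr(as.character(signif(pmin_, 6)), 8); wr(as.character(signif(pmax_, 6)), 8)
  wr(rep(as.character(dmin), ns), 8); wr(rep(as.character(dmax), ns), 8)
  wr(rep("", ns), 80)                         # prefiltering
  wr(rep(as.character(fs), ns), 8)            # samples per record
  wr(rep("", ns), 32)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- data[s, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round((seg - pmin_[s]) / gain[s]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  if (file.size(path) < 256) stop("empty or truncated EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) stop("malformed EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  seek(con, header_bytes)
  if (length(unique(spr)) != 1) {
    stop("minimal EDF reader requires equal sampling rates on all signals")
  }
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                     endian = "little")
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (dig - dmin[s]) * gain[s] + pmin_[s]
    }
  }
  new_recording(data, fs, labels)
}

#' Write adjacency snapshots as delimited matrices with a manifest
#'
#' One tab-delimited dense matrix per snapshot time (rows = source nodes)
#' plus `manifest.csv` (`time_sample,filename`).
#'
#' @param network An `effective_network`.
#' @param dir Output directory.
#' @return Invisibly, the manifest tibble.
#' @export
write_snapshots <- function(network, dir) {
  stopifnot(inherits(network, "effective_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- tibble::tibble(
    time_sample = network$times,
    filename = sprintf("snapshot_%08d.txt", network$times)
  )
  for (t in seq_along(network$times)) {
    utils::write.table(network$W[, , t],
                       file.path(dir, manifest$filename[t]), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
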