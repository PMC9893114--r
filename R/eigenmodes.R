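#' Complex eigenmode spectrum of an asymmetric adjacency matrix
#'
#' Eigenpairs are sorted by eigenvalue modulus, descending (ties broken by
#' angle, ascending); eigenvectors are scaled to unit 2-norm before their
#' component moduli are taken. An eigenvalue modulus measures the stretch of
#' its mode, the angle its rotation; conjugate pairs share a modulus and
#' component moduli.
#'
#' Matrices whose nonzero pattern contains no directed cycle are nilpotent,
#' so their true spectrum is identically zero; this is detected exactly via
#' a DAG check and the moduli forced to zero (dense eigensolvers return
#' spurious moduli of order `norm * eps^(1/N)` for defective nilpotent
#' matrices).
#'
#' @param A Square numeric matrix with finite entries.
#' @return An object of class `complex_spectrum`: `values` (complex, sorted),
#'   `moduli`, `angles`, `vectors` (complex, unit columns), `comp_moduli`
#'   (matrix; column `i` holds the component moduli of eigenvector `i`),
#'   and `N`.
#' @export
complex_spectrum <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be a square matrix")
  if (!all(is.finite(A))) stop("A must have finite entries")
  N <- nrow(A)
  ev <- eigen(A)
  values <- as.complex(ev$values)
  vectors <- ev$vectors
  if (!is.complex(vectors)) vectors <- vectors + 0i
  if (is_acyclic(A)) values[] <- 0 + 0i
  ord <- order(-Mod(values), Arg(values))
  values <- values[ord]
  vectors <- vectors[, ord, drop = FALSE]
  norms <- sqrt(colSums(Mod(vectors)^2))
  norms[norms == 0] <- 1
  vectors <- sweep(vectors, 2L, norms, "/")
  structure(
    list(values = values, moduli = Mod(values), angles = Arg(values),
         vectors = vectors, comp_moduli = Mod(vectors), N = N),
    class = "complex_spectrum"
  )
}

# nonzero pattern has no directed cycle <=> A is nilpotent
is_acyclic <- function(A) {
  g <- igraph::graph_from_adjacency_matrix((A != 0) * 1, mode = "directed")
  igraph::is_dag(g)
}

#' @export
print.complex_spectrum <- function(x, ...) {
  cat("<complex_spectrum> N =", x$N, "; leading moduli:",
      paste(signif(utils::head(x$moduli, 4), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Modulus-band partition of one eigenvector layer
#'
#' The component moduli of the layer's eigenvector are split into three
#' bands relative to their own mean `AVG` and standard deviation `SD`:
#' weak `[0, AVG + SD]`, balance `(AVG + SD, AVG + 2 SD]`, and strong
#' `(AVG + 2 SD, Inf)`. The nonempty bands are the layer's modules; `p` is
#' the module-size heterogeneity correction
#' `sum_j |m_j - N / M| / N`, in `[0, 1)`.
#'
#' The first layer (largest modulus) represents the undivided global mode
#' and is never partitioned, so `layer_index` must be at least 2. Band
#' comparisons use an absolute tolerance of `1e-9 * (1 + max modulus)` so
#' that numerically equal components land in one band deterministically.
#'
#' @param component_moduli Numeric vector of the eigenvector's component
#'   moduli (length N).
#' @param layer_index Layer number `i >= 2`.
#' @return A list with `layer_index`, `labels` (factor: weak/balance/strong),
#'   `module_sizes` (named, nonempty bands only), `M`, `p`, `avg`, `sd`.
#' @export
partition_layer <- function(component_moduli, layer_index) {
  stopifnot(layer_index >= 2)
  cm <- as.numeric(component_moduli)
  if (!length(cm)) stop("empty component vector")
  N <- length(cm)
  avg <- mean(cm)
  s <- stats::sd(cm)
  if (N == 1 || !is.finite(s)) s <- 0
  tol <- 1e-9 * (1 + max(cm))
  labels <- factor(
    ifelse(cm > avg + 2 * s + tol, "strong",
           ifelse(cm > avg + s + tol, "balance", "weak")),
    levels = c("weak", "balance", "strong")
  )
  sizes <- table(labels)
  sizes <- sizes[sizes > 0]
  M <- length(sizes)
  # capped at 1: for N > 12 the raw sum can exceed 1 (three very skewed
  # modules), which would make the layer measure negative
  p <- min(sum(abs(as.numeric(sizes) - N / M)) / N, 1)
  list(layer_index = layer_index, labels = labels,
       module_sizes = as.integer(sizes), M = M, p = p, avg = avg, sd = s)
}

#' Weighted measure of one eigenmode layer
#'
#' `H_i = |Lambda_i|^2 * M_i * (1 - p_i) / N^2`: the squared stretch of the
#' layer, weighted by its module count and discounted for module-size
#' heterogeneity.
#'
#' @param eigen_modulus Eigenvalue modulus of the layer.
#' @param M Number of nonempty modules in the layer.
#' @param p Heterogeneity correction in `[0, 1)`.
#' @param N Total node count.
#' @return Scalar layer measure, nonnegative.
#' @export
layer_measure <- function(eigen_modulus, M, p, N) {
  stopifnot(N >= 1)
  eigen_modulus^2 * M * (1 - p) / N^2
}

#' Oscillation-balance indices of one adjacency snapshot
#'
#' The slow-global index `H_in` is the measure of the undivided first layer
#' (`|Lambda_1|^2 / N^2`); the strong-local index `H_se` sums the
#' band-partitioned measures of layers 2..N. The balance `H_sb_raw` is
#' their difference, and `H_sb_norm = (H_in - H_se) / (H_in + H_se)` is its
#' per-snapshot normalization to `[-1, 1]` (0 when both indices are 0):
#' negative values mean strong-local dominance, positive slow-global
#' dominance.
#'
#' @param x A square nonnegative matrix or a `complex_spectrum`.
#' @return One-row tibble `H_in, H_se, H_sb_raw, H_sb_norm`.
#' @export
oscillation_indices <- function(x) {
  spec <- if (inherits(x, "complex_spectrum")) x else complex_spectrum(x)
  N <- spec$N
  stopifnot(N >= 2)
  H_in <- spec$moduli[1]^2 / N^2  # undivided: M_1 = 1, p_1 = 0
  H_se <- 0
  for (i in 2:N) {
    if (spec$moduli[i] == 0) next
    part <- partition_layer(spec$comp_moduli[, i], i)
    H_se <- H_se + layer_measure(spec$moduli[i], part$M, part$p, N)
  }
  total <- H_in + H_se
  tibble::tibble(
    H_in = H_in, H_se = H_se, H_sb_raw = H_in - H_se,
    H_sb_norm = if (total == 0) 0 else (H_in - H_se) / total
  )
}

#' Per-layer table of eigenmode measures
#'
#' @inheritParams oscillation_indices
#' @return Tibble `layer, modulus, angle, M, p, H` (layer 1 undivided).
#' @export
layer_table <- function(x) {
  spec <- if (inherits(x, "complex_spectrum")) x else complex_spectrum(x)
  N <- spec$N
  rows <- lapply(seq_len(N), function(i) {
    if (i == 1) {
      M <- 1L; p <- 0
    } else {
      part <- partition_layer(spec$comp_moduli[, i], i)
      M <- part$M; p <- part$p
    }
    tibble::tibble(layer = i, modulus = spec$moduli[i],
                   angle = spec$angles[i], M = M, p = p,
                   H = layer_measure(spec$moduli[i], M, p, N))
  })
  dplyr::bind_rows(rows)
}

#' Oscillation-balance time course of an effective network
#'
#' Computes the per-snapshot indices for every adjacency snapshot, carrying
#' the snapshot time and (when annotations are present) the phase label of
#' the window midpoint.
#'
#' @param network An `effective_network` from [build_network()].
#' @param hsb_normalization `"ratio"` (per-snapshot, default) or
#'   `"max_abs"` (divide `H_sb_raw` by its maximum absolute value over the
#'   whole time course).
#' @return A tibble of class `osc_indices` with columns `time`, `H_in`,
#'   `H_se`, `H_sb_raw`, `H_sb_norm`, and `phase` if annotations exist.
#' @export
index_time_course <- function(network,
                              hsb_normalization = c("ratio", "max_abs")) {
  stopifnot(inherits(network, "effective_network"),
            length(network$times) >= 1)
  hsb_normalization <- match.arg(hsb_normalization)
  out <- purrr::map_dfr(seq_along(network$times), function(t) {
    oscillation_indices(network$W[, , t])
  })
  out <- tibble::add_column(out, time = network$times, .before = 1)
  if (hsb_normalization == "max_abs") {
    mx <- max(abs(out$H_sb_raw))
    out$H_sb_norm <- if (mx == 0) rep(0, nrow(out)) else out$H_sb_raw / mx
  }
  if (!is.null(network$annotations)) {
    mid <- out$time - network$params$delta_n / 2
    out$phase <- phase_at(network$annotations, mid)
  }
  class(out) <- c("osc_indices", class(out))
  out
}

# phase label of given sample positions, NA outside all windows
phase_at <- function(annotations, samples) {
  lab <- rep(NA_character_, length(samples))
  for (k in seq_len(nrow(annotations))) {
    inside <- samples >= annotations$start_sample[k] &
      samples <= annotations$end_sample[k]
    lab[inside] <- annotations$label[k]
  }
  lab
}
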