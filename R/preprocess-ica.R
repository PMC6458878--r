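# Restricted Infomax ICA: PCA whitening to the retained-channel rank
# followed by natural-gradient Infomax with a logistic nonlinearity.
# Written here because no installed R package provides Infomax ICA; the
# "restricted" part is the PCA rank reduction before unmixing.

#' Independent component decomposition (restricted Infomax)
#'
#' Decomposes a recording into independent components.  Channels listed in
#' \code{exclude} (typically bad channels) are left out of the
#' decomposition.  Data are mean-centered and PCA-whitened to their
#' numerical rank (optionally capped), then unmixed with the Infomax
#' natural-gradient rule.  The decomposition is deterministic given
#' \code{seed}; components are ordered by decreasing projected variance.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param exclude Channel names excluded from the decomposition.
#' @param n_comp Number of components (default: rank of the retained data).
#' @param seed Seed for the weight initialization and data shuffling.
#' @param max_iter Maximum training passes.
#' @param tol Convergence tolerance on the weight increment.
#' @param max_samples Training-sample cap; unmixing is estimated on an
#'   evenly subsampled stretch but applied to all samples.
#' @return Object of class \code{"ica_decomposition"}: \code{mixing}
#'   (channels x components), \code{unmixing} (components x channels),
#'   \code{activations} (components x time), \code{channel_names},
#'   \code{center}, \code{excluded}.
#' @export
decompose_ica <- function(rec, exclude = character(), n_comp = NULL,
                          seed = 1, max_iter = 60, tol = 1e-6,
                          max_samples = 30000L) {
  keep <- setdiff(rec$channel_names, exclude)
  idx <- match(keep, rec$channel_names)
  x <- rec$samples[idx, , drop = FALSE]
  center <- rowMeans(x)
  x <- x - center
  n <- ncol(x)

  cv <- tcrossprod(x) / (n - 1)
  eig <- eigen(cv, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  rank <- sum(pos)
  k <- min(n_comp %||% rank, rank)
  if (k < 1) stop_input("rank-deficient data: no components retained")
  if (!is.null(n_comp) && n_comp > rank)
    stop_input("requested %d components but data rank is %d", n_comp, rank)
  d <- eig$values[seq_len(k)]
  E <- eig$vectors[, seq_len(k), drop = FALSE]
  sphere <- diag(1 / sqrt(d), k) %*% t(E)     # k x channels
  desphere <- E %*% diag(sqrt(d), k)

  xs <- sphere %*% x                           # whitened, k x n
  if (n > max_samples) {
    sel <- round(seq(1, n, length.out = max_samples))
    xt <- xs[, sel, drop = FALSE]
  } else xt <- xs
  nt <- ncol(xt)

  W <- with_seed(seed, {
    xt <- xt[, sample.int(nt), drop = FALSE]   # fixed shuffling
    diag(k) + 0.01 * matrix(stats::rnorm(k * k), k)
  })

  # extended Infomax: per-component sign K switches the nonlinearity
  # between super-Gaussian (+1) and sub-Gaussian (-1) behavior
  block <- max(32L, min(256L, floor(nt / 8)))
  lrate <- 0.005 / log(k + 2)
  I_k <- diag(k)
  K <- diag(1, k)
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (s in seq(1, nt - block + 1, by = block)) {
      u <- W %*% xt[, s:(s + block - 1), drop = FALSE]
      tu <- tanh(u)
      W <- W + lrate * ((I_k - (K %*% tu) %*% t(u) / block -
                           tcrossprod(u) / block) %*% W)
      if (!all(is.finite(W))) stop_input("ICA diverged; lower the learning rate")
    }
    # re-estimate source kurtosis signs on the full training set
    u_all <- W %*% xt
    ks <- sign(rowMeans(1 / cosh(u_all)^2) * rowMeans(u_all^2) -
                 rowMeans(tanh(u_all) * u_all))
    ks[ks == 0] <- 1
    diag(K) <- ks
    delta <- sqrt(sum((W - W_old)^2) / k^2)
    if (delta < tol) break
    if (delta > 1) { lrate <- lrate * 0.5; W <- W_old }
  }

  unmixing <- W %*% sphere                     # k x channels
  mixing <- desphere %*% solve(W)              # channels x k
  acts <- unmixing %*% x
  ord <- order(colSums(mixing^2) * apply(acts, 1, stats::var),
               decreasing = TRUE)
  structure(list(mixing = mixing[, ord, drop = FALSE],
                 unmixing = unmixing[ord, , drop = FALSE],
                 activations = acts[ord, , drop = FALSE],
                 channel_names = keep, center = center,
                 excluded = exclude, srate = rec$srate),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition: %d components from %d channels>\n",
              nrow(x$unmixing), length(x$channel_names)))
  invisible(x)
}

#' Classify artifact components
#'
#' Flags components whose signatures are typical of (a) eye blinks: high
#' correlation of the component activation with a frontal low-frequency
#' template signal together with a frontal-dominant mixing topography,
#' (b) muscle activity: spectral power increasing above 20 Hz relative to
#' the 5-15 Hz range, or (c) line noise: dominant 45-55 Hz power.
#'
#' @param ica An \code{\link{decompose_ica}} result.
#' @param rec The recording the decomposition came from.
#' @param blink_cor Blink template correlation threshold.
#' @param blink_frontal Fraction of topography power on frontal channels
#'   required for a blink flag.
#' @param muscle_db High/low spectral ratio threshold in dB.
#' @param line_ratio Mean 45-55 Hz power over mean broadband (1 Hz-Nyquist)
#'   power, in dB, above which a component is flagged as line noise.
#' @return Integer vector of flagged component indices.
#' @export
classify_artifact_components <- function(ica, rec, blink_cor = 0.6,
                                         blink_frontal = 0.5,
                                         muscle_db = 0, line_ratio = 7) {
  fw <- tryCatch(frontal_weights(ica$channel_names),
                 error = function(e) rep(0, length(ica$channel_names)))
  frontal <- fw > 0.5
  fs <- ica$srate
  template <- if (any(frontal)) {
    tmp <- colMeans(rec$samples[match(ica$channel_names[frontal],
                                      rec$channel_names), , drop = FALSE])
    flt <- signal::butter(2, min(4 / (fs / 2), 0.9), type = "low")
    signal::filtfilt(flt, tmp)
  } else NULL

  flagged <- integer(0)
  for (j in seq_len(nrow(ica$activations))) {
    a <- ica$activations[j, ]
    topo <- ica$mixing[, j]^2
    is_blink <- FALSE
    if (!is.null(template) && stats::sd(a) > 0 && stats::sd(template) > 0) {
      frontal_share <- sum(topo[frontal]) / sum(topo)
      is_blink <- abs(stats::cor(a, template)) > blink_cor &&
        frontal_share > blink_frontal
    }
    spec <- stats::spec.pgram(stats::ts(a, frequency = fs), plot = FALSE,
                              taper = 0.1, detrend = TRUE)
    pw <- function(lo, hi) {
      s <- spec$freq >= lo & spec$freq <= hi
      if (any(s)) mean(spec$spec[s]) else NA_real_
    }
    hi <- pw(20, min(45, fs / 2 - 1)); lo <- pw(5, 15)
    is_muscle <- is.finite(hi) && is.finite(lo) && db(hi) - db(lo) > muscle_db
    l45 <- pw(45, min(55, fs / 2 - 0.5)); tot <- pw(1, fs / 2 - 0.5)
    is_line <- is.finite(l45) && is.finite(tot) && tot > 0 &&
      db(l45) - db(tot) > line_ratio
    if (is_blink || is_muscle || is_line) flagged <- c(flagged, j)
  }
  flagged
}

#' Remove components from a recording
#'
#' Reconstructs the recording with the flagged component activations
#' zeroed (inverse ICA).  Removing an empty index set returns data
#' identical to the ICA's reconstruction of the input; channels excluded
#' from the decomposition are untouched.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param ica An \code{\link{decompose_ica}} result for this recording.
#' @param indices Component indices to remove.
#' @return The cleaned recording.
#' @export
remove_components <- function(rec, ica, indices = integer()) {
  if (!length(indices)) return(rec)
  if (any(indices < 1 | indices > nrow(ica$unmixing)))
    stop_input("component index out of range")
  idx <- match(ica$channel_names, rec$channel_names)
  x <- rec$samples[idx, , drop = FALSE] - ica$center
  contrib <- ica$mixing[, indices, drop = FALSE] %*%
    ica$activations[indices, , drop = FALSE]
  out <- rec
  out$samples[idx, ] <- x - contrib + ica$center
  out
}
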