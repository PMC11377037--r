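#' @name eta
#' @title Event-triggered average estimation and sparse-PCA denoising
#'
#' @description
#' The linear receptive-field estimate of the pipeline: stimulus and
#' responses are brought to a common 30 Hz clock (sample-and-hold for the
#' piecewise-constant stimulus, linear interpolation for rates), each
#' response trace is normalized by its sum, and the event-triggered average
#' (ETA) is the product of the signed stimulus matrix with the normalized
#' response vector over a lag window. The lag axis `tau` is the time by
#' which the stimulus precedes the response: `tau` in [-0.5 s, 2 s], the
#' first 500 ms (tau < 0, stimulus after the response) serving as the
#' baseline segment for the variance-ratio quality criterion.
NULL

#' Compute raw event-triggered averages
#'
#' For each neuron and stimulus condition,
#' `ETA(tau) = sum_t s(t - tau) r(t) / sum_t r(t)`,
#' with s in {-1, +1} and r the non-negative event rate. Because each trace
#' is normalized by its own sum, ETA amplitudes are comparable across
#' neurons and conditions, and the estimator is invariant to positive
#' rescaling of a response trace.
#'
#' @param stim a `stim_sequence`.
#' @param responses a `response_matrix` (timebins x neurons). If its rate
#'   differs from 30 Hz the rates are linearly interpolated onto the 30 Hz
#'   analysis clock.
#' @param lag_window_s lag range in seconds, default c(-0.5, 2).
#' @return object of class `eta_set`: `eta` (lags x 4 x neurons; NA slices
#'   for all-zero response traces), `lag_s`, `excluded_zero` (logical),
#'   `neurons` metadata.
#' @export
compute_eta <- function(stim, responses, lag_window_s = c(-0.5, 2)) {
  stopifnot(inherits(stim, "stim_sequence"),
            inherits(responses, "response_matrix"))
  S <- upsample_stimulus(stim)          # T x 4 in {-1, +1} at 30 Hz
  R <- responses$rates
  if (responses$rate_hz != ANALYSIS_RATE_HZ) {
    t_in <- (seq_len(nrow(R)) - 1) / responses$rate_hz
    t_out <- seq(0, max(t_in), by = 1 / ANALYSIS_RATE_HZ)
    R <- apply(R, 2, function(r) stats::approx(t_in, r, xout = t_out)$y)
  }
  t_len <- min(nrow(S), nrow(R))
  if (nrow(S) != nrow(R)) {
    S <- S[seq_len(t_len), , drop = FALSE]
    R <- R[seq_len(t_len), , drop = FALSE]
  }
  lag_bins <- seq(round(lag_window_s[1] * ANALYSIS_RATE_HZ),
                  round(lag_window_s[2] * ANALYSIS_RATE_HZ))
  lo <- min(lag_bins); hi <- max(lag_bins)
  # valid response times: t - tau within [1, T] for every tau in the window
  t_idx <- (max(1L, 1L + hi)):(min(t_len, t_len + lo))
  if (length(t_idx) < 10L) abort("stimulus too short for the lag window")

  n <- ncol(R)
  sums <- colSums(R[t_idx, , drop = FALSE])
  excluded <- sums <= 0
  Rn <- R[t_idx, , drop = FALSE]
  Rn[, !excluded] <- sweep(Rn[, !excluded, drop = FALSE], 2,
                           sums[!excluded], "/")
  eta <- array(NA_real_, dim = c(length(lag_bins), 4L, n),
               dimnames = list(NULL, CHANNEL_NAMES, NULL))
  for (j in seq_along(lag_bins)) {
    tau <- lag_bins[j]
    eta[j, , ] <- t(S[t_idx - tau, , drop = FALSE]) %*% Rn
  }
  eta[, , excluded] <- NA_real_
  structure(
    list(eta = eta, lag_s = lag_bins / ANALYSIS_RATE_HZ,
         excluded_zero = excluded, neurons = responses$neurons),
    class = "eta_set"
  )
}

#' @export
print.eta_set <- function(x, ...) {
  cat(sprintf("<eta_set> %d neurons, %d lag bins (%.2f..%.2f s)%s\n",
              dim(x$eta)[3], dim(x$eta)[1], min(x$lag_s), max(x$lag_s),
              if (!is.null(x$include)) sprintf(", %d pass quality", sum(x$include)) else ""))
  invisible(x)
}

#' Variance-ratio kernel quality and inclusion flag
#'
#' Per condition, quality = var(full ETA) / var(baseline segment), the
#' baseline being the first 500 ms of the ETA (lags < 0). A neuron is
#' included when the quality of the UV or green *center* ETA is at least
#' `threshold` (default 10).
#'
#' @param etaset an `eta_set`.
#' @param threshold inclusion threshold on max(GreenC, UVC) quality.
#' @param baseline_s baseline duration in seconds (default 0.5).
#' @return the `eta_set` with `quality` (neurons x 4), `include` (logical)
#'   added. A zero-variance baseline yields quality +Inf (passes, with a
#'   degenerate-baseline warning).
#' @export
kernel_quality <- function(etaset, threshold = 10, baseline_s = 0.5) {
  stopifnot(inherits(etaset, "eta_set"))
  base_idx <- baseline_bins(etaset, baseline_s)
  n <- dim(etaset$eta)[3]
  quality <- matrix(NA_real_, n, 4, dimnames = list(NULL, CHANNEL_NAMES))
  degenerate <- FALSE
  for (i in seq_len(n)) {
    if (etaset$excluded_zero[i]) next
    for (ch in 1:4) {
      k <- etaset$eta[, ch, i]
      vb <- stats::var(k[base_idx])
      vf <- stats::var(k)
      if (vb == 0) {
        quality[i, ch] <- if (vf == 0) 1 else Inf
        if (vf > 0) degenerate <- TRUE
      } else {
        quality[i, ch] <- vf / vb
      }
    }
  }
  if (degenerate) warning("degenerate zero-variance baseline; quality set to +Inf")
  etaset$quality <- quality
  etaset$include <- !etaset$excluded_zero &
    pmax(quality[, "GreenC"], quality[, "UVC"]) >= threshold
  etaset$include[is.na(etaset$include)] <- FALSE
  etaset$quality_threshold <- threshold
  etaset
}

baseline_bins <- function(etaset, baseline_s = 0.5) {
  which(etaset$lag_s < min(etaset$lag_s) + baseline_s - 1e-9)
}

# neurons x (4 * lags) matrix of concatenated condition ETAs (included only)
eta_feature_matrix <- function(etaset, which_neurons = NULL) {
  if (is.null(which_neurons)) {
    which_neurons <- if (!is.null(etaset$include)) which(etaset$include)
    else seq_len(dim(etaset$eta)[3])
  }
  n_lag <- dim(etaset$eta)[1]
  X <- t(matrix(etaset$eta[, , which_neurons, drop = FALSE],
                nrow = n_lag * 4L))
  attr(X, "neurons") <- which_neurons
  attr(X, "n_lag") <- n_lag
  X
}

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

#' Fit a sparse PCA basis to concatenated ETAs
#'
#' Concatenates the four condition ETAs of the included neurons into a
#' neurons x time matrix and extracts sparse components by rank-one
#' deflation with structured, soft-thresholded power iterations: at each
#' iteration the loading vector is restricted to the stimulus-condition
#' segment carrying the most energy and soft-thresholded within it. Each
#' component therefore captures exactly one of the four stimulus
#' conditions, which is what makes the components interpretable. The
#' reconstruction for any number of leading components is the least-squares
#' projection onto their span, so the reconstruction-MSE curve over
#' component counts is monotone non-increasing by construction.
#'
#' @param etaset an `eta_set` that has passed [kernel_quality()].
#' @param n_components number of components to keep (default 8).
#' @param sparsity soft-threshold level within the selected condition
#'   segment, as a fraction of the largest loading magnitude per iteration,
#'   in [0, 1) (default 0.2).
#' @param mse_range component counts over which to report the
#'   reconstruction-MSE curve (default 2:12).
#' @return object of class `eta_pca`: `loadings` (time x k), `center`,
#'   `attribution` (condition index + energy fraction per component),
#'   `mse_curve` (data.frame n, mse), `n_components`, `sparsity`.
#' @export
fit_sparse_pca <- function(etaset, n_components = 8, sparsity = 0.2,
                           mse_range = 2:12) {
  X <- eta_feature_matrix(etaset)
  if (nrow(X) < n_components) {
    abort("need at least n_components included neurons")
  }
  n_max <- max(n_components, max(mse_range))
  rank_lim <- min(dim(X))
  if (n_max > rank_lim) {
    warning("rank-deficient ETA matrix: reducing components to ", rank_lim)
    n_max <- rank_lim
    n_components <- min(n_components, rank_lim)
    mse_range <- mse_range[mse_range <= rank_lim]
  }
  center <- colMeans(X)
  X0 <- sweep(X, 2, center)
  Xr <- X0
  p <- ncol(X0)
  n_lag <- attr(X, "n_lag")
  seg <- rep(1:4, each = n_lag)
  V <- matrix(0, p, n_max)
  for (j in seq_len(n_max)) {
    sv <- svd(Xr, nu = 1, nv = 1)
    u <- sv$u[, 1]; v <- sv$v[, 1]
    for (it in 1:30) {
      z <- as.vector(crossprod(Xr, u))
      # restrict to the condition segment carrying the most energy, then
      # soft-threshold within it
      gsel <- which.max(tapply(z^2, seg, sum))
      z[seg != gsel] <- 0
      v_new <- soft_threshold(z, sparsity * max(abs(z)))
      nv <- sqrt(sum(v_new^2))
      if (nv == 0) break
      v_new <- v_new / nv
      u_new <- Xr %*% v_new
      nu_ <- sqrt(sum(u_new^2))
      if (nu_ == 0) break
      u_new <- u_new / nu_
      if (sum((v_new - v)^2) < 1e-10) { v <- v_new; u <- as.vector(u_new); break }
      v <- v_new; u <- as.vector(u_new)
    }
    d <- as.numeric(crossprod(u, Xr %*% v))
    V[, j] <- v
    Xr <- Xr - d * (u %*% t(v))
  }
  attribution <- t(apply(V, 2, function(v) {
    e <- tapply(v^2, seg, sum)
    e <- e / sum(e)
    c(condition = unname(which.max(e)), energy = max(e))
  }))
  mse_curve <- data.frame(
    n = mse_range,
    mse = vapply(mse_range, function(k) {
      Vk <- V[, seq_len(k), drop = FALSE]
      W <- t(qr.solve(crossprod(Vk), crossprod(Vk, t(X0))))
      mean((X0 - W %*% t(Vk))^2)
    }, numeric(1))
  )
  structure(
    list(loadings = V[, seq_len(n_components), drop = FALSE],
         loadings_all = V, center = center,
         attribution = attribution[seq_len(n_components), , drop = FALSE],
         mse_curve = mse_curve, n_components = n_components,
         sparsity = sparsity, n_lag = n_lag),
    class = "eta_pca"
  )
}

#' Project ETAs onto a sparse-PCA basis and reconstruct
#'
#' Adds per-neuron PC weights (least-squares projection onto the basis) and
#' PCA-reconstructed kernels to the `eta_set`. Excluded neurons keep NA
#' weights and reconstructions.
#'
#' @param etaset an `eta_set` with inclusion flags.
#' @param basis an `eta_pca`.
#' @return the `eta_set` with `pc_weights` (neurons x k) and `recon`
#'   (lags x 4 x neurons) added.
#' @export
apply_sparse_pca <- function(etaset, basis) {
  stopifnot(inherits(etaset, "eta_set"), inherits(basis, "eta_pca"))
  n <- dim(etaset$eta)[3]
  n_lag <- dim(etaset$eta)[1]
  keep <- which(if (!is.null(etaset$include)) etaset$include
                else !etaset$excluded_zero)
  X <- eta_feature_matrix(etaset, keep)
  X0 <- sweep(X, 2, basis$center)
  V <- basis$loadings
  W <- t(qr.solve(crossprod(V), crossprod(V, t(X0))))
  recon_flat <- sweep(W %*% t(V), 2, basis$center, "+")
  pc_weights <- matrix(NA_real_, n, ncol(V))
  pc_weights[keep, ] <- W
  recon <- array(NA_real_, dim = dim(etaset$eta),
                 dimnames = dimnames(etaset$eta))
  for (i in seq_along(keep)) {
    recon[, , keep[i]] <- matrix(recon_flat[i, ], n_lag, 4L)
  }
  etaset$pc_weights <- pc_weights
  etaset$recon <- recon
  etaset
}
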