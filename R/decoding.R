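#' @name decoding
#' @title Decoding stimulus luminance and color from population responses
#'
#' @description
#' Trial-wise population decoding with a cross-validated RBF-kernel SVM.
#' Each stimulus frame is one trial; a neuron's trial feature is the
#' Hamming-weighted sum of its rate samples from 50 ms after stimulus onset
#' to offset. Luminance trials are frames where the green and UV channels
#' of a compartment agree (both On or both Off); color trials are frames
#' where they disagree (green-only vs UV-only). Accuracy is converted to
#' discriminability in bits via the mutual information of the confusion
#' table, with 0 bits at the 50% chance level and 1 bit at perfect balanced
#' binary decoding.
#'
#' The classifier is a least-squares SVM with an RBF kernel (closed-form
#' dual solve); no R SVM package is available in the target environment and
#' the decoding properties asserted here are robust to the SVM variant.
NULL

#' Extract trial-wise decoding features
#'
#' For every stimulus frame (trial), each neuron's feature is the
#' Hamming-weighted sum of its 30 Hz rate samples falling strictly later
#' than 50 ms after frame onset and no later than frame offset.
#'
#' @param responses a `response_matrix` at the 30 Hz analysis rate.
#' @param stim the `stim_sequence` the responses were recorded to.
#' @param onset_skip_s seconds after onset excluded from the window (0.05).
#' @return object of class `trial_features`: `features` (trials x neurons),
#'   `stim_frames` (trials x 4 binary matrix), `window_bins`, `hamming`.
#' @export
extract_trial_features <- function(responses, stim, onset_skip_s = 0.05) {
  stopifnot(inherits(responses, "response_matrix"),
            inherits(stim, "stim_sequence"))
  if (responses$rate_hz != ANALYSIS_RATE_HZ) {
    abort("responses must be on the 30 Hz analysis clock")
  }
  bins_per_frame <- as.integer(round(ANALYSIS_RATE_HZ / stim$rate_hz))
  n_frames <- min(stim$frames, nrow(responses$rates) %/% bins_per_frame)
  # sample j (1-based) of a frame sits at offset (j-1)/30 s after onset
  offs <- (seq_len(bins_per_frame) - 1) / ANALYSIS_RATE_HZ
  in_window <- offs > onset_skip_s
  k <- sum(in_window)
  if (k < 1) abort("decoding window contains no samples")
  w <- hamming_window(k)
  feats <- matrix(0, n_frames, ncol(responses$rates))
  sel <- which(in_window)
  for (j in seq_along(sel)) {
    rows <- (seq_len(n_frames) - 1L) * bins_per_frame + sel[j]
    feats <- feats + w[j] * responses$rates[rows, , drop = FALSE]
  }
  structure(
    list(features = feats,
         stim_frames = stim$channels[seq_len(n_frames), , drop = FALSE],
         window_bins = sel, hamming = w,
         neurons = responses$neurons),
    class = "trial_features"
  )
}

#' Hamming window of length n
#' @keywords internal
hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Trial class labels for a decoding target
#'
#' Luminance labels ("On"/"Off") are defined on frames where the green and
#' UV channel of the compartment agree; color labels ("green"/"UV") on
#' frames where they disagree. Other frames get NA and are dropped by
#' [decode_class()].
#'
#' @param tf a `trial_features` object.
#' @param compartment "center" or "surround".
#' @param target "luminance" or "color".
#' @return factor of length n_trials with NA for non-qualifying trials.
#' @export
trial_labels <- function(tf, compartment = c("center", "surround"),
                         target = c("luminance", "color")) {
  compartment <- match.arg(compartment)
  target <- match.arg(target)
  g <- tf$stim_frames[, if (compartment == "center") "GreenC" else "GreenS"]
  u <- tf$stim_frames[, if (compartment == "center") "UVC" else "UVS"]
  if (target == "luminance") {
    lab <- ifelse(g == u, ifelse(g == 1, "On", "Off"), NA_character_)
  } else {
    lab <- ifelse(g != u, ifelse(g == 1, "green", "UV"), NA_character_)
  }
  factor(lab)
}

# ---- RBF least-squares SVM ---------------------------------------------------

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

# Train a binary least-squares SVM in the dual: solve
# [0 1'; 1 K + I/C] [b; alpha] = [0; y] with y in {-1, +1}.
lssvm_fit <- function(X, y, C = 1, gamma = NULL) {
  stopifnot(length(unique(y)) == 2)
  lev <- sort(unique(as.character(y)))
  yy <- ifelse(as.character(y) == lev[2], 1, -1)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- if (v > 0) 1 / (ncol(X) * v) else 1
  }
  K <- rbf_kernel(X, X, gamma)
  n <- nrow(X)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(1 / C, n)))
  sol <- tryCatch(solve(A, c(0, yy)),
                  error = function(e) qr.solve(A, c(0, yy)))
  list(X = X, alpha = sol[-1], b = sol[1], gamma = gamma, levels = lev)
}

lssvm_predict <- function(fit, Xnew) {
  f <- rbf_kernel(Xnew, fit$X, fit$gamma) %*% fit$alpha + fit$b
  factor(ifelse(f >= 0, fit$levels[2], fit$levels[1]), levels = fit$levels)
}

#' Cross-validated decoding of a binary trial label
#'
#' Trials with NA labels are dropped; the rest are split into `n_folds`
#' contiguous equal-size blocks (temporal structure preserved). For each
#' split, `n_neurons` neurons are subsampled without replacement (seeded),
#' features are standardized per neuron using training-fold statistics
#' only, an RBF least-squares SVM is trained on the other blocks, and
#' accuracy plus confusion-table mutual information are computed on the
#' held-out block. If a fold misses a class, folds are re-blocked by
#' interleaving with a warning.
#'
#' @param features trials x neurons matrix (or `trial_features`).
#' @param labels factor of per-trial labels (NA = drop).
#' @param n_neurons neurons to subsample (default: all).
#' @param seed integer seed for the subsample.
#' @param n_folds number of cross-validation blocks (10).
#' @param C,gamma SVM regularization and RBF width (gamma default
#'   1/(n_features * var), the library-conventional "scale" choice).
#' @return object of class `decoding_result`: `splits` (data.frame: split,
#'   accuracy in %, bits), `mean_accuracy`, `mean_bits`, `n_neurons`.
#' @export
decode_class <- function(features, labels, n_neurons = NULL, seed = 1,
                         n_folds = 10, C = 1, gamma = NULL) {
  if (inherits(features, "trial_features")) features <- features$features
  keep <- !is.na(labels)
  X <- features[keep, , drop = FALSE]
  y <- droplevels(factor(labels[keep]))
  if (nlevels(y) != 2) abort("decode_class needs exactly 2 classes")
  n_trials <- nrow(X)
  if (n_trials < 2 * n_folds) abort("too few trials for ", n_folds, " folds")
  if (is.null(n_neurons)) n_neurons <- ncol(X)
  if (n_neurons > ncol(X)) abort("n_neurons exceeds population size")
  idx <- with_seed(seed, sample.int(ncol(X), n_neurons))
  X <- X[, idx, drop = FALSE]

  fold <- make_folds(y, n_folds)
  splits <- data.frame(split = seq_len(n_folds), accuracy = NA_real_,
                       bits = NA_real_)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- fold == f
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sd_, "/")
    fit <- lssvm_fit(Xtr, y[tr], C = C, gamma = gamma)
    pred <- lssvm_predict(fit, Xte)
    tab <- table(true = factor(y[te], levels = levels(y)),
                 pred = factor(pred, levels = levels(y)))
    splits$accuracy[f] <- 100 * sum(diag(tab)) / sum(tab)
    splits$bits[f] <- accuracy_to_information(tab)
  }
  structure(
    list(splits = splits,
         mean_accuracy = mean(splits$accuracy),
         mean_bits = mean(splits$bits),
         n_neurons = n_neurons, n_trials = n_trials,
         classes = levels(y)),
    class = "decoding_result"
  )
}

# contiguous equal-size blocks; re-block by interleaving if a fold misses a
# class
make_folds <- function(y, n_folds) {
  n <- length(y)
  fold <- ceiling(seq_len(n) / n * n_folds)
  ok <- all(vapply(seq_len(n_folds), function(f) {
    length(unique(y[fold == f])) == nlevels(y)
  }, logical(1)))
  if (!ok) {
    warning("a contiguous fold misses a class; re-blocking by interleaving")
    fold <- (seq_len(n) - 1L) %% n_folds + 1L
  }
  fold
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s | n=%d neurons, %d trials: %.1f%% / %.3f bits (mean of %d splits)\n",
              paste(x$classes, collapse = " vs "), x$n_neurons, x$n_trials,
              x$mean_accuracy, x$mean_bits, nrow(x$splits)))
  invisible(x)
}

#' Convert a confusion table to mutual information (bits)
#'
#' `MI = sum_ij p_ij log2( p_ij / (p_i. p_.j) )` with `0 log 0 := 0`, where
#' p_ij is the joint probability of true class i and predicted class j.
#' For balanced binary classes with symmetric errors this equals
#' `1 - H2(accuracy)`; chance (50%) gives 0 bits, perfect decoding 1 bit.
#'
#' @param confusion a contingency table/matrix of counts (true x predicted).
#' @return mutual information in bits.
#' @export
accuracy_to_information <- function(confusion) {
  tab <- as.matrix(confusion)
  if (length(tab) == 0 || any(tab < 0) || sum(tab) <= 0) {
    abort("confusion table must be non-negative with positive sum")
  }
  p <- tab / sum(tab)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  terms <- p * log2(p / outer(pi_, pj_))
  sum(terms[p > 0])
}

#' Compare two decoding results with a Bonferroni-corrected t-test
#'
#' Unpaired two-sample t-test on the per-split discriminability values,
#' with the p-value multiplied by the number of comparisons (capped at 1).
#'
#' @param result_a,result_b `decoding_result` objects (or numeric vectors
#'   of per-split values).
#' @param n_comparisons number of comparisons for the Bonferroni correction.
#' @param measure which per-split value to compare: "bits" or "accuracy".
#' @return list: `p`, `p_adj`, `t`, `df`, `mean_a`, `mean_b`. When both
#'   groups have zero variance, p is 1 for equal means and NA (undefined)
#'   otherwise.
#' @export
compare_results <- function(result_a, result_b, n_comparisons = 1,
                            measure = c("bits", "accuracy")) {
  measure <- match.arg(measure)
  a <- if (inherits(result_a, "decoding_result")) result_a$splits[[measure]] else result_a
  b <- if (inherits(result_b, "decoding_result")) result_b$splits[[measure]] else result_b
  if (length(a) < 2 || length(b) < 2) abort("need >= 2 splits per result")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
    return(list(p = p, p_adj = if (is.na(p)) NA_real_ else min(1, p * n_comparisons),
                t = if (is.na(p)) NA_real_ else 0,
                df = length(a) + length(b) - 2,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(p = tt$p.value, p_adj = min(1, tt$p.value * n_comparisons),
       t = unname(tt$statistic), df = unname(tt$parameter),
       mean_a = mean(a), mean_b = mean(b))
}
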