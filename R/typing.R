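#' @name typing
#' @title Functional response types: Gaussian mixture clustering and the
#'   cortical distribution index
#'
#' @description
#' Clusters the 8-dimensional ETA PC-weight vectors into functional
#' response types with a full-covariance Gaussian mixture model fitted by
#' EM (k-means initialization, multiple restarts, diagonal regularization
#' floor). The component count is selected by mean held-out log-likelihood
#' over 10 train/test splits. Separability is validated by generating
#' labeled data from the fitted components and measuring assignment
#' accuracy, and anterior/posterior enrichment of each type is quantified
#' by the cortical distribution index — the Michelson contrast of the
#' fractions of anterior and posterior neurons assigned to the type.
NULL

log_gauss_density <- function(X, mu, sigma) {
  d <- ncol(X)
  L <- chol(sigma)
  z <- forwardsolve(t(L), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * d * log(2 * pi)
}

rowlogsumexp <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

regularize_cov <- function(sigma, floor) {
  sigma <- (sigma + t(sigma)) / 2
  sigma + diag(floor, nrow(sigma))
}

#' Fit a Gaussian mixture model by EM
#'
#' Full covariances with a diagonal regularization floor of
#' `1e-6 * trace(cov(X)) / d`. Initialization by k-means; `n_restarts`
#' independent starts, the fit with the best log-likelihood kept.
#'
#' @param X numeric matrix (observations x dimensions).
#' @param K number of components.
#' @param seed integer seed.
#' @param n_restarts independent k-means/EM restarts (default 10).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return object of class `gmm`: `K`, `means` (K x d), `covs` (d x d x K),
#'   `weights`, `loglik` (total on X), `assignments`, `responsibilities`.
#' @export
fit_gmm <- function(X, K, seed = 1, n_restarts = 10, max_iter = 300,
                    tol = 1e-7) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(K >= 1, n > K)
  floor_reg <- 1e-6 * sum(diag(stats::cov(X))) / d
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch(
        em_gmm_once(X, K, floor_reg, max_iter, tol),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) abort("GMM fit failed for all restarts")
  best$K <- K
  best$reg <- floor_reg
  class(best) <- "gmm"
  best
}

em_gmm_once <- function(X, K, floor_reg, max_iter, tol) {
  n <- nrow(X); d <- ncol(X)
  if (K == 1) {
    km_cl <- rep(1L, n)
  } else {
    km_cl <- stats::kmeans(X, centers = K, nstart = 10, iter.max = 100)$cluster
  }
  means <- do.call(rbind, lapply(seq_len(K), function(k) colMeans(X[km_cl == k, , drop = FALSE])))
  covs <- array(0, c(d, d, K))
  weights <- tabulate(km_cl, K) / n
  for (k in seq_len(K)) {
    xk <- X[km_cl == k, , drop = FALSE]
    covs[, , k] <- regularize_cov(
      if (nrow(xk) > d) stats::cov(xk) else diag(d) * sum(diag(stats::cov(X))) / d,
      floor_reg)
  }
  loglik_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k) {
      log(weights[k]) + log_gauss_density(X, means[k, ], covs[, , k])
    }, numeric(n))
    lse <- rowlogsumexp(logd)
    loglik <- sum(lse)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    weights <- nk / n
    means <- crossprod(resp, X) / nk
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, means[k, ])
      covs[, , k] <- regularize_cov(
        crossprod(Xc * resp[, k], Xc) / nk[k], floor_reg)
    }
    if (abs(loglik - loglik_old) < tol * (abs(loglik_old) + 1)) break
    loglik_old <- loglik
  }
  logd <- vapply(seq_len(K), function(k) {
    log(weights[k]) + log_gauss_density(X, means[k, ], covs[, , k])
  }, numeric(n))
  lse <- rowlogsumexp(logd)
  resp <- exp(logd - lse)
  list(means = means, covs = covs, weights = weights,
       loglik = sum(lse), responsibilities = resp,
       assignments = max.col(resp))
}

#' Per-observation log-likelihood and posterior under a fitted GMM
#'
#' @param model a `gmm`.
#' @param X observations.
#' @return list: `loglik` (total), `per_obs`, `responsibilities`,
#'   `assignments`.
#' @export
gmm_score <- function(model, X) {
  X <- as.matrix(X)
  logd <- vapply(seq_len(model$K), function(k) {
    log(model$weights[k]) + log_gauss_density(X, model$means[k, ], model$covs[, , k])
  }, numeric(nrow(X)))
  if (nrow(X) == 1) logd <- matrix(logd, 1)
  lse <- rowlogsumexp(logd)
  resp <- exp(logd - lse)
  list(loglik = sum(lse), per_obs = lse, responsibilities = resp,
       assignments = max.col(resp))
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("<gmm> K=%d, d=%d, loglik=%.1f\n", x$K, ncol(x$means), x$loglik))
  invisible(x)
}

#' Select the component count by held-out likelihood and fit the final model
#'
#' For each K in `k_range` and each of `n_splits` random 90/10 train/test
#' splits, a GMM is fitted on the training part and its mean per-point
#' log-likelihood evaluated on the held-out part. The final model is refit
#' on all data at the K with the highest mean held-out log-likelihood,
#' ties broken toward smaller K.
#'
#' @param weights neurons x d PC-weight matrix.
#' @param k_range candidate component counts.
#' @param seed integer seed.
#' @param n_splits train/test splits (10).
#' @param holdout held-out fraction (0.1).
#' @param selection_restarts EM restarts per candidate fit (kept small; the
#'   final fit uses `final_restarts`).
#' @param final_restarts restarts for the final full-data fit (10).
#' @return list: `curve` (data.frame K, mean_holdout_loglik), `K`, `model`
#'   (the final `gmm`).
#' @export
select_and_fit <- function(weights, k_range, seed = 1, n_splits = 10,
                           holdout = 0.1, selection_restarts = 2,
                           final_restarts = 10) {
  X <- as.matrix(weights)
  n <- nrow(X)
  if (n < 10 * max(k_range)) {
    warning("fewer than 10 observations per component at max(k_range)")
  }
  ll <- matrix(NA_real_, length(k_range), n_splits)
  for (s in seq_len(n_splits)) {
    test_idx <- with_seed(child_seed(seed, 100L + s),
                          sample.int(n, max(1, round(holdout * n))))
    Xtr <- X[-test_idx, , drop = FALSE]
    Xte <- X[test_idx, , drop = FALSE]
    for (ki in seq_along(k_range)) {
      fit <- fit_gmm(Xtr, k_range[ki], seed = child_seed(seed, 1000L + s * 37L + ki),
                     n_restarts = selection_restarts)
      ll[ki, s] <- gmm_score(fit, Xte)$loglik / nrow(Xte)
    }
  }
  curve <- data.frame(K = k_range, mean_holdout_loglik = rowMeans(ll))
  best_k <- k_range[which.max(curve$mean_holdout_loglik)]  # first max: smaller K
  model <- fit_gmm(X, best_k, seed = child_seed(seed, 999L),
                   n_restarts = final_restarts)
  list(curve = curve, K = best_k, model = model)
}

#' Generated-label assignment accuracy of a fitted mixture
#'
#' Samples `n_per_component` points from each fitted component (its mean
#' and covariance), classifies them by the model's posterior argmax, and
#' reports the fraction assigned back to the generating component.
#'
#' @param model a `gmm`.
#' @param n_per_component samples per component (1000).
#' @param seed integer seed.
#' @return list: `per_component` (data.frame component, accuracy),
#'   `mean`, `sd`.
#' @export
assignment_accuracy <- function(model, n_per_component = 1000, seed = 1) {
  acc <- with_seed(seed, {
    vapply(seq_len(model$K), function(k) {
      L <- chol(model$covs[, , k])
      Z <- matrix(stats::rnorm(n_per_component * ncol(model$means)),
                  n_per_component)
      Xk <- sweep(Z %*% L, 2, model$means[k, ], "+")
      mean(gmm_score(model, Xk)$assignments == k)
    }, numeric(1))
  })
  list(per_component = data.frame(component = seq_len(model$K), accuracy = acc),
       mean = mean(acc), sd = stats::sd(acc))
}

#' Cortical distribution index
#'
#' Michelson contrast of a response type's prevalence in anterior versus
#' posterior V1: `(n_anterior - n_posterior) / (n_anterior + n_posterior)`,
#' where the inputs are the fractions of each field's neurons assigned to
#' the type. +1 marks a type found only in anterior V1, -1 only in
#' posterior V1, 0 an even distribution; +/-0.33 corresponds to a 2:1
#' enrichment.
#'
#' @param n_anterior,n_posterior non-negative prevalences (fractions or
#'   counts; the index is scale-invariant in each pair). Vectorized.
#' @return index in [-1, 1]; NA (with a warning) where both inputs are 0.
#' @export
distribution_index <- function(n_anterior, n_posterior) {
  if (any(n_anterior < 0) || any(n_posterior < 0)) {
    abort("prevalences must be non-negative")
  }
  tot <- n_anterior + n_posterior
  if (length(tot) == 1 && tot == 0) {
    abort("distribution index undefined: type absent from both fields")
  }
  idx <- (n_anterior - n_posterior) / tot
  if (any(tot == 0)) {
    warning("type absent from both fields: index set to NA")
    idx[tot == 0] <- NA_real_
  }
  idx
}

#' Distribution index per response type from assignments and fields
#'
#' @param assignments integer type assignment per neuron.
#' @param field character "anterior"/"posterior" per neuron.
#' @param K number of types (default: max assignment).
#' @param use "fraction" (default; per-field fractions, as in the index
#'   definition) or "count" (raw counts).
#' @return data.frame: type, n_anterior, n_posterior, index.
#' @export
type_distribution_indices <- function(assignments, field,
                                      K = max(assignments),
                                      use = c("fraction", "count")) {
  use <- match.arg(use)
  stopifnot(length(assignments) == length(field),
            all(field %in% c("anterior", "posterior")))
  n_ant_tot <- sum(field == "anterior")
  n_post_tot <- sum(field == "posterior")
  cnt_a <- tabulate(assignments[field == "anterior"], K)
  cnt_p <- tabulate(assignments[field == "posterior"], K)
  if (use == "fraction") {
    a <- if (n_ant_tot > 0) cnt_a / n_ant_tot else cnt_a
    p <- if (n_post_tot > 0) cnt_p / n_post_tot else cnt_p
  } else {
    a <- cnt_a; p <- cnt_p
  }
  data.frame(type = seq_len(K), n_anterior = a, n_posterior = p,
             index = suppressWarnings(distribution_index(a, p)))
}

#' Partition response types by cortical enrichment
#'
#' Types with distribution index within (-threshold, threshold) are "even";
#' above threshold "anterior"; below -threshold "posterior".
#'
#' @param indices numeric distribution indices (one per type), or the
#'   data.frame from [type_distribution_indices()].
#' @param threshold enrichment threshold (0.3).
#' @return data.frame: type, index, group (factor even/anterior/posterior).
#' @export
enrichment_partition <- function(indices, threshold = 0.3) {
  if (is.data.frame(indices)) {
    type <- indices$type; idx <- indices$index
  } else {
    type <- seq_along(indices); idx <- indices
  }
  group <- ifelse(is.na(idx), NA_character_,
                  ifelse(idx >= threshold, "anterior",
                         ifelse(idx <= -threshold, "posterior", "even")))
  data.frame(type = type, index = idx,
             group = factor(group, levels = c("even", "anterior", "posterior")))
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Shortest-augmenting-path implementation for rectangular cost matrices
#' (rows <= cols), used to match fitted mixture components to planted type
#' labels.
#'
#' @param cost numeric cost matrix, nrow(cost) <= ncol(cost).
#' @return integer vector: for each row, the assigned column.
#' @export
hungarian_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) abort("cost matrix must have nrow <= ncol")
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)    # p[j+1]: row assigned to column j (0 = virtual)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_col <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign_col[p[j + 1]] <- j
  assign_col
}

#' Hungarian-matched agreement between two labelings
#'
#' Relabels `pred` by the minimum-cost (maximum-overlap) matching to
#' `truth` and returns the fraction of agreeing labels.
#'
#' @param truth,pred integer label vectors of equal length.
#' @return agreement fraction in [0, 1].
#' @export
matched_agreement <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  kt <- max(truth); kp <- max(pred)
  K <- max(kt, kp)
  conf <- table(factor(pred, levels = 1:K), factor(truth, levels = 1:K))
  perm <- hungarian_assignment(-conf)  # maximize overlap
  sum(conf[cbind(1:K, perm)]) / length(truth)
}
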