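#' @name object_detection
#' @title Per-type detectability of dark UV objects in noise scenes
#'
#' @description
#' Linear-nonlinear simulation of per-response-type responses to
#' two-channel scenes: each type is modeled as a uniform square RF of 10
#' degrees visual angle whose green and UV weights are the type's mean
#' center ETA peak amplitudes. Scenes are converted to contrast (pixel
#' minus channel mean), filtered with the RF in each channel, the channel
#' maps combined by the type's weights, and all map values above the
#' rectification threshold summed into one response per scene and type.
#' Object presence (a dark ellipse in the UV channel) is then decoded per
#' type and reported as discriminability in bits.
NULL

#' Build per-type simulated receptive fields
#'
#' One RF per response type, weighted by the type's mean center-amplitude
#' pair over its member neurons. Types whose mean weights are both
#' (near-)zero are skipped with a warning.
#'
#' @param assignments integer type assignment per neuron.
#' @param amplitudes data.frame with per-neuron `green_c`, `uv_c` (rows
#'   aligned with `assignments`), e.g. from [peak_amplitudes()].
#' @param rf_size_deg side of the square RF in degrees (10).
#' @param px_per_deg pixels per degree (2).
#' @return object of class `type_rfs`: data.frame `weights` (type, w_green,
#'   w_uv), `side_px`.
#' @export
build_type_rfs <- function(assignments, amplitudes, rf_size_deg = 10,
                           px_per_deg = 2) {
  stopifnot(length(assignments) == nrow(amplitudes))
  K <- max(assignments)
  w <- data.frame(
    type = seq_len(K),
    w_green = as.vector(tapply(amplitudes$green_c, factor(assignments, 1:K),
                               mean)),
    w_uv = as.vector(tapply(amplitudes$uv_c, factor(assignments, 1:K), mean))
  )
  zero <- is.na(w$w_green) | (abs(w$w_green) < 1e-12 & abs(w$w_uv) < 1e-12)
  if (any(zero)) {
    warning("skipping ", sum(zero), " type(s) with zero-magnitude weights")
    w <- w[!zero, , drop = FALSE]
  }
  structure(list(weights = w,
                 side_px = max(1L, as.integer(round(rf_size_deg * px_per_deg)))),
            class = "type_rfs")
}

# box-filter sum over k x k windows ("valid" region) via summed-area table
box_sum <- function(img, k) {
  S <- rbind(0, apply(rbind(img), 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  nr <- nrow(img) - k + 1L
  nc <- ncol(img) - k + 1L
  if (nr < 1 || nc < 1) abort("RF larger than the scene")
  i <- seq_len(nr); j <- seq_len(nc)
  S[i + k, j + k, drop = FALSE] - S[i, j + k, drop = FALSE] -
    S[i + k, j, drop = FALSE] + S[i, j, drop = FALSE]
}

#' Simulate per-type responses to a set of scenes
#'
#' @param rfs a `type_rfs`.
#' @param scenes list of `scene` objects.
#' @param threshold rectification threshold on the combined activity map
#'   (default 0: sum of all positive values).
#' @return matrix scenes x types of non-negative responses; attribute
#'   `"map_sd"` holds the pooled s.d. of combined map values across scenes
#'   and types (the natural unit for the threshold).
#' @export
simulate_scene_responses <- function(rfs, scenes, threshold = 0) {
  stopifnot(inherits(rfs, "type_rfs"), length(scenes) > 0)
  k <- rfs$side_px
  W <- rfs$weights
  resp <- matrix(0, length(scenes), nrow(W),
                 dimnames = list(NULL, paste0("type", W$type)))
  ss <- 0; nvals <- 0
  for (s in seq_along(scenes)) {
    sc <- scenes[[s]]
    g <- sc$green - mean(sc$green)
    u <- sc$uv - mean(sc$uv)
    cg <- box_sum(g, k)
    cu <- box_sum(u, k)
    for (ti in seq_len(nrow(W))) {
      map <- W$w_green[ti] * cg + W$w_uv[ti] * cu
      resp[s, ti] <- sum(map[map > threshold])
      ss <- ss + sum(map^2); nvals <- nvals + length(map)
    }
  }
  attr(resp, "map_sd") <- sqrt(ss / nvals)
  resp
}

#' Decode object presence per response type
#'
#' For each type, the scalar scene responses are decoded (object vs noise)
#' with the cross-validated RBF-SVM of the decoding module; scene order is
#' shuffled once (seeded) so the contiguous folds contain both classes.
#'
#' @param responses scenes x types matrix from [simulate_scene_responses()].
#' @param labels factor/character of length scenes ("object"/"noise").
#' @param seed integer seed (shuffle + decoder).
#' @param n_folds cross-validation folds (10).
#' @param ... passed to [decode_class()].
#' @return data.frame: type, mean_accuracy, mean_bits, sd_bits; per-split
#'   results in attribute `"splits"`.
#' @export
decode_object_presence <- function(responses, labels, seed = 1, n_folds = 10,
                                   ...) {
  stopifnot(nrow(responses) == length(labels))
  ord <- with_seed(child_seed(seed, 77L), sample.int(nrow(responses)))
  labels <- factor(labels)[ord]
  responses <- responses[ord, , drop = FALSE]
  types <- colnames(responses)
  out <- vector("list", ncol(responses))
  splits <- vector("list", ncol(responses))
  for (ti in seq_len(ncol(responses))) {
    x <- responses[, ti, drop = FALSE]
    if (stats::sd(x) == 0) {
      # constant responses carry no information: chance, 0 bits
      out[[ti]] <- data.frame(type = types[ti], mean_accuracy = 50,
                              mean_bits = 0, sd_bits = 0)
      next
    }
    dr <- decode_class(x, labels, seed = child_seed(seed, 200L + ti),
                       n_folds = n_folds, ...)
    out[[ti]] <- data.frame(type = types[ti],
                            mean_accuracy = dr$mean_accuracy,
                            mean_bits = dr$mean_bits,
                            sd_bits = stats::sd(dr$splits$bits))
    splits[[ti]] <- transform(dr$splits, type = types[ti])
  }
  res <- do.call(rbind, out)
  attr(res, "splits") <- do.call(rbind, splits)
  res
}
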