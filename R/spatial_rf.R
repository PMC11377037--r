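#' @name spatial_rf
#' @title Sparse-noise spatial receptive fields and overlap index
#'
#' @description
#' Spatial ETAs from sparse-noise responses: per neuron, the
#' stimulus-matrix x response-matrix product collapsed over polarity and
#' color gives an 8 x 5 map. Because On and Off deviations cancel when
#' averaged signed, the map averages the *magnitudes* of the bright-dot and
#' dark-dot deviation maps. Neurons are gated by the linear correlation
#' between map-predicted and observed responses (include when r > 0.25),
#' maps are bilinearly upsampled to 40 x 25 and peak-normalized, and the
#' overlap index is the fraction of suprathreshold (> 0.25 of peak) pixels
#' falling inside the 37.5-degree center spot of the color-noise stimulus.
NULL

#' Compute raw spatial ETAs from sparse-noise responses
#'
#' @param responses a `sparse_responses` object.
#' @return object of class `spatial_rf_set`: `maps` (n_x x n_y x neurons),
#'   `flat_flag` (logical: near-flat map), `stim`, `neurons`.
#' @export
compute_spatial_eta <- function(responses) {
  stopifnot(inherits(responses, "sparse_responses"))
  stim <- responses$stim
  cond <- stim$conditions[stim$sequence$cond_id, ]
  R <- responses$rates
  n <- ncol(R)
  dev <- sweep(R, 2, colMeans(R))
  maps <- array(0, c(stim$n_x, stim$n_y, n))
  for (pol in c("bright", "dark")) {
    sel <- cond$polarity == pol
    # mean deviation per grid cell (colors pooled), then rectified;
    # cell index is column-major (ix fastest) to match array filling
    cell <- factor((cond$iy[sel] - 1L) * stim$n_x + cond$ix[sel],
                   levels = seq_len(stim$n_x * stim$n_y))
    m <- rowsum(dev[sel, , drop = FALSE], cell, reorder = TRUE) /
      as.vector(table(cell))
    maps <- maps + array(abs(m), c(stim$n_x, stim$n_y, n)) / 2
  }
  flat <- apply(maps, 3, function(m) {
    mx <- max(m); mn <- min(m)
    mx <= 0 || (mn > 0 && mx / mn < 1.1)
  })
  structure(list(maps = maps, flat_flag = flat, stim = stim,
                 neurons = responses$neurons),
            class = "spatial_rf_set")
}

#' Linear prediction quality of spatial ETAs
#'
#' Predicts each presentation's response as the flattened ETA value at the
#' presented dot position and correlates prediction with observation.
#'
#' @param rfset a `spatial_rf_set`.
#' @param responses the `sparse_responses` the maps came from.
#' @param r_threshold inclusion threshold on the correlation (0.25).
#' @return the `spatial_rf_set` with `prediction_r` and `include` added;
#'   zero-variance predictions give NA and exclusion.
#' @export
prediction_quality <- function(rfset, responses, r_threshold = 0.25) {
  stopifnot(inherits(rfset, "spatial_rf_set"),
            inherits(responses, "sparse_responses"))
  stim <- rfset$stim
  cond <- stim$conditions[stim$sequence$cond_id, ]
  pos_idx <- cbind(cond$ix, cond$iy)
  n <- dim(rfset$maps)[3]
  r <- vapply(seq_len(n), function(i) {
    pred <- rfset$maps[, , i][pos_idx]
    if (stats::sd(pred) == 0 || stats::sd(responses$rates[, i]) == 0) {
      return(NA_real_)
    }
    stats::cor(pred, responses$rates[, i])
  }, numeric(1))
  rfset$prediction_r <- r
  rfset$include <- !is.na(r) & r > r_threshold
  rfset$r_threshold <- r_threshold
  rfset
}

#' Bilinear upsampling of a grid map
#'
#' Values are taken at cell centers; output pixel centers are interpolated
#' (edge values extended beyond the outermost centers).
#'
#' @param map n_x x n_y matrix.
#' @param factor integer upsampling factor per axis (5: 8x5 -> 40x25).
#' @return (n_x*factor) x (n_y*factor) matrix.
#' @export
upsample_map <- function(map, factor = 5) {
  nx <- nrow(map); ny <- ncol(map)
  gx <- (seq_len(nx * factor) - 0.5) / factor + 0.5
  gy <- (seq_len(ny * factor) - 0.5) / factor + 0.5
  tmp <- apply(map, 2, function(col) {
    stats::approx(seq_len(nx), col, xout = gx, rule = 2)$y
  })
  t(apply(tmp, 1, function(row) {
    stats::approx(seq_len(ny), row, xout = gy, rule = 2)$y
  }))
}

#' Overlap of a spatial RF with the noise-stimulus center spot
#'
#' On the peak-normalized upsampled map, the overlap index is the number of
#' pixels above `contour` inside the center disc divided by the number of
#' pixels above `contour` anywhere.
#'
#' @param up_map peak-normalized upsampled map (max = 1).
#' @param stim the `sparse_noise` object (for screen geometry).
#' @param center_diameter_deg diameter of the noise center spot (37.5).
#' @param contour contour threshold relative to peak (0.25).
#' @param center_deg disc center in degrees (default c(0, 0), screen center).
#' @return overlap fraction in [0, 1]; NA if no suprathreshold pixels.
#' @export
overlap_index <- function(up_map, stim, center_diameter_deg = 37.5,
                          contour = 0.25, center_deg = c(0, 0)) {
  stopifnot(inherits(stim, "sparse_noise"))
  factor_x <- nrow(up_map) / stim$n_x
  factor_y <- ncol(up_map) / stim$n_y
  # upsampled pixel centers in grid coordinates, then degrees
  gx <- (seq_len(nrow(up_map)) - 0.5) / factor_x + 0.5
  gy <- (seq_len(ncol(up_map)) - 0.5) / factor_y + 0.5
  cell <- (stim$screen_deg - 2 * stim$margin_deg) / c(stim$n_x, stim$n_y)
  x_deg <- -stim$screen_deg[1] / 2 + stim$margin_deg + cell[1] * (gx - 0.5)
  y_deg <- -stim$screen_deg[2] / 2 + stim$margin_deg + cell[2] * (gy - 0.5)
  supra <- up_map > contour
  if (!any(supra)) return(NA_real_)
  d2 <- outer((x_deg - center_deg[1])^2, (y_deg - center_deg[2])^2, "+")
  inside <- d2 <= (center_diameter_deg / 2)^2
  sum(supra & inside) / sum(supra)
}

#' Per-neuron spatial RF summary table
#'
#' Runs the full spatial pipeline: raw maps, prediction gating, upsampling,
#' peak normalization, overlap index.
#'
#' @param responses a `sparse_responses`.
#' @param factor upsampling factor (5).
#' @param ... passed to [overlap_index()].
#' @return list: `table` (data.frame neuron_id, argmax_deg_x, argmax_deg_y,
#'   prediction_r, overlap, include), `rfset`.
#' @export
spatial_rf_table <- function(responses, factor = 5, ...) {
  rfset <- compute_spatial_eta(responses)
  rfset <- prediction_quality(rfset, responses)
  stim <- rfset$stim
  n <- dim(rfset$maps)[3]
  res <- lapply(seq_len(n), function(i) {
    m <- rfset$maps[, , i]
    am <- which(m == max(m), arr.ind = TRUE)[1, ]
    ov <- if (rfset$include[i] && max(m) > 0) {
      overlap_index(upsample_map(m, factor) / max(upsample_map(m, factor)),
                    stim, ...)
    } else NA_real_
    data.frame(neuron_id = rfset$neurons$neuron_id[i],
               argmax_deg_x = stim$x_deg[am[1]],
               argmax_deg_y = stim$y_deg[am[2]],
               prediction_r = rfset$prediction_r[i],
               overlap = ov,
               include = rfset$include[i])
  })
  list(table = do.call(rbind, res), rfset = rfset)
}
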