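#' @name stimgen
#' @title Stimulus generation: color noise, sparse noise, noise scenes
#'
#' @description
#' Generators for the three stimulus ensembles of the pipeline:
#' a 4-channel balanced binary center-surround color noise (UV/green,
#' center/surround) updated at 5 Hz, a sparse-noise dot paradigm on an
#' 8 x 5 grid for spatial receptive-field mapping, and two-channel
#' (green, UV) gradient-noise scenes with optional dark UV ellipse
#' "predator-like" objects.
#'
#' All generators are pure functions of their `seed`.
NULL

CHANNEL_NAMES <- c("GreenC", "UVC", "GreenS", "UVS")

#' Generate balanced binary center-surround color noise
#'
#' Each of the four channels (green center, UV center, green surround,
#' UV surround) is an exactly balanced binary sequence: a random permutation
#' of `frames/2` ones and `frames/2` zeros, independently per channel. The
#' {0,1} intensities map to {-1,+1} contrast for analysis, so every channel
#' is an exactly zero-mean regressor.
#'
#' @param duration_s stimulus duration in seconds (default 1500, i.e. 25 min).
#' @param rate_hz update rate in frames per second (default 5).
#' @param seed integer seed.
#' @return an object of class `stim_sequence`: list with `frames`, `rate_hz`,
#'   `channels` (frames x 4 binary matrix, columns GreenC, UVC, GreenS, UVS)
#'   and `seed`.
#' @examples
#' stim <- make_color_noise(duration_s = 60, rate_hz = 5, seed = 1)
#' colSums(stim$channels)  # exactly frames/2 each
#' @export
make_color_noise <- function(duration_s = 1500, rate_hz = 5, seed = 1) {
  frames_num <- duration_s * rate_hz
  if (abs(frames_num - round(frames_num)) > 1e-9) {
    abort("duration_s * rate_hz must be an integer number of frames")
  }
  frames <- as.integer(round(frames_num))
  if (frames %% 2L != 0L) {
    abort("frame count must be even: exact balance is impossible for ",
          frames, " frames")
  }
  channels <- with_seed(seed, {
    vapply(CHANNEL_NAMES, function(ch) {
      sample(rep(c(0L, 1L), frames %/% 2L))
    }, integer(frames))
  })
  structure(
    list(frames = frames, rate_hz = rate_hz, channels = channels, seed = seed),
    class = "stim_sequence"
  )
}

#' Map binary stimulus intensities to signed contrast
#'
#' @param stim a `stim_sequence`.
#' @return frames x 4 matrix with values in {-1, +1}.
#' @export
stim_contrast <- function(stim) {
  stopifnot(inherits(stim, "stim_sequence"))
  2 * stim$channels - 1
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat(sprintf("<stim_sequence> %d frames @ %g Hz (%.1f min), 4 channels, seed %d\n",
              x$frames, x$rate_hz, x$frames / x$rate_hz / 60, x$seed))
  invisible(x)
}

#' Generate a sparse-noise dot sequence
#'
#' Bright (255) and dark (0) UV and green dots on a gray (127) background,
#' presented at 8 x 5 grid positions (screen margins excluded), each
#' condition repeated `repeats` times in randomized order (a fresh
#' permutation of all conditions per repeat block).
#'
#' @param n_x,n_y grid positions along the horizontal/vertical axis (8, 5).
#' @param dot_size_deg dot size in degrees of visual angle (12).
#' @param repeats repetitions per condition (50).
#' @param presentation_ms presentation time per dot (200).
#' @param screen_deg screen extent in degrees, c(width, height) (120 x 90).
#' @param margin_deg excluded screen margin; default half a dot width.
#' @param seed integer seed.
#' @return object of class `sparse_noise`: `conditions` (data.frame with
#'   cond_id, ix, iy, x_deg, y_deg, polarity, color), `sequence` (data.frame
#'   with presentation order: pres, rep, cond_id), plus the grid geometry.
#' @export
make_sparse_noise <- function(n_x = 8, n_y = 5, dot_size_deg = 12,
                              repeats = 50, presentation_ms = 200,
                              screen_deg = c(120, 90),
                              margin_deg = dot_size_deg / 2, seed = 1) {
  stopifnot(n_x >= 1, n_y >= 1, repeats >= 1)
  usable <- screen_deg - 2 * margin_deg
  if (any(usable <= 0)) abort("margin_deg leaves no usable screen area")
  cell <- usable / c(n_x, n_y)
  x_deg <- -screen_deg[1] / 2 + margin_deg + cell[1] * (seq_len(n_x) - 0.5)
  y_deg <- -screen_deg[2] / 2 + margin_deg + cell[2] * (seq_len(n_y) - 0.5)

  conditions <- expand.grid(ix = seq_len(n_x), iy = seq_len(n_y),
                            polarity = c("bright", "dark"),
                            color = c("UV", "green"),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conditions$cond_id <- seq_len(nrow(conditions))
  conditions$x_deg <- x_deg[conditions$ix]
  conditions$y_deg <- y_deg[conditions$iy]
  conditions$value <- ifelse(conditions$polarity == "bright", 255L, 0L)

  order_mat <- with_seed(seed, {
    vapply(seq_len(repeats), function(r) sample.int(nrow(conditions)),
           integer(nrow(conditions)))
  })
  sequence <- data.frame(
    pres = seq_len(nrow(conditions) * repeats),
    rep = rep(seq_len(repeats), each = nrow(conditions)),
    cond_id = as.vector(order_mat)
  )
  structure(
    list(conditions = conditions, sequence = sequence,
         n_x = n_x, n_y = n_y, x_deg = x_deg, y_deg = y_deg,
         dot_size_deg = dot_size_deg, presentation_ms = presentation_ms,
         screen_deg = screen_deg, margin_deg = margin_deg,
         repeats = repeats, seed = seed),
    class = "sparse_noise"
  )
}

#' @export
print.sparse_noise <- function(x, ...) {
  cat(sprintf("<sparse_noise> %dx%d grid, %d conditions x %d repeats = %d presentations\n",
              x$n_x, x$n_y, nrow(x$conditions), x$repeats, nrow(x$sequence)))
  invisible(x)
}

# ---- gradient (Perlin) noise -------------------------------------------------

# Classic 2-D gradient noise on an integer lattice with quintic fade,
# vectorized over all pixels. Output is approximately in [-1, 1].
perlin_layer <- function(nrow_px, ncol_px, scale) {
  gx <- ceiling((ncol_px - 1) / scale) + 1L
  gy <- ceiling((nrow_px - 1) / scale) + 1L
  theta <- matrix(stats::runif(gy * gx, 0, 2 * pi), gy, gx)
  grad_x <- cos(theta); grad_y <- sin(theta)

  x <- matrix(rep((seq_len(ncol_px) - 1) / scale, each = nrow_px), nrow_px)
  y <- matrix(rep((seq_len(nrow_px) - 1) / scale, ncol_px), nrow_px)
  x0 <- floor(x); y0 <- floor(y)
  dx <- x - x0; dy <- y - y0

  idx <- function(iy, ix) cbind(as.vector(iy) + 1L, as.vector(ix) + 1L)
  dot <- function(iy, ix, ox, oy) {
    ii <- idx(iy, ix)
    matrix(grad_x[ii] * as.vector(ox) + grad_y[ii] * as.vector(oy),
           nrow_px, ncol_px)
  }
  n00 <- dot(y0, x0, dx, dy)
  n10 <- dot(y0, x0 + 1, dx - 1, dy)
  n01 <- dot(y0 + 1, x0, dx, dy - 1)
  n11 <- dot(y0 + 1, x0 + 1, dx - 1, dy - 1)

  fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)
  u <- fade(dx); v <- fade(dy)
  nx0 <- n00 + u * (n10 - n00)
  nx1 <- n01 + u * (n11 - n01)
  nx0 + v * (nx1 - nx0)
}

# Fractal sum of octaves; persistence halves the amplitude per octave.
perlin_noise <- function(nrow_px, ncol_px, scale = 16, octaves = 3,
                         persistence = 0.5) {
  out <- matrix(0, nrow_px, ncol_px)
  amp <- 1
  sc <- scale
  for (o in seq_len(octaves)) {
    out <- out + amp * perlin_layer(nrow_px, ncol_px, max(sc, 1.5))
    amp <- amp * persistence
    sc <- sc / 2
  }
  out
}

rescale01 <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(matrix(0.5, nrow(m), ncol(m)))
  (m - rng[1]) / diff(rng)
}

#' Generate a two-channel noise scene with an optional dark UV object
#'
#' Each channel (green, UV) is an independent gradient-noise field rescaled
#' to [0, 1]. For object scenes, a dark ellipse of given (or randomized)
#' size, position and angle is added to the UV channel only, by scaling the
#' UV intensities inside the ellipse towards zero; the green channel never
#' contains the object.
#'
#' @param size_px image size `c(nrow, ncol)` in pixels (default 64 x 64,
#'   i.e. 32 x 32 degrees at the default 2 px/degree).
#' @param object `NULL` for a pure noise scene; `"random"` to draw ellipse
#'   parameters from the default ranges; or a list with elements
#'   `center` (c(row, col), px), `axes` (semi-axes c(a, b), px),
#'   `angle` (radians) and optionally `depth` (darkening fraction in (0, 1],
#'   default 0.8).
#' @param seed integer seed.
#' @param scale,octaves gradient-noise parameters: lattice spacing in pixels
#'   of the coarsest octave and number of octaves. The default scale (16 px
#'   = 8 degrees) puts the noise correlation length near the typical object
#'   size.
#' @return object of class `scene`: list with `green` and `uv` channel
#'   matrices in [0, 1], `has_object`, `object` (parameters or NULL),
#'   `size_px`, `seed`.
#' @export
make_scene <- function(size_px = c(64, 64), object = NULL, seed = 1,
                       scale = 16, octaves = 3) {
  stopifnot(length(size_px) == 2, all(size_px >= 8))
  res <- with_seed(seed, {
    green <- rescale01(perlin_noise(size_px[1], size_px[2], scale, octaves))
    uv <- rescale01(perlin_noise(size_px[1], size_px[2], scale, octaves))
    obj <- object
    if (identical(obj, "random")) {
      a <- stats::runif(1, 0.12, 0.25) * min(size_px)
      b <- stats::runif(1, 0.08, 0.18) * min(size_px)
      margin <- max(a, b) + 1
      obj <- list(
        center = c(stats::runif(1, margin, size_px[1] - margin),
                   stats::runif(1, margin, size_px[2] - margin)),
        axes = c(a, b),
        angle = stats::runif(1, 0, pi),
        depth = 0.8
      )
    }
    list(green = green, uv = uv, object = obj)
  })
  green <- res$green; uv <- res$uv; obj <- res$object
  if (!is.null(obj)) {
    if (is.null(obj$depth)) obj$depth <- 0.8
    stopifnot(length(obj$center) == 2, length(obj$axes) == 2,
              all(obj$axes > 0), obj$depth > 0, obj$depth <= 1)
    r_max <- max(obj$axes)
    if (obj$center[1] - r_max < 1 || obj$center[1] + r_max > size_px[1] ||
        obj$center[2] - r_max < 1 || obj$center[2] + r_max > size_px[2]) {
      abort("ellipse does not fit within the image bounds")
    }
    inside <- ellipse_mask(size_px, obj$center, obj$axes, obj$angle)
    # darken UV inside the ellipse; strictly darker wherever uv > 0
    uv[inside] <- uv[inside] * (1 - obj$depth)
  }
  structure(
    list(green = green, uv = uv, has_object = !is.null(obj), object = obj,
         size_px = size_px, seed = seed),
    class = "scene"
  )
}

# logical matrix: pixels inside a rotated ellipse
ellipse_mask <- function(size_px, center, axes, angle) {
  row <- matrix(rep(seq_len(size_px[1]), size_px[2]), size_px[1])
  col <- matrix(rep(seq_len(size_px[2]), each = size_px[1]), size_px[1])
  dr <- row - center[1]; dc <- col - center[2]
  ca <- cos(angle); sa <- sin(angle)
  u <- dc * ca + dr * sa
  v <- -dc * sa + dr * ca
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

#' Generate a batch of scenes
#'
#' @param n number of scenes.
#' @param with_object logical: add a randomized dark UV ellipse to each scene.
#' @param seed integer seed (each scene gets a derived child seed).
#' @param ... passed to [make_scene()].
#' @return list of `scene` objects.
#' @export
make_scenes <- function(n, with_object = FALSE, seed = 1, ...) {
  lapply(seq_len(n), function(i) {
    make_scene(object = if (with_object) "random" else NULL,
               seed = child_seed(seed, i + if (with_object) 500000L else 0L),
               ...)
  })
}

#' Per-scene contrast statistic
#'
#' Root-mean-square deviation of pixel intensities from the scene mean,
#' pooled over both channels.
#'
#' @param scene a `scene`.
#' @return non-negative scalar.
#' @export
scene_contrast <- function(scene) {
  px <- c(scene$green, scene$uv)
  sqrt(mean((px - mean(px))^2))
}

#' Match the contrast distribution of object scenes to noise scenes
#'
#' Rescales each object scene's pixel deviations (around its pooled mean) so
#' that the empirical distribution of the per-scene contrast statistic over
#' the object set equals that of the noise set: the i-th smallest object
#' contrast is mapped onto the corresponding quantile of the noise
#' contrasts. Matching is idempotent and leaves a scene already at its
#' target contrast unchanged.
#'
#' @param object_scenes,noise_scenes non-empty lists of `scene` objects.
#' @return the object scenes, rescaled; scale factors in attribute `"scale"`.
#' @export
match_contrast <- function(object_scenes, noise_scenes) {
  if (length(object_scenes) == 0 || length(noise_scenes) == 0) {
    abort("scene sets must be non-empty")
  }
  c_obj <- vapply(object_scenes, scene_contrast, numeric(1))
  c_noise <- vapply(noise_scenes, scene_contrast, numeric(1))
  if (any(c_obj == 0) || any(c_noise == 0)) {
    abort("constant (zero-contrast) image in input")
  }
  n <- length(c_obj)
  # target for rank i among n: the matching quantile of the noise contrasts
  probs <- (rank(c_obj, ties.method = "first") - 0.5) / n
  target <- stats::quantile(c_noise, probs = probs, names = FALSE, type = 7)
  s <- target / c_obj
  out <- mapply(function(scene, si) {
    m <- mean(c(scene$green, scene$uv))
    scene$green <- m + (scene$green - m) * si
    scene$uv <- m + (scene$uv - m) * si
    scene
  }, object_scenes, s, SIMPLIFY = FALSE)
  attr(out, "scale") <- s
  out
}
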