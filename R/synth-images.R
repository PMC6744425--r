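#' Generate greyscale stimulus images
#'
#' Renders one synthetic object image per stimulus: bar-shaped stimuli as
#' high-aspect-ratio ellipses (bounding-box aspect ratio > 2) and blob-shaped
#' stimuli as near-circular ellipses (aspect ratio < 1.5), on a black
#' background. Intensity, texture, position, and orientation jitter are drawn
#' independently of animacy, so animacy is not recoverable from the images by
#' construction -- mirroring the role of the real stimuli, where low-level
#' image structure carries shape but not category.
#'
#' @param design A design tibble from [generate_design()].
#' @param size Image side in pixels (>= 64).
#' @param seed Integer seed (an `"images"` substream is derived from it).
#' @return A named list (by `stimulus_id`) of `size x size` matrices in `[0, 1]`.
#' @export
generate_images <- function(design, size = 128, seed = 1L) {
  if (!is.numeric(size) || length(size) != 1 || size < 64) {
    ndba_abort("`size` must be a single number >= 64.", "ndba_invalid_argument")
  }
  size <- as.integer(size)
  xs <- matrix(seq_len(size), size, size)
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)

  imgs <- lapply(seq_len(nrow(design)), function(i) {
    sid <- design$stimulus_id[[i]]
    bar <- design$shape[[i]] == "bar"
    with_substream(seed, "images", sid, code = {
      # Shape-dependent geometry; everything else independent of animacy.
      if (bar) {
        a <- size * 0.33 * runif(1, 0.92, 1.08)
        b <- size * 0.10 * runif(1, 0.92, 1.08)
        theta <- runif(1, -15, 15) * pi / 180
      } else {
        a <- size * 0.21 * runif(1, 0.92, 1.08)
        b <- size * 0.17 * runif(1, 0.92, 1.08)
        theta <- runif(1, 0, pi)
      }
      cx <- size / 2 + runif(1, -0.03, 0.03) * size
      cy <- size / 2 + runif(1, -0.03, 0.03) * size
      dx <- xs - cx; dy <- ys - cy
      u <- (dx * cos(theta) + dy * sin(theta)) / a
      v <- (-dx * sin(theta) + dy * cos(theta)) / b
      mask <- (u^2 + v^2) <= 1
      base <- runif(1, 0.5, 0.9)
      # Smooth low-frequency texture: a few random sinusoids.
      tex <- matrix(0, size, size)
      for (k in 1:4) {
        f <- runif(2, 1, 4) / size
        phi <- runif(1, 0, 2 * pi)
        tex <- tex + runif(1, 0.02, 0.06) * sin(2 * pi * (f[1] * xs + f[2] * ys) + phi)
      }
      img <- ifelse(mask, pmin(1, pmax(0, base + tex)), 0)
      img
    })
  })
  names(imgs) <- as.character(design$stimulus_id)
  imgs
}

#' Bounding-box aspect ratio of the object in an image
#'
#' @param image A numeric matrix; pixels above `threshold` count as object.
#' @param threshold Intensity threshold.
#' @return Ratio of the longer to the shorter bounding-box side.
#' @export
image_aspect_ratio <- function(image, threshold = 0.05) {
  idx <- which(image > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NA_real_)
  h <- diff(range(idx[, 1])) + 1
  w <- diff(range(idx[, 2])) + 1
  max(h, w) / min(h, w)
}
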