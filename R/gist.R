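#' Frequency-domain Gabor filter bank
#'
#' Builds `orientations x scales` one-sided frequency-domain filters: Gaussian
#' in log2 spatial frequency around octave-spaced center frequencies
#' (`0.25, 0.125, ...` cycles/pixel) and Gaussian in orientation, with angular
#' bandwidth `pi / orientations / sqrt(2)` so the bank tiles `[0, pi)` with
#' near-uniform summed energy. One-sided filters yield the analytic-signal
#' envelope, whose squared magnitude is the local filter energy averaged by
#' [compute_gist()].
#'
#' @param orientations,scales Number of orientations and scales (>= 1).
#' @param image_size Image side in pixels; must fit at least one cycle of the
#'   lowest center frequency (`image_size >= 2^(scales + 1)`).
#' @return A list of class `ndba_gabor_bank` with `filters` (list of complex-
#'   compatible real matrices) and `meta` (tibble: orientation, scale, theta,
#'   freq_cpp).
#' @export
gabor_bank <- function(orientations = 8, scales = 4, image_size = 128) {
  if (orientations < 1 || scales < 1) {
    ndba_abort("`orientations` and `scales` must be >= 1.", "ndba_invalid_argument")
  }
  n <- as.integer(image_size)
  if (n < 2^(scales + 1)) {
    ndba_abort(sprintf(
      "image_size %d too small for %d octave-spaced scales (need >= %d).",
      n, scales, 2^(scales + 1)), "ndba_invalid_argument")
  }
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / n  # cycles/pixel
  kx <- matrix(k, n, n)
  ky <- matrix(k, n, n, byrow = TRUE)
  f <- sqrt(kx^2 + ky^2)
  ang <- atan2(ky, kx)
  sigma_f <- 0.5                                  # octaves
  sigma_theta <- (pi / orientations) / sqrt(2)

  meta <- tidyr::expand_grid(orientation = seq_len(orientations),
                             scale = seq_len(scales)) |>
    dplyr::mutate(theta = (.data$orientation - 1) * pi / orientations,
                  freq_cpp = 0.25 / 2^(.data$scale - 1))
  filters <- purrr::pmap(meta, function(orientation, scale, theta, freq_cpp) {
    radial <- matrix(0, n, n)
    nz <- f > 0
    radial[nz] <- exp(-(log2(f[nz] / freq_cpp))^2 / (2 * sigma_f^2))
    # One-sided (direction, not orientation): angular distance mod 2*pi.
    d <- atan2(sin(ang - theta), cos(ang - theta))
    g <- radial * exp(-d^2 / (2 * sigma_theta^2))
    g[1, 1] <- 0                                  # no DC
    g
  })
  structure(list(filters = filters, meta = meta, image_size = n,
                 orientations = orientations, scales = scales),
            class = "ndba_gabor_bank")
}

#' GIST-style image descriptor
#'
#' Computes the filter-energy image for every Gabor filter in the bank,
#' averages the energy within each cell of a `grid x grid` partition of the
#' image, and concatenates the block means. The descriptor has length
#' `grid^2 * orientations * scales` (512 for the 4/8/4 default), laid out
#' block-major, then orientation, then scale (scale varying fastest). Images
#' are intensity-normalized (zero mean, unit variance) before filtering, so
#' the descriptor is invariant to adding a constant to all pixels.
#'
#' @param image A finite numeric matrix, min dimension >= `grid`.
#' @param grid Blocks per side.
#' @param orientations,scales Filter bank shape (ignored when `bank` given).
#' @param bank Optional precomputed [gabor_bank()] matching `dim(image)`.
#' @param normalize Intensity-normalize before filtering (default TRUE).
#' @return A numeric vector of class `gist_descriptor` with attributes
#'   `grid`, `orientations`, `scales`.
#' @export
compute_gist <- function(image, grid = 4, orientations = 8, scales = 4,
                         bank = NULL, normalize = TRUE) {
  if (!is.matrix(image) || !all(is.finite(image))) {
    ndba_abort("`image` must be a finite numeric matrix.", "ndba_invalid_input")
  }
  if (min(dim(image)) < grid) {
    ndba_abort("Image smaller than the block grid.", "ndba_invalid_argument")
  }
  if (nrow(image) != ncol(image)) {
    ndba_abort("`image` must be square.", "ndba_invalid_argument")
  }
  n <- nrow(image)
  if (is.null(bank)) bank <- gabor_bank(orientations, scales, n)
  if (bank$image_size != n) {
    ndba_abort("Filter bank size does not match image size.", "ndba_invalid_argument")
  }
  if (normalize) {
    s <- sd(image)
    image <- if (s > 0) (image - mean(image)) / s else image * 0
  }
  fimg <- stats::fft(image)
  row_block <- ceiling(seq_len(n) * grid / n)
  col_block <- ceiling(seq_len(n) * grid / n)
  counts <- as.vector(table(row_block)) %o% as.vector(table(col_block))

  n_filt <- nrow(bank$meta)
  out <- array(0, dim = c(bank$scales, bank$orientations, grid * grid))
  for (i in seq_len(n_filt)) {
    resp <- stats::fft(fimg * bank$filters[[i]], inverse = TRUE) / (n * n)
    energy <- Mod(resp)^2
    bm <- rowsum(energy, row_block)
    bm <- t(rowsum(t(bm), col_block)) / counts     # grid x grid block means
    o <- bank$meta$orientation[[i]]; sc <- bank$meta$scale[[i]]
    out[sc, o, ] <- as.vector(t(bm))               # blocks row-major
  }
  structure(as.vector(out), class = "gist_descriptor",
            grid = grid, orientations = bank$orientations, scales = bank$scales)
}

#' GIST descriptors for a set of images
#'
#' @param images A named list of equally sized square matrices (names are
#'   stimulus ids).
#' @inheritParams compute_gist
#' @return A tibble with `stimulus_id` plus one column per descriptor entry
#'   (`g0001`, ...).
#' @export
gist_descriptors <- function(images, grid = 4, orientations = 8, scales = 4,
                             normalize = TRUE) {
  n <- nrow(images[[1]])
  bank <- gabor_bank(orientations, scales, n)
  desc <- purrr::map(images, compute_gist, grid = grid, bank = bank,
                     normalize = normalize)
  m <- do.call(rbind, lapply(desc, as.numeric))
  colnames(m) <- sprintf("g%04d", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(stimulus_id = as.integer(names(images))),
    tibble::as_tibble(m)
  )
}

# Cluster pairs for cross-decoding: train on the pair matched on the nuisance
# dimension and differing in the decoded dimension, test on the complementary
# matched pair, both directions.
crossdecode_pairs <- function(design, dimension) {
  other <- if (dimension == "animacy") "shape" else "animacy"
  split(as.character(unique(design$cluster)),
        design[[other]][match(unique(design$cluster), design$cluster)])
}

#' Descriptor-level cross-decoding control
#'
#' Trains a regularized linear discriminant on the descriptors of one
#' cluster pair matched on the orthogonal dimension (e.g. for animacy: the two
#' bar-shaped clusters) and tests it on the complementary matched pair, in
#' both directions. Features are z-scored using training statistics. Train and
#' test never share stimuli.
#'
#' @param descriptors A tibble from [gist_descriptors()] (or any tibble with
#'   `stimulus_id` plus numeric feature columns).
#' @param design A design tibble from [generate_design()].
#' @param dimension `"animacy"` or `"shape"`.
#' @param shrinkage Passed to [fit_lda()].
#' @return A tibble with one row per fold: `fold`, `train_clusters`,
#'   `test_clusters`, `n_test`, `accuracy`.
#' @export
crossdecode_descriptors <- function(descriptors, design,
                                    dimension = c("animacy", "shape"),
                                    shrinkage = "lw") {
  dimension <- match.arg(dimension)
  counts <- table(design$cluster)
  if (any(counts < 2)) {
    ndba_abort("Need >= 2 stimuli per cluster for cross-decoding.",
               "ndba_invalid_argument")
  }
  feat <- as.matrix(descriptors[setdiff(names(descriptors), "stimulus_id")])
  rownames(feat) <- descriptors$stimulus_id
  labels <- task_labels(design, dimension)
  pairs <- crossdecode_pairs(design, dimension)

  purrr::imap_dfr(pairs, function(train_clusters, pair_name) {
    train_stim <- design$stimulus_id[design$cluster %in% train_clusters]
    test_stim <- setdiff(design$stimulus_id, train_stim)
    tr <- match(as.character(train_stim), rownames(feat))
    te <- match(as.character(test_stim), rownames(feat))
    mu <- colMeans(feat[tr, , drop = FALSE])
    sg <- apply(feat[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    ztr <- sweep(sweep(feat[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    zte <- sweep(sweep(feat[te, , drop = FALSE], 2, mu), 2, sg, "/")
    y_tr <- labels[match(train_stim, design$stimulus_id)]
    y_te <- labels[match(test_stim, design$stimulus_id)]
    fit <- fit_lda(ztr, y_tr, shrinkage = shrinkage)
    pred <- predict(fit, zte)
    test_clusters <- setdiff(as.character(unique(design$cluster)), train_clusters)
    tibble::tibble(
      fold = match(pair_name, names(pairs)),
      train_clusters = paste(train_clusters, collapse = "+"),
      test_clusters = paste(test_clusters, collapse = "+"),
      n_test = length(test_stim),
      accuracy = mean(pred == y_te)
    )
  })
}
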