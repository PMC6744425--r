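#' Build searchlight neighborhoods
#'
#' For every voxel, the `k` nearest voxels (including itself) by Euclidean
#' distance on the grid coordinates, with ties broken lexicographically by
#' (z, y, x) for determinism. With isotropic voxels the grid metric and the
#' millimetre metric are equivalent.
#'
#' @param voxel_coords Integer matrix `[voxel x 3]` of unique grid coordinates.
#' @param k Neighborhood size (default 100).
#' @return A list of integer member vectors, one per center voxel, of class
#'   `ndba_neighborhoods` with attributes `k` and `coords`.
#' @export
build_neighborhoods <- function(voxel_coords, k = 100) {
  if (k < 1) ndba_abort("`k` must be >= 1.", "ndba_invalid_argument")
  voxel_coords <- as.matrix(voxel_coords)
  if (anyDuplicated(voxel_coords)) {
    ndba_abort("Voxel coordinates must be unique.", "ndba_invalid_argument")
  }
  v <- nrow(voxel_coords)
  k <- min(k, v)
  d2 <- as.matrix(stats::dist(voxel_coords))^2
  zyx <- order(voxel_coords[, 3], voxel_coords[, 2], voxel_coords[, 1])
  rank_zyx <- integer(v)
  rank_zyx[zyx] <- seq_len(v)
  nb <- lapply(seq_len(v), function(i) {
    ord <- order(d2[i, ], rank_zyx)
    sort(ord[seq_len(k)])
  })
  structure(nb, class = "ndba_neighborhoods", k = k, coords = voxel_coords)
}

#' Searchlight decoding accuracy map for one subject
#'
#' Runs cross-validated linear-discriminant decoding within every
#' neighborhood's voxels and stores the pooled held-out accuracy at the center
#' voxel. Neighborhoods whose fit fails yield `NaN` (with a warning) rather
#' than aborting the map.
#'
#' @param subject An `ndba_patterns` object.
#' @param labels Per-stimulus two-class labels.
#' @param neighborhoods From [build_neighborhoods()].
#' @param shrinkage `"lw"` (Ledoit-Wolf) or a fixed value in `[0, 1]`.
#' @return A numeric accuracy vector, one entry per center voxel.
#' @export
run_searchlight <- function(subject, labels, neighborhoods, shrinkage = "lw") {
  fl <- flatten_patterns(subject)
  y <- factor(labels)[fl$info$stimulus]
  shrink_code <- if (identical(shrinkage, "lw")) -1 else shrinkage
  acc <- sl_crossval_accuracy(fl$x, as.integer(y) - 1L,
                              as.integer(fl$info$run),
                              unclass(neighborhoods), shrink_code)
  if (anyNA(acc)) {
    warning(sprintf("%d of %d neighborhoods failed to fit; stored as NaN.",
                    sum(is.na(acc)), length(acc)))
    acc[is.na(acc)] <- NaN
  }
  acc
}

#' Group-level searchlight significance with FDR control
#'
#' Per voxel, a one-sample one-sided t-test of the subjects' accuracies
#' against chance, then Benjamini-Hochberg adjustment over all testable
#' voxels, and a significance mask at the given adjusted-p threshold
#' (default 0.005, mirroring typical searchlight map thresholds).
#'
#' @param accuracy_maps Numeric matrix `[subject x voxel]`.
#' @param chance Chance accuracy (default 0.5).
#' @param q_threshold FDR-adjusted p threshold for the mask.
#' @return A tibble `(voxel, mean_accuracy, t, p, q, significant)`.
#' @export
group_significance <- function(accuracy_maps, chance = 0.5, q_threshold = 0.005) {
  accuracy_maps <- as.matrix(accuracy_maps)
  n <- nrow(accuracy_maps)
  if (n < 2) ndba_abort("Need >= 2 subjects for group inference.",
                        "ndba_invalid_argument")
  m <- colMeans(accuracy_maps)
  s <- apply(accuracy_maps, 2, sd)
  tstat <- (m - chance) / (s / sqrt(n))
  p <- pt(tstat, df = n - 1, lower.tail = FALSE)
  # Degenerate columns: no spread. At or below chance -> p = 1; above -> p -> 0.
  zero_sd <- !is.na(s) & s == 0
  p[zero_sd & m <= chance] <- 1
  p[zero_sd & m > chance] <- 0
  tstat[zero_sd] <- ifelse(m[zero_sd] > chance, Inf, 0)
  bad <- apply(accuracy_maps, 2, function(col) any(!is.finite(col)))
  p[bad] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  tibble::tibble(
    voxel = seq_along(m),
    mean_accuracy = m,
    t = tstat,
    p = p,
    q = q,
    significant = !is.na(q) & q <= q_threshold
  )
}

#' Select the top-classifying voxels within the significant area
#'
#' The `ceiling(fraction * |mask|)` voxels with the highest group-mean
#' accuracy inside the significance mask; ties broken lexicographically by
#' (z, y, x) coordinate. An empty mask signals "no significant decoding" as a
#' condition of class `ndba_empty_roi`, so pipelines can skip the dependent
#' distance analysis for that dimension.
#'
#' @param group_result Tibble from [group_significance()].
#' @param voxel_coords Integer matrix `[voxel x 3]`.
#' @param fraction Fraction of the mask to keep (default 0.10).
#' @return Sorted integer voxel indices of the ROI.
#' @export
select_top_voxels <- function(group_result, voxel_coords, fraction = 0.10) {
  mask <- which(group_result$significant & is.finite(group_result$mean_accuracy))
  if (length(mask) == 0) {
    ndba_abort("No significant decoding: the ROI is empty.", "ndba_empty_roi")
  }
  n_roi <- ceiling(fraction * length(mask))
  ord <- order(-group_result$mean_accuracy[mask],
               voxel_coords[mask, 3], voxel_coords[mask, 2], voxel_coords[mask, 1])
  sort(mask[ord[seq_len(n_roi)]])
}

#' Tidy a searchlight map into voxel coordinates
#'
#' @param accuracy Numeric map (one value per voxel) or matrix
#'   `[subject x voxel]` (averaged).
#' @param voxel_coords Integer matrix `[voxel x 3]`.
#' @return A tibble `(voxel, x, y, z, accuracy)`.
#' @export
searchlight_map <- function(accuracy, voxel_coords) {
  if (is.matrix(accuracy)) accuracy <- colMeans(accuracy)
  tibble::tibble(voxel = seq_along(accuracy),
                 x = voxel_coords[, 1], y = voxel_coords[, 2],
                 z = voxel_coords[, 3], accuracy = accuracy)
}
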