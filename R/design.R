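#' Stimulus clusters and task names
#'
#' The assumed study design uses 32 greyscale object images in four
#' subordinate clusters (pets, insects, tools, vegetables) that cross animacy
#' with real-world shape, plus a contrived indoor/outdoor grouping that
#' crisscrosses both dimensions. Subjects categorize the same stimuli under
#' three tasks.
#'
#' @return Character vectors of cluster and task names.
#' @export
ndba_clusters <- function() c("pets", "insects", "tools", "vegetables")

#' @rdname ndba_clusters
#' @export
ndba_tasks <- function() c("animacy", "shape", "indoor_outdoor")

#' Generate the crossed stimulus design
#'
#' Builds the label structure over exemplar stimuli: four clusters of
#' `n_per_cluster` exemplars each, with animacy constant within cluster
#' (pets, insects animate; tools, vegetables inanimate), real-world shape
#' (bar vs blob) constant within cluster and counterbalanced across animacy,
#' and an indoor/outdoor grouping (indoor = pets + tools) that spans both
#' animacy levels and both shape levels, so it is not linearly separable
#' along either dimension alone.
#'
#' @param n_per_cluster Number of exemplars per cluster (default 8, giving
#'   the standard 32-stimulus design).
#' @param bar_clusters Which one animate and one inanimate cluster carry the
#'   high-aspect-ratio ("bar") shape. The assignment is a design choice;
#'   the default makes insects and tools bar-like.
#' @return A tibble with columns `stimulus_id` (integer, 0-based), `cluster`,
#'   `animacy`, `shape`, `crisscross` (all factors).
#' @examples
#' generate_design(8)
#' @export
generate_design <- function(n_per_cluster = 8,
                            bar_clusters = c("insects", "tools")) {
  if (!is.numeric(n_per_cluster) || length(n_per_cluster) != 1 ||
      is.na(n_per_cluster) || n_per_cluster < 1) {
    ndba_abort("`n_per_cluster` must be a single integer >= 1.",
               "ndba_invalid_argument")
  }
  n_per_cluster <- as.integer(n_per_cluster)
  clusters <- ndba_clusters()
  bar_clusters <- match.arg(bar_clusters, clusters, several.ok = TRUE)
  animate_clusters <- c("pets", "insects")
  if (sum(bar_clusters %in% animate_clusters) != 1 || length(bar_clusters) != 2) {
    ndba_abort("`bar_clusters` must name exactly one animate and one inanimate cluster.",
               "ndba_invalid_argument")
  }
  cluster <- rep(clusters, each = n_per_cluster)
  tibble::tibble(
    stimulus_id = seq_along(cluster) - 1L,
    cluster = factor(cluster, levels = clusters),
    animacy = factor(ifelse(cluster %in% animate_clusters, "animate", "inanimate"),
                     levels = c("animate", "inanimate")),
    shape = factor(ifelse(cluster %in% bar_clusters, "bar", "blob"),
                   levels = c("bar", "blob")),
    crisscross = factor(ifelse(cluster %in% c("pets", "tools"), "indoor", "outdoor"),
                        levels = c("indoor", "outdoor"))
  )
}

#' Per-stimulus category labels for a task
#'
#' @param design A design tibble from [generate_design()].
#' @param task One of `"animacy"`, `"shape"`, `"indoor_outdoor"`.
#' @return A factor of length `nrow(design)` with the two task categories.
#' @export
task_labels <- function(design, task = ndba_tasks()) {
  task <- match.arg(task)
  switch(task,
         animacy = design$animacy,
         shape = design$shape,
         indoor_outdoor = design$crisscross)
}

# The classifier dimension backing each task; the crisscross task has none
# (it uses the percentile-summed combination of both).
task_dimension <- function(task) {
  switch(task, animacy = "animacy", shape = "shape", indoor_outdoor = NA_character_)
}
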