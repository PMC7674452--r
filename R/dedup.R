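#' Doublet-linking configuration
#'
#' A physical droplet intersects several consecutive optical sections and is
#' detected once per section; these "doublets" must be counted once. Two
#' detections are candidate views of the same droplet when their slices are
#' close in z and their centroids close in (y, x). Centroid distance (rather
#' than pixel overlap) is used because consecutive-slice cross-sections of
#' one droplet differ in size.
#'
#' @param link_radius Maximum centroid (y, x) distance in pixels.
#' @param max_z_gap Maximum slice-index difference (default 1: adjacent or
#'   same slice).
#' @return A `link_config` object.
#' @export
link_config <- function(link_radius = 5, max_z_gap = 1L) {
  stopifnot(link_radius >= 0, max_z_gap >= 1)
  structure(list(link_radius = link_radius, max_z_gap = as.integer(max_z_gap)),
            class = "link_config")
}

#' Group doublet detections into clusters
#'
#' Builds a graph with an edge between every pair of particles whose slice
#' indices differ by at most `max_z_gap` and whose centroid distance is at
#' most `link_radius`, and partitions particles into its connected
#' components. Chaining is transitive: a droplet spanning three or more
#' slices collapses into a single cluster even though its extreme sections
#' are not directly linked.
#'
#' @param particles Particle tibble (needs `slice`, `centroid_y`,
#'   `centroid_x`).
#' @param cfg A [link_config()].
#' @return The tibble with an integer `cluster_id` column; every particle
#'   belongs to exactly one cluster.
#' @export
link_doublets <- function(particles, cfg = link_config()) {
  n <- nrow(particles)
  if (n == 0) {
    particles$cluster_id <- integer()
    return(particles)
  }
  ij <- which(
    outer(particles$slice, particles$slice,
          function(a, b) abs(a - b) <= cfg$max_z_gap) &
    (outer(particles$centroid_y, particles$centroid_y, "-")^2 +
       outer(particles$centroid_x, particles$centroid_x, "-")^2
     <= cfg$link_radius^2),
    arr.ind = TRUE)
  ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(ij) > 0) g <- igraph::add_edges(g, t(ij))
  particles$cluster_id <- as.integer(igraph::components(g)$membership)
  particles
}

#' Resolve doublet clusters, keeping the largest candidate
#'
#' Exactly one particle is retained per cluster: the one with the greatest
#' pixel count, ties broken by lower slice index, then lower centroid y,
#' then lower centroid x. Discarded doublets remain in the table with
#' `kept_after_dedup = FALSE` so the CSV output stays auditable; summaries
#' exclude them.
#'
#' @param particles Particle tibble with a `cluster_id` column (see
#'   [link_doublets()]).
#' @return The tibble with `kept_after_dedup` set.
#' @export
resolve_clusters <- function(particles) {
  if (nrow(particles) == 0) return(particles)
  ord <- order(particles$cluster_id, -particles$area_px, particles$slice,
               particles$centroid_y, particles$centroid_x)
  keep_rows <- ord[!duplicated(particles$cluster_id[ord])]
  particles$kept_after_dedup <- seq_len(nrow(particles)) %in% keep_rows
  particles
}

#' Remove z-dimension doublets
#'
#' Convenience wrapper: [link_doublets()] then [resolve_clusters()]. The
#' operation is idempotent — re-running it on its own output changes
#' nothing, because any two retained particles close enough to link would
#' already have shared a cluster.
#'
#' @inheritParams link_doublets
#' @return Particle tibble with `cluster_id` and `kept_after_dedup` columns.
#' @export
dedup_particles <- function(particles, cfg = link_config()) {
  resolve_clusters(link_doublets(particles, cfg))
}
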