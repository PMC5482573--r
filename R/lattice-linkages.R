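#' Neighbor pairs of lattice particles
#'
#' All unordered particle pairs whose center distance is strictly below
#' `max_distance`, with the relative pose of the second member expressed in
#' the first member's reference frame: rotation `R_i^-1 R_j`, translation
#' `R_i^-1 (c_j - c_i)`. The relative pose of (j,i) is the inverse of that of
#' (i,j).
#'
#' @param table particle table with finalized poses.
#' @param max_distance neighbor cutoff in voxels.
#' @return data.frame: `i`, `j` (particle ids), `distance`, `rot`, `tilt`,
#'   `psi` (relative rotation, degrees), `tx`, `ty`, `tz` (relative
#'   translation, voxels).
#' @export
neighbor_pairs <- function(table, max_distance) {
  n <- nrow(table)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0),
                               distance = numeric(0), rot = numeric(0),
                               tilt = numeric(0), psi = numeric(0),
                               tx = numeric(0), ty = numeric(0),
                               tz = numeric(0)))
  pos <- cbind(table$x + table$sx, table$y + table$sy, table$z + table$sz)
  out <- NULL
  for (a in seq_len(n - 1)) {
    Ra <- euler_to_matrix(c(table$rot[a], table$tilt[a], table$psi[a]))
    for (b in (a + 1):n) {
      d <- sqrt(sum((pos[b, ] - pos[a, ])^2))
      if (d >= max_distance) next
      Rb <- euler_to_matrix(c(table$rot[b], table$tilt[b], table$psi[b]))
      Rrel <- t(Ra) %*% Rb
      trel <- as.numeric(t(Ra) %*% (pos[b, ] - pos[a, ]))
      e <- matrix_to_euler(Rrel)
      out <- rbind(out, data.frame(i = table$particle_id[a],
                                   j = table$particle_id[b], distance = d,
                                   rot = e[1], tilt = e[2], psi = e[3],
                                   tx = trel[1], ty = trel[2], tz = trel[3]))
    }
  }
  rownames(out) <- NULL
  out
}

# Metric between two relative poses: rotation geodesic (deg) plus weighted
# translation (voxels). Symmetrized over the two traversal directions of the
# unordered pair, so the labelling of pair members does not matter.
linkage_pose_distance <- function(p, q, rot_weight = 1) {
  d1 <- rotation_distance(p$R, q$R) * rot_weight + sqrt(sum((p$t - q$t)^2))
  qi <- list(R = t(q$R), t = as.numeric(-t(q$R) %*% q$t))
  d2 <- rotation_distance(p$R, qi$R) * rot_weight + sqrt(sum((p$t - qi$t)^2))
  min(d1, d2)
}

#' Cluster neighbor pairs into linkage classes
#'
#' Agglomerative (average-linkage) clustering of the relative poses under a
#' symmetrized rotation-plus-translation metric (default 1 degree == 1
#' voxel). Cut either at `n_classes` or at a distance `cutoff`.
#'
#' @param pairs output of [neighbor_pairs()].
#' @param n_classes number of classes to return (optional).
#' @param cutoff metric cut height (used if `n_classes` is NULL).
#' @param rot_weight voxels per degree in the metric.
#' @return list: `pairs` (input with `class` labels), `sizes` (class sizes),
#'   `mean_pose` (per-class mean relative pose as a data.frame).
#' @export
cluster_linkages <- function(pairs, n_classes = NULL, cutoff = NULL,
                             rot_weight = 1) {
  n <- nrow(pairs)
  if (is.null(n_classes) && is.null(cutoff))
    stop("provide n_classes or cutoff")
  if (!is.null(n_classes) && n < n_classes)
    stop(sprintf("%d pairs cannot form %d classes", n, n_classes))
  ps <- lapply(seq_len(n), function(i)
    list(R = euler_to_matrix(c(pairs$rot[i], pairs$tilt[i], pairs$psi[i])),
         t = c(pairs$tx[i], pairs$ty[i], pairs$tz[i])))
  dm <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) if (b > a)
    dm[a, b] <- dm[b, a] <- linkage_pose_distance(ps[[a]], ps[[b]], rot_weight)
  if (n == 1) {
    lab <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(dm), method = "average")
    lab <- if (!is.null(n_classes)) stats::cutree(hc, k = n_classes)
           else stats::cutree(hc, h = cutoff)
  }
  # relabel classes by decreasing size for determinism
  sizes <- table(lab)
  newlab <- match(lab, as.integer(names(sort(sizes, decreasing = TRUE))))
  pairs$class <- newlab
  mp <- NULL
  for (cl in sort(unique(newlab))) {
    idx <- which(newlab == cl)
    # chordal mean rotation projected back to SO(3)
    M <- Reduce("+", lapply(ps[idx], function(p) p$R)) / length(idx)
    sv <- svd(M)
    R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
    tmean <- colMeans(do.call(rbind, lapply(ps[idx], function(p) p$t)))
    e <- matrix_to_euler(R)
    mp <- rbind(mp, data.frame(class = cl, size = length(idx),
                               rot = e[1], tilt = e[2], psi = e[3],
                               tx = tmean[1], ty = tmean[2], tz = tmean[3]))
  }
  list(pairs = pairs, sizes = as.integer(table(newlab)), mean_pose = mp)
}
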