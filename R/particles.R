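#' Construct a particle table
#'
#' The particle table is a plain data.frame, one row per subtomogram, with
#' mandatory columns: `particle_id`, `vesicle_id`, `x`, `y`, `z` (0-based
#' voxel-center coordinates of the extraction point), `rot`, `tilt`, `psi`
#' (ZXZ intrinsic Euler angles, degrees, mapping the reference frame onto the
#' particle) and `sx`, `sy`, `sz` (residual shifts in voxels, reference
#' frame). Optional columns: `cc` (constrained cross-correlation in
#' `[-1, 1]`), `half_set` (1 or 2), `class`.
#'
#' @param df data.frame carrying at least the mandatory columns; missing pose
#'   or shift columns are initialized to 0.
#' @return validated particle table (data.frame).
#' @export
particle_table <- function(df) {
  for (col in c("rot", "tilt", "psi", "sx", "sy", "sz"))
    if (is.null(df[[col]])) df[[col]] <- 0
  need <- c("particle_id", "vesicle_id", "x", "y", "z",
            "rot", "tilt", "psi", "sx", "sy", "sz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("particle table is missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(df$cc) && length(df$cc) && any(!is.na(df$cc)))
    stopifnot(all(df$cc >= -1 & df$cc <= 1, na.rm = TRUE))
  rownames(df) <- NULL
  df
}

row_pose <- function(table, i) {
  pose(table$rot[i], table$tilt[i], table$psi[i],
       c(table$sx[i], table$sy[i], table$sz[i]))
}

set_row_pose <- function(table, i, p) {
  table$rot[i] <- p$euler[1]; table$tilt[i] <- p$euler[2]
  table$psi[i] <- p$euler[3]
  table$sx[i] <- p$shift[1]; table$sy[i] <- p$shift[2]; table$sz[i] <- p$shift[3]
  table
}

#' Pick particles on a vesicle surface
#'
#' Quasi-uniform surface points at approximately `spacing` separation
#' (deterministic Fibonacci lattice), each with an initial pose aligning the
#' reference z axis with the outward normal and zero azimuth. In practice the
#' surface is oversampled relative to the expected lattice spacing and
#' duplicates are removed after alignment.
#'
#' @param center vesicle center, 0-based voxel coordinates.
#' @param radius vesicle radius in voxels.
#' @param spacing target point separation in voxels.
#' @param vesicle_id id recorded for every picked point.
#' @return a particle table.
#' @export
sample_vesicle_surface <- function(center, radius, spacing, vesicle_id = 1L) {
  stopifnot(spacing > 0, radius > 0)
  npt <- max(1L, as.integer(round(4 * pi * radius^2 / spacing^2)))
  normals <- fibonacci_sphere(npt)
  pts <- sweep(normals * radius, 2, center, "+")
  eul <- t(apply(normals, 1, normal_to_euler))
  particle_table(data.frame(
    particle_id = seq_len(npt), vesicle_id = vesicle_id,
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    rot = eul[, 1], tilt = eul[, 2], psi = eul[, 3],
    nx = normals[, 1], ny = normals[, 2], nz = normals[, 3]))
}

#' Extract a cubic subtomogram
#'
#' Cuts the `box`-sided cube centered on the voxel nearest `center`. The cut
#' must lie fully inside the tomogram; there is no silent padding. The
#' tomogram's wedge is attached to the result.
#'
#' @param tomo a `density_map`.
#' @param center 0-based voxel coordinates.
#' @param box even box side in voxels.
#' @param wedge the tomogram's [wedge_spec()].
#' @return list with `map` (a `density_map`) and `wedge`.
#' @export
extract_subtomogram <- function(tomo, center, box, wedge = wedge_spec()) {
  stopifnot(box %% 2 == 0, all(box <= dim(tomo$data)))
  c0 <- round(center)                  # 0-based nearest voxel
  lo <- c0 - box / 2 + 1               # 1-based start index
  hi <- lo + box - 1
  if (any(lo < 1) || any(hi > dim(tomo$data)))
    stop(sprintf("box of %d voxels at (%s) extends outside the tomogram",
                 box, paste(c0, collapse = ",")))
  sub <- tomo$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  list(map = density_map(sub, tomo$voxel_size), wedge = wedge,
       center_voxel = c0)
}

#' Split a particle table into odd/even-vesicle halves
#'
#' Gold-standard half-set split: half 1 holds the odd-numbered vesicles,
#' half 2 the even-numbered ones, so no vesicle contributes to both halves.
#'
#' @param table a particle table with `vesicle_id`.
#' @return list of two particle tables with `half_set` set to 1 and 2.
#' @export
split_halves <- function(table) {
  odd <- table[table$vesicle_id %% 2 == 1, , drop = FALSE]
  even <- table[table$vesicle_id %% 2 == 0, , drop = FALSE]
  if (nrow(odd)) odd$half_set <- 1L else odd$half_set <- integer(0)
  if (nrow(even)) even$half_set <- 2L else even$half_set <- integer(0)
  rownames(odd) <- rownames(even) <- NULL
  list(odd, even)
}
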