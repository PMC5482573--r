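#' Leaf phantom specification
#'
#' Describes the ground-truth density of one "leaf" — the asymmetric unit of a
#' membrane coat lattice (for COPI: one coatomer complex plus two Arf1
#' molecules) — as a sum of isotropic 3D Gaussian blobs, plus an optional
#' extra "GAP" blob standing in for a bound ArfGAP catalytic domain.
#'
#' The default blob layout is deliberately asymmetric (no nontrivial rotation
#' maps it onto itself), so that pose recovery from the phantom is well-posed.
#' Blob centers are in Angstrom in the leaf frame: the z axis is the outward
#' membrane normal and the origin sits on the membrane surface at the triad
#' center.
#'
#' @param centers n x 3 matrix of blob centers (Angstrom, leaf frame).
#' @param sigmas numeric(n) blob standard deviations (Angstrom).
#' @param weights numeric(n) peak amplitudes (unitless).
#' @param gap_blob list(center, sigma, weight) for the optional extra density.
#' @param symmetry_order rotational symmetry of the triad (3 for C3 coats).
#' @param box_size phantom box side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(centers = default_leaf_blobs()$centers,
                         sigmas = default_leaf_blobs()$sigmas,
                         weights = default_leaf_blobs()$weights,
                         gap_blob = default_gap_blob(),
                         symmetry_order = 3,
                         box_size = 32,
                         voxel_size = 4) {
  centers <- rbind(centers)
  stopifnot(ncol(centers) == 3, length(sigmas) == nrow(centers),
            length(weights) == nrow(centers), symmetry_order >= 1)
  structure(list(centers = centers, sigmas = sigmas, weights = weights,
                 gap_blob = gap_blob, symmetry_order = symmetry_order,
                 box_size = as.integer(box_size), voxel_size = voxel_size),
            class = "phantom_spec")
}

# Blob layout for the default leaf: a lumpy, chirally asymmetric cluster
# spreading off the triad axis with long internal lever arms, so that small
# rotations cannot be absorbed by a compensating translation (keeps pose
# recovery well-conditioned). The two membrane-proximal blobs sit where the
# Arf1 anchors would.
default_leaf_blobs <- function() {
  list(centers = rbind(c(  0,   0, 14),
                       c( 22,  14, 20),
                       c( 38,  -8, 26),
                       c( 12, -26, 30),
                       c( -8,  24, 34),
                       c( 28,  30, 40),
                       c( 44,  12, 42),
                       c(  6,   6, 44),
                       c( 10,   8, 10),
                       c( 40,  -6, 12)),
       sigmas  = c(7, 6, 6, 5.5, 5.5, 5, 5, 6, 5.5, 5.5),
       weights = c(1.0, 0.9, 0.85, 0.8, 0.8, 0.7, 0.7, 0.75, 0.7, 0.7))
}

# Extra blob near the central (triad-axis proximal) Arf1 position.
default_gap_blob <- function() {
  list(center = c(4, 2, 26), sigma = 6, weight = 0.8)
}

# Add weight*exp(-r^2/(2 sigma^2)) to `arr` around a voxel-space center,
# evaluated on the 3-sigma bounding box only.
add_gaussian_blob <- function(arr, center_vox, sigma_vox, weight) {
  d <- dim(arr)
  lo <- pmax(1, floor(center_vox + 1 - 3 * sigma_vox))
  hi <- pmin(d, ceiling(center_vox + 1 + 3 * sigma_vox))
  if (any(lo > hi)) return(arr)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  gx <- exp(-((ix - 1 - center_vox[1])^2) / (2 * sigma_vox^2))
  gy <- exp(-((iy - 1 - center_vox[2])^2) / (2 * sigma_vox^2))
  gz <- exp(-((iz - 1 - center_vox[3])^2) / (2 * sigma_vox^2))
  blk <- weight * (gx %o% gy %o% gz)
  arr[ix, iy, iz] <- arr[ix, iy, iz] + blk
  arr
}

#' Build the leaf phantom density
#'
#' Renders the leaf's Gaussian blobs onto a cubic grid with the leaf origin at
#' the box center. Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @param with_gap logical; include the extra GAP blob.
#' @return a `density_map`.
#' @export
build_leaf_phantom <- function(spec, with_gap = FALSE) {
  n <- spec$box_size
  vs <- spec$voxel_size
  ctr <- (n - 1) / 2
  arr <- array(0, c(n, n, n))
  centers <- spec$centers
  sigmas <- spec$sigmas
  weights <- spec$weights
  if (with_gap) {
    if (is.null(spec$gap_blob)) stop("with_gap = TRUE but spec has no gap_blob")
    centers <- rbind(centers, spec$gap_blob$center)
    sigmas <- c(sigmas, spec$gap_blob$sigma)
    weights <- c(weights, spec$gap_blob$weight)
  }
  for (b in seq_along(sigmas)) {
    cv <- centers[b, ] / vs + ctr
    sv <- sigmas[b] / vs
    if (any(cv - 3 * sv < 0) || any(cv + 3 * sv > n - 1))
      stop(sprintf("blob %d (center %s A) extends outside the %d-voxel box",
                   b, paste(round(centers[b, ], 1), collapse = ","), n))
    arr <- add_gaussian_blob(arr, cv, sv, weights[b])
  }
  density_map(arr, vs)
}

#' Vesicle scene specification
#'
#' Describes a synthetic field of coated vesicles: spheres decorated with
#' C3-symmetric triads of leaves, mimicking in-vitro-budded coated vesicles at
#' desk scale.
#'
#' @param vesicle_radii radii in Angstrom, recycled to `n_vesicles`.
#' @param n_vesicles number of vesicles.
#' @param triads_per_vesicle triads placed on each vesicle.
#' @param membrane_shell numeric(3): radial offset (A), Gaussian thickness (A),
#'   amplitude. Amplitude 0 disables the membrane.
#' @param gap_fraction fraction of leaves carrying the GAP blob, in `[0,1]`.
#' @param noise_sigma white-noise standard deviation added to the scene.
#' @param seed integer seed; all scene randomness flows from it.
#' @param box_size scene box side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param min_separation_deg minimum great-circle separation between triads.
#' @param tilt_jitter_deg sd of a random tilt of the leaf axis away from the
#'   surface normal (0 = perfectly membrane-normal coat).
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(vesicle_radii = 110, n_vesicles = 1,
                       triads_per_vesicle = 6,
                       membrane_shell = c(0, 10, 0.3),
                       gap_fraction = 0, noise_sigma = 0, seed = 1,
                       box_size = 96, voxel_size = 4,
                       min_separation_deg = 50, tilt_jitter_deg = 0) {
  stopifnot(gap_fraction >= 0, gap_fraction <= 1, n_vesicles >= 1)
  structure(list(vesicle_radii = rep_len(vesicle_radii, n_vesicles),
                 n_vesicles = as.integer(n_vesicles),
                 triads_per_vesicle = as.integer(triads_per_vesicle),
                 membrane_shell = membrane_shell,
                 gap_fraction = gap_fraction, noise_sigma = noise_sigma,
                 seed = as.integer(seed), box_size = as.integer(box_size),
                 voxel_size = voxel_size,
                 min_separation_deg = min_separation_deg,
                 tilt_jitter_deg = tilt_jitter_deg),
            class = "scene_spec")
}

# Evaluate code with a locally seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rejection-sample unit vectors with pairwise angular separation >= min_sep.
sample_sphere_separated <- function(n, min_sep_deg, max_retries = 1000) {
  pts <- matrix(0, 0, 3)
  cos_min <- cos(min_sep_deg * pi / 180)
  tries <- 0
  while (nrow(pts) < n) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2))
    if (nrow(pts) == 0 || all(pts %*% v < cos_min)) {
      pts <- rbind(pts, v)
    } else {
      tries <- tries + 1
      if (tries > max_retries)
        stop(sprintf(paste0("could not place %d triads at >= %.0f deg ",
                            "separation; achieved %d"),
                     n, min_sep_deg, nrow(pts)))
    }
  }
  pts
}

#' Build a synthetic coated-vesicle scene with ground truth
#'
#' Places `n_vesicles` membrane spheres in the scene box, decorates each with
#' non-overlapping triads whose leaf axes point along the outward normal
#' (random azimuth), renders every leaf's Gaussian blobs, and records the true
#' center, pose, vesicle id and GAP class of every leaf.
#'
#' @param scene a [scene_spec()].
#' @param phantom a [phantom_spec()].
#' @return list with `map` (a `density_map`) and `truth` (data.frame with
#'   columns particle_id, vesicle_id, triad_id, x, y, z (0-based voxels),
#'   rot, tilt, psi (degrees), class).
#' @export
build_vesicle_scene <- function(scene, phantom) {
  n <- scene$box_size
  vs <- scene$voxel_size
  half_extent <- max(sqrt(rowSums(phantom$centers^2))) + 3 * max(phantom$sigmas)
  margin <- max(scene$vesicle_radii) + half_extent
  if (2 * margin > n * vs)
    stop(sprintf("vesicle (radius + leaf extent = %.0f A) does not fit in the %.0f A box",
                 margin, n * vs))
  with_seed(scene$seed, {
    centers_A <- vesicle_centers(scene, margin)
    arr <- array(0, c(n, n, n))
    truth <- NULL
    pid <- 0L
    for (v in seq_len(scene$n_vesicles)) {
      rv <- scene$vesicle_radii[v]
      cv <- centers_A[v, ]
      if (scene$membrane_shell[3] > 0)
        arr <- add_membrane_shell(arr, cv / vs, (rv + scene$membrane_shell[1]) / vs,
                                  scene$membrane_shell[2] / vs,
                                  scene$membrane_shell[3])
      axes <- sample_sphere_separated(scene$triads_per_vesicle,
                                      scene$min_separation_deg)
      for (tr in seq_len(nrow(axes))) {
        u <- axes[tr, ]
        if (scene$tilt_jitter_deg > 0) {
          jit_axis <- stats::rnorm(3)
          jit_axis <- jit_axis - sum(jit_axis * u) * u
          jit_axis <- jit_axis / sqrt(sum(jit_axis^2))
          u <- as.numeric(axis_angle_matrix(jit_axis,
                 stats::rnorm(1, 0, scene$tilt_jitter_deg)) %*% u)
        }
        azimuth <- stats::runif(1, 0, 360)
        e0 <- normal_to_euler(u)
        p_A <- cv + rv * u               # triad center on the sphere
        p_vox <- p_A / vs                # 0-based voxel coords
        for (k in seq_len(phantom$symmetry_order) - 1) {
          pid <- pid + 1L
          psi <- (azimuth + k * 360 / phantom$symmetry_order) %% 360
          eu <- c(e0[1], e0[2], psi)
          R <- euler_to_matrix(eu)
          arr <- render_leaf(arr, phantom, p_vox, R, with_gap = FALSE)
          truth <- rbind(truth, data.frame(
            particle_id = pid, vesicle_id = v,
            triad_id = (v - 1) * scene$triads_per_vesicle + tr,
            x = p_vox[1], y = p_vox[2], z = p_vox[3],
            rot = eu[1], tilt = eu[2], psi = eu[3], class = 0L))
        }
      }
    }
    truth <- gap_assignment(truth, scene$gap_fraction,
                            seed = scene$seed + 104729L)
    # render the GAP blobs for the positive leaves
    if (any(truth$class == 1L) && !is.null(phantom$gap_blob)) {
      for (i in which(truth$class == 1L)) {
        R <- euler_to_matrix(c(truth$rot[i], truth$tilt[i], truth$psi[i]))
        ctr_vox <- c(truth$x[i], truth$y[i], truth$z[i])
        gb <- phantom$gap_blob
        cw <- ctr_vox + as.numeric(R %*% gb$center) / vs
        arr <- add_gaussian_blob(arr, cw, gb$sigma / vs, gb$weight)
      }
    }
    if (scene$noise_sigma > 0)
      arr <- arr + stats::rnorm(length(arr), 0, scene$noise_sigma)
    rownames(truth) <- NULL
    vesicles <- data.frame(vesicle_id = seq_len(scene$n_vesicles),
                           x = centers_A[, 1] / vs, y = centers_A[, 2] / vs,
                           z = centers_A[, 3] / vs,
                           radius_A = scene$vesicle_radii)
    list(map = density_map(arr, vs), truth = truth, vesicles = vesicles)
  })
}

# Lay vesicle centers on a grid, greedily picking cells that maximize the
# minimum pairwise separation; errors if vesicles would overlap.
vesicle_centers <- function(scene, margin) {
  n <- scene$box_size * scene$voxel_size
  nv <- scene$n_vesicles
  if (nv == 1) return(rbind(rep(n / 2, 3)))
  per_side <- max(2, ceiling(nv^(1 / 3)))
  lo <- margin; hi <- n - margin
  if (hi <= lo) stop("vesicles do not fit in the scene box")
  g <- seq(lo, hi, length.out = per_side)
  cells <- as.matrix(expand.grid(x = g, y = g, z = g))
  chosen <- 1L
  while (length(chosen) < nv) {
    rest <- setdiff(seq_len(nrow(cells)), chosen)
    dmin <- sapply(rest, function(i)
      min(sqrt(rowSums((cells[chosen, , drop = FALSE] -
                        matrix(cells[i, ], length(chosen), 3,
                               byrow = TRUE))^2))))
    chosen <- c(chosen, rest[which.max(dmin)])
  }
  ctrs <- cells[chosen, , drop = FALSE]
  dd <- as.matrix(stats::dist(ctrs))
  diag(dd) <- Inf
  if (min(dd) < 1.9 * margin)
    stop("vesicles do not fit without overlap; enlarge the box or shrink radii")
  ctrs
}

add_membrane_shell <- function(arr, center_vox, radius_vox, thick_vox, amp) {
  d <- dim(arr)
  rr <- radius_vox + 3 * thick_vox
  lo <- pmax(1, floor(center_vox + 1 - rr))
  hi <- pmin(d, ceiling(center_vox + 1 + rr))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx2 <- (ix - 1 - center_vox[1])^2
  dy2 <- (iy - 1 - center_vox[2])^2
  dz2 <- (iz - 1 - center_vox[3])^2
  r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  arr[ix, iy, iz] <- arr[ix, iy, iz] + amp * exp(-(r - radius_vox)^2 / (2 * thick_vox^2))
  arr
}

# Render one leaf's blobs (optionally the GAP blob) at center `p_vox` with
# rotation R (leaf frame -> scene frame).
render_leaf <- function(arr, phantom, p_vox, R, with_gap = FALSE) {
  vs <- phantom$voxel_size
  for (b in seq_along(phantom$sigmas)) {
    cw <- p_vox + as.numeric(R %*% phantom$centers[b, ]) / vs
    arr <- add_gaussian_blob(arr, cw, phantom$sigmas[b] / vs,
                             phantom$weights[b])
  }
  if (with_gap && !is.null(phantom$gap_blob)) {
    gb <- phantom$gap_blob
    cw <- p_vox + as.numeric(R %*% gb$center) / vs
    arr <- add_gaussian_blob(arr, cw, gb$sigma / vs, gb$weight)
  }
  arr
}

#' Assign GAP-positive labels to a fraction of leaves
#'
#' Labels exactly `round(N * gap_fraction)` leaves as class 1 (GAP present) by
#' seeded sampling without replacement; all others are class 0.
#'
#' @param truth a ground-truth table with one row per leaf.
#' @param gap_fraction fraction in `[0,1]`.
#' @param seed integer seed.
#' @return the table with its `class` column reassigned.
#' @export
gap_assignment <- function(truth, gap_fraction, seed = 1) {
  stopifnot(gap_fraction >= 0, gap_fraction <= 1)
  n <- nrow(truth)
  npos <- floor(n * gap_fraction + 0.5)
  truth$class <- 0L
  if (npos > 0) {
    idx <- with_seed(seed, sample.int(n, npos))
    truth$class[idx] <- 1L
  }
  truth
}
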