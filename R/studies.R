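#' Simulate a set of leaf subtomograms with known poses
#'
#' Draws uniformly random orientations and small shifts, renders the leaf
#' phantom under each pose, imposes the missing wedge in Fourier space, and
#' adds white noise at the requested signal-to-noise ratio (variance ratio of
#' the wedge-filtered signal to the noise). Initial pose estimates are the
#' truth perturbed by a bounded random rotation, emulating the hand-off from
#' a coarser preliminary alignment stage.
#'
#' @param n number of particles.
#' @param snr signal-to-noise variance ratio (Inf = noise-free).
#' @param phantom a [phantom_spec()].
#' @param wedge a [wedge_spec()].
#' @param seed integer seed.
#' @param gap_fraction fraction of leaves rendered with the GAP blob.
#' @param init_cone_deg,init_psi_deg,init_shift bounds of the initial-pose
#'   perturbation (degrees, degrees, voxels).
#' @param noise_seed separate seed for the noise draws (defaults to a value
#'   derived from `seed`). Two simulations sharing `seed` but differing in
#'   `noise_seed` have identical orientations — hence identical
#'   missing-wedge coverage — and independent noise, which is what maps
#'   destined for difference analysis need.
#' @return list: `subs` (particle maps), `table` (particle table with
#'   perturbed initial poses), `truth` (table of true poses and `class`),
#'   `wedge_array`, `phantom`.
#' @export
simulate_leaf_particles <- function(n, snr = 0.3,
                                    phantom = phantom_spec(),
                                    wedge = wedge_spec(-60, 60), seed = 1,
                                    gap_fraction = 0,
                                    init_cone_deg = 6, init_psi_deg = 5,
                                    init_shift = 1.5,
                                    noise_seed = seed + 424243L) {
  nb <- phantom$box_size
  wm <- wedge_mask(nb, wedge)
  truth <- data.frame(particle_id = seq_len(n),
                      vesicle_id = rep(1:2, length.out = n),
                      x = 0, y = 0, z = 0, rot = 0, tilt = 0, psi = 0,
                      sx = 0, sy = 0, sz = 0, class = 0L)
  truth <- gap_assignment(truth, gap_fraction, seed = seed + 7919L)
  with_seed(seed, {
    subs <- vector("list", n)
    tb <- truth
    for (i in seq_len(n)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))  # uniform axis
      e <- c(stats::runif(1, 0, 360),
             acos(stats::runif(1, -1, 1)) * 180 / pi,
             stats::runif(1, 0, 360))
      sh <- stats::runif(3, -init_shift, init_shift)
      p <- pose(e[1], e[2], e[3], sh)
      truth[i, c("rot", "tilt", "psi")] <- e
      truth[i, c("sx", "sy", "sz")] <- sh
      # render the posed blobs analytically: the forward model is exact,
      # free of any resampling kernel
      ctr <- (nb - 1) / 2 + sh
      arr <- render_leaf(array(0, c(nb, nb, nb)), phantom, ctr,
                         pose_matrix(p), with_gap = truth$class[i] == 1L)
      m <- density_map(arr, phantom$voxel_size)
      fm <- stats::fft(m$data) * wm
      md <- Re(stats::fft(fm, inverse = TRUE)) / length(fm)
      subs[[i]] <- density_map(array(md, dim(m$data)), phantom$voxel_size)
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      Rinit <- pose_matrix(p) %*%
        axis_angle_matrix(ax, stats::runif(1, -init_cone_deg, init_cone_deg)) %*%
        rot_z(stats::runif(1, -init_psi_deg, init_psi_deg))
      ei <- matrix_to_euler(Rinit)
      tb[i, c("rot", "tilt", "psi")] <- ei
      tb[i, c("sx", "sy", "sz")] <- 0
    }
    if (is.finite(snr)) {
      with_seed(noise_seed, {
        for (i in seq_len(n)) {
          md <- subs[[i]]$data
          subs[[i]]$data <- md +
            array(stats::rnorm(length(md), 0, stats::sd(md) / sqrt(snr)),
                  dim(md))
        }
      })
    }
    list(subs = subs, table = particle_table(tb[setdiff(names(tb), "class")]),
         truth = truth, wedge_array = wm, phantom = phantom)
  })
}

# Default hierarchical schedule for the recovery studies: coarse cone pass
# then two fine passes; finest angular step 2.5 degrees.
recovery_schedule <- function() {
  alignment_schedule(cone_deg = c(10, 5, 5), cone_step = c(5, 2.5, 2.5),
                     inplane_range = c(5, 2.5, 2.5),
                     inplane_step = c(5, 2.5, 2.5),
                     shift_limit = 3, lowpass_A = c(20, 16, 16),
                     max_iterations = 3)
}

#' Pose-recovery study on synthetic leaves
#'
#' Simulates `n` wedge-filtered noisy leaf particles, refines their poses
#' against the known leaf reference with a hierarchical angular search, and
#' measures the per-particle angular (geodesic) and translational errors
#' against ground truth.
#'
#' @param n particles per seed.
#' @param snr signal-to-noise variance ratio.
#' @param seed integer seed.
#' @param schedule an [alignment_schedule()]; default: 10/5/5 degree cone
#'   passes with finest step 2.5 degrees.
#' @param phantom a [phantom_spec()].
#' @param wedge a [wedge_spec()].
#' @return list: `median_angular_error_deg`, `median_shift_error_vox`,
#'   `finest_step_deg`, per-particle `angular_error_deg` and
#'   `shift_error_vox`, and the refined `table`.
#' @export
leaf_recovery_study <- function(n = 200, snr = 0.3, seed = 1,
                                schedule = recovery_schedule(),
                                phantom = phantom_spec(),
                                wedge = wedge_spec(-60, 60)) {
  sim <- simulate_leaf_particles(n, snr, phantom, wedge, seed)
  ref <- build_leaf_phantom(phantom)
  res <- iterate_alignment(sim$subs, sim$table, ref, schedule,
                           wedge = sim$wedge_array, sym_order = 1,
                           update_reference = FALSE)
  tb <- res$table
  ang <- shift <- numeric(n)
  for (i in seq_len(n)) {
    Rt <- euler_to_matrix(c(sim$truth$rot[i], sim$truth$tilt[i],
                            sim$truth$psi[i]))
    Rf <- euler_to_matrix(c(tb$rot[i], tb$tilt[i], tb$psi[i]))
    ang[i] <- rotation_distance(Rt, Rf)
    shift[i] <- sqrt(sum((c(sim$truth$sx[i], sim$truth$sy[i], sim$truth$sz[i]) -
                          c(tb$sx[i], tb$sy[i], tb$sz[i]))^2))
  }
  list(median_angular_error_deg = stats::median(ang),
       median_shift_error_vox = stats::median(shift),
       finest_step_deg = min(schedule$cone_step),
       angular_error_deg = ang, shift_error_vox = shift, table = tb)
}

#' Gold-standard half-set FSC study
#'
#' Two fully independent half-sets of synthetic leaves are aligned and
#' averaged; the masked FSC between the two half averages is evaluated for
#' nested particle subsets, showing how resolution improves with particle
#' number. A matched pure-noise pair is evaluated the same way as a null.
#'
#' @param n_per_half particle counts at which to read the resolution
#'   (averages use the first N particles of each half).
#' @param snr signal-to-noise variance ratio of the particles.
#' @param seed integer seed.
#' @param criterion FSC criterion for the resolution readout.
#' @param phantom a [phantom_spec()].
#' @param wedge a [wedge_spec()].
#' @return list: `resolutions_A` (named by N), `noise_fsc_mean` (mean FSC of
#'   the pure-noise pair), `curves` (fsc_curve per N).
#' @export
halfset_fsc_study <- function(n_per_half = c(10, 100), snr = 0.5, seed = 1,
                              criterion = 0.143,
                              phantom = phantom_spec(),
                              wedge = wedge_spec(-60, 60)) {
  nmax <- max(n_per_half)
  nb <- phantom$box_size
  ref <- build_leaf_phantom(phantom)
  sched <- alignment_schedule(cone_deg = 5, cone_step = 2.5,
                              inplane_range = 2.5, inplane_step = 2.5,
                              shift_limit = 2, lowpass_A = 20,
                              max_iterations = 1)
  halves <- lapply(1:2, function(h) {
    sim <- simulate_leaf_particles(nmax, snr, phantom, wedge,
                                   seed = seed + h * 1000L)
    res <- iterate_alignment(sim$subs, sim$table, ref, sched,
                             wedge = sim$wedge_array,
                             update_reference = FALSE)
    list(sim = sim, table = res$table)
  })
  mask <- soft_mask(nb, "sphere", radius = nb / 3, soft_edge_width = 3)
  resolutions <- numeric(length(n_per_half))
  curves <- vector("list", length(n_per_half))
  for (j in seq_along(n_per_half)) {
    nn <- n_per_half[j]
    avgs <- lapply(halves, function(h) {
      poses <- lapply(seq_len(nn), function(i) row_pose(h$table, i))
      average_particles(h$sim$subs[seq_len(nn)], poses, h$sim$wedge_array)
    })
    curves[[j]] <- fsc(avgs[[1]], avgs[[2]], mask)
    resolutions[j] <- as.numeric(resolution_at(curves[[j]], criterion))
  }
  names(resolutions) <- paste0("N", n_per_half)
  noise_fsc <- with_seed(seed + 5000L, {
    mk <- function() {
      vols <- lapply(seq_len(min(20, nmax)), function(i)
        density_map(array(stats::rnorm(nb^3), c(nb, nb, nb)),
                    phantom$voxel_size))
      Reduce(function(a, b) as_map_like(a, a$data + b$data), vols)
    }
    fsc(mk(), mk())
  })
  list(resolutions_A = resolutions, noise_fsc_mean = mean(noise_fsc$fsc),
       curves = curves, noise_curve = noise_fsc)
}

# Seeding references for classification: a "dataset" average (carrying the
# dataset's GAP occupancy) and a GAP-free "control" average. The two samples
# share the same orientations (matched missing-wedge coverage, independent
# noise), the standard precaution when two maps will be differenced —
# mismatched coverage leaves a structured residual that the classifier would
# latch onto.
make_reference_pair <- function(n, gap_fraction, snr, phantom, wedge, seed) {
  gfs <- c(gap_fraction, 0)
  lapply(seq_along(gfs), function(j) {
    s <- simulate_leaf_particles(n, snr, phantom, wedge, seed,
                                 gap_fraction = gfs[j],
                                 init_cone_deg = 0, init_psi_deg = 0,
                                 noise_seed = seed + j * 101L)
    poses <- lapply(seq_len(n), function(i) row_pose(s$truth, i))
    average_particles(s$subs, poses, s$wedge_array)
  })
}

#' GAP-localization classification study
#'
#' The synthetic analogue of localizing a substoichiometric ArfGAP density:
#' a leaf population carries an extra GAP blob on a fraction of particles;
#' two-class multireference classification (seeded by a GAP-dataset average
#' and a control average, three iterations) separates the subpopulations.
#' The class-difference map is segmented and its largest component compared
#' with the planted blob position; a permutation control (labels shuffled)
#' calibrates the noise-component size.
#'
#' @param n_leaves dataset size.
#' @param gap_fraction planted GAP-positive fraction (0 for the null study).
#' @param snr signal-to-noise variance ratio.
#' @param seed integer seed.
#' @param n_iterations classification iterations (default 3).
#' @param n_ref_sample particles per seeding-reference average.
#' @param threshold_sigma segmentation threshold in difference-map sigma
#'   units; class differences between noisy averages are segmented at 3 sigma
#'   (1 sigma, the [segment_extra_densities()] default, percolates on such
#'   maps).
#' @param n_permutations label permutations for the null calibration; the
#'   control statistic is the maximum over permutations, so enough draws are
#'   needed for a stable upper bound (default 20, a ~95% bound).
#' @param phantom a [phantom_spec()].
#' @param wedge a [wedge_spec()].
#' @return list: `accuracy`, `positive_fraction`, `true_fraction`,
#'   `largest_volume`, `largest_centroid`, `expected_centroid`,
#'   `centroid_error_vox`, `perm_max_volume`, `labels`, `truth_class`,
#'   `diff_map`, `segmentation`.
#' @export
gap_classification_study <- function(n_leaves = 60, gap_fraction = 0.65,
                                     snr = 0.5, seed = 1, n_iterations = 3,
                                     n_ref_sample = 24, threshold_sigma = 3,
                                     n_permutations = 20,
                                     phantom = phantom_spec(),
                                     wedge = wedge_spec(-60, 60)) {
  sim <- simulate_leaf_particles(n_leaves, snr, phantom, wedge, seed,
                                 gap_fraction = gap_fraction,
                                 init_cone_deg = 4, init_psi_deg = 4)
  # the "dataset" reference carries the dataset's own GAP occupancy (for the
  # null study both seeding references are GAP-free, as for a non-binding
  # GAP); the pair shares orientations so its wedge coverage is matched
  refs <- make_reference_pair(n_ref_sample, gap_fraction, snr, phantom,
                              wedge, seed + 101L)
  cls <- multireference_classify(sim$subs, sim$table, refs,
                                 n_iterations = n_iterations,
                                 wedge = sim$wedge_array,
                                 cone_deg = 3, cone_step = 3,
                                 inplane_range = 3, inplane_step = 3,
                                 shift_limit = 2)
  labels <- cls$labels                 # 1 = GAP reference
  truth <- sim$truth$class             # 1 = GAP present
  accuracy <- mean((labels == 1L) == (truth == 1L))
  class_avg <- function(lab) {
    idx <- which(labels == lab)
    if (!length(idx)) return(NULL)
    poses <- lapply(idx, function(i) row_pose(cls$table, i))
    average_particles(sim$subs[idx], poses, sim$wedge_array)
  }
  d1 <- class_avg(1L); d2 <- class_avg(2L)
  if (is.null(d1) || is.null(d2)) {
    nb0 <- phantom$box_size
    diffm <- density_map(array(0, c(nb0, nb0, nb0)), phantom$voxel_size)
  } else {
    diffm <- as_map_like(d1, d1$data - d2$data)
  }
  seg <- segment_extra_densities(diffm, threshold_sigma = threshold_sigma)
  nb <- phantom$box_size
  expected <- (nb - 1) / 2 + phantom$gap_blob$center / phantom$voxel_size
  largest_vol <- if (nrow(seg$components)) seg$components$volume[1] else 0
  largest_cen <- if (nrow(seg$components))
    unlist(seg$components[1, c("x", "y", "z")]) else rep(NA_real_, 3)
  perm_max <- with_seed(seed + 4242L, {
    vols <- numeric(n_permutations)
    for (p in seq_len(n_permutations)) {
      pl <- sample(labels)
      idx1 <- which(pl == 1L); idx2 <- which(pl == 2L)
      if (!length(idx1) || !length(idx2)) { vols[p] <- 0; next }
      a1 <- average_particles(sim$subs[idx1],
                              lapply(idx1, function(i) row_pose(cls$table, i)),
                              sim$wedge_array)
      a2 <- average_particles(sim$subs[idx2],
                              lapply(idx2, function(i) row_pose(cls$table, i)),
                              sim$wedge_array)
      pd <- as_map_like(a1, a1$data - a2$data)
      ps <- segment_extra_densities(pd, threshold_sigma = threshold_sigma)
      vols[p] <- if (nrow(ps$components)) ps$components$volume[1] else 0
    }
    max(vols)
  })
  list(accuracy = accuracy,
       positive_fraction = mean(labels == 1L),
       true_fraction = mean(truth == 1L),
       largest_volume = largest_vol,
       largest_centroid = largest_cen,
       expected_centroid = expected,
       centroid_error_vox = sqrt(sum((largest_cen - expected)^2)),
       perm_max_volume = perm_max,
       labels = labels, truth_class = truth,
       diff_map = diffm, segmentation = seg)
}
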