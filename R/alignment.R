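#' Fourier band-pass mask
#'
#' Binary spherical band-pass over the unshifted FFT grid.
#'
#' @param n box side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param lowpass_A keep frequencies below `1/lowpass_A` (NULL = no cut).
#' @param highpass_A remove frequencies below `1/highpass_A` (NULL = none).
#' @return 3D 0/1 array.
#' @export
bandpass_mask <- function(n, voxel_size, lowpass_A = NULL, highpass_A = NULL) {
  k <- freq_grid(n, voxel_size)$kmag
  m <- array(1, c(n, n, n))
  if (!is.null(lowpass_A)) m[k > 1 / lowpass_A] <- 0
  if (!is.null(highpass_A)) m[k < 1 / highpass_A] <- 0
  m
}

# Resolve a wedge argument (weight array, wedge_spec, or NULL) to an array.
wedge_weight <- function(w, n) {
  if (is.null(w)) return(array(1, c(n, n, n)))
  if (inherits(w, "wedge_spec")) return(wedge_mask(n, w))
  stopifnot(all(dim(w) == c(n, n, n)))
  w
}

fftshift3 <- function(x) {
  n <- dim(x)
  idx <- lapply(n, function(m) c((floor(m / 2) + 1):m, 1:floor(m / 2)))
  x[idx[[1]], idx[[2]], idx[[3]]]
}

ifftshift3 <- function(x) {
  n <- dim(x)
  idx <- lapply(n, function(m) c((ceiling(m / 2) + 1):m, 1:ceiling(m / 2)))
  x[idx[[1]], idx[[2]], idx[[3]]]
}

#' Missing-wedge constrained cross-correlation
#'
#' Normalized correlation computed only over the Fourier components inside
#' the intersection of the two wedges and the band-pass. Equivalent to the
#' real-space normalized dot product of the two wedge- and band-filtered
#' volumes. The DC component is excluded, so the score is invariant to
#' additive offsets and positive rescaling.
#'
#' @param a,b `density_map`s of equal (cubic) shape.
#' @param wedge_a,wedge_b wedge weights: arrays, [wedge_spec()]s or NULL.
#' @param bandpass 3D weight array (e.g. from [bandpass_mask()]) or NULL.
#' @return correlation in `[-1, 1]`.
#' @export
constrained_cc <- function(a, b, wedge_a = NULL, wedge_b = NULL,
                           bandpass = NULL) {
  stopifnot(all(dim(a$data) == dim(b$data)))
  n <- dim(a$data)[1]
  w <- wedge_weight(wedge_a, n) * wedge_weight(wedge_b, n)
  if (!is.null(bandpass)) w <- w * bandpass
  w[1, 1, 1] <- 0
  if (sum(w) == 0) stop("empty wedge/band-pass intersection")
  fa <- stats::fft(a$data) * w
  fb <- stats::fft(b$data) * w
  na <- sqrt(sum(Mod(fa)^2)); nb <- sqrt(sum(Mod(fb)^2))
  if (na == 0 || nb == 0) stop("map has no power inside the constrained region")
  Re(sum(fa * Conj(fb))) / (na * nb)
}

#' Rotation search grid
#'
#' Offsets for a hierarchical angular search: cone offsets of the symmetry
#' axis up to `cone_deg` in steps of `cone_step`, crossed with in-plane
#' offsets spanning `+/- inplane_range` in steps of `inplane_step`. An
#' `inplane_range >= 180` scans the full circle.
#'
#' @param cone_deg,cone_step cone aperture and step (degrees).
#' @param inplane_range,inplane_step in-plane scan half-range and step.
#' @return list of 3x3 offset rotation matrices (identity included first).
#' @export
angular_grid <- function(cone_deg, cone_step, inplane_range, inplane_step) {
  stopifnot(inplane_step > 0)
  if (inplane_range >= 180) {
    psis <- seq(0, 360 - inplane_step, by = inplane_step)
  } else {
    psis <- seq(-inplane_range, inplane_range, by = inplane_step)
  }
  dirs <- list(c(0, 0))
  if (cone_deg > 0 && cone_step > 0) {
    for (theta in seq(cone_step, cone_deg, by = cone_step)) {
      nphi <- max(1, round(360 * sin(theta * pi / 180) / cone_step))
      for (phi in seq(0, 360 - 360 / nphi, by = 360 / nphi))
        dirs[[length(dirs) + 1]] <- c(phi, theta)
    }
  }
  grid <- list()
  for (d in dirs) {
    # tilt the axis by theta toward azimuth phi without net in-plane twist
    base <- euler_to_matrix(c(d[1], d[2], -d[1]))
    for (p in psis) grid[[length(grid) + 1]] <- base %*% rot_z(p)
  }
  grid
}

fft_shift_coords <- function(n) {
  i <- 0:(n - 1)
  i[i >= ceiling(n / 2)] <- i[i >= ceiling(n / 2)] - n
  i
}

# Parabolic sub-voxel refinement along one axis; returns offset in (-0.5, 0.5).
parabolic_offset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (abs(den) < 1e-12) return(0)
  off <- 0.5 * (ym - yp) / den
  max(-0.5, min(0.5, off))
}

#' Align one subtomogram to a reference
#'
#' Scans the rotation grid `init_pose x offsets`; for each rotation the best
#' translation is found at the constrained cross-correlation peak (FFT-based,
#' limited to `shift_limit` voxels, parabolic sub-voxel refinement).
#'
#' @param sub particle `density_map`.
#' @param ref reference `density_map` (same box).
#' @param wedge the particle's wedge (array or [wedge_spec()]).
#' @param cone_deg,cone_step,inplane_range,inplane_step search grid, degrees.
#' @param shift_limit maximum |shift| per axis (voxels).
#' @param lowpass_A optional low-pass (Angstrom) applied inside the scoring.
#' @param init_pose current pose estimate (its rotation seeds the grid).
#' @param mask optional real-space mask multiplied onto the reference.
#' @return list with `pose` (rotation + shift) and `cc`.
#' @export
align_particle <- function(sub, ref, wedge = NULL, cone_deg = 0, cone_step = 1,
                           inplane_range = 180, inplane_step = 30,
                           shift_limit = 4, lowpass_A = NULL,
                           init_pose = pose(), mask = NULL) {
  n <- dim(sub$data)[1]
  stopifnot(all(dim(ref$data) == dim(sub$data)))
  w <- wedge_weight(wedge, n)
  if (!is.null(lowpass_A))
    w <- w * bandpass_mask(n, sub$voxel_size, lowpass_A)
  w[1, 1, 1] <- 0
  fsub <- stats::fft(sub$data) * w
  nsub <- sqrt(sum(Mod(fsub)^2))
  if (nsub == 0) stop("particle has no power inside the constrained region")
  refd <- if (is.null(mask)) ref else as_map_like(ref, ref$data * mask)
  tvals <- fft_shift_coords(n)
  allowed <- abs(tvals) <= shift_limit
  grid <- angular_grid(cone_deg, cone_step, inplane_range, inplane_step)
  R0 <- pose_matrix(init_pose)
  best <- list(cc = -Inf)
  for (Roff in grid) {
    Rc <- R0 %*% Roff
    rot <- rotate_map(refd, Rc)
    frot <- stats::fft(rot$data) * w
    nrot <- sqrt(sum(Mod(frot)^2))
    if (nrot == 0) next
    ccvol <- Re(stats::fft(fsub * Conj(frot), inverse = TRUE)) / (nsub * nrot)
    ccvol[!allowed, , ] <- -Inf
    ccvol[, !allowed, ] <- -Inf
    ccvol[, , !allowed] <- -Inf
    pk <- which.max(ccvol)
    if (ccvol[pk] > best$cc) {
      ijk <- arrayInd(pk, dim(ccvol))
      best <- list(cc = ccvol[pk], R = Rc, idx = ijk, ccvol = ccvol)
    }
  }
  # sub-voxel peak refinement with periodic neighbor indexing
  ijk <- best$idx
  shift <- numeric(3)
  for (ax in 1:3) {
    i <- ijk[ax]
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    pick <- function(j) { v <- ijk; v[ax] <- j; best$ccvol[v[1], v[2], v[3]] }
    ym <- pick(im); yp <- pick(ip)
    off <- if (is.finite(ym) && is.finite(yp))
      parabolic_offset(ym, best$ccvol[ijk[1], ijk[2], ijk[3]], yp) else 0
    shift[ax] <- tvals[i] + off
  }
  e <- matrix_to_euler(best$R)
  list(pose = pose(e[1], e[2], e[3], shift), cc = best$cc)
}

# Rotate a Fourier-space weight volume (unshifted layout) by rotation R.
rotate_fourier_weight <- function(w, R) {
  s <- fftshift3(w)
  d <- dim(s)
  ctr <- (d - 1) / 2
  A <- t(R)
  b <- ctr - as.numeric(A %*% ctr)
  out <- array(c_affine_sample(as.numeric(s), as.integer(d), A, b), d)
  ifftshift3(out)
}

#' Wedge-compensated particle averaging
#'
#' Transforms each particle back into the reference frame with the inverse of
#' its pose, accumulates Fourier components weighted by each particle's
#' rotated wedge, and divides by the summed wedge coverage (floored to avoid
#' noise amplification where coverage is sparse). Frequencies with
#' essentially zero coverage are set to 0.
#'
#' @param subs list of particle `density_map`s.
#' @param poses list of `pose`s (reference -> particle).
#' @param wedges list of wedge weights (arrays or [wedge_spec()]s), or a
#'   single wedge shared by all particles.
#' @param floor_frac coverage floor as a fraction of the particle count.
#' @return the average `density_map`.
#' @export
average_particles <- function(subs, poses, wedges = NULL, floor_frac = 0.1) {
  stopifnot(length(subs) >= 1, length(subs) == length(poses))
  n <- dim(subs[[1]]$data)[1]
  if (!is.list(wedges) || inherits(wedges, "wedge_spec"))
    wedges <- rep(list(wedges), length(subs))
  num <- array(0 + 0i, c(n, n, n))
  den <- array(0, c(n, n, n))
  for (i in seq_along(subs)) {
    back <- apply_pose_inverse(subs[[i]], poses[[i]])
    w <- wedge_weight(wedges[[i]], n)
    Rinv <- t(pose_matrix(poses[[i]]))
    wrot <- rotate_fourier_weight(w, Rinv)
    num <- num + stats::fft(back$data) * wrot
    den <- den + wrot
  }
  nfloor <- floor_frac * length(subs)
  favg <- num / pmax(den, nfloor)
  favg[den < 1e-6] <- 0
  as_map_like(subs[[1]], Re(stats::fft(favg, inverse = TRUE)) / length(favg))
}

#' Apply Cn symmetry to a map
#'
#' Mean of the n copies rotated by multiples of 360/n degrees about the axis.
#'
#' @param map a `density_map`.
#' @param order symmetry order n (1 = identity).
#' @param axis symmetry axis (default z).
#' @param interp_order interpolation order for the rotations (1 or 3).
#' @return symmetrized `density_map`.
#' @export
apply_symmetry <- function(map, order, axis = c(0, 0, 1), interp_order = 1L) {
  stopifnot(order >= 1)
  if (order == 1) return(map)
  acc <- map$data
  for (k in seq_len(order - 1))
    acc <- acc + rotate_map(map, axis_angle_matrix(axis, k * 360 / order),
                            order = interp_order)$data
  as_map_like(map, acc / order)
}

#' Expand triad particles to their asymmetric units (leaves)
#'
#' Each Cn-symmetric particle becomes n leaf records whose poses are composed
#' with the k*(360/n) degree symmetry rotations about the reference symmetry
#' axis, so each leaf can subsequently be refined independently.
#'
#' @param table triad-level particle table.
#' @param order symmetry order n.
#' @return leaf-level particle table with n x nrow rows; `leaf_index` records
#'   the symmetry copy and `parent_id` the originating triad particle.
#' @export
expand_to_asymmetric_units <- function(table, order) {
  stopifnot(order >= 1)
  out <- NULL
  for (k in seq_len(order) - 1) {
    blk <- table
    for (i in seq_len(nrow(table))) {
      p <- pose_compose(row_pose(table, i), pose(psi = k * 360 / order))
      blk <- set_row_pose(blk, i, p)
    }
    blk$parent_id <- table$particle_id
    blk$leaf_index <- k + 1L
    out <- rbind(out, blk)
  }
  out$particle_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# One batch alignment pass: equivalent to calling align_particle() on every
# particle with the same offset grid, but the rotated-reference FFTs are
# computed once and shared. Each particle is first resampled into its current
# reference frame (inverse of its pose rotation), so candidate rotations are
# pure offsets; the particle's wedge is rotated along with it.
batch_align_iteration <- function(subs, table, ref, offsets, wedge,
                                  shift_limit, bandpass = NULL) {
  n <- dim(ref$data)[1]
  frots <- lapply(offsets, function(Roff)
    stats::fft(rotate_map(ref, Roff, order = 3L)$data))
  tvals <- fft_shift_coords(n)
  allowed <- abs(tvals) <= shift_limit
  out_pose <- vector("list", nrow(table))
  out_cc <- numeric(nrow(table))
  for (i in seq_len(nrow(table))) {
    R0 <- euler_to_matrix(c(table$rot[i], table$tilt[i], table$psi[i]))
    subrot <- apply_pose_inverse(subs[[i]],
                                 pose(table$rot[i], table$tilt[i], table$psi[i]),
                                 order = 3L)
    w <- wedge_weight(if (is.list(wedge) && !inherits(wedge, "wedge_spec"))
      wedge[[i]] else wedge, n)
    wi <- rotate_fourier_weight(w, t(R0))
    if (!is.null(bandpass)) wi <- wi * bandpass
    wi[1, 1, 1] <- 0
    w2 <- wi * wi
    fsub <- stats::fft(subrot$data)
    nsub <- sqrt(sum(Mod(fsub)^2 * w2))
    if (nsub == 0) stop("particle ", i, " has no power inside the wedge")
    fsubw2 <- fsub * w2
    best <- list(cc = -Inf)
    for (o in seq_along(offsets)) {
      frot <- frots[[o]]
      nrot <- sqrt(sum(Mod(frot)^2 * w2))
      if (nrot == 0) next
      ccvol <- Re(stats::fft(fsubw2 * Conj(frot), inverse = TRUE)) /
        (nsub * nrot)
      ccvol[!allowed, , ] <- -Inf
      ccvol[, !allowed, ] <- -Inf
      ccvol[, , !allowed] <- -Inf
      pk <- which.max(ccvol)
      if (ccvol[pk] > best$cc)
        best <- list(cc = ccvol[pk], o = o, idx = arrayInd(pk, dim(ccvol)),
                     ccvol = ccvol)
    }
    ijk <- best$idx
    shift <- numeric(3)
    for (ax in 1:3) {
      ii <- ijk[ax]
      im <- if (ii == 1) n else ii - 1
      ip <- if (ii == n) 1 else ii + 1
      pick <- function(j) { v <- ijk; v[ax] <- j; best$ccvol[v[1], v[2], v[3]] }
      ym <- pick(im); yp <- pick(ip)
      off <- if (is.finite(ym) && is.finite(yp))
        parabolic_offset(ym, best$ccvol[ijk[1], ijk[2], ijk[3]], yp) else 0
      shift[ax] <- tvals[ii] + off
    }
    R <- R0 %*% offsets[[best$o]]
    e <- matrix_to_euler(R)
    out_pose[[i]] <- pose(e[1], e[2], e[3], as.numeric(R0 %*% shift))
    out_cc[i] <- best$cc
  }
  list(poses = out_pose, cc = out_cc)
}

#' Alignment schedule
#'
#' Per-iteration search parameters. If `max_iterations` exceeds the number of
#' rows the last row is repeated. Convergence: median angular change below
#' half the current angular step AND median shift change below 0.5 voxel.
#'
#' @param cone_deg,cone_step cone search per iteration (degrees).
#' @param inplane_range,inplane_step in-plane search per iteration (degrees).
#' @param shift_limit translation bound (voxels).
#' @param lowpass_A reference low-pass per iteration (Angstrom).
#' @param max_iterations iteration cap.
#' @return an `alignment_schedule` (data.frame plus attributes).
#' @export
alignment_schedule <- function(cone_deg = c(20, 10, 5),
                               cone_step = c(10, 5, 2.5),
                               inplane_range = c(180, 15, 7.5),
                               inplane_step = c(30, 5, 2.5),
                               shift_limit = 4,
                               lowpass_A = 35,
                               max_iterations = 10) {
  df <- data.frame(cone_deg = cone_deg, cone_step = cone_step,
                   inplane_range = inplane_range, inplane_step = inplane_step,
                   shift_limit = shift_limit, lowpass_A = lowpass_A)
  stopifnot(all(df$cone_step > 0), all(df$lowpass_A > 0))
  attr(df, "max_iterations") <- max_iterations
  class(df) <- c("alignment_schedule", class(df))
  df
}

schedule_row <- function(schedule, it) {
  schedule[min(it, nrow(schedule)), , drop = FALSE]
}

#' Iterative alignment and averaging
#'
#' One half-set's refinement loop: at each iteration the reference is
#' low-pass filtered per the schedule, every particle is aligned to it, a new
#' wedge-compensated average is formed and Cn symmetry is applied. Stops at
#' convergence (median pose change small) or `max_iterations`; if the mean
#' cross-correlation decreases three iterations running, a warning is issued
#' and the best iteration is returned.
#'
#' @param subs list of particle `density_map`s.
#' @param table particle table holding initial poses (row i matches
#'   `subs[[i]]`).
#' @param initial_ref starting reference `density_map`.
#' @param schedule an [alignment_schedule()].
#' @param wedge shared wedge (array or [wedge_spec()]) or list per particle.
#' @param sym_order Cn symmetry applied to each new reference.
#' @param mask optional real-space mask on the reference during alignment.
#' @param update_reference if FALSE the initial reference is kept throughout
#'   (pure pose refinement against an external reference); if TRUE (default)
#'   a new wedge-compensated average replaces the reference each iteration.
#' @return list: `table` (poses and `cc` updated), `reference` (final
#'   `density_map`), `history` (per-iteration data.frame: iteration, mean_cc,
#'   median_dang, median_dshift), `references` (list of per-iteration maps).
#' @export
iterate_alignment <- function(subs, table, initial_ref, schedule,
                              wedge = NULL, sym_order = 1, mask = NULL,
                              update_reference = TRUE) {
  stopifnot(length(subs) == nrow(table))
  ref <- initial_ref
  history <- NULL
  refs <- list()
  best <- list(cc = -Inf)
  decreasing <- 0
  prev_cc <- -Inf
  maxit <- attr(schedule, "max_iterations")
  if (is.null(maxit)) maxit <- nrow(schedule)
  for (it in seq_len(maxit)) {
    srow <- schedule_row(schedule, it)
    ref_lp <- lowpass_map(ref, srow$lowpass_A)
    if (!is.null(mask)) ref_lp <- as_map_like(ref_lp, ref_lp$data * mask)
    offsets <- angular_grid(srow$cone_deg, srow$cone_step,
                            srow$inplane_range, srow$inplane_step)
    bp <- bandpass_mask(dim(ref$data)[1], ref$voxel_size, srow$lowpass_A)
    res <- batch_align_iteration(subs, table, ref_lp, offsets, wedge,
                                 srow$shift_limit, bandpass = bp)
    dang <- dshift <- numeric(nrow(table))
    poses <- res$poses
    cc <- res$cc
    for (i in seq_len(nrow(table))) {
      p0 <- row_pose(table, i)
      dang[i] <- rotation_distance(pose_matrix(p0), pose_matrix(poses[[i]]))
      dshift[i] <- sqrt(sum((p0$shift - poses[[i]]$shift)^2))
      table <- set_row_pose(table, i, poses[[i]])
    }
    table$cc <- cc
    if (update_reference) {
      ref <- average_particles(subs, poses, wedge)
      if (sym_order > 1) ref <- apply_symmetry(ref, sym_order)
    }
    refs[[it]] <- ref
    history <- rbind(history, data.frame(
      iteration = it, mean_cc = mean(cc),
      median_dang = stats::median(dang),
      median_dshift = stats::median(dshift)))
    if (mean(cc) > best$cc)
      best <- list(cc = mean(cc), table = table, ref = ref, it = it)
    decreasing <- if (mean(cc) < prev_cc) decreasing + 1 else 0
    prev_cc <- mean(cc)
    if (decreasing >= 3) {
      warning("mean cross-correlation decreased for 3 iterations; returning best iteration ", best$it)
      return(list(table = best$table, reference = best$ref,
                  history = history, references = refs))
    }
    if (stats::median(dang) < srow$cone_step / 2 &&
        stats::median(dshift) < 0.5) break
  }
  list(table = table, reference = ref, history = history, references = refs)
}

#' Remove misaligned particles by cross-correlation threshold
#'
#' @param table particle table with `cc` scores.
#' @param threshold absolute cutoff; used when `rule = "absolute"`.
#' @param rule "absolute" (keep `cc >= threshold`) or "mean_sd" (keep
#'   `cc >= mean(cc) - k * sd(cc)`).
#' @param k multiplier for the "mean_sd" rule.
#' @return the cleaned particle table.
#' @export
clean_by_cc <- function(table, threshold = NULL, rule = c("mean_sd", "absolute"),
                        k = 2) {
  rule <- match.arg(rule)
  stopifnot(!is.null(table$cc))
  thr <- switch(rule,
                absolute = { stopifnot(!is.null(threshold)); threshold },
                mean_sd = mean(table$cc) - k * stats::sd(table$cc))
  out <- table[table$cc >= thr, , drop = FALSE]
  if (nrow(out) == 0)
    stop(sprintf("cc threshold %.3f removed every particle; review the threshold", thr))
  rownames(out) <- NULL
  out
}

#' Distance-based duplicate removal
#'
#' Greedy: particles are visited in decreasing cc order; one is kept iff no
#' already-kept particle lies strictly closer than `min_distance` (positions
#' include the pose shifts). Never increases the count; idempotent.
#'
#' @param table particle table.
#' @param min_distance exclusion radius in voxels.
#' @return deduplicated particle table (original row order preserved).
#' @export
remove_duplicates <- function(table, min_distance) {
  if (nrow(table) <= 1) return(table)
  pos <- cbind(table$x + table$sx, table$y + table$sy, table$z + table$sz)
  cc <- if (is.null(table$cc)) rep(0, nrow(table)) else table$cc
  ord <- order(-cc, seq_len(nrow(table)))
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0) { kept <- i; next }
    d2 <- colSums((t(pos[kept, , drop = FALSE]) - pos[i, ])^2)
    if (all(d2 >= min_distance^2)) kept <- c(kept, i)
  }
  out <- table[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}
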