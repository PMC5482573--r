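test_that("constrained cc: self-correlation, negation, rescaling and symmetry", {
  a <- rand_map(8, seed = 31)
  wa <- wedge_mask(8, wedge_spec(-60, 60))
  expect_equal(constrained_cc(a, a, wa, wa), 1, tolerance = 1e-6)
  neg <- density_map(-a$data, a$voxel_size)
  expect_equal(constrained_cc(a, neg, wa, wa), -1, tolerance = 1e-6)
  b <- rand_map(8, seed = 32)
  cc <- constrained_cc(a, b, wa, wa)
  expect_equal(constrained_cc(b, a, wa, wa), cc, tolerance = 1e-12)
  scaled <- density_map(3.7 * b$data + 2, b$voxel_size)   # DC is excluded
  expect_equal(constrained_cc(a, scaled, wa, wa), cc, tolerance = 1e-9)
  expect_error(constrained_cc(a, b, bandpass = array(0, c(8, 8, 8))), "empty")
})

test_that("constrained cc equals the real-space oracle on random pairs", {
  set.seed(33)
  for (trial in 1:5) {
    a <- density_map(array(rnorm(512), c(8, 8, 8)), 2)
    b <- density_map(array(rnorm(512), c(8, 8, 8)), 2)
    wa <- wedge_mask(8, wedge_spec(-60, 60))
    wb <- wedge_mask(8, wedge_spec(-50, 70))
    bp <- bandpass_mask(8, 2, lowpass_A = 6)
    W <- wa * wb * bp; W[1, 1, 1] <- 0
    expect_equal(constrained_cc(a, b, wa, wb, bp), cc_oracle(a, b, W),
                 tolerance = 1e-6)
  }
})

test_that("alignment recovers on-grid rotations exactly and integer shifts to sub-voxel", {
  ref <- build_leaf_phantom(tiny_phantom(box = 24, voxel = 4))
  part <- apply_pose(ref, pose(0, 0, 60))
  res <- align_particle(part, ref, cone_deg = 0, inplane_range = 180,
                        inplane_step = 30, shift_limit = 3)
  expect_equal(tomocoat:::rotation_distance(euler_to_matrix(c(0, 0, 60)),
                                            euler_to_matrix(res$pose$euler)),
               0, tolerance = 1e-6)
  expect_gt(res$cc, 0.99)
  part2 <- apply_pose(ref, pose(0, 0, 0, c(2, -1, 3)))
  res2 <- align_particle(part2, ref, cone_deg = 0, inplane_range = 0,
                         inplane_step = 30, shift_limit = 4)
  expect_equal(res2$pose$shift, c(2, -1, 3), tolerance = 0.02)
})

test_that("alignment agrees with an exhaustive brute-force search over the same grid", {
  set.seed(34)
  ph <- tiny_phantom(box = 16, voxel = 4)
  ref <- build_leaf_phantom(ph)
  wspec <- wedge_spec(-60, 60)
  wm <- wedge_mask(16, wspec)
  true_pose <- pose(0, 0, 40, c(1, 0, -1))
  m <- apply_pose(ref, true_pose)
  filt <- Re(fft(fft(m$data) * wm, inverse = TRUE)) / length(wm)
  noisy <- density_map(filt + rnorm(length(filt), 0, sd(filt) / sqrt(0.5)), 4)
  psis <- seq(0, 80, by = 20)
  res <- align_particle(noisy, ref, wedge = wm, cone_deg = 0,
                        inplane_range = 0, inplane_step = 1, shift_limit = 2,
                        init_pose = pose(0, 0, 0))
  # run the scan psi-by-psi through the same public interface
  best <- list(cc = -Inf)
  for (p in psis) {
    r <- align_particle(noisy, ref, wedge = wm, cone_deg = 0,
                        inplane_range = 0, inplane_step = 1, shift_limit = 2,
                        init_pose = pose(0, 0, p))
    if (r$cc > best$cc) best <- list(cc = r$cc, pose = r$pose)
  }
  full <- align_particle(noisy, ref, wedge = wm, cone_deg = 0,
                         inplane_range = 180, inplane_step = 20,
                         shift_limit = 2, init_pose = pose(0, 0, 0))
  # brute-force oracle: real-space constructed candidates scored independently
  oracle <- list(cc = -Inf)
  shifts <- expand.grid(sx = -2:2, sy = -2:2, sz = -2:2)
  for (p in seq(0, 340, by = 20)) {
    for (s in seq_len(nrow(shifts))) {
      cand <- apply_pose(ref, pose(0, 0, p, as.numeric(shifts[s, ])))
      cc <- constrained_cc(noisy, cand, wedge_a = wm)
      if (cc > oracle$cc) oracle <- list(cc = cc, psi = p,
                                         shift = as.numeric(shifts[s, ]))
    }
  }
  expect_lt(tomocoat:::rotation_distance(euler_to_matrix(full$pose$euler),
                                         euler_to_matrix(c(0, 0, oracle$psi))),
            1e-6)
  expect_equal(round(full$pose$shift), oracle$shift, tolerance = 1e-9)
})

test_that("wedge-compensated averaging: identity case and noise suppression", {
  ph <- tiny_phantom(box = 16, voxel = 4)
  ref <- build_leaf_phantom(ph)
  wm <- wedge_mask(16, wedge_spec(-60, 60))
  filt <- density_map(Re(fft(fft(ref$data) * wm, inverse = TRUE)) / length(wm), 4)
  avg1 <- average_particles(list(filt), list(pose()), list(wm))
  expect_gt(cor(as.numeric(avg1$data), as.numeric(filt$data)), 0.999)
  # complementary wedges: union coverage, per-frequency weight <= 2
  w1 <- wedge_mask(16, wedge_spec(-60, 60))
  w2 <- tomocoat:::rotate_fourier_weight(w1, axis_angle_matrix(c(0, 1, 0), 90))
  den <- w1 + w2
  expect_true(all(den <= 2 + 1e-9))
  expect_gt(mean(den > 0.5), mean(w1 > 0.5))
  # averaging noisy copies beats any single particle
  set.seed(35)
  poses <- lapply(1:20, function(i) pose(runif(1, 0, 360),
                                         acos(runif(1, -1, 1)) * 180 / pi,
                                         runif(1, 0, 360)))
  subs <- lapply(poses, function(p) {
    m <- apply_pose(ref, p)
    f <- Re(fft(fft(m$data) * wm, inverse = TRUE)) / length(wm)
    density_map(f + rnorm(length(f), 0, sd(f)), 4)
  })
  avg <- average_particles(subs, poses, wm)
  cc_avg <- cor(as.numeric(avg$data), as.numeric(ref$data))
  cc_single <- sapply(seq_along(subs), function(i)
    cor(as.numeric(apply_pose_inverse(subs[[i]], poses[[i]])$data),
        as.numeric(ref$data)))
  expect_gt(cc_avg, max(cc_single))
})

test_that("Cn symmetrization: C1 identity, rotational invariance, mean preservation", {
  m <- build_leaf_phantom(tiny_phantom(box = 24, voxel = 4))
  expect_identical(apply_symmetry(m, 1)$data, m$data)
  sm <- lowpass_map(m, 8 * m$voxel_size)   # band-limit well below Nyquist
  s3 <- apply_symmetry(sm, 3, interp_order = 3L)
  rot <- rotate_map(s3, axis_angle_matrix(c(0, 0, 1), 120), order = 3L)
  core <- 5:20    # rotation clips corners; compare the interior
  rel <- max(abs(s3$data[core, core, core] - rot$data[core, core, core])) /
    max(abs(s3$data))
  expect_lt(rel, 1e-2)
  # integral preservation, checked on the compact-support map
  s3c <- apply_symmetry(m, 3, interp_order = 3L)
  expect_equal(mean(s3c$data), mean(m$data),
               tolerance = 1e-4 * mean(m$data) / mean(m$data))
})

test_that("asymmetric-unit expansion composes the symmetry rotations", {
  tb <- particle_table(data.frame(particle_id = 1:10, vesicle_id = 1,
                                  x = runif(10), y = runif(10), z = runif(10),
                                  rot = runif(10, 0, 360),
                                  tilt = runif(10, 0, 180),
                                  psi = runif(10, 0, 360)))
  leaves <- expand_to_asymmetric_units(tb, 3)
  expect_equal(nrow(leaves), 30)
  for (pid in 1:3) {
    rows <- leaves[leaves$parent_id == pid, ]
    R1 <- euler_to_matrix(c(rows$rot[1], rows$tilt[1], rows$psi[1]))
    axis <- R1 %*% c(0, 0, 1)
    for (k in 2:3) {
      Rk <- euler_to_matrix(c(rows$rot[k], rows$tilt[k], rows$psi[k]))
      ang <- tomocoat:::rotation_distance(Rk, axis_angle_matrix(axis, (k - 1) * 120) %*% R1)
      expect_lt(ang, 1e-5)
    }
  }
})

test_that("cc cleaning implements both threshold rules", {
  tb <- particle_table(data.frame(particle_id = 1:3, vesicle_id = 1,
                                  x = 0, y = 0, z = 0))
  tb$cc <- c(0.9, 0.5, 0.1)
  kept <- clean_by_cc(tb, threshold = 0.4, rule = "absolute")
  expect_setequal(kept$cc, c(0.9, 0.5))
  expect_equal(nrow(clean_by_cc(tb, threshold = 0, rule = "absolute")), 3)
  expect_error(clean_by_cc(tb, threshold = 0.95, rule = "absolute"), "threshold")
  set.seed(36)
  big <- particle_table(data.frame(particle_id = 1:4000, vesicle_id = 1,
                                   x = 0, y = 0, z = 0))
  big$cc <- pmin(1, pmax(-1, rnorm(4000, 0.5, 0.1)))
  frac <- 1 - nrow(clean_by_cc(big, rule = "mean_sd", k = 1)) / 4000
  expect_equal(frac, 0.16, tolerance = 0.02)
})

test_that("duplicate removal matches the greedy oracle and is idempotent", {
  tb <- particle_table(data.frame(particle_id = 1:2, vesicle_id = 1,
                                  x = c(0, 5), y = 0, z = 0))
  tb$cc <- c(0.9, 0.8)
  out <- remove_duplicates(tb, 10)
  expect_equal(out$cc, 0.9)
  # exactly at the threshold: both kept (strict inequality)
  tb$x <- c(0, 10)
  expect_equal(nrow(remove_duplicates(tb, 10)), 2)
  set.seed(37)
  for (trial in 1:5) {
    n <- 40
    big <- particle_table(data.frame(particle_id = 1:n, vesicle_id = 1,
                                     x = runif(n, 0, 30), y = runif(n, 0, 30),
                                     z = runif(n, 0, 30)))
    big$cc <- runif(n)
    got <- remove_duplicates(big, 6)
    expect_identical(got$particle_id, dedup_oracle(big, 6)$particle_id)
    expect_lte(nrow(got), n)
    expect_identical(remove_duplicates(got, 6)$particle_id, got$particle_id)
  }
})

test_that("iterative alignment converges from sub-grid perturbations on clean data", {
  set.seed(38)
  sim <- simulate_leaf_particles(12, snr = Inf, phantom = phantom_spec(),
                                 seed = 39, init_cone_deg = 4, init_psi_deg = 4)
  ref <- build_leaf_phantom(phantom_spec())
  sched <- alignment_schedule(cone_deg = 5, cone_step = 2.5,
                              inplane_range = 5, inplane_step = 2.5,
                              shift_limit = 3, lowpass_A = 16,
                              max_iterations = 3)
  res <- iterate_alignment(sim$subs, sim$table, ref, sched,
                           wedge = sim$wedge_array, update_reference = FALSE)
  expect_lte(nrow(res$history), 3)
  ang <- sapply(seq_len(12), function(i)
    tomocoat:::rotation_distance(
      euler_to_matrix(c(sim$truth$rot[i], sim$truth$tilt[i], sim$truth$psi[i])),
      euler_to_matrix(c(res$table$rot[i], res$table$tilt[i], res$table$psi[i]))))
  # the blob phantom's rotation-shift near-degeneracy sets a floor around
  # one grid step; require convergence within twice the finest step
  expect_lte(median(ang), 2 * 2.5)
  # mean cc non-decreasing on clean data
  expect_true(all(diff(res$history$mean_cc) > -1e-6))
})
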