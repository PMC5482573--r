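test_that("soft masks are bounded, taper correctly, and have the right core volume", {
  m0 <- soft_mask(48, "cylinder", radius = 10, height = 20, soft_edge_width = 0)
  expect_true(all(m0$data %in% c(0, 1)))
  m <- soft_mask(48, "cylinder", radius = 10, height = 20, soft_edge_width = 3)
  expect_true(all(m$data >= 0 & m$data <= 1))
  expect_equal(sum(m0$data), pi * 10^2 * 20, tolerance = 0.02)
  s <- soft_mask(48, "sphere", radius = 10, soft_edge_width = 0)
  expect_equal(sum(s$data), 4 / 3 * pi * 10^3, tolerance = 0.02)
})

test_that("FSC is 1 against itself, -1 against the negation, and matches a per-shell oracle", {
  m <- rand_map(16, voxel = 2, seed = 41)
  self <- fsc(m, m)
  expect_true(all(abs(self$fsc - 1) < 1e-9))
  neg <- fsc(m, density_map(-m$data, 2))
  expect_true(all(abs(neg$fsc + 1) < 1e-9))
  a <- rand_map(16, voxel = 2, seed = 42)
  b <- rand_map(16, voxel = 2, seed = 43)
  curve <- fsc(a, b)
  # brute-force per-shell complex correlation
  fa <- fft(a$data); fb <- fft(b$data)
  n <- 16
  kv <- freq_grid(n, 1)$kmag * n
  shell <- pmin(round(kv), 8)
  for (s in 1:8) {
    sel <- shell == s
    oracle <- Re(sum(fa[sel] * Conj(fb[sel]))) /
      sqrt(sum(Mod(fa[sel])^2) * sum(Mod(fb[sel])^2))
    expect_equal(curve$fsc[curve$shell == s], oracle, tolerance = 1e-9)
  }
  expect_lt(abs(mean(curve$fsc)), 0.2)   # independent noise decorrelates
})

test_that("criterion crossing is interpolated, bounded by Nyquist, and monotone", {
  m <- rand_map(16, voxel = 2, seed = 44)
  const <- fsc(m, m)
  expect_equal(resolution_at(const, 0.143), 2 * 2)   # Nyquist = 2 * voxel
  # hand-computed linear interpolation between two shells
  curve <- data.frame(shell = 1:2, freq = c(0.050, 0.0556),
                      resolution = 1 / c(0.050, 0.0556),
                      fsc = c(0.2, 0.1), zero_power = FALSE)
  class(curve) <- c("fsc_curve", class(curve))
  t <- (0.2 - 0.143) / (0.2 - 0.1)
  kc <- 0.050 + t * (0.0556 - 0.050)
  expect_equal(resolution_at(curve, 0.143), 1 / kc, tolerance = 1e-12)
  # 0.5 crossing is at lower frequency than 0.143 for a monotone curve
  mono <- data.frame(shell = 1:5, freq = seq(0.02, 0.10, by = 0.02),
                     resolution = 1 / seq(0.02, 0.10, by = 0.02),
                     fsc = c(0.9, 0.6, 0.3, 0.12, 0.05), zero_power = FALSE)
  class(mono) <- c("fsc_curve", class(mono))
  expect_gt(resolution_at(mono, 0.5), resolution_at(mono, 0.143))
  # uniformly raising the curve never worsens the resolution
  up <- mono; up$fsc <- pmin(1, mono$fsc + 0.1)
  expect_lte(resolution_at(up, 0.143), resolution_at(mono, 0.143))
  # all-below curve flags and returns the poorest shell
  low <- mono; low$fsc <- rep(0.05, 5)
  r <- resolution_at(low, 0.143)
  expect_equal(attr(r, "flag"), "below_criterion")
})

test_that("local resolution separates a structured region from pure noise", {
  set.seed(45)
  n <- 32
  base <- build_leaf_phantom(tiny_phantom(box = n, voxel = 2))
  h1 <- base$data + array(rnorm(n^3, 0, 0.02), c(n, n, n))
  h2 <- base$data + array(rnorm(n^3, 0, 0.02), c(n, n, n))
  # wipe the shared structure from one octant: there the halves are pure noise
  h1[17:32, 17:32, 17:32] <- rnorm(16^3, 0, 0.2)
  h2[17:32, 17:32, 17:32] <- rnorm(16^3, 0, 0.2)
  lr <- local_resolution(density_map(h1, 2), density_map(h2, 2),
                         window = 16, step = 8, criterion = 0.143)
  expect_true(all(lr$data >= 2 * 2 - 1e-9))
  struct_res <- lr$data[13, 13, 13]
  noise_res <- lr$data[25, 25, 25]
  expect_lt(struct_res, noise_res)
  ident <- local_resolution(base, base, window = 16, step = 8)
  expect_true(all(abs(ident$data - 4) < 1e-6))
  expect_error(local_resolution(base, base, window = 64), "window")
})

test_that("B-factor scaling matches the closed form and boosts high frequencies", {
  n <- 32
  x <- 0:(n - 1)
  vol <- density_map(array(outer(outer(cos(2 * pi * 8 * x / n), rep(1, n)),
                                 rep(1, n)), c(n, n, n)), 2)
  k0 <- 8 / (n * 2)
  sharp <- bfactor_sharpen(vol, -1400)
  expect_equal(max(sharp$data) / max(vol$data), exp(1400 * k0^2 / 4),
               tolerance = 1e-6)
  m <- rand_map(16, voxel = 4, seed = 46)
  expect_equal(bfactor_sharpen(m, 0)$data, m$data, tolerance = 1e-9)
  ps <- function(map) {
    f <- Mod(fft(map$data))^2
    kv <- freq_grid(16, 1)$kmag * 16
    c(lo = sum(f[kv <= 3 & kv >= 1]), hi = sum(f[kv >= 6 & kv <= 8]))
  }
  p0 <- ps(m); p1 <- ps(bfactor_sharpen(m, -1400))
  expect_gt(p1[["hi"]] / p1[["lo"]], p0[["hi"]] / p0[["lo"]])
})

test_that("local masked refinement recombines exactly on exclusive mask support", {
  ph <- tiny_phantom(box = 16, voxel = 4)
  ref <- build_leaf_phantom(ph)
  sim <- simulate_leaf_particles(6, snr = Inf, phantom = ph, seed = 47,
                                 init_cone_deg = 0, init_psi_deg = 0)
  sched <- alignment_schedule(cone_deg = 0, cone_step = 1, inplane_range = 0,
                              inplane_step = 1, shift_limit = 1,
                              lowpass_A = 16, max_iterations = 1)
  ones <- density_map(array(1, c(16, 16, 16)), 4)
  single <- local_align_and_combine(sim$subs, sim$table, ref, list(ones),
                                    sched, wedge = sim$wedge_array)
  global <- single$locals[[1]]$reference
  expect_equal(single$map$data, global$data, tolerance = 1e-9)
  # two disjoint binary masks: each voxel equals its own local average
  m1 <- density_map(array(0, c(16, 16, 16)), 4); m1$data[1:8, , ] <- 1
  m2 <- density_map(array(0, c(16, 16, 16)), 4); m2$data[9:16, , ] <- 1
  two <- local_align_and_combine(sim$subs, sim$table, ref, list(m1, m2),
                                 sched, wedge = sim$wedge_array)
  expect_equal(two$map$data[1:8, , ], two$locals[[1]]$reference$data[1:8, , ],
               tolerance = 1e-9)
  expect_equal(two$map$data[9:16, , ], two$locals[[2]]$reference$data[9:16, , ],
               tolerance = 1e-9)
  zero <- density_map(array(0, c(16, 16, 16)), 4)
  expect_error(local_align_and_combine(sim$subs, sim$table, ref, list(zero),
                                       sched), "mask 1")
})

test_that("half-map FSC of disjoint particle subsets improves with subset size", {
  h <- halfset_fsc_study(n_per_half = c(6, 24), snr = 0.5, seed = 48,
                         phantom = tiny_phantom(box = 16, voxel = 4))
  expect_lte(h$resolutions_A[["N24"]], h$resolutions_A[["N6"]])
  expect_lt(abs(h$noise_fsc_mean), 0.1)
})
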