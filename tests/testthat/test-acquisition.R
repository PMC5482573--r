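test_that("dose-symmetric ordering covers the range with the side-alternation rule", {
  o <- dose_symmetric_order(60, 3)
  expect_length(o, 41)
  expect_setequal(o, seq(-60, 60, by = 3))
  expect_equal(o[1:5], c(0, 3, -3, -6, 6))
  expect_equal(dose_symmetric_order(0, 3), 0)
  expect_error(dose_symmetric_order(50, 3), "not a multiple")
})

test_that("zero-tilt projection is the beam-axis sum and the projection theorem holds", {
  vol <- rand_map(32, voxel = 2, seed = 21)
  ts <- project_scene(vol, 0, ctf = NULL, noise_sigma = 0)
  expect_equal(ts$images[, , 1], apply(vol$data, c(1, 2), sum),
               tolerance = 1e-12)
  F2 <- fft(ts$images[, , 1])
  sec <- fft(vol$data)[, , 1]
  expect_lt(max(Mod(F2 - sec)) / max(Mod(sec)), 1e-6)
  # determinism without noise
  ts2 <- project_scene(vol, c(0, 30, -30), ctf = NULL, noise_sigma = 0)
  ts3 <- project_scene(vol, c(0, 30, -30), ctf = NULL, noise_sigma = 0)
  expect_identical(ts2$images, ts3$images)
})

test_that("accumulated dose is non-decreasing along the acquisition order", {
  vol <- rand_map(16, seed = 3)
  ts <- project_scene(vol, dose_symmetric_order(60, 15), total_dose = 85)
  ord <- order(ts$acquisition_order)
  expect_true(all(diff(ts$accumulated_dose[ord]) >= 0))
  expect_equal(max(ts$accumulated_dose), 85, tolerance = 1e-12)
})

test_that("dose filter matches the scalar attenuation formula and only removes power", {
  n <- 64
  x <- 0:(n - 1)
  img <- outer(cos(2 * pi * 16 * x / n), rep(1, n))   # k = 0.25 1/A at 1 A/px
  out <- dose_filter(img, 30, 1)
  ne <- 0.245 * 0.25^(-1.665) + 2.81
  expect_equal(max(abs(out)) / max(abs(img)), exp(-30 / (2 * ne)),
               tolerance = 1e-6)
  expect_identical(dose_filter(img, 0, 1), img)
  # strictly decreases total power, never boosts any amplitude
  set.seed(4)
  noise <- matrix(rnorm(n * n), n, n)
  f0 <- Mod(fft(noise)); f1 <- Mod(fft(dose_filter(noise, 40, 1)))
  expect_lt(sum(f1^2), sum(f0^2))
  expect_true(all(f1 <= f0 + 1e-9))
})

test_that("phase flipping is involutive and restores projection phases", {
  ph <- build_leaf_phantom(tiny_phantom(box = 32, voxel = 2))
  clean <- project_scene(ph, 0, ctf = NULL)
  series <- project_scene(ph, 0, ctf = ctf_params(), seed = 7)
  corr <- ctf_correct(series)
  twice <- ctf_correct(corr)
  expect_equal(twice$images, series$images, tolerance = 1e-9)
  n <- 32
  f1 <- fft(clean$images[, , 1]); f2 <- fft(corr$images[, , 1])
  k <- sqrt(outer(tomocoat:::fft_freqs(n, 2)^2,
                  tomocoat:::fft_freqs(n, 2)^2, "+"))
  lambda <- tomocoat:::electron_wavelength(300)
  kzero <- sqrt(1 / (lambda * -corr$defocus_um[1] * 1e4))
  sel <- k > 0 & k < 0.8 * kzero & Mod(f1) > 1e-6 * max(Mod(f1))
  rms <- sqrt(mean((Arg(f2[sel] * Conj(f1[sel])) * 180 / pi)^2))
  expect_lt(rms, 1)
  broken <- series; broken$defocus_um <- NA
  expect_error(ctf_correct(broken), "defocus")
})

test_that("weighted back-projection reconstructs a point at its voxel and is linear", {
  vol <- array(0, c(32, 32, 32)); vol[17, 17, 17] <- 1
  ts <- project_scene(density_map(vol, 2), dose_symmetric_order(90, 1), ctf = NULL)
  rec <- reconstruct_wbp(ts)
  expect_equal(as.integer(which(rec$data == max(rec$data), arr.ind = TRUE)[1, ]),
               c(17, 17, 17))
  # linearity
  a <- rand_map(16, seed = 5); b <- rand_map(16, seed = 6)
  tilts <- dose_symmetric_order(60, 20)
  ra <- reconstruct_wbp(project_scene(a, tilts, ctf = NULL))
  rb <- reconstruct_wbp(project_scene(b, tilts, ctf = NULL))
  rab <- reconstruct_wbp(project_scene(density_map(a$data + b$data, a$voxel_size),
                                       tilts, ctf = NULL))
  expect_equal(rab$data, ra$data + rb$data,
               tolerance = 1e-6 * max(abs(rab$data)))
})

test_that("dense-angle reconstruction correlates with the phantom; +-60 elongates along the beam", {
  ph <- build_leaf_phantom(tiny_phantom(box = 32, voxel = 2))
  rec <- reconstruct_wbp(project_scene(ph, dose_symmetric_order(90, 1), ctf = NULL))
  expect_gt(cor(as.numeric(rec$data), as.numeric(ph$data)), 0.95)
  # sphere reconstructed from a +-60 wedge is axially smeared
  ax <- 0:31
  r <- sqrt(outer(outer((ax - 15.5)^2, (ax - 15.5)^2, "+"), (ax - 15.5)^2, "+"))
  sph <- density_map((r < 5) * 1, 2)
  rec60 <- reconstruct_wbp(project_scene(sph, dose_symmetric_order(60, 3), ctf = NULL))
  fwhm <- function(v) { v <- v - min(v); sum(v > max(v) / 2) }
  expect_gt(fwhm(rec60$data[16, 16, ]) / fwhm(rec60$data[, 16, 16]), 1)
})

test_that("wedge mask geometry: full range is all ones, missing third, Friedel symmetry", {
  expect_true(all(wedge_mask(16, wedge_spec(-90, 90)) == 1))
  n <- 48
  w <- wedge_mask(n, wedge_spec(-60, 60), softness_deg = 0)
  kv <- freq_grid(n, 1)$kmag * n
  ball <- kv <= n / 2
  expect_equal(1 - mean(w[ball]), 1 / 3, tolerance = 0.02)
  flip <- function(x) x[c(1, n:2), c(1, n:2), c(1, n:2)]
  expect_equal(w, flip(w), tolerance = 1e-12)
  ws <- wedge_mask(n, wedge_spec(-60, 60), softness_deg = 5)
  expect_true(all(ws >= 0 & ws <= 1))
  expect_equal(ws, flip(ws), tolerance = 1e-12)
})

test_that("a particle cut from a +-60 reconstruction has little power in the missing wedge", {
  # well-sampled blobs (sigma >= voxel) so the particle spectrum, not the
  # extraction window, dominates the measurement
  ph <- phantom_spec(centers = rbind(c(10, 0, 8), c(-8, 10, -4), c(4, -10, 14)),
                     sigmas = c(6, 5, 5), weights = c(1, 0.8, 0.7),
                     gap_blob = NULL, symmetry_order = 3,
                     box_size = 32, voxel_size = 4)
  sc <- scene_spec(vesicle_radii = 50, n_vesicles = 1, triads_per_vesicle = 1,
                   membrane_shell = c(0, 8, 0), seed = 5,
                   box_size = 64, voxel_size = 4)
  s <- build_vesicle_scene(sc, ph)
  ts <- project_scene(s$map, dose_symmetric_order(60, 3), ctf = NULL)
  tomo <- reconstruct_wbp(ts)
  row <- s$truth[1, ]
  sub <- extract_subtomogram(tomo, c(row$x, row$y, row$z), 32)$map
  w <- wedge_mask(32, wedge_spec(-60, 60))
  pw <- Mod(fft(sub$data - mean(sub$data)))^2
  pw[1, 1, 1] <- 0
  missing <- sum(pw * (1 - w)) / sum(pw * w)
  expect_lt(missing, 0.05)
})
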