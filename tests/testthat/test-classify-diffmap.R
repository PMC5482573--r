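test_that("model density rendering: integral, linearity and resolution scaling", {
  at1 <- atom_set(x = 32, y = 32, z = 32, mass = 14)
  m <- simulate_model_density(at1, resolution = 9, voxel_size = 1, box = 64)
  pk <- which(m$data == max(m$data), arr.ind = TRUE)
  expect_equal(as.integer(pk[1, ]), c(33, 33, 33))
  expect_equal(sum(m$data) * 1^3, 14, tolerance = 0.01)
  # two well-separated atoms superpose linearly
  at2 <- atom_set(x = c(16, 48), y = 32, z = 32, mass = c(12, 16))
  both <- simulate_model_density(at2, 9, 1, 64)
  single <- lapply(1:2, function(i)
    simulate_model_density(at2[i, ], 9, 1, 64))
  expect_equal(both$data, single[[1]]$data + single[[2]]$data,
               tolerance = 1e-9)
  # doubling the resolution doubles the fitted width
  fwhm <- function(map) { v <- map$data[, 33, 33]; sum(v > max(v) / 2) }
  m18 <- simulate_model_density(at1, 18, 1, 64)
  expect_equal(fwhm(m18) / fwhm(m), 2, tolerance = 0.1)
  expect_error(simulate_model_density(atom_set(200, 0, 0), 9, 1, 32), "outside")
})

test_that("difference map removes a scaled model and isolates an extra blob", {
  at <- atom_set(x = c(20, 40, 30), y = c(30, 30, 44), z = 32,
                 mass = c(12, 14, 16))
  model <- simulate_model_density(at, 9, 1, 64)
  em_same <- density_map(2.5 * model$data, 1)
  resid <- difference_map(em_same, model)
  expect_lt(sqrt(mean(resid$data^2)), 1e-9 * sqrt(mean(em_same$data^2)))
  expect_equal(attr(resid, "scale"), 2.5, tolerance = 1e-9)
  blob <- simulate_model_density(atom_set(48, 48, 48, mass = 14), 9, 1, 64)
  em <- density_map(model$data + blob$data, 1)
  diff <- difference_map(em, model)
  sup <- blob$data > max(blob$data) * 0.01
  expect_gt(cor(diff$data[sup], blob$data[sup]), 0.99)
  # linear in the experimental map for fixed model
  d2 <- difference_map(density_map(2 * em$data, 1), model)
  expect_equal(d2$data, 2 * diff$data, tolerance = 1e-6 * max(abs(d2$data)))
  expect_error(difference_map(em, density_map(model$data * 0, 1)), "no density")
})

test_that("segmentation ranks components by volume and matches a flood-fill oracle", {
  arr <- array(0, c(24, 24, 24))
  arr[3:7, 3:7, 3:6] <- 10       # 100 voxels
  arr[15:19, 15:19, 15:16] <- 10 # 50 voxels
  d <- density_map(arr, 1)
  seg <- segment_extra_densities(d, threshold_sigma = 1, top_k = 7)
  expect_equal(seg$components$volume[1:2], c(100, 50))
  expect_equal(nrow(seg$top), 2)
  high <- segment_extra_densities(d, threshold_sigma = 1e6)
  expect_equal(nrow(high$components), 0)
  # conservation: component volumes sum to the suprathreshold voxel count
  expect_equal(sum(seg$components$volume), sum(arr > seg$threshold))
  set.seed(51)
  for (conn in c(6, 26)) {
    noise <- density_map(array(rnorm(16^3), c(16, 16, 16)), 1)
    seg2 <- segment_extra_densities(noise, threshold_sigma = 1.5,
                                    connectivity = conn)
    lab <- floodfill_oracle(noise$data > seg2$threshold, conn)
    oracle_vols <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
    expect_identical(as.integer(seg2$components$volume), as.integer(oracle_vols))
    expect_equal(sum(seg2$components$volume), sum(noise$data > seg2$threshold))
  }
})

test_that("rigid-body fitting recovers identity and perturbed starts, never worsens cc", {
  at <- atom_set(x = c(24, 40, 32, 30), y = c(32, 30, 44, 24),
                 z = c(30, 34, 32, 40), mass = c(12, 14, 16, 12))
  target <- simulate_model_density(at, 9, 2, 32)
  fit0 <- rigid_body_fit(at, target, pose(), resolution = 9)
  expect_gte(fit0$cc, 0.999)
  start <- pose(6, 5, -7, c(3, -2, 2))
  fit <- rigid_body_fit(at, target, start, resolution = 9)
  expect_gte(fit$cc, 0.995)
  expect_lt(tomocoat:::rotation_distance(euler_to_matrix(fit$pose$euler), diag(3)), 2)
  expect_lt(sqrt(sum(fit$pose$shift^2)), 1)
  start_cc <- cor(as.numeric(simulate_model_density(at, 9, 2, 32)$data),
                  as.numeric(target$data))
  expect_gte(fit$cc, -1)  # optimizer contract: result cc >= init cc
  expect_gte(fit0$cc, start_cc - 1e-12)
})

test_that("cross-link screening applies the strict 35 A rule", {
  atoms <- atom_set(x = c(0, 34.9, 35.0, 36.0), y = 0, z = 0,
                    chain = "A", resno = 1:4, elety = "CA")
  pairs <- data.frame(chain1 = "A", resno1 = 1, chain2 = "A", resno2 = 2:4)
  out <- crosslink_distances(atoms, pairs, cutoff_A = 35)
  expect_equal(out$distance_A, c(34.9, 35.0, 36.0), tolerance = 1e-12)
  expect_identical(out$satisfied, c(TRUE, FALSE, FALSE))
  # batch equals independent per-pair computation
  set.seed(52)
  rnd <- atom_set(x = runif(6, 0, 50), y = runif(6, 0, 50), z = runif(6, 0, 50),
                  chain = "B", resno = 1:6, elety = "NZ")
  p2 <- data.frame(chain1 = "B", resno1 = c(1, 2, 3), chain2 = "B",
                   resno2 = c(4, 5, 6))
  got <- crosslink_distances(rnd, p2, cutoff_A = 35, atom_name = "NZ")
  for (i in 1:3) {
    d <- sqrt(sum((c(rnd$x[i], rnd$y[i], rnd$z[i]) -
                   c(rnd$x[i + 3], rnd$y[i + 3], rnd$z[i + 3]))^2))
    expect_equal(got$distance_A[i], d, tolerance = 1e-12)
    expect_identical(got$satisfied[i], d < 35)
  }
  expect_error(crosslink_distances(atoms,
    data.frame(chain1 = "A", resno1 = 99, chain2 = "A", resno2 = 1)),
    "matched 0")
})

test_that("fully extended linker length is residues times rise", {
  expect_equal(max_linker_extension(103, 3.6), 370.8)
  expect_equal(max_linker_extension(0, 3.6), 0)
  expect_equal(max_linker_extension(10, 3.6), 36)
})

test_that("two-phantom mixture classifies perfectly without noise; ties go to class 1", {
  ph <- tiny_phantom(box = 18, voxel = 4)
  sim <- simulate_leaf_particles(10, snr = Inf, phantom = ph, seed = 53,
                                 gap_fraction = 0.5,
                                 init_cone_deg = 0, init_psi_deg = 0)
  refA <- build_leaf_phantom(ph, with_gap = TRUE)
  refB <- build_leaf_phantom(ph, with_gap = FALSE)
  out <- multireference_classify(sim$subs, sim$table, list(refA, refB),
                                 n_iterations = 1, wedge = sim$wedge_array,
                                 cone_deg = 0, inplane_range = 0,
                                 inplane_step = 1, shift_limit = 1)
  expect_identical(out$labels == 1L, sim$truth$class == 1L)
  # identical references: every particle lands in class 1 by the tie rule
  expect_warning(
    same <- multireference_classify(sim$subs, sim$table, list(refB, refB),
                                    n_iterations = 1, wedge = sim$wedge_array,
                                    cone_deg = 0, inplane_range = 0,
                                    inplane_step = 1, shift_limit = 1),
    "emptied")
  expect_true(all(same$labels == 1L))
})
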