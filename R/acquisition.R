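#' Dose-symmetric tilt ordering
#'
#' Generates the full tilt list `{-max_tilt, ..., +max_tilt}` in
#' dose-symmetric acquisition order: starting at 0 and alternating sides with
#' increasing magnitude (0, +s, -s, -2s, +2s, +3s, -3s, ...), so that the
#' lowest-dose images are the low-tilt ones. The dose rank of an angle equals
#' its index in the returned vector.
#'
#' @param max_tilt maximum tilt in degrees.
#' @param step tilt increment in degrees; must divide `max_tilt`.
#' @return numeric vector of tilt angles in acquisition order.
#' @export
dose_symmetric_order <- function(max_tilt, step) {
  stopifnot(step > 0)
  if (max_tilt == 0) return(0)
  if (abs(max_tilt / step - round(max_tilt / step)) > 1e-9)
    stop(sprintf("tilt range %g is not a multiple of step %g", max_tilt, step))
  nmag <- round(max_tilt / step)
  out <- 0
  for (k in seq_len(nmag)) {
    a <- k * step
    if (k %% 2 == 1) out <- c(out, a, -a) else out <- c(out, -a, a)
  }
  out
}

#' Missing-wedge specification
#' @param tilt_min,tilt_max tilt range in degrees, both in `[-90, 90]`.
#' @return a `wedge_spec` object.
#' @export
wedge_spec <- function(tilt_min = -60, tilt_max = 60) {
  stopifnot(tilt_min < tilt_max, tilt_min >= -90, tilt_max <= 90)
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max),
            class = "wedge_spec")
}

#' CTF parameter set
#' @param voltage_kv acceleration voltage (kV).
#' @param cs_mm spherical aberration (mm).
#' @param amplitude_contrast fraction in `[0,1]`.
#' @return a `ctf_params` object.
#' @export
ctf_params <- function(voltage_kv = 300, cs_mm = 2.7,
                       amplitude_contrast = 0.07) {
  structure(list(voltage_kv = voltage_kv, cs_mm = cs_mm,
                 amplitude_contrast = amplitude_contrast),
            class = "ctf_params")
}

# Relativistic electron wavelength in Angstrom.
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Evaluate the contrast transfer function
#'
#' Standard oscillatory CTF. Defocus follows the underfocus-negative sign
#' convention used in tomography metadata: `defocus_um = -2` means 2 um
#' underfocus and gives the usual negative-contrast first band.
#'
#' @param k spatial frequency (1/Angstrom), any shape.
#' @param defocus_um defocus in micrometers (negative = underfocus).
#' @param params a [ctf_params()].
#' @return CTF values, same shape as `k`.
#' @export
ctf_eval <- function(k, defocus_um, params = ctf_params()) {
  lambda <- electron_wavelength(params$voltage_kv)
  dz <- -defocus_um * 1e4                # underfocus in Angstrom, positive
  cs <- params$cs_mm * 1e7
  chi <- pi * lambda * dz * k^2 - pi / 2 * cs * lambda^3 * k^4
  a <- params$amplitude_contrast
  -(sqrt(1 - a^2) * sin(chi) + a * cos(chi))
}

#' Simulate a tilt series from a scene volume
#'
#' Parallel-beam projections about the grid Y tilt axis, optionally convolved
#' with a per-image CTF and corrupted by white Gaussian noise. Dose is spread
#' uniformly over the tilts in acquisition order; per-image defocus is drawn
#' uniformly from `defocus_range_um`.
#'
#' @param scene a cubic `density_map`.
#' @param tilts tilt angles in acquisition order (e.g. from
#'   [dose_symmetric_order()]).
#' @param ctf a [ctf_params()] or NULL for no CTF.
#' @param noise_sigma white-noise sd added to each image.
#' @param seed integer seed for noise and defocus draws.
#' @param total_dose total exposure over the series (e/A^2).
#' @param defocus_range_um length-2 defocus range (um, negative = underfocus).
#' @return a `tilt_series`: images (n x n x ntilt array, stacked in angle
#'   order), tilt_angles, acquisition_order (dose rank per image),
#'   accumulated_dose (e/A^2 after each image), defocus_um, pixel_size.
#' @export
project_scene <- function(scene, tilts, ctf = NULL, noise_sigma = 0, seed = 1,
                          total_dose = 85, defocus_range_um = c(-5, -2)) {
  d <- dim(scene$data)
  stopifnot(length(unique(d)) == 1)
  n <- d[1]
  ntilt <- length(tilts)
  ord_angle <- order(tilts)            # stack sorted by angle
  angles <- tilts[ord_angle]
  dose_rank <- match(angles, tilts)    # acquisition index of each image
  dose_per_tilt <- total_dose / ntilt
  accumulated <- dose_rank * dose_per_tilt
  with_seed(seed, {
    defocus <- stats::runif(ntilt, min(defocus_range_um), max(defocus_range_um))
    imgs <- array(0, c(n, n, ntilt))
    ctr <- (n - 1) / 2
    kx <- fft_freqs(n, scene$voxel_size)
    kmag2d <- sqrt(outer(kx^2, kx^2, "+"))
    for (i in seq_len(ntilt)) {
      a <- angles[i] * pi / 180
      R <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
      b <- (d - 1) / 2 - as.numeric(R %*% ((d - 1) / 2))
      rs <- c_affine_sample(as.numeric(scene$data), as.integer(d), R, b)
      proj <- rowSums(matrix(rs, n * n, n))
      img <- matrix(proj, n, n)
      if (!is.null(ctf)) {
        tf <- ctf_eval(kmag2d, defocus[i], ctf)
        img <- Re(stats::fft(stats::fft(img) * tf, inverse = TRUE)) / (n * n)
      }
      if (noise_sigma > 0)
        img <- img + matrix(stats::rnorm(n * n, 0, noise_sigma), n, n)
      imgs[, , i] <- img
    }
    structure(list(images = imgs, tilt_angles = angles,
                   acquisition_order = dose_rank,
                   accumulated_dose = accumulated, defocus_um = defocus,
                   pixel_size = scene$voxel_size),
              class = "tilt_series")
  })
}

#' Exposure-curve parameters for dose filtering
#'
#' Constants of the critical-exposure curve `Ne(k) = a * k^b + c` (k in 1/A);
#' defaults are the published exposure-filter values for 300 kV data.
#'
#' @param a,b,c curve constants; `a > 0`, `b < 0`, `c > 0`.
#' @return a `dose_filter_params` object.
#' @export
dose_filter_params <- function(a = 0.245, b = -1.665, c = 2.81) {
  stopifnot(a > 0, b < 0, c > 0)
  structure(list(a = a, b = b, c = c), class = "dose_filter_params")
}

#' Exposure-dependent low-pass (dose) filter
#'
#' Attenuates Fourier amplitudes by `exp(-N / (2 * Ne(k)))` where `N` is the
#' accumulated dose and `Ne(k) = a k^b + c` is the critical exposure at
#' frequency `k`. `N = 0` is the identity; attenuation tends to 1 as k -> 0.
#'
#' @param image 2D numeric matrix.
#' @param accumulated_dose dose N in e/A^2 (>= 0).
#' @param pixel_size Angstrom per pixel.
#' @param params a [dose_filter_params()].
#' @return filtered image.
#' @export
dose_filter <- function(image, accumulated_dose, pixel_size,
                        params = dose_filter_params()) {
  stopifnot(accumulated_dose >= 0)
  if (accumulated_dose == 0) return(image)
  n1 <- nrow(image); n2 <- ncol(image)
  k <- sqrt(outer(fft_freqs(n1, pixel_size)^2, fft_freqs(n2, pixel_size)^2, "+"))
  ne <- params$a * k^params$b + params$c   # k = 0 -> Inf -> attenuation 1
  att <- exp(-accumulated_dose / (2 * ne))
  Re(stats::fft(stats::fft(image) * att, inverse = TRUE)) / (n1 * n2)
}

#' Dose-filter every image of a tilt series
#' @param series a `tilt_series`.
#' @param params a [dose_filter_params()].
#' @return the filtered `tilt_series`.
#' @export
dose_filter_series <- function(series, params = dose_filter_params()) {
  for (i in seq_along(series$tilt_angles))
    series$images[, , i] <- dose_filter(series$images[, , i],
                                        series$accumulated_dose[i],
                                        series$pixel_size, params)
  series
}

#' CTF correction by phase flipping
#'
#' Flips the sign of Fourier components wherever the CTF model is negative.
#' Applying the correction twice is the identity.
#'
#' @param series a `tilt_series` with per-image defocus.
#' @param params a [ctf_params()].
#' @return the phase-flipped `tilt_series`.
#' @export
ctf_correct <- function(series, params = ctf_params()) {
  if (is.null(series$defocus_um) || anyNA(series$defocus_um))
    stop("ctf_correct requires a defocus value for every image")
  n <- dim(series$images)[1]
  k <- sqrt(outer(fft_freqs(n, series$pixel_size)^2,
                  fft_freqs(n, series$pixel_size)^2, "+"))
  for (i in seq_along(series$tilt_angles)) {
    s <- sign(ctf_eval(k, series$defocus_um[i], params))
    s[s == 0] <- 1
    img <- series$images[, , i]
    series$images[, , i] <- Re(stats::fft(stats::fft(img) * s,
                                          inverse = TRUE)) / (n * n)
  }
  series
}

#' Weighted back-projection reconstruction
#'
#' Ramp-filters each image along the direction perpendicular to the tilt axis
#' and back-projects into a cubic volume. The tilt axis is the grid Y axis.
#'
#' @param series a `tilt_series` (square images).
#' @param size output box side in voxels (defaults to the image side).
#' @return a `density_map`.
#' @export
reconstruct_wbp <- function(series, size = dim(series$images)[1]) {
  n <- dim(series$images)[1]
  stopifnot(dim(series$images)[2] == n)
  ntilt <- length(series$tilt_angles)
  ramp <- abs(fft_freqs(n, series$pixel_size))
  filtered <- array(0, c(n, n, ntilt))
  for (i in seq_len(ntilt)) {
    ft <- stats::mvfft(series$images[, , i]) * ramp
    filtered[, , i] <- Re(stats::mvfft(ft, inverse = TRUE)) / n
  }
  out <- c_backproject(as.numeric(filtered), as.integer(dim(filtered)),
                       series$tilt_angles, as.integer(size))
  vol <- array(out, c(size, size, size)) * pi / (2 * ntilt) * series$pixel_size
  density_map(vol, series$pixel_size)
}

#' Fourier-space missing-wedge mask
#'
#' Binary-or-soft weights over a cubic Fourier grid (unshifted FFT layout):
#' 1 where the tilt range sampled, 0 inside the missing wedge, with an
#' optional cosine-tapered edge. The mask is Friedel-symmetric. The tilt axis
#' is Y and the beam axis is Z, matching [project_scene()].
#'
#' @param n box side in voxels.
#' @param wedge a [wedge_spec()].
#' @param softness_deg angular width of the cosine edge (0 = hard).
#' @return 3D array of weights in `[0,1]`.
#' @export
wedge_mask <- function(n, wedge = wedge_spec(), softness_deg = 0) {
  f <- fft_freqs(n, 1)
  kx <- array(rep(f, times = n * n), c(n, n, n))
  kz <- array(rep(f, each = n * n), c(n, n, n))
  # tilt at which the plane through k is sampled: kx sin(a) + kz cos(a) = 0
  a0 <- atan2(-kz, kx) * 180 / pi
  a0[a0 > 90] <- a0[a0 > 90] - 180     # fold to (-90, 90]
  a0[a0 <= -90] <- a0[a0 <= -90] + 180
  # distance (deg) outside the sampled range
  d <- pmax(wedge$tilt_min - a0, a0 - wedge$tilt_max, 0)
  d2 <- pmax(wedge$tilt_min - (a0 - 180), (a0 - 180) - wedge$tilt_max, 0)
  d3 <- pmax(wedge$tilt_min - (a0 + 180), (a0 + 180) - wedge$tilt_max, 0)
  d <- pmin(d, d2, d3)
  if (softness_deg <= 0) {
    w <- (d <= 0) * 1
  } else {
    w <- array(0, c(n, n, n))
    w[d <= 0] <- 1
    mid <- d > 0 & d < softness_deg
    w[mid] <- 0.5 * (1 + cos(pi * d[mid] / softness_deg))
  }
  w[1, 1, 1] <- 1                      # DC always sampled
  w[kx == 0 & kz == 0] <- 1            # tilt-axis line is in every projection
  # enforce Friedel symmetry exactly: on an even grid the Nyquist-plane bins
  # alias +0.5 and -0.5 cycles together, which for an asymmetric tilt range
  # would otherwise give w(k) != w(-k); take the conservative minimum
  idx <- lapply(rep(n, 3), function(m) c(1, m:2))
  pmin(w, w[idx[[1]], idx[[2]], idx[[3]]])
}
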