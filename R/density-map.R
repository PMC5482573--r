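#' Construct a density map
#'
#' A `density_map` is the package's universal volume container: a 3D numeric
#' array with a voxel spacing in Angstrom and an origin (the position of voxel
#' `[1,1,1]`'s center in Angstrom). Tomograms, references, masks and difference
#' maps are all `density_map` objects.
#'
#' @param data 3D numeric array.
#' @param voxel_size voxel spacing in Angstrom per voxel (scalar).
#' @param origin numeric(3), position of the first voxel center in Angstrom.
#' @return A `density_map` object.
#' @export
density_map <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(voxel_size), length(voxel_size) == 1L, voxel_size > 0)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("density_map: %d x %d x %d voxels, %.3f A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$data)

as_map_like <- function(template, data) {
  density_map(data, template$voxel_size, template$origin)
}

#' Spatial frequency magnitude grid
#'
#' Returns the 3D array of Fourier frequency magnitudes (1/Angstrom) matching
#' R's unshifted [stats::fft()] layout for a cubic box.
#'
#' @param n box side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @return list with components `kx`, `ky`, `kz` (per-axis frequency vectors)
#'   and `kmag` (3D array of |k|).
#' @export
freq_grid <- function(n, voxel_size = 1) {
  f <- fft_freqs(n, voxel_size)
  k2 <- outer(f^2, f^2, "+")
  kmag <- sqrt(outer(k2, f^2, "+"))
  list(kx = f, ky = f, kz = f, kmag = kmag)
}

# fftfreq-style frequency vector (cycles per Angstrom), unshifted order.
fft_freqs <- function(n, voxel_size = 1) {
  i <- 0:(n - 1)
  i[i >= ceiling(n / 2)] <- i[i >= ceiling(n / 2)] - n
  i / (n * voxel_size)
}

# Apply a Fourier-space transfer function (3D array, unshifted) to a map.
apply_transfer <- function(map, transfer) {
  ft <- stats::fft(map$data) * transfer
  as_map_like(map, Re(stats::fft(ft, inverse = TRUE)) / length(ft))
}

#' Low-pass filter a map
#'
#' Soft (cosine-edged) spherical low-pass in Fourier space.
#'
#' @param map a `density_map`.
#' @param resolution cutoff resolution in Angstrom.
#' @param soft_width transition width in Fourier voxels (default 3).
#' @return filtered `density_map`.
#' @export
lowpass_map <- function(map, resolution, soft_width = 3) {
  n <- dim(map$data)[1]
  fg <- freq_grid(n, map$voxel_size)
  kc <- 1 / resolution
  dk <- soft_width / (n * map$voxel_size)
  tr <- raised_cosine_step(fg$kmag, kc, dk)
  apply_transfer(map, tr)
}

# 1 below edge, cosine taper of width `dk` beyond, 0 above.
raised_cosine_step <- function(x, edge, dk) {
  if (dk <= 0) return((x <= edge) * 1)
  w <- array(0, dim = if (is.array(x)) dim(x) else length(x))
  w[x <= edge] <- 1
  mid <- x > edge & x < edge + dk
  w[mid] <- 0.5 * (1 + cos(pi * (x[mid] - edge) / dk))
  w
}

#' Normalize a map to zero mean and unit standard deviation
#' @param map a `density_map`.
#' @return normalized `density_map`.
#' @export
normalize_map <- function(map) {
  s <- stats::sd(map$data)
  if (s == 0) s <- 1
  as_map_like(map, (map$data - mean(map$data)) / s)
}
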