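#' Soft real-space mask
#'
#' Cylindrical or spherical mask: 1 in the core, cosine falloff over
#' `soft_edge_width` voxels, 0 outside. The cylinder axis is z.
#'
#' @param n box side in voxels.
#' @param shape "cylinder" or "sphere".
#' @param center 0-based voxel coordinates (default box center).
#' @param radius core radius in voxels.
#' @param height cylinder core height in voxels (ignored for spheres).
#' @param soft_edge_width cosine edge width in voxels (0 = binary).
#' @return a `density_map` of weights in `[0,1]`.
#' @export
soft_mask <- function(n, shape = c("cylinder", "sphere"), center = NULL,
                      radius = n / 4, height = n / 2, soft_edge_width = 3) {
  shape <- match.arg(shape)
  if (is.null(center)) center <- rep((n - 1) / 2, 3)
  ax <- (0:(n - 1))
  dx <- ax - center[1]; dy <- ax - center[2]; dz <- ax - center[3]
  if (shape == "sphere") {
    r <- sqrt(outer(outer(dx^2, dy^2, "+"), dz^2, "+"))
    d <- r - radius
  } else {
    rxy <- sqrt(outer(dx^2, dy^2, "+"))
    radial <- array(rxy, c(n, n, n)) - radius
    axial <- array(rep(abs(dz), each = n * n), c(n, n, n)) - height / 2
    d <- pmax(radial, axial)
  }
  if (soft_edge_width <= 0) {
    w <- (d <= 0) * 1
  } else {
    w <- array(0, c(n, n, n))
    w[d <= 0] <- 1
    mid <- d > 0 & d < soft_edge_width
    w[mid] <- 0.5 * (1 + cos(pi * d[mid] / soft_edge_width))
  }
  density_map(w, 1)
}

#' Fourier shell correlation
#'
#' Per-shell correlation `FSC(k) = Re(sum F1 F2*) / sqrt(sum|F1|^2 sum|F2|^2)`
#' over 1-Fourier-voxel shells. Shells with zero power in either map get
#' correlation 0 and are flagged.
#'
#' @param map1,map2 `density_map`s of equal cubic shape.
#' @param mask optional soft real-space mask (`density_map` or array).
#' @return an `fsc_curve`: data.frame with columns `shell`, `freq` (1/A),
#'   `resolution` (A), `fsc`, `zero_power`; attribute `voxel_size`.
#' @export
fsc <- function(map1, map2, mask = NULL) {
  stopifnot(all(dim(map1$data) == dim(map2$data)))
  n <- dim(map1$data)[1]
  m <- if (is.null(mask)) 1 else if (inherits(mask, "density_map"))
    mask$data else mask
  f1 <- stats::fft(map1$data * m)
  f2 <- stats::fft(map2$data * m)
  kvox <- freq_grid(n, 1)$kmag * n      # radius in Fourier voxels
  shell <- pmin(round(kvox), floor(n / 2))
  sidx <- as.integer(shell) + 1L
  num <- rowsum(as.numeric(Re(f1 * Conj(f2))), sidx)
  p1 <- rowsum(as.numeric(Mod(f1)^2), sidx)
  p2 <- rowsum(as.numeric(Mod(f2)^2), sidx)
  shells <- as.integer(rownames(num)) - 1L
  keep <- shells >= 1 & shells <= floor(n / 2)
  shells <- shells[keep]
  num <- num[keep]; p1 <- p1[keep]; p2 <- p2[keep]
  zero <- p1 == 0 | p2 == 0
  corr <- ifelse(zero, 0, num / sqrt(p1 * p2))
  freq <- shells / (n * map1$voxel_size)
  out <- data.frame(shell = shells, freq = freq, resolution = 1 / freq,
                    fsc = corr, zero_power = zero)
  attr(out, "voxel_size") <- map1$voxel_size
  class(out) <- c("fsc_curve", class(out))
  out
}

#' Resolution at an FSC criterion
#'
#' First downward crossing of the criterion, linearly interpolated between
#' shells. If the curve never falls below the criterion the Nyquist
#' resolution (2 x voxel size) is returned; if it starts below, the worst
#' shell is returned with attribute `flag = "below_criterion"`.
#'
#' @param curve an [fsc()] curve.
#' @param criterion FSC threshold in (0, 1), e.g. 0.143 or 0.5.
#' @return resolution in Angstrom (possibly with a `flag` attribute).
#' @export
resolution_at <- function(curve, criterion = 0.143) {
  stopifnot(criterion > 0, criterion < 1)
  nyq <- 1 / curve$freq[length(curve$freq)]
  if (!is.null(curve$zero_power)) {
    # shells with no power in either map carry no information
    curve <- curve[!curve$zero_power, , drop = FALSE]
    if (nrow(curve) == 0) return(nyq)
  }
  f <- curve$fsc; k <- curve$freq
  below <- which(f < criterion)
  if (length(below) == 0) return(1 / k[length(k)])
  i <- below[1]
  if (i == 1) {
    res <- 1 / k[1]                    # poorest shell; nothing is resolved
    attr(res, "flag") <- "below_criterion"
    return(res)
  }
  # interpolate frequency of the crossing between shells i-1 and i
  t <- (f[i - 1] - criterion) / (f[i - 1] - f[i])
  kc <- k[i - 1] + t * (k[i] - k[i - 1])
  1 / kc
}

#' Local resolution map
#'
#' FSC between the two half maps inside a soft-edged spherical window moved
#' on a regular grid; the criterion-crossing resolution is assigned to the
#' window center and interpolated (trilinearly) between grid points.
#'
#' @param half1,half2 half maps (`density_map`s, equal cubic shape).
#' @param window window side in voxels (>= 8).
#' @param step window-center step in voxels.
#' @param criterion FSC criterion.
#' @param soft_edge window mask soft edge (voxels).
#' @return `density_map` of local resolutions (Angstrom).
#' @export
local_resolution <- function(half1, half2, window = 20, step = 4,
                             criterion = 0.143, soft_edge = 3) {
  n <- dim(half1$data)[1]
  if (window > n) stop("window larger than the map")
  stopifnot(window >= 8)
  vs <- half1$voxel_size
  wm <- soft_mask(window, "sphere", radius = window / 2 - soft_edge,
                  soft_edge_width = soft_edge)
  half <- window / 2
  centers <- seq(half, n - half, by = step)   # 1-based window start = c-half+1
  nc <- length(centers)
  coarse <- array(NA_real_, c(nc, nc, nc))
  for (a in seq_len(nc)) for (b in seq_len(nc)) for (cix in seq_len(nc)) {
    lo <- c(centers[a], centers[b], centers[cix]) - half + 1
    hi <- lo + window - 1
    w1 <- density_map(half1$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]], vs)
    w2 <- density_map(half2$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]], vs)
    cv <- fsc(w1, w2, wm)
    coarse[a, b, cix] <- as.numeric(resolution_at(cv, criterion))
  }
  # trilinear upsample of the coarse grid onto the full grid, with
  # nearest-edge extension outside the covered region
  if (nc == 1)
    return(density_map(array(coarse[1, 1, 1], c(n, n, n)), vs))
  ax <- pmin(pmax((0:(n - 1) - (centers[1] - 1)) / step, 0), nc - 1)
  i0 <- pmin(floor(ax), nc - 2); fx <- pmin(pmax(ax - i0, 0), 1)
  gather <- function(ix, jy, kz) coarse[cbind(ix + 1, jy + 1, kz + 1)]
  full <- array(0, c(n, n, n))
  idx <- as.matrix(expand.grid(a = seq_len(n), b = seq_len(n), c = seq_len(n)))
  ia <- i0[idx[, 1]]; ib <- i0[idx[, 2]]; ic <- i0[idx[, 3]]
  fa <- fx[idx[, 1]]; fb <- fx[idx[, 2]]; fc <- fx[idx[, 3]]
  acc <- 0
  for (da in 0:1) for (db in 0:1) for (dc in 0:1) {
    w <- (if (da == 1) fa else 1 - fa) * (if (db == 1) fb else 1 - fb) *
      (if (dc == 1) fc else 1 - fc)
    acc <- acc + w * gather(ia + da, ib + db, ic + dc)
  }
  full[] <- acc
  density_map(full, vs)
}

#' B-factor sharpening
#'
#' Scales Fourier amplitudes by `exp(-B k^2 / 4)` (negative B sharpens) and
#' optionally applies a post-sharpening low-pass filter.
#'
#' @param map a `density_map`.
#' @param B B-factor in Angstrom^2 (e.g. -1400 to sharpen).
#' @param post_lowpass_A optional low-pass resolution (Angstrom).
#' @return sharpened `density_map`.
#' @export
bfactor_sharpen <- function(map, B, post_lowpass_A = NULL) {
  stopifnot(abs(B) < 1e5)
  n <- dim(map$data)[1]
  k <- freq_grid(n, map$voxel_size)$kmag
  out <- apply_transfer(map, exp(-B * k^2 / 4))
  if (!is.null(post_lowpass_A)) out <- lowpass_map(out, post_lowpass_A)
  out
}

#' Local masked refinement with map recombination
#'
#' Runs one alignment pass per focus mask (each mask multiplied onto the
#' reference during scoring), then recombines: the combined map is
#' `sum(mask_i * avg_i) / sum(mask_i)` wherever the mask sum exceeds a small
#' floor, and 0 elsewhere. This lets locally flexible regions be averaged at
#' their own best pose.
#'
#' @param subs list of particle `density_map`s.
#' @param table particle table with current poses.
#' @param ref global reference.
#' @param masks list of `density_map` masks (e.g. from [soft_mask()]).
#' @param schedule [alignment_schedule()] for the local passes.
#' @param wedge wedge (array, [wedge_spec()], or list).
#' @param sym_order symmetry applied to each local average.
#' @param eps mask-sum floor below which the combined map is set to 0.
#' @return list: `map` (combined `density_map`), `locals` (per-mask
#'   [iterate_alignment()] results).
#' @export
local_align_and_combine <- function(subs, table, ref, masks, schedule,
                                    wedge = NULL, sym_order = 1, eps = 1e-3) {
  stopifnot(length(masks) >= 1)
  n <- dim(ref$data)[1]
  num <- array(0, c(n, n, n))
  den <- array(0, c(n, n, n))
  locals <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]$data
    if (sum(m) == 0) stop(sprintf("mask %d has zero coverage", i))
    res <- iterate_alignment(subs, table, ref, schedule, wedge = wedge,
                             sym_order = sym_order, mask = masks[[i]]$data)
    locals[[i]] <- res
    num <- num + m * res$reference$data
    den <- den + m
  }
  comb <- ifelse(den > eps, num / pmax(den, eps), 0)
  list(map = as_map_like(ref, array(comb, c(n, n, n))), locals = locals)
}
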