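#' Multireference classification
#'
#' The substoichiometric-ligand localization procedure: each particle is
#' aligned against every reference and assigned to the one giving the highest
#' constrained cross-correlation (ties to the lowest class index); class
#' averages are then re-formed and the process repeated. With two references
#' (ligand-bound vs unbound) and three iterations this is the standard
#' approach for separating a mixed leaf population.
#'
#' @param subs list of particle `density_map`s.
#' @param table particle table with current poses (row i = `subs[[i]]`).
#' @param refs list of >= 2 reference `density_map`s.
#' @param n_iterations number of classify/re-average rounds (default 3).
#' @param wedge wedge (array, [wedge_spec()], or per-particle list).
#' @param mask optional real-space mask on references during scoring.
#' @param cone_deg,cone_step,inplane_range,inplane_step,shift_limit local
#'   search grid for the per-reference alignment.
#' @param lowpass_A optional scoring low-pass (Angstrom).
#' @return list: `labels` (integer per particle), `class_maps` (list of
#'   `density_map`s), `table` (with `class` and updated poses), `history`
#'   (per-iteration class sizes).
#' @export
multireference_classify <- function(subs, table, refs, n_iterations = 3,
                                    wedge = NULL, mask = NULL,
                                    cone_deg = 6, cone_step = 3,
                                    inplane_range = 6, inplane_step = 3,
                                    shift_limit = 2, lowpass_A = NULL) {
  stopifnot(length(refs) >= 2, n_iterations >= 1,
            length(subs) == nrow(table))
  nref <- length(refs)
  labels <- rep(1L, length(subs))
  history <- NULL
  for (it in seq_len(n_iterations)) {
    poses <- vector("list", length(subs))
    ccs <- numeric(length(subs))
    for (i in seq_along(subs)) {
      p0 <- row_pose(table, i)
      best_cc <- -Inf; best_cls <- 1L; best_pose <- p0
      for (r in seq_len(nref)) {
        res <- align_particle(subs[[i]], refs[[r]],
                              wedge = if (is.list(wedge) &&
                                          !inherits(wedge, "wedge_spec"))
                                wedge[[i]] else wedge,
                              cone_deg = cone_deg, cone_step = cone_step,
                              inplane_range = inplane_range,
                              inplane_step = inplane_step,
                              shift_limit = shift_limit,
                              lowpass_A = lowpass_A,
                              init_pose = p0, mask = mask)
        if (res$cc > best_cc + 1e-12) {   # strict: ties keep lowest index
          best_cc <- res$cc; best_cls <- r; best_pose <- res$pose
        }
      }
      labels[i] <- best_cls
      ccs[i] <- best_cc
      poses[[i]] <- best_pose
      table <- set_row_pose(table, i, best_pose)
    }
    table$cc <- ccs
    for (r in seq_len(nref)) {
      idx <- which(labels == r)
      if (length(idx) == 0) {
        warning(sprintf("class %d emptied at iteration %d; keeping its previous average", r, it))
        next
      }
      refs[[r]] <- average_particles(subs[idx], poses[idx],
                                     if (is.list(wedge) &&
                                         !inherits(wedge, "wedge_spec"))
                                       wedge[idx] else wedge)
    }
    history <- rbind(history, data.frame(iteration = it,
                                         t(tabulate(labels, nref))))
  }
  table$class <- labels
  list(labels = labels, class_maps = refs, table = table, history = history)
}

#' Atom set constructor
#'
#' A minimal coordinate/mass table: positions in Angstrom plus per-atom
#' weights, with optional residue/chain labels for selector resolution.
#'
#' @param x,y,z coordinates (Angstrom).
#' @param mass per-atom weights (> 0); defaults to 1.
#' @param chain,resno,elety optional labels (chain id, residue number, atom
#'   name).
#' @return data.frame of class `atom_set`.
#' @export
atom_set <- function(x, y, z, mass = 1, chain = NA, resno = NA, elety = NA) {
  df <- data.frame(x = x, y = y, z = z,
                   mass = rep_len(mass, length(x)),
                   chain = rep_len(chain, length(x)),
                   resno = rep_len(resno, length(x)),
                   elety = rep_len(elety, length(x)))
  stopifnot(all(is.finite(df$x + df$y + df$z)), all(df$mass > 0))
  class(df) <- c("atom_set", class(df))
  df
}

# Approximate atomic masses for the common protein elements.
element_masses <- c(H = 1, C = 12, N = 14, O = 16, P = 31, S = 32)

#' Read atoms from a PDB file
#'
#' Coordinate-only PDB reader (via bio3d): positions, element-derived masses,
#' residue numbers, chains and atom names are consumed; everything else is
#' ignored.
#'
#' @param path PDB file path.
#' @return an [atom_set()].
#' @export
read_pdb_atoms <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_pdb_atoms requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- sub("[0-9'].*$", "", trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                             substr(trimws(at$elety), 1, 1),
                                             at$elesy)))
  mass <- element_masses[toupper(elem)]
  mass[is.na(mass)] <- 12
  atom_set(at$x, at$y, at$z, mass = as.numeric(mass),
           chain = at$chain, resno = at$resno, elety = trimws(at$elety))
}

#' Simulate density from an atomic model
#'
#' Renders each atom as an isotropic 3D Gaussian of width
#' `sigma = sigma_factor * resolution` and integral proportional to its mass
#' (the molmap convention), on a cubic grid.
#'
#' @param atoms an [atom_set()].
#' @param resolution target resolution in Angstrom.
#' @param voxel_size Angstrom per voxel.
#' @param box box side in voxels.
#' @param origin position of the first voxel center (Angstrom).
#' @param sigma_factor Gaussian width per unit resolution (default 0.225).
#' @return a `density_map` whose integral (sum x voxel volume) equals the
#'   total mass.
#' @export
simulate_model_density <- function(atoms, resolution, voxel_size, box,
                                   origin = c(0, 0, 0), sigma_factor = 0.225) {
  sigma <- sigma_factor * resolution
  sv <- sigma / voxel_size
  arr <- array(0, c(box, box, box))
  pos_vox <- (cbind(atoms$x, atoms$y, atoms$z) -
              matrix(origin, nrow(atoms), 3, byrow = TRUE)) / voxel_size
  bad <- which(apply(pos_vox, 1, function(p)
    any(p - 3 * sv < 0) || any(p + 3 * sv > box - 1)))
  if (length(bad))
    stop("atoms outside the box (3-sigma support): rows ",
         paste(utils::head(bad, 10), collapse = ", "))
  amp <- atoms$mass / ((2 * pi)^1.5 * sigma^3) * voxel_size^3
  for (i in seq_len(nrow(atoms)))
    arr <- add_gaussian_blob(arr, pos_vox[i, ], sv, amp[i])
  density_map(arr, voxel_size, origin)
}

#' Model-versus-map difference map
#'
#' Subtracts the model density from the experimental map after least-squares
#' amplitude scaling of the model over the mask region.
#'
#' @param em_map experimental `density_map`.
#' @param model_map simulated model `density_map` (same grid).
#' @param mask optional weight array or `density_map` defining the scaling
#'   region (default: everywhere).
#' @return `density_map` of `em - s * model`; the fitted scale is attached as
#'   attribute `scale`.
#' @export
difference_map <- function(em_map, model_map, mask = NULL) {
  stopifnot(all(dim(em_map$data) == dim(model_map$data)))
  m <- if (is.null(mask)) 1 else if (inherits(mask, "density_map"))
    mask$data else mask
  denom <- sum(model_map$data^2 * m)
  if (denom == 0) stop("model map has no density inside the mask")
  s <- sum(em_map$data * model_map$data * m) / denom
  out <- as_map_like(em_map, em_map$data - s * model_map$data)
  attr(out, "scale") <- s
  out
}

#' Segment and rank extra densities
#'
#' Thresholds the difference map at `threshold_sigma` standard deviations,
#' labels connected components (6/18/26 connectivity) and ranks them by voxel
#' volume, largest first.
#'
#' @param diff a difference `density_map`.
#' @param threshold_sigma threshold in map-sigma units.
#' @param connectivity 6, 18 or 26.
#' @param top_k number of leading components of interest.
#' @return list: `components` (data.frame rank, label, volume (voxels),
#'   centroid x/y/z (0-based voxels, density-weighted)), `top` (the first
#'   `top_k` rows), `threshold` (absolute density threshold used).
#' @export
segment_extra_densities <- function(diff, threshold_sigma = 1,
                                    connectivity = 26, top_k = 7) {
  stopifnot(connectivity %in% c(6, 18, 26), top_k >= 1)
  thr <- threshold_sigma * stats::sd(diff$data)
  mask <- diff$data > thr
  if (!any(mask))
    return(list(components = data.frame(rank = integer(0), label = integer(0),
                                        volume = integer(0), x = numeric(0),
                                        y = numeric(0), z = numeric(0)),
                top = NULL, threshold = thr))
  lab <- c_label_components(as.logical(mask), as.integer(dim(diff$data)),
                            as.integer(connectivity))
  lab <- array(lab, dim(diff$data))
  idx <- which(lab > 0)
  ijk <- arrayInd(idx, dim(lab)) - 1    # 0-based voxel coords
  li <- lab[idx]
  wt <- diff$data[idx]
  vol <- tabulate(li)
  cx <- rowsum(ijk[, 1] * wt, li) / rowsum(wt, li)
  cy <- rowsum(ijk[, 2] * wt, li) / rowsum(wt, li)
  cz <- rowsum(ijk[, 3] * wt, li) / rowsum(wt, li)
  comp <- data.frame(label = seq_along(vol), volume = vol,
                     x = as.numeric(cx), y = as.numeric(cy),
                     z = as.numeric(cz))
  comp <- comp[order(-comp$volume, comp$label), ]
  comp$rank <- seq_len(nrow(comp))
  comp <- comp[, c("rank", "label", "volume", "x", "y", "z")]
  rownames(comp) <- NULL
  list(components = comp, top = utils::head(comp, top_k), threshold = thr)
}

#' Rigid-body fit of an atomic model into a map
#'
#' Local maximization of the real-space correlation between the simulated
#' model density and the map over the six rigid-body parameters, starting
#' from `init`. Rotations act about the model centroid; shifts are in
#' Angstrom.
#'
#' @param atoms an [atom_set()].
#' @param map target `density_map`.
#' @param init starting `pose` (shift interpreted in Angstrom).
#' @param resolution rendering resolution for the model density (Angstrom).
#' @return list: `pose`, `cc`, `improved` (FALSE if the optimizer could not
#'   beat the starting pose, in which case `init` is returned).
#' @export
rigid_body_fit <- function(atoms, map, init = pose(), resolution) {
  box <- dim(map$data)[1]
  vs <- map$voxel_size
  ctr <- colMeans(cbind(atoms$x, atoms$y, atoms$z))
  render_cc <- function(par) {
    R <- euler_to_matrix(par[1:3])
    pos <- t(R %*% (t(cbind(atoms$x, atoms$y, atoms$z)) - ctr)) +
      matrix(ctr + par[4:6], nrow(atoms), 3, byrow = TRUE)
    at <- atoms; at$x <- pos[, 1]; at$y <- pos[, 2]; at$z <- pos[, 3]
    sim <- tryCatch(simulate_model_density(at, resolution, vs, box,
                                           origin = map$origin),
                    error = function(e) NULL)
    if (is.null(sim)) return(-1)
    stats::cor(as.numeric(sim$data), as.numeric(map$data))
  }
  p0 <- c(init$euler, init$shift)
  cc0 <- render_cc(p0)
  opt <- stats::optim(p0, function(p) -render_cc(p), method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  if (-opt$value <= cc0 + 1e-12)
    return(list(pose = init, cc = cc0, improved = FALSE))
  e <- opt$par
  list(pose = pose(e[1], e[2], e[3], e[4:6]), cc = -opt$value,
       improved = TRUE)
}

#' Cross-link distance screening
#'
#' Measures Euclidean distances between selected atom pairs and flags each
#' pair as satisfying the cross-link criterion iff its distance is strictly
#' below the cutoff (default 35 Angstrom, the standard lysine cross-linker
#' reach).
#'
#' @param atoms an [atom_set()] with `chain`/`resno`/`elety` labels.
#' @param pairs data.frame with columns `chain1`, `resno1`, `chain2`,
#'   `resno2` and optionally `elety1`/`elety2` (default atom name used
#'   otherwise).
#' @param cutoff_A distance criterion in Angstrom.
#' @param atom_name default atom to select within a residue (e.g. "CA" or the
#'   lysine side-chain "NZ").
#' @return data.frame: pair index, the selectors, `distance_A`, `satisfied`.
#' @export
crosslink_distances <- function(atoms, pairs, cutoff_A = 35,
                                atom_name = "CA") {
  stopifnot(cutoff_A > 0)
  resolve <- function(chain, resno, elety) {
    sel <- which(atoms$resno == resno & atoms$elety == elety &
                 (is.na(chain) | atoms$chain == chain))
    if (length(sel) != 1)
      stop(sprintf("selector chain=%s resno=%s atom=%s matched %d atoms",
                   chain, resno, elety, length(sel)))
    sel
  }
  out <- NULL
  for (i in seq_len(nrow(pairs))) {
    e1 <- if (!is.null(pairs$elety1)) pairs$elety1[i] else atom_name
    e2 <- if (!is.null(pairs$elety2)) pairs$elety2[i] else atom_name
    a <- resolve(pairs$chain1[i], pairs$resno1[i], e1)
    b <- resolve(pairs$chain2[i], pairs$resno2[i], e2)
    d <- sqrt((atoms$x[a] - atoms$x[b])^2 + (atoms$y[a] - atoms$y[b])^2 +
              (atoms$z[a] - atoms$z[b])^2)
    out <- rbind(out, data.frame(pair = i,
                                 chain1 = pairs$chain1[i], resno1 = pairs$resno1[i],
                                 chain2 = pairs$chain2[i], resno2 = pairs$resno2[i],
                                 distance_A = d, satisfied = d < cutoff_A))
  }
  rownames(out) <- NULL
  out
}

#' Maximum extension of an unstructured linker
#'
#' Fully extended contour length: residue count times the per-residue rise of
#' an extended polypeptide (~3.6 Angstrom). A 103-residue linker can reach
#' about 370 Angstrom.
#'
#' @param n_residues number of residues (>= 0).
#' @param rise_per_residue Angstrom per residue (default 3.6).
#' @return length in Angstrom.
#' @export
max_linker_extension <- function(n_residues, rise_per_residue = 3.6) {
  stopifnot(n_residues >= 0)
  n_residues * rise_per_residue
}
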