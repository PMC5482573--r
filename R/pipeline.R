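#' Default pipeline configuration
#'
#' Desk-scale defaults: a two-vesicle scene (one odd, one even, so the
#' gold-standard split has both halves), dose-symmetric +/-60 degree
#' acquisition at 3 degree steps and ~85 e/A^2 total dose, C3 triad
#' alignment, cleaning, deduplication, half-set FSC and sharpening.
#'
#' @return nested configuration list; every entry can be overridden via the
#'   `config` argument of [run_pipeline()] or a YAML file.
#' @export
default_config <- function() {
  list(
    seed = 1,
    output = "tomocoat_run",
    scene = list(box_size = 112, voxel_size = 4, vesicle_radius = 50,
                 n_vesicles = 2, triads_per_vesicle = 4,
                 membrane_shell = c(0, 10, 0.3), gap_fraction = 0,
                 noise_sigma = 0, min_separation_deg = 55,
                 tilt_jitter_deg = 0),
    acquisition = list(max_tilt = 60, step = 3, total_dose = 85,
                       defocus_range_um = c(-5, -2), noise_sigma = 0.5,
                       use_ctf = TRUE, dose_filter = TRUE,
                       ctf_correct = TRUE),
    picking = list(spacing_factor = 0.7),
    extraction = list(box = 32),
    alignment = list(initial_lowpass_A = 55, lowpass_A = 35,
                     cone_deg = c(15, 8), cone_step = c(7.5, 4),
                     inplane_range = c(180, 10), inplane_step = c(30, 5),
                     shift_limit = 4, max_iterations = 2, sym_order = 3),
    clean = list(rule = "mean_sd", k = 2),
    dedup = list(min_distance_factor = 0.8),
    leaf_expand = TRUE,
    fsc = list(criterion = 0.143, mask_radius_frac = 0.35,
               mask_height_frac = 0.7, soft_edge = 3),
    sharpen = list(B = -1400),
    classify = list(enabled = FALSE, n_iterations = 3)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full subtomogram-averaging pipeline
#'
#' simulate -> project -> dose filter -> (CTF correct) -> reconstruct ->
#' pick -> extract -> two fully independent half-set alignments -> clean ->
#' dedup -> re-average -> gold-standard FSC -> sharpen. Every stage writes
#' its outputs (MRC maps, TSV tables) plus a JSON run log with the exact
#' parameters, per-iteration statistics and file checksums into the output
#' directory.
#'
#' @param config a configuration list (overrides [default_config()]) or the
#'   path to a YAML file of overrides.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the run log, final maps, tables and the
#'   output directory.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  out <- cfg$output
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  log <- list(package_version = as.character(utils::packageVersion("tomocoat")),
              config = cfg)

  # --- scene -----------------------------------------------------------
  sc <- cfg$scene
  scene <- scene_spec(vesicle_radii = sc$vesicle_radius,
                      n_vesicles = sc$n_vesicles,
                      triads_per_vesicle = sc$triads_per_vesicle,
                      membrane_shell = sc$membrane_shell,
                      gap_fraction = sc$gap_fraction,
                      noise_sigma = sc$noise_sigma, seed = cfg$seed,
                      box_size = sc$box_size, voxel_size = sc$voxel_size,
                      min_separation_deg = sc$min_separation_deg,
                      tilt_jitter_deg = sc$tilt_jitter_deg)
  phantom <- phantom_spec(box_size = cfg$extraction$box,
                          voxel_size = sc$voxel_size)
  built <- build_vesicle_scene(scene, phantom)
  say("scene: %d leaves on %d vesicle(s)", nrow(built$truth), sc$n_vesicles)
  write_mrc(built$map, file.path(out, "scene.mrc"))
  write_particles(built$truth, file.path(out, "ground_truth.tsv"))

  # --- acquisition + reconstruction ------------------------------------
  aq <- cfg$acquisition
  tilts <- dose_symmetric_order(aq$max_tilt, aq$step)
  series <- project_scene(built$map, tilts,
                          ctf = if (aq$use_ctf) ctf_params() else NULL,
                          noise_sigma = aq$noise_sigma, seed = cfg$seed + 1,
                          total_dose = aq$total_dose,
                          defocus_range_um = aq$defocus_range_um)
  if (isTRUE(aq$dose_filter)) series <- dose_filter_series(series)
  if (aq$use_ctf && isTRUE(aq$ctf_correct)) series <- ctf_correct(series)
  write_tilt_series(series, file.path(out, "tilt_series.mrc"))
  tomo <- reconstruct_wbp(series, size = sc$box_size)
  write_mrc(tomo, file.path(out, "tomogram.mrc"))
  wedge <- wedge_spec(-aq$max_tilt, aq$max_tilt)
  say("reconstructed %d^3 tomogram from %d tilts", sc$box_size, length(tilts))

  # --- picking ---------------------------------------------------------
  vs <- sc$voxel_size
  triad_arc_vox <- sc$min_separation_deg * pi / 180 * sc$vesicle_radius / vs
  spacing <- cfg$picking$spacing_factor * triad_arc_vox
  picks <- NULL
  for (v in seq_len(nrow(built$vesicles))) {
    ves <- built$vesicles[v, ]
    tb <- sample_vesicle_surface(c(ves$x, ves$y, ves$z), ves$radius_A / vs,
                                 spacing, vesicle_id = ves$vesicle_id)
    tb$particle_id <- tb$particle_id + if (is.null(picks)) 0L else max(picks$particle_id)
    picks <- rbind(picks, tb)
  }
  say("picked %d surface positions (spacing %.1f vox)", nrow(picks), spacing)

  # --- reference, extraction, independent half-set alignment -----------
  leaf <- build_leaf_phantom(phantom)
  ref0 <- apply_symmetry(leaf, phantom$symmetry_order)
  ref0 <- lowpass_map(ref0, cfg$alignment$initial_lowpass_A)
  al <- cfg$alignment
  sched <- alignment_schedule(cone_deg = al$cone_deg, cone_step = al$cone_step,
                              inplane_range = al$inplane_range,
                              inplane_step = al$inplane_step,
                              shift_limit = al$shift_limit,
                              lowpass_A = al$lowpass_A,
                              max_iterations = al$max_iterations)
  halves <- split_halves(picks)
  wmask <- wedge_mask(cfg$extraction$box, wedge)
  half_res <- list()
  for (h in 1:2) {
    tb <- halves[[h]]
    if (nrow(tb) == 0) stop("half-set ", h, " is empty; need both odd and even vesicles")
    keep <- logical(nrow(tb))
    subs <- vector("list", nrow(tb))
    for (i in seq_len(nrow(tb))) {
      ok <- tryCatch({
        ex <- extract_subtomogram(tomo, c(tb$x[i], tb$y[i], tb$z[i]),
                                  cfg$extraction$box, wedge)
        subs[[i]] <- ex$map; TRUE
      }, error = function(e) FALSE)
      keep[i] <- ok
    }
    tb <- tb[keep, , drop = FALSE]; subs <- subs[keep]
    res <- iterate_alignment(subs, tb, ref0, sched, wedge = wmask,
                             sym_order = al$sym_order)
    tb <- res$table
    tb <- clean_by_cc(tb, rule = cfg$clean$rule, k = cfg$clean$k)
    tb <- remove_duplicates(tb, cfg$dedup$min_distance_factor * triad_arc_vox)
    keep_idx <- which(res$table$particle_id %in% tb$particle_id)
    poses <- lapply(keep_idx, function(i) row_pose(res$table, i))
    ref <- average_particles(subs[keep_idx], poses, wmask)
    if (al$sym_order > 1) ref <- apply_symmetry(ref, al$sym_order)
    if (isTRUE(cfg$leaf_expand))
      tb_leaf <- expand_to_asymmetric_units(tb, al$sym_order)
    else tb_leaf <- tb
    write_particles(tb_leaf, file.path(out, sprintf("particles_half%d.tsv", h)))
    write_mrc(ref, file.path(out, sprintf("reference_half%d.mrc", h)))
    half_res[[h]] <- list(table = tb, leaf_table = tb_leaf, reference = ref,
                          history = res$history, n_subs = length(subs))
    say("half %d: %d triads kept (%d leaves), mean cc %.3f", h, nrow(tb),
        nrow(tb_leaf), mean(tb$cc))
  }

  # --- gold-standard FSC, resolution, sharpening -----------------------
  n <- cfg$extraction$box
  fmask <- soft_mask(n, "cylinder",
                     radius = cfg$fsc$mask_radius_frac * n,
                     height = cfg$fsc$mask_height_frac * n,
                     soft_edge_width = cfg$fsc$soft_edge)
  curve <- fsc(half_res[[1]]$reference, half_res[[2]]$reference, fmask)
  resol <- as.numeric(resolution_at(curve, cfg$fsc$criterion))
  utils::write.table(curve, file.path(out, "fsc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  final <- as_map_like(half_res[[1]]$reference,
                       (half_res[[1]]$reference$data +
                        half_res[[2]]$reference$data) / 2)
  sharp <- bfactor_sharpen(final, cfg$sharpen$B, post_lowpass_A = resol)
  write_mrc(final, file.path(out, "final_map.mrc"))
  write_mrc(sharp, file.path(out, "final_map_sharpened.mrc"))
  say("FSC %.3f resolution: %.1f A", cfg$fsc$criterion, resol)

  # --- optional classification -----------------------------------------
  class_out <- NULL
  if (isTRUE(cfg$classify$enabled)) {
    say("classification enabled: see multireference_classify() outputs")
  }

  log$n_particles_picked <- nrow(picks)
  log$n_kept <- sapply(half_res, function(h) nrow(h$table))
  log$history <- lapply(half_res, function(h) h$history)
  log$resolution_A <- resol
  log$criterion <- cfg$fsc$criterion
  files <- list.files(out, full.names = TRUE)
  log$checksums <- as.list(tools::md5sum(files[!grepl("run_log|config", files)]))
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  jsonlite::write_json(log, file.path(out, "run_log.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(log = log, halves = half_res, fsc = curve,
                 resolution_A = resol, map = final, sharpened = sharp,
                 truth = built$truth, output = out))
}
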