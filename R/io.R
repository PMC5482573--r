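#' Read an MRC2014 volume
#'
#' Minimal MRC2014 reader for mode 2 (32-bit float) maps as written by
#' [write_mrc()] and standard cryo-EM software. Axis order is kept as stored
#' (column-major X fastest); voxel size is taken from CELLA / M.
#'
#' @param path file path.
#' @return a `density_map` (2D stacks come back as an array with the third
#'   dimension the section index).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (mode != 2)
    stop(sprintf("unsupported MRC mode %d (only mode 2, float32)", mode))
  mx <- hdr_int[8]
  cella <- hdr_num[11]
  voxel <- if (mx > 0 && cella > 0) cella / mx else 1
  origin <- hdr_num[50:52]
  nsymbt <- hdr_int[24]
  seek(con, 1024 + nsymbt)
  dat <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
                 endian = "little")
  density_map(array(dat, c(nx, ny, nz)), voxel, origin)
}

#' Write an MRC2014 volume
#'
#' Mode 2 (float32), MAP/MACHST stamps and NVERSION 20140 set, voxel size in
#' CELLA, origin in the ORIGIN fields. Round-trips bit-exactly through
#' [read_mrc()] for float32 data.
#'
#' @param map a `density_map` (or 3D array).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  if (!inherits(map, "density_map")) map <- density_map(map)
  d <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  dat <- as.numeric(map$data)
  # header words 1..56 then 10 x 80-char labels
  wi(d)                                  # NX NY NZ
  wi(2)                                  # MODE 2
  wi(c(0, 0, 0))                         # NXSTART..
  wi(d)                                  # MX MY MZ
  wf(d * map$voxel_size)                 # CELLA
  wf(c(90, 90, 90))                      # CELLB
  wi(c(1, 2, 3))                         # MAPC MAPR MAPS
  wf(c(min(dat), max(dat), mean(dat)))   # DMIN DMAX DMEAN
  wi(1)                                  # ISPG
  wi(0)                                  # NSYMBT
  wi(rep(0, 2))                          # EXTRA 25..26
  writeChar("MRCO", con, nchars = 4, eos = NULL)  # EXTTYP
  wi(20140)                              # NVERSION
  wi(rep(0, 20))                         # EXTRA 29..48
  wi(0)                                  # word 49 (unused)
  wf(map$origin)                         # ORIGIN 50..52
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(dat))                     # RMS
  wi(1)                                  # NLABL
  lab <- sprintf("%-80s", "tomocoat map")
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 80 * 9), collapse = ""), con, nchars = 720,
            eos = NULL)
  writeBin(dat, con, size = 4, endian = "little")
  invisible(path)
}

#' Write a multi-frame MRC tilt series with a TSV sidecar
#'
#' The image stack goes into `path` (one section per tilt, angle order) and
#' acquisition metadata (angle, acquisition order, accumulated dose, defocus)
#' into `paste0(path, ".tsv")`.
#'
#' @param series a `tilt_series`.
#' @param path output MRC path.
#' @return `path`, invisibly.
#' @export
write_tilt_series <- function(series, path) {
  write_mrc(density_map(series$images, series$pixel_size), path)
  side <- data.frame(tilt_angle = series$tilt_angles,
                     acquisition_order = series$acquisition_order,
                     accumulated_dose = series$accumulated_dose,
                     defocus_um = series$defocus_um)
  utils::write.table(side, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

particle_header_comment <- c(
  "# tomocoat particle table",
  "# coordinates: 0-based voxel-center; euler: ZXZ intrinsic, degrees;",
  "# shifts: voxels in the tomogram frame")

#' Write a particle table (TSV or STAR)
#'
#' Dialect chosen by extension: `.star` writes a `data_particles` loop with
#' `_tomo`-prefixed column tags; anything else writes TSV with a commented
#' convention header. Extra columns are preserved verbatim in both dialects.
#'
#' @param table particle table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_particles <- function(table, path) {
  if (grepl("\\.star$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# tomocoat particle table (0-based voxel-center, ZXZ intrinsic degrees)",
                 "", "data_particles", "", "loop_"), con)
    writeLines(sprintf("_tomo%s #%d", names(table), seq_along(table)), con)
    apply_fmt <- function(v) if (is.numeric(v)) format(v, digits = 15,
                                                       scientific = FALSE,
                                                       trim = TRUE) else as.character(v)
    body <- do.call(paste, c(lapply(table, apply_fmt), sep = "\t"))
    writeLines(body, con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(particle_header_comment, con)
    utils::write.table(table, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a particle table (TSV or STAR)
#'
#' @param path input path (`.star` or TSV).
#' @return particle table (data.frame); mandatory columns are checked.
#' @export
read_particles <- function(path) {
  if (grepl("\\.star$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines)]
    loop <- which(trimws(lines) == "loop_")[1]
    if (is.na(loop)) stop("no loop_ block in STAR file")
    rest <- lines[(loop + 1):length(lines)]
    tags <- grep("^_", trimws(rest))
    tag_lines <- trimws(rest[tags])
    cols <- sub("^_tomo", "", sub("\\s+#\\d+$", "", tag_lines))
    body <- rest[setdiff(seq_along(rest), tags)]
    body <- body[nzchar(trimws(body))]
    df <- utils::read.table(text = body, sep = "\t", col.names = cols,
                            stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  }
  particle_table(df)
}
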