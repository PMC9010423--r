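# 3-D gas-probability grids: construction, statistics, accumulation from
# aligned trajectory frames, and CCP4/MRC + OpenDX map I/O.
#
# Convention: `values` is an R array indexed [i, j, k] along x, y, z; the
# in-memory vector is therefore x-fastest, matching an MRC file written with
# MAPC,MAPR,MAPS = 1,2,3. `origin` is the centre of voxel [1,1,1].

#' 3-D scalar occupancy grid
#'
#' @param values 3-D numeric array (units atoms/voxel), finite and >= 0.
#' @param origin Centre of voxel `[1,1,1]` in angstroms.
#' @param spacing Voxel edge in angstroms (default 0.5).
#' @return Object of class `density_grid`.
#' @export
density_grid <- function(values, origin = c(0, 0, 0), spacing = 0.5) {
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  stopifnot(spacing > 0, length(origin) == 3)
  if (!all(is.finite(values))) stop("grid values must be finite")
  if (any(values < 0)) stop("grid values must be non-negative")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = spacing, dims = dim(values)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  s <- grid_stats(x)
  cat(sprintf("density_grid %d x %d x %d, spacing %.3g A, mean %.4g, sd %.4g, max %.4g\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, s$mean, s$std, s$max))
  invisible(x)
}

#' Mean, standard deviation and maximum over a sampling box
#'
#' The standard deviation is the population value (divisor N), matching the
#' r.m.s.-from-mean convention used for map thresholding.
#'
#' @param grid A [density_grid()].
#' @return List with `mean`, `std`, `max` (atoms/voxel).
#' @export
grid_stats <- function(grid) {
  v <- as.numeric(grid$values)
  if (!length(v)) stop("empty grid")
  m <- mean(v)
  list(mean = m, std = sqrt(mean((v - m)^2)), max = max(v))
}

#' Peak detection threshold: mean + k * sigma
#'
#' @param stats Either a [grid_stats()] list or a [density_grid()].
#' @param k Sigma multiplier (default 5).
#' @return Threshold in atoms/voxel.
#' @export
peak_threshold <- function(stats, k = 5) {
  if (inherits(stats, "density_grid")) stats <- grid_stats(stats)
  stats$mean + k * stats$std
}

#' Voxel centre coordinates for integer voxel indices (1-based)
#' @keywords internal
voxel_centre <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep((idx - 1) * grid$spacing, 2, grid$origin, `+`)
}

# 1-based voxel index of a point; nearest-voxel (centre) convention
point_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  floor(sweep(xyz, 2, grid$origin, `-`) / grid$spacing + 0.5) + 1
}

#' Ordered trajectory frames of protein beads and gas positions
#'
#' @param reference N x 3 matrix of reference protein bead coordinates.
#' @param frames List of frames, each a list with `protein` (N x 3) and
#'   `gas` (M x 3, M may vary by frame; may have zero rows).
#' @param frame_interval Optional time between frames (arbitrary units).
#' @export
trajectory_frames <- function(reference, frames, frame_interval = NULL) {
  reference <- as.matrix(reference)
  if (!length(frames)) stop("at least one frame is required")
  for (f in frames) {
    if (nrow(as.matrix(f$protein)) != nrow(reference))
      stop("per-frame protein bead count must equal the reference")
  }
  structure(list(reference = reference, frames = frames,
                 frame_interval = frame_interval),
            class = "trajectory_frames")
}

#' Accumulate a time-averaged gas occupancy grid from trajectory frames
#'
#' Each frame is rigid-aligned to the reference on its protein beads
#' (Kabsch); the same transform is applied to the frame's gas positions,
#' each of which adds one count to its containing voxel. Final values are
#' divided by the frame count, giving time-averaged atoms/voxel. Gas
#' positions outside the box are dropped and counted.
#'
#' @param traj A [trajectory_frames()] object.
#' @param spacing Voxel edge in angstroms (default 0.5).
#' @param box 2 x 3 matrix `rbind(min, max)` of the sampling box corners in
#'   angstroms; defaults to the reference bounding box padded by 8 A.
#' @return A [density_grid()] with attributes `n_frames`, `n_dropped` and
#'   `n_binned`.
#' @export
accumulate_density <- function(traj, spacing = 0.5, box = NULL) {
  stopifnot(inherits(traj, "trajectory_frames"))
  nf <- length(traj$frames)
  if (nf < 1) stop("zero frames")
  if (is.null(box)) {
    box <- rbind(apply(traj$reference, 2, min) - 8,
                 apply(traj$reference, 2, max) + 8)
  }
  box <- as.matrix(box)
  dims <- pmax(1L, as.integer(floor((box[2, ] - box[1, ]) / spacing)) + 1L)
  counts <- array(0, dims)
  origin <- box[1, ]
  grid0 <- list(origin = origin, spacing = spacing)
  dropped <- 0L
  binned <- 0L
  for (f in traj$frames) {
    prot <- as.matrix(f$protein)
    gas <- as.matrix(f$gas)
    if (!nrow(gas)) next
    fit <- superpose(prot, traj$reference)
    gas_al <- apply_transform(gas, fit$rotation, fit$translation)
    idx <- floor(sweep(gas_al, 2, origin, `-`) / spacing + 0.5) + 1
    inb <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
      idx[, 2] >= 1 & idx[, 2] <= dims[2] &
      idx[, 3] >= 1 & idx[, 3] <= dims[3]
    dropped <- dropped + sum(!inb)
    binned <- binned + sum(inb)
    if (any(inb)) {
      lin <- idx[inb, 1] + dims[1] * (idx[inb, 2] - 1) +
        dims[1] * dims[2] * (idx[inb, 3] - 1)
      tab <- tabulate(lin, nbins = prod(dims))
      counts <- counts + array(tab, dims)
    }
  }
  g <- density_grid(counts / nf, origin = origin, spacing = spacing)
  attr(g, "n_frames") <- nf
  attr(g, "n_dropped") <- dropped
  attr(g, "n_binned") <- binned
  g
}

#' Read a density grid from CCP4/MRC or OpenDX
#'
#' MRC/CCP4 files are read as mode 2 (32-bit float) with the axis order
#' normalized to x-fastest; OpenDX text maps are transposed from their
#' z-fastest layout. Grids are expected to use a uniform cubic voxel.
#'
#' @param path Map file path.
#' @param format `"mrc"`, `"ccp4"` (synonymous) or `"dx"`; `"auto"` guesses
#'   from the extension.
#' @return A [density_grid()].
#' @export
read_map <- function(path, format = c("auto", "mrc", "ccp4", "dx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.dx$", path, ignore.case = TRUE)) "dx" else "mrc"
  if (format == "dx") read_dx(path) else read_mrc(path)
}

#' @rdname read_map
#' @param grid A [density_grid()] to write.
#' @export
write_map <- function(grid, path, format = c("auto", "mrc", "ccp4", "dx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dx$", path, ignore.case = TRUE)) "dx" else "mrc"
  if (format == "dx") write_dx(grid, path) else write_mrc(grid, path)
  invisible(path)
}

read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop("not an MRC/CCP4 map (file shorter than the 1024-byte header): ",
         path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  mapcrs <- hdr_int[17:19]
  seek(con, 52 * 4)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MAP ") && mode != 2)
    stop("unrecognized map format: mode=", mode, ", magic='", magic,
         "', dims=", paste(nxyz, collapse = "x"))
  if (mode != 2)
    stop("only mode 2 (32-bit float) MRC maps are supported; got mode ",
         mode)
  mxyz <- hdr_int[8:10]
  cella <- hdr_num[11:13]
  spacing <- cella[1] / max(mxyz[1], 1)
  seek(con, 49 * 4)
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 23 * 4)
  nsymbt <- hdr_int[24]
  seek(con, 1024 + nsymbt)
  nvox <- prod(nxyz)
  v <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(v) != nvox)
    stop("truncated map data: expected ", nvox, " voxels, got ", length(v))
  arr <- array(v, nxyz)  # file order: axis mapc fastest
  perm <- order(mapcrs)  # normalize to x-fastest
  if (!all(perm == 1:3)) arr <- aperm(arr, perm)
  density_grid(pmax(arr, 0), origin = origin, spacing = spacing)
}

write_mrc <- function(grid, path) {
  dims <- grid$dims
  v <- grid$values
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  s <- grid_stats(grid)
  wi(dims)                       # NX NY NZ (x fastest)
  wi(2)                          # MODE 2 float
  wi(c(0, 0, 0))                 # NXSTART..
  wi(dims)                       # MX MY MZ
  wf(dims * grid$spacing)        # CELLA
  wf(c(90, 90, 90))              # CELLB
  wi(c(1, 2, 3))                 # MAPC MAPR MAPS
  wf(c(min(v), max(v), s$mean))  # DMIN DMAX DMEAN
  wi(1)                          # ISPG
  wi(0)                          # NSYMBT
  wi(rep(0, 25))                 # EXTRA (words 26-50 start); 25 words
  wf(grid$origin)                # ORIGIN x y z (words 50-52)
  writeChar("MAP ", con, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(s$std)                      # RMS
  wi(0)                          # NLABL
  writeBin(raw(800), con)        # labels
  wf(as.numeric(v))
  invisible(path)
}

read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file is not an OpenDX map: ", path)
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (!length(gp)) stop("not an OpenDX grid (no 'gridpositions' object): ",
                        path)
  dims <- as.integer(utils::tail(strsplit(trimws(gp[1]), "[[:space:]]+")[[1]], 3))
  org <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(org), "[[:space:]]+")[[1]][2:4])
  deltas <- grep("^delta", lines, value = TRUE)
  dm <- t(vapply(deltas[1:3], function(s)
    as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]][2:4]), numeric(3)))
  spacing <- dm[1, 1]
  if (max(abs(dm - diag(rep(spacing, 3)))) > 1e-6)
    stop("only axis-aligned cubic-voxel OpenDX grids are supported")
  start <- grep("data follows", lines)[1] + 1
  end <- length(lines)
  obj_end <- grep("^(object|attribute|component)", lines[start:end])
  if (length(obj_end)) end <- start + min(obj_end) - 2
  v <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "[[:space:]]+")))
  v <- v[!is.na(v)]
  if (length(v) != prod(dims))
    stop("OpenDX data block has ", length(v), " values, expected ",
         prod(dims))
  arr <- aperm(array(v, rev(dims)), 3:1)  # DX is z-fastest
  density_grid(pmax(arr, 0), origin = origin, spacing = spacing)
}

write_dx <- function(grid, path) {
  dims <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(dims))), con)
  v <- as.numeric(aperm(grid$values, 3:1))  # z-fastest on disk
  pad <- (-length(v)) %% 3
  vv <- c(v, rep(NA, pad))
  m <- matrix(vv, ncol = 3, byrow = TRUE)
  rows <- apply(m, 1, function(r)
    paste(sprintf("%.9g", r[!is.na(r)]), collapse = " "))
  writeLines(rows, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Molar concentration of gas atoms in a simulation box
#'
#' @param n_atoms Number of gas atoms in the box.
#' @param box_dims Box edge lengths in angstroms (length 3).
#' @return Concentration in mol/L.
#' @export
gas_molarity <- function(n_atoms, box_dims) {
  stopifnot(n_atoms > 0, length(box_dims) == 3, all(box_dims > 0))
  avogadro <- 6.02214076e23
  vol_litre <- prod(box_dims) * 1e-27
  n_atoms / avogadro / vol_litre
}

#' Bulk reference density of gas atoms, in atoms per voxel
#'
#' The nominal bulk density used as the Boltzmann reference: gas atoms
#' spread uniformly over the simulation box, expressed per voxel of the
#' analysis grid.
#'
#' @param n_atoms Number of gas atoms in the box.
#' @param box_dims Box edge lengths in angstroms (length 3).
#' @param spacing Analysis voxel edge in angstroms (default 0.5).
#' @return Atoms per voxel.
#' @export
bulk_reference_density <- function(n_atoms, box_dims, spacing = 0.5) {
  stopifnot(n_atoms > 0, all(box_dims > 0), spacing > 0)
  n_atoms / prod(box_dims) * spacing^3
}
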