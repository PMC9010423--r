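# Classification of noble-gas sites into the three crystallographic
# groups: internal cavity, lipid-facing surface, and membrane-plane
# crystal contact. Burial is decided by an exterior flood fill over a
# probe-accessible voxel grid; crystal contacts by symmetry expansion.

#' Van der Waals radii used by the burial test (angstroms)
#' @export
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

#' Default vdW radius for elements not in [VDW_RADII]
#' @keywords internal
DEFAULT_VDW <- 1.70

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- DEFAULT_VDW
  unname(r)
}

#' Membrane slab annotation (evidence only)
#'
#' @param z_min,z_max Slab bounds along the membrane normal, angstroms.
#' @param axis Unit membrane normal (default +z).
#' @export
membrane_slab <- function(z_min, z_max, axis = c(0, 0, 1)) {
  stopifnot(z_min < z_max, length(axis) == 3)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(axis = axis, z_min = z_min, z_max = z_max),
            class = "membrane_slab")
}

# Probe-accessibility grid over the model's bounding box; returns the grid
# geometry, the free mask (voxel centre farther than vdW + probe from every
# atom) and the exterior-connected free mask (6-connectivity flood fill
# from the box boundary).
accessibility_grid <- function(model, probe_radius = 1.2,
                               grid_spacing = 1.0, pad = NULL) {
  xyz <- coords(model)
  radii <- vdw_radius(model$atoms$element)
  if (is.null(pad)) pad <- max(radii) + probe_radius + 2 * grid_spacing
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- as.integer(floor((hi - lo) / grid_spacing)) + 1L
  free <- array(TRUE, dims)
  # block voxels within (vdW + probe) of each atom, over a local sub-box
  for (a in seq_len(nrow(xyz))) {
    r <- radii[a] + probe_radius
    i0 <- pmax(1L, as.integer(floor((xyz[a, ] - r - lo) / grid_spacing)) + 1L)
    i1 <- pmin(dims, as.integer(ceiling((xyz[a, ] + r - lo) / grid_spacing)) + 1L)
    if (any(i0 > i1)) next
    ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]; kk <- i0[3]:i1[3]
    cx <- lo[1] + (ii - 1) * grid_spacing
    cy <- lo[2] + (jj - 1) * grid_spacing
    cz <- lo[3] + (kk - 1) * grid_spacing
    d2 <- outer(outer((cx - xyz[a, 1])^2, (cy - xyz[a, 2])^2, `+`),
                (cz - xyz[a, 3])^2, `+`)
    sub <- free[ii, jj, kk, drop = FALSE]
    sub[d2 <= r^2] <- FALSE
    free[ii, jj, kk] <- sub
  }
  # exterior = free voxels reachable from the boundary; iterative dilation
  ext <- array(FALSE, dims)
  ext[1, , ] <- free[1, , ]; ext[dims[1], , ] <- free[dims[1], , ]
  ext[, 1, ] <- ext[, 1, ] | free[, 1, ]
  ext[, dims[2], ] <- ext[, dims[2], ] | free[, dims[2], ]
  ext[, , 1] <- ext[, , 1] | free[, , 1]
  ext[, , dims[3]] <- ext[, , dims[3]] | free[, , dims[3]]
  repeat {
    grown <- ext
    grown[-1, , ] <- grown[-1, , ] | ext[-dims[1], , ]
    grown[-dims[1], , ] <- grown[-dims[1], , ] | ext[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | ext[, -dims[2], ]
    grown[, -dims[2], ] <- grown[, -dims[2], ] | ext[, -1, ]
    grown[, , -1] <- grown[, , -1] | ext[, , -dims[3]]
    grown[, , -dims[3]] <- grown[, , -dims[3]] | ext[, , -1]
    grown <- grown & free
    if (identical(grown, ext)) break
    ext <- grown
  }
  list(origin = lo, spacing = grid_spacing, dims = dims, free = free,
       exterior = ext)
}

#' Is a point buried (not probe-connected to the exterior)?
#'
#' A point is internal when its voxel cannot be connected to the bounding
#' box exterior by a flood fill over voxels whose distance to every atom
#' exceeds that atom's vdW radius plus `probe_radius`. A point whose own
#' voxel is blocked (the site presses against the vdW envelope of the
#' walls) inherits the exterior status of the nearest free voxel within
#' 2 A; with no free voxel that close it is enclosed in the wall and
#' counts as buried.
#'
#' @param model A [structure_model()] providing the occluding atoms.
#' @param points M x 3 matrix of query positions.
#' @param probe_radius Probe radius in angstroms (default 1.2).
#' @param grid_spacing Flood-fill voxel size in angstroms (default 1.0).
#' @param acc Optional precomputed [accessibility_grid()] result.
#' @return Logical vector of length M.
#' @export
is_buried <- function(model, points, probe_radius = 1.2, grid_spacing = 1.0,
                      acc = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (is.null(acc))
    acc <- accessibility_grid(model, probe_radius, grid_spacing)
  idx <- floor(sweep(points, 2, acc$origin, `-`) / acc$spacing + 0.5) + 1
  vapply(seq_len(nrow(points)), function(m) {
    i <- idx[m, ]
    if (any(i < 1) || any(i > acc$dims)) return(FALSE)  # outside the box
    if (acc$free[i[1], i[2], i[3]])
      return(!acc$exterior[i[1], i[2], i[3]])
    # blocked voxel: decide by the nearest free voxel within 2 A
    w <- as.integer(ceiling(2 / acc$spacing))
    ii <- max(1, i[1] - w):min(acc$dims[1], i[1] + w)
    jj <- max(1, i[2] - w):min(acc$dims[2], i[2] + w)
    kk <- max(1, i[3] - w):min(acc$dims[3], i[3] + w)
    sub_free <- which(acc$free[ii, jj, kk, drop = FALSE], arr.ind = TRUE)
    if (!nrow(sub_free)) return(TRUE)  # enclosed in the wall itself
    cen <- cbind(ii[sub_free[, 1]], jj[sub_free[, 2]], kk[sub_free[, 3]])
    pos <- sweep((cen - 1) * acc$spacing, 2, acc$origin, `+`)
    d2 <- rowSums(sweep(pos, 2, points[m, ])^2)
    near <- cen[which.min(d2), ]
    !acc$exterior[near[1], near[2], near[3]]
  }, logical(1))
}

#' Classify noble-gas sites into internal / crystal_contact / surface
#'
#' Precedence: internal first (exterior flood-fill burial test), then
#' crystal_contact (any non-identity symmetry-image atom within
#' `contact_cutoff`), otherwise surface. A membrane slab, when supplied, is
#' recorded as evidence only and never changes the label. Sites farther
#' than 15 A from every protein atom are labelled surface with a
#' "detached site" warning.
#'
#' @param model A [structure_model()]; protein atoms are used for burial,
#'   and its cell + symops (if present) for contact detection.
#' @param sites data.frame of gas sites with columns `x`, `y`, `z` and
#'   optionally `id`, `element`, `occ`, `b`.
#' @param contact_cutoff Gas-to-image-atom contact distance, angstroms
#'   (default 4).
#' @param probe_radius Burial probe radius, angstroms (default 1.2).
#' @param grid_spacing Burial grid spacing, angstroms (default 1.0).
#' @param slab Optional [membrane_slab()], evidence only.
#' @return data.frame: site columns plus `label` (factor internal /
#'   surface / crystal_contact), `buried`, `nearest_mate_dist`, `in_slab`.
#' @export
classify_sites <- function(model, sites, contact_cutoff = 4.0,
                           probe_radius = 1.2, grid_spacing = 1.0,
                           slab = NULL) {
  # occluders for the burial test: protein plus non-water, non-gas
  # heteroatoms (lipid fragments, synthetic cage walls); never the gas
  a <- model$atoms
  occl_keep <- a$resname %in% AA3 |
    (a$type == "HETATM" & !a$resname %in% c("HOH", "WAT", "DOD") &
       !a$element %in% GAS_ELEMENTS)
  protein <- structure_model(a[occl_keep, , drop = FALSE], cell = model$cell,
                             symops = model$symops, label = model$label)
  if (n_atoms(protein) == 0) protein <- model
  if (n_atoms(protein) == 0) stop("model has no atoms")
  sites <- as.data.frame(sites)
  if (!nrow(sites)) {
    sites$label <- factor(character(0),
                          levels = c("internal", "surface", "crystal_contact"))
    return(sites)
  }
  if (!"id" %in% names(sites)) sites$id <- seq_len(nrow(sites))
  pts <- as.matrix(sites[, c("x", "y", "z")])
  dmin <- sqrt(pmax(apply(cross_dist2(pts, coords(protein)), 1, min), 0))
  detached <- dmin > 15
  if (any(detached))
    warning(sum(detached), " detached site(s) farther than 15 A from all ",
            "protein atoms; classified as surface")
  buried <- is_buried(protein, pts, probe_radius, grid_spacing)
  mate <- rep(Inf, nrow(sites))
  # contacts are to symmetry-related molecules (protein/lipid), not to
  # lattice images of the gas atoms themselves
  if (!is.null(model$cell) && !is.null(model$symops))
    mate <- nearest_symmetry_contact(protein, pts)
  label <- ifelse(detached, "surface",
                  ifelse(buried, "internal",
                         ifelse(mate <= contact_cutoff, "crystal_contact",
                                "surface")))
  in_slab <- rep(NA, nrow(sites))
  if (!is.null(slab)) {
    zproj <- pts %*% slab$axis
    in_slab <- zproj >= slab$z_min & zproj <= slab$z_max
  }
  sites$label <- factor(label,
                        levels = c("internal", "surface", "crystal_contact"))
  sites$buried <- buried
  sites$nearest_mate_dist <- mate
  sites$in_slab <- as.logical(in_slab)
  sites
}

#' Per-group site summary (counts, mean occupancy, mean B)
#'
#' @param classified Output of [classify_sites()] (must carry `label`;
#'   `occ` and `b` columns are averaged when present).
#' @return data.frame with one row per label plus a `total` row.
#' @export
summarize_groups <- function(classified) {
  levs <- c("internal", "surface", "crystal_contact")
  lab <- factor(as.character(classified$label), levels = levs)
  n <- as.integer(table(lab))
  mean_or_na <- function(col) {
    if (!col %in% names(classified)) return(rep(NA_real_, length(levs) + 1))
    v <- classified[[col]]
    c(vapply(levs, function(l) {
      s <- v[lab == l]
      if (length(s)) mean(s) else NA_real_
    }, numeric(1)), if (length(v)) mean(v) else NA_real_)
  }
  out <- data.frame(label = c(levs, "total"),
                    n = c(n, sum(n)),
                    mean_occupancy = mean_or_na("occ"),
                    mean_b = mean_or_na("b"))
  rownames(out) <- NULL
  out
}
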