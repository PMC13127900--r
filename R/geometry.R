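# Geometry: volumes, surface areas and sphericity from anisotropic, gapped
# multislice label volumes.
#
# Label scheme used throughout: 0 = background, 1 = placenta,
# 2 = non-placental uterine wall, 3 = intra-uterine contents (fetus + fluid).

LBL_PLACENTA <- 1L
LBL_WALL     <- 2L
LBL_CONTENT  <- 3L

#' Acquisition grid geometry
#'
#' Describes the sampling grid of a multislice acquisition: in-plane voxel
#' size, slice thickness, and interslice spacing (centre-to-centre; larger
#' than the thickness when a slice gap is used). Volumes are gap-aware: each
#' slice represents its full interslice band.
#'
#' @param voxel_size_mm length-3 numeric: in-plane voxel sizes and slice
#'   thickness, mm. Default `c(2.4, 2.4, 6)`.
#' @param slice_spacing_mm centre-to-centre slice spacing, mm; must be at
#'   least the slice thickness. Default 10.
#' @return an object of class `uterodyn_geometry`.
#' @export
grid_geometry <- function(voxel_size_mm = c(2.4, 2.4, 6),
                          slice_spacing_mm = 10) {
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
            slice_spacing_mm > 0)
  if (slice_spacing_mm < voxel_size_mm[3])
    stop("grid_geometry: slice spacing (", slice_spacing_mm,
         " mm) is smaller than the slice thickness (", voxel_size_mm[3],
         " mm)")
  structure(list(voxel_size_mm = as.numeric(voxel_size_mm),
                 slice_spacing_mm = as.numeric(slice_spacing_mm)),
            class = "uterodyn_geometry")
}

#' Sphericity of a closed shape
#'
#' \eqn{\Psi = \pi^{1/3} (6V)^{2/3} / A}: 1 for a sphere and below 1 for any
#' other closed shape (up to discretisation error when V and A come from a
#' mesh).
#'
#' @param V volume, mm^3 (must be positive).
#' @param A closed-surface area, mm^2 (must be positive).
#' @return dimensionless sphericity, vectorised over `V` and `A`.
#' @examples
#' sphericity(4 * pi / 3, 4 * pi)  # unit sphere: exactly 1
#' @export
sphericity <- function(V, A) {
  if (any(!is.finite(V)) || any(!is.finite(A)) || any(V <= 0) || any(A <= 0))
    stop("sphericity: V and A must be positive and finite")
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Ellipsoid surface area by quadrature
#'
#' Midpoint-rule integration of the exact parametric surface integral.
#' Used as an independent oracle for mesh-based area estimates.
#'
#' @param a,b,c semi-axes, mm.
#' @param n quadrature points per dimension.
#' @return surface area, mm^2.
#' @export
ellipsoid_surface_area <- function(a, b, c, n = 800) {
  th <- (seq_len(n) - 0.5) * pi / n
  ph <- (seq_len(n) - 0.5) * 2 * pi / n
  st <- sin(th); ct <- cos(th)
  cp <- cos(ph); sp <- sin(ph)
  # |r_theta x r_phi| = sin(th) * sqrt(b^2 c^2 sin^2 th cos^2 ph
  #                      + a^2 c^2 sin^2 th sin^2 ph + a^2 b^2 cos^2 th)
  f <- sqrt(outer(st^2, (b * c * cp)^2 + (a * c * sp)^2) +
              (a * b)^2 * outer(ct^2, rep(1, n))) * st
  sum(f) * (pi / n) * (2 * pi / n)
}

# ---- mesh utilities (triangle soup: n x 9 matrix, one triangle per row) ----

.mesh_area <- function(tri) {
  if (nrow(tri) == 0) return(0)
  ux <- tri[, 4] - tri[, 1]; uy <- tri[, 5] - tri[, 2]; uz <- tri[, 6] - tri[, 3]
  vx <- tri[, 7] - tri[, 1]; vy <- tri[, 8] - tri[, 2]; vz <- tri[, 9] - tri[, 3]
  cx <- uy * vz - uz * vy
  cy <- uz * vx - ux * vz
  cz <- ux * vy - uy * vx
  0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
}

.mesh_tri_areas <- function(tri) {
  if (nrow(tri) == 0) return(numeric(0))
  ux <- tri[, 4] - tri[, 1]; uy <- tri[, 5] - tri[, 2]; uz <- tri[, 6] - tri[, 3]
  vx <- tri[, 7] - tri[, 1]; vy <- tri[, 8] - tri[, 2]; vz <- tri[, 9] - tri[, 3]
  cx <- uy * vz - uz * vy
  cy <- uz * vx - ux * vz
  cz <- ux * vy - uy * vx
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

.mesh_volume <- function(tri) {
  if (nrow(tri) == 0) return(0)
  # divergence theorem on the (consistently oriented) triangle soup
  det <- tri[, 1] * (tri[, 5] * tri[, 9] - tri[, 6] * tri[, 8]) -
         tri[, 2] * (tri[, 4] * tri[, 9] - tri[, 6] * tri[, 7]) +
         tri[, 3] * (tri[, 4] * tri[, 8] - tri[, 5] * tri[, 7])
  abs(sum(det)) / 6
}

.mesh_centroids <- function(tri) {
  cbind((tri[, 1] + tri[, 4] + tri[, 7]) / 3,
        (tri[, 2] + tri[, 5] + tri[, 8]) / 3,
        (tri[, 3] + tri[, 6] + tri[, 9]) / 3)
}

# trilinear interpolation of a 3D field at world points (N x 3), grid origin
# at the first voxel centre
.trilinear <- function(field, spacing, origin, pts) {
  dm <- dim(field)
  fx <- pmin(pmax((pts[, 1] - origin[1]) / spacing[1], 0), dm[1] - 1 - 1e-9)
  fy <- pmin(pmax((pts[, 2] - origin[2]) / spacing[2], 0), dm[2] - 1 - 1e-9)
  fz <- pmin(pmax((pts[, 3] - origin[3]) / spacing[3], 0), dm[3] - 1 - 1e-9)
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  idx <- function(i, j, k) 1 + i + dm[1] * (j + dm[2] * k)
  f <- as.vector(field)
  v000 <- f[idx(i0, j0, k0)];     v100 <- f[idx(i0 + 1, j0, k0)]
  v010 <- f[idx(i0, j0 + 1, k0)]; v110 <- f[idx(i0 + 1, j0 + 1, k0)]
  v001 <- f[idx(i0, j0, k0 + 1)]; v101 <- f[idx(i0 + 1, j0, k0 + 1)]
  v011 <- f[idx(i0, j0 + 1, k0 + 1)]; v111 <- f[idx(i0 + 1, j0 + 1, k0 + 1)]
  (v000 * (1 - wx) + v100 * wx) * (1 - wy) * (1 - wz) +
  (v010 * (1 - wx) + v110 * wx) * wy * (1 - wz) +
  (v001 * (1 - wx) + v101 * wx) * (1 - wy) * wz +
  (v011 * (1 - wx) + v111 * wx) * wy * wz
}

# Per-slice signed in-plane distance (positive inside), stacked; cap in mm.
# Empty slices adjacent to populated ones get the mid-gap convention
# min(sd_neighbour - spacing, -spacing/2): the object is assumed to close at
# most half an interslice gap beyond its last populated slice (its true
# through-plane extent is unobservable on gapped data), instead of being
# clipped at that slice.
.sd_stack <- function(mask, dx, dy, cap = 60, spacing = NULL) {
  dm <- dim(mask)
  out <- array(0, dm)
  pop <- logical(dm[3])
  for (k in seq_len(dm[3])) {
    pop[k] <- any(mask[, , k])
    out[, , k] <- .cpp_sedt2d(mask[, , k], dx, dy, cap)
  }
  if (!is.null(spacing)) {
    for (k in seq_len(dm[3])) {
      if (pop[k]) next
      cand <- NULL
      if (k > 1 && pop[k - 1]) cand <- out[, , k - 1]
      if (k < dm[3] && pop[k + 1])
        cand <- if (is.null(cand)) out[, , k + 1]
                else pmax(cand, out[, , k + 1])
      if (!is.null(cand))
        out[, , k] <- pmin(cand - spacing, -spacing / 2)
    }
  }
  out
}

# linear interpolation of a slice stack from slice positions z_sl to z_out
.interp_z <- function(stack, z_sl, z_out) {
  dm <- dim(stack)
  out <- array(0, c(dm[1], dm[2], length(z_out)))
  for (m in seq_along(z_out)) {
    z <- z_out[m]
    if (z <= z_sl[1]) { out[, , m] <- stack[, , 1]; next }
    if (z >= z_sl[length(z_sl)]) { out[, , m] <- stack[, , dm[3]]; next }
    k <- findInterval(z, z_sl)
    w <- (z - z_sl[k]) / (z_sl[k + 1] - z_sl[k])
    out[, , m] <- stack[, , k] * (1 - w) + stack[, , k + 1] * w
  }
  out
}

#' Isosurface mesh of a binary mask
#'
#' Reconstructs the mask surface as a triangle mesh. For gapped multislice
#' masks (`slice_spacing_mm` given) each slice is converted to a signed
#' in-plane distance map, the maps are linearly interpolated across the slice
#' gap onto a near-isotropic grid, and the zero level set is triangulated by
#' marching tetrahedra. For isotropic masks (`slice_spacing_mm = NULL`) a full
#' 3D signed distance transform is used instead.
#'
#' @param mask logical 3D array.
#' @param voxel_size_mm length-3 voxel size (third entry: slice thickness).
#' @param slice_spacing_mm interslice spacing, or `NULL` for isotropic input.
#' @param iso_dz target through-plane sampling of the reconstruction, mm;
#'   defaults to the mean in-plane voxel size.
#' @param smooth_vox SD (in voxels, per axis) of a Gaussian smoothing of the
#'   distance field before iso-surfacing; suppresses the half-voxel
#'   staircase of binary-mask distance maps, which otherwise inflates area.
#'   Set 0 to disable.
#' @return a list with `triangles` (n x 9 matrix of vertex coordinates),
#'   `area_mm2`, `volume_mm3` (divergence-theorem volume of the closed mesh),
#'   and the signed-distance `field`, `spacing` and `origin` used.
#' @export
mask_mesh <- function(mask, voxel_size_mm, slice_spacing_mm = NULL,
                      iso_dz = NULL, smooth_vox = 0.8) {
  stopifnot(length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim(mask))
  dx <- voxel_size_mm[1]; dy <- voxel_size_mm[2]
  if (is.null(slice_spacing_mm)) {
    sp <- as.numeric(voxel_size_mm)
    field <- .cpp_sedt3d(as.vector(mask), dim(mask), sp, cap = 60)
    origin <- c(0, 0, 0)
    sm <- rep(smooth_vox, 3)
  } else {
    iso_dz <- iso_dz %||% mean(c(dx, dy))
    z_sl <- (seq_len(dim(mask)[3]) - 1) * slice_spacing_mm
    z_out <- seq(0, max(z_sl), by = iso_dz)
    field <- .interp_z(.sd_stack(mask, dx, dy, spacing = slice_spacing_mm),
                       z_sl, z_out)
    sp <- c(dx, dy, iso_dz)
    origin <- c(0, 0, 0)
    # through-plane already smooth (linear shape interpolation): blur in-plane
    sm <- c(smooth_vox, smooth_vox, 0)
  }
  if (any(sm > 0))
    field <- .cpp_blur3d(as.vector(field), dim(field), sm)
  tri <- .cpp_march_tets(as.vector(field), dim(field), sp, origin, 0)
  list(triangles = tri, area_mm2 = .mesh_area(tri),
       volume_mm3 = .mesh_volume(tri), field = field, spacing = sp,
       origin = origin)
}

#' Measure one frame of a dynamic series
#'
#' Computes compartment volumes and (optionally) surface areas from a single
#' label volume on a gapped multislice grid.
#'
#' Volumes are gap-aware voxel counts: voxel count x in-plane voxel area x
#' interslice spacing, so each slice stands for its full band. Surface areas
#' are measured on a shape-based interpolated reconstruction: per-slice
#' signed distance maps are interpolated across the gap to a near-isotropic
#' grid, the zero level set is triangulated, and triangle areas are summed.
#' The placental bed area is the part of the placental surface in contact
#' with the uterine wall; the non-placental wall area is the part of the
#' intra-uterine content surface in contact with the wall (the wall's inner
#' surface not covered by placenta). Both are computed by complements: the
#' placental surface facing the intra-uterine contents is identified by the
#' interpolated content signed distance at triangle centroids and the bed is
#' the remainder (and analogously for the content surface). Classifying
#' against the fat neighbouring compartment rather than the thin wall keeps
#' the interface well defined where the surface runs parallel to the slices.
#'
#' @param labels integer 3D array with labels 0..3 (see package docs).
#' @param geom a [grid_geometry()].
#' @param timestamp_s acquisition time of the frame, seconds.
#' @param measures character subset of `c("volumes", "surfaces",
#'   "sphericity")`. `"surfaces"` computes all areas; `"sphericity"` is a
#'   cheaper mode computing only the total placental surface (enough for
#'   sphericity), leaving interface areas `NA`.
#' @param iso_dz through-plane sampling for surface reconstruction, mm.
#' @param interface_tol_mm contact tolerance for interface classification;
#'   default one in-plane voxel.
#' @return one-row `data.frame` with columns `timestamp_s`,
#'   `placental_volume_mm3`, `nonplacental_content_volume_mm3`,
#'   `wall_volume_mm3`, `placental_surface_area_mm2`,
#'   `placental_bed_area_mm2`, `nonplacental_wall_area_mm2`,
#'   `empty_placenta`. Area columns are `NA` when `"surfaces"` is not
#'   requested, and 0 (with a warning) when the placenta mask is empty.
#' @export
measure_frame <- function(labels, geom, timestamp_s = NA_real_,
                          measures = c("volumes", "surfaces"),
                          iso_dz = NULL, interface_tol_mm = NULL) {
  if (!inherits(geom, "uterodyn_geometry"))
    stop("measure_frame: 'geom' must be a grid_geometry()")
  if (length(dim(labels)) != 3)
    stop("measure_frame: 'labels' must be a 3D array")
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad))
    stop("measure_frame: undeclared label values: ",
         paste(bad, collapse = ", "))
  vs <- geom$voxel_size_mm
  vox_vol <- vs[1] * vs[2] * geom$slice_spacing_mm
  counts <- tabulate(as.vector(labels), nbins = 3L)
  out <- data.frame(
    timestamp_s = timestamp_s,
    placental_volume_mm3 = counts[1] * vox_vol,
    nonplacental_content_volume_mm3 = counts[3] * vox_vol,
    wall_volume_mm3 = counts[2] * vox_vol,
    placental_surface_area_mm2 = NA_real_,
    placental_bed_area_mm2 = NA_real_,
    nonplacental_wall_area_mm2 = NA_real_,
    empty_placenta = counts[1] == 0L)
  want_all <- "surfaces" %in% measures
  want_sph <- want_all || ("sphericity" %in% measures)
  if (!want_sph) return(out)
  tol <- interface_tol_mm %||% 1.25 * max(vs[1], vs[2])
  iso_dz <- iso_dz %||% mean(vs[1:2])
  sp <- c(vs[1], vs[2], iso_dz)
  # meshes are built on a bounding-box crop (interface adjacency is local,
  # so cropping the neighbour's distance field to the same box is safe)
  crop_of <- function(mask, margin_vox = 8L) {
    w <- which(mask, arr.ind = TRUE)
    dm <- dim(mask)
    lo <- pmax(apply(w, 2, min) - c(margin_vox, margin_vox, 1L), 1L)
    hi <- pmin(apply(w, 2, max) + c(margin_vox, margin_vox, 1L), dm)
    list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  }
  # total surface area of `mask` and the part of it facing `neighbour`
  split_by_neighbour <- function(mask, neighbour = NULL) {
    cr <- crop_of(mask)
    mk <- mask[cr$x, cr$y, cr$z, drop = FALSE]
    m <- mask_mesh(mk, vs, geom$slice_spacing_mm, iso_dz = iso_dz)
    if (nrow(m$triangles) == 0) return(list(total = 0, facing = 0))
    if (is.null(neighbour)) return(list(total = .mesh_area(m$triangles),
                                        facing = NA_real_))
    nb <- neighbour[cr$x, cr$y, cr$z, drop = FALSE]
    z_sl <- (seq_len(dim(nb)[3]) - 1) * geom$slice_spacing_mm
    z_out <- seq(0, max(z_sl), by = iso_dz)
    nb_field <- .interp_z(.sd_stack(nb, vs[1], vs[2],
                                    spacing = geom$slice_spacing_mm),
                          z_sl, z_out)
    areas <- .mesh_tri_areas(m$triangles)
    nd <- .trilinear(nb_field, sp, c(0, 0, 0), .mesh_centroids(m$triangles))
    list(total = sum(areas), facing = sum(areas[nd > -tol]))
  }
  if (counts[1] == 0L) {
    warning("measure_frame: empty placenta mask; surface measures set to 0")
    out$placental_surface_area_mm2 <- 0
    out$placental_bed_area_mm2 <- 0
  } else {
    pl <- split_by_neighbour(labels == LBL_PLACENTA,
                             if (want_all) labels == LBL_CONTENT)
    out$placental_surface_area_mm2 <- pl$total
    # bed = placental surface not facing the intra-uterine contents
    out$placental_bed_area_mm2 <- if (want_all) pl$total - pl$facing
                                  else NA_real_
  }
  if (want_all && counts[3] > 0L) {
    ct <- split_by_neighbour(labels == LBL_CONTENT, labels == LBL_PLACENTA)
    # wall inner surface not covered by placenta
    out$nonplacental_wall_area_mm2 <- ct$total - ct$facing
  }
  out
}
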