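# Core containers and discrete operators for time-resolved voxel velocity fields.

#' Label codes used in segmentation volumes
#'
#' Canonical integer codes for the three tissue classes of a segmented
#' aneurysm geometry: voxels outside the lumen, the parent artery, and the
#' aneurysm sac.
#' @export
LABELS <- c(outside = 0L, parent_artery = 1L, sac = 2L)

#' Construct a time-resolved 3-component voxel velocity field
#'
#' The container holds one signed velocity component per spatial direction per
#' time frame, on a regular voxel grid, in m/s. Frame times are cycle phases:
#' midpoints of the acquisition windows, strictly increasing within one cardiac
#' cycle of length \code{period}.
#'
#' @param vx,vy,vz 4-D arrays (nx, ny, nz, n_frames), velocity in m/s along
#'   the three world axes.
#' @param spacing numeric(3), voxel edge lengths in mm, all > 0.
#' @param times numeric(n_frames), frame midpoints in seconds, strictly
#'   increasing, within \code{[0, period]}.
#' @param period cardiac cycle length in seconds.
#' @param affine 4x4 matrix mapping 0-based voxel index (i, j, k, 1) to world
#'   coordinates in mm; defaults to \code{diag(c(spacing, 1))} (first voxel
#'   center at the world origin).
#' @return An object of class \code{velocity_field}.
#' @export
velocity_field <- function(vx, vy, vz, spacing, times, period, affine = NULL) {
  dm <- dim(vx)
  if (length(dm) == 3L) {
    dm <- c(dm, 1L)
    dim(vx) <- dm; dim(vy) <- dm; dim(vz) <- dm
  }
  if (length(dm) != 4L) stop("velocity components must be 4-D arrays (x, y, z, frame)")
  if (!identical(dim(vy), dm) || !identical(dim(vz), dm))
    stop("velocity component arrays must share dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive voxel edge lengths in mm")
  times <- as.numeric(times)
  nt <- dm[4L]
  if (length(times) != nt) stop("length(times) must equal the number of frames")
  if (nt > 1L && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (!is.finite(period) || period <= 0) stop("period must be a positive cycle length in s")
  if (any(times < 0) || any(times > period)) stop("frame times must lie within [0, period]")
  if (any(!is.finite(vx)) || any(!is.finite(vy)) || any(!is.finite(vz)))
    stop("velocity samples must be finite")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be a 4x4 matrix")
  structure(
    list(vx = vx, vy = vy, vz = vz, spacing = spacing, affine = affine,
         times = times, period = period),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  dm <- dim(x$vx)
  cat(sprintf("velocity_field: %d x %d x %d voxels, %d frame(s)\n", dm[1], dm[2], dm[3], dm[4]))
  cat(sprintf("  spacing %.3g x %.3g x %.3g mm, cycle %.4g s\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$period))
  invisible(x)
}

n_frames <- function(field) dim(field$vx)[4L]

grid_dim <- function(field) dim(field$vx)[1:3]

check_frame <- function(field, frame) {
  nt <- n_frames(field)
  if (length(frame) != 1L || is.na(frame) || frame < 1L || frame > nt)
    stop(sprintf("frame must be in 1..%d", nt))
  as.integer(frame)
}

#' Extract the three component volumes of one time frame
#'
#' @param field a \code{velocity_field}.
#' @param frame 1-based frame index.
#' @return list of three 3-D arrays \code{vx}, \code{vy}, \code{vz} in m/s.
#' @export
frame_velocity <- function(field, frame) {
  frame <- check_frame(field, frame)
  list(vx = field$vx[, , , frame, drop = TRUE],
       vy = field$vy[, , , frame, drop = TRUE],
       vz = field$vz[, , , frame, drop = TRUE])
}

#' Construct a segmented aneurysm geometry
#'
#' Holds the per-voxel tissue labels (outside / parent artery / sac) that
#' restrict every intra-aneurysmal average, plus (optionally) the triangulated
#' wall surface used for wall shear stress.
#'
#' @param labels integer 3-D array using the codes in \code{\link{LABELS}}.
#' @param spacing numeric(3) voxel edge lengths in mm.
#' @param affine 4x4 index-to-world (mm) map; default \code{diag(c(spacing, 1))}.
#' @param surface optional \code{triangle_mesh} wall surface (vertices in mm,
#'   outward normals).
#' @return An object of class \code{segmented_geometry} with the sac voxel
#'   count stored as \code{$sac_voxel_count}.
#' @export
segmented_geometry <- function(labels, spacing, affine = NULL, surface = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  lab <- as.integer(labels)
  bad <- setdiff(unique(lab), unname(LABELS))
  if (length(bad) > 0)
    stop("unknown label code(s): ", paste(bad, collapse = ", "))
  dim(lab) <- dim(labels)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive mm lengths")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  if (!is.null(surface) && !inherits(surface, "triangle_mesh"))
    stop("surface must be a triangle_mesh")
  structure(
    list(labels = lab, spacing = spacing, affine = as.matrix(affine),
         surface = surface, sac_voxel_count = sum(lab == LABELS[["sac"]])),
    class = "segmented_geometry"
  )
}

#' @export
print.segmented_geometry <- function(x, ...) {
  dm <- dim(x$labels)
  cat(sprintf("segmented_geometry: %d x %d x %d voxels\n", dm[1], dm[2], dm[3]))
  cat(sprintf("  sac: %d voxels, parent artery: %d voxels%s\n",
              x$sac_voxel_count, sum(x$labels == LABELS[["parent_artery"]]),
              if (is.null(x$surface)) "" else sprintf(", wall surface: %d triangles", nrow(x$surface$faces))))
  invisible(x)
}

#' Logical masks over the segmentation
#'
#' \code{fluid_mask} marks all lumen voxels (parent artery plus sac);
#' \code{sac_mask} marks the aneurysm sac only.
#' @param geom a \code{segmented_geometry}.
#' @export
fluid_mask <- function(geom) geom$labels != LABELS[["outside"]]

#' @rdname fluid_mask
#' @export
sac_mask <- function(geom) geom$labels == LABELS[["sac"]]

#' Fluid properties of the working fluid
#'
#' Defaults are the blood-mimicking glycerol mixture used throughout:
#' density 1141 kg/m^3 and dynamic viscosity 4.1 mPa s.
#'
#' @param density fluid density in kg/m^3.
#' @param viscosity dynamic viscosity in Pa s.
#' @export
fluid_properties <- function(density = 1141, viscosity = 4.1e-3) {
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (!is.finite(viscosity) || viscosity <= 0) stop("viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity), class = "fluid_properties")
}

#' Define a bounded cross-section plane
#'
#' The integration surface for planar recirculation: a point, a unit normal,
#' and in-plane bounds given either as a disc radius or a polygon in the
#' plane's own 2-D coordinates.
#'
#' @param origin numeric(3), a world-mm point on the plane.
#' @param normal numeric(3), plane normal (normalized internally, must be nonzero).
#' @param radius disc radius in mm bounding the integration area, or NULL.
#' @param polygon optional n x 2 matrix of in-plane vertex coordinates (mm)
#'   bounding the integration area (used when \code{radius} is NULL).
#' @export
cross_section_plane <- function(origin, normal, radius = NULL, polygon = NULL) {
  origin <- as.numeric(origin); normal <- as.numeric(normal)
  if (length(origin) != 3L || length(normal) != 3L) stop("origin and normal must be length-3")
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn == 0) stop("normal must be a nonzero vector")
  normal <- normal / nn
  if (is.null(radius) && is.null(polygon)) stop("plane bounds required: radius or polygon")
  if (!is.null(radius) && (!is.finite(radius) || radius <= 0)) stop("radius must be > 0")
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L) stop("polygon must be an n x 2 matrix, n >= 3")
  }
  structure(list(origin = origin, normal = normal, radius = radius, polygon = polygon),
            class = "cross_section_plane")
}

# Orthonormal in-plane basis (e1, e2) completing the plane normal.
plane_basis <- function(normal) {
  a <- c(1, 0, 0)
  if (abs(normal[1]) >= max(abs(normal[2]), abs(normal[3]))) a <- c(0, 1, 0)
  e1 <- crossprod3(normal, a)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod3(normal, e1)
  list(e1 = e1, e2 = e2)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# World mm -> continuous 0-based voxel index, n x 3 in, n x 3 out.
world_to_index <- function(points, affine) {
  points <- matrix(points, ncol = 3L)
  inv <- solve(affine)
  t(inv %*% rbind(t(points), 1))[, 1:3, drop = FALSE]
}

# 0-based voxel index -> world mm.
index_to_world <- function(idx, affine) {
  idx <- matrix(idx, ncol = 3L)
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

# Shift a 3-D array by one voxel along an axis; vacated entries become `fill`.
shift_array <- function(a, axis, by, fill = NA_real_) {
  dm <- dim(a)
  out <- array(fill, dm)
  n <- dm[axis]
  if (n <= abs(by)) return(out)
  src <- dst <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  if (by > 0) { src[[axis]] <- (1 + by):n; dst[[axis]] <- 1:(n - by) }
  else        { src[[axis]] <- 1:(n + by); dst[[axis]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Partial derivative of a masked scalar volume along one axis (spacing h):
# central differences where both neighbours are fluid, one-sided where only
# one is, NA where neither is. Never treats non-fluid voxels as zero.
masked_derivative <- function(u, mask, h, axis) {
  up <- shift_array(u, axis, +1L)
  um <- shift_array(u, axis, -1L)
  mp <- shift_array(mask, axis, +1L, fill = FALSE)
  mm <- shift_array(mask, axis, -1L, fill = FALSE)
  d <- array(NA_real_, dim(u))
  both <- mask & mp & mm
  fwd <- mask & mp & !mm
  bwd <- mask & !mp & mm
  d[both] <- (up[both] - um[both]) / (2 * h)
  d[fwd] <- (up[fwd] - u[fwd]) / h
  d[bwd] <- (u[bwd] - um[bwd]) / h
  d
}

#' Vorticity of one frame of the intra-aneurysmal velocity field
#'
#' Computes the curl of the velocity field at every fluid voxel by finite
#' differences: second-order central differences where the full stencil is
#' fluid, first-order one-sided at fluid voxels bordering the wall. Non-fluid
#' voxels are returned as NA, never treated as zero velocity. Each partial
#' derivative uses its own axis spacing, so anisotropic voxels are handled
#' exactly.
#'
#' @param field a \code{velocity_field} (m/s; spacing in mm).
#' @param geom a \code{segmented_geometry}; the fluid mask is the union of
#'   parent-artery and sac labels.
#' @param frame 1-based frame index.
#' @return list of three 3-D arrays \code{wx}, \code{wy}, \code{wz} in 1/s,
#'   NA at non-fluid voxels.
#' @export
vorticity <- function(field, geom, frame) {
  mask <- fluid_mask(geom)
  if (!any(mask)) stop("no fluid voxels in segmentation")
  idx <- which(mask, arr.ind = TRUE)
  ext <- apply(idx, 2L, function(v) diff(range(v)) + 1L)
  thin <- which(ext < 2L)
  if (length(thin) > 0)
    stop(sprintf("degenerate stencil: fluid region is fewer than 2 voxels thick along axis %s",
                 paste(c("x", "y", "z")[thin], collapse = ", ")))
  v <- frame_velocity(field, frame)
  h <- field$spacing / 1000  # mm -> m so that curl of m/s is 1/s
  dwdy <- masked_derivative(v$vz, mask, h[2], 2L)
  dvdz <- masked_derivative(v$vy, mask, h[3], 3L)
  dudz <- masked_derivative(v$vx, mask, h[3], 3L)
  dwdx <- masked_derivative(v$vz, mask, h[1], 1L)
  dvdx <- masked_derivative(v$vy, mask, h[1], 1L)
  dudy <- masked_derivative(v$vx, mask, h[2], 2L)
  list(wx = dwdy - dvdz, wy = dudz - dwdx, wz = dvdx - dudy)
}

#' Per-voxel velocity magnitude of one frame
#'
#' @inheritParams vorticity
#' @return 3-D array of Euclidean norms in m/s.
#' @export
velocity_magnitude <- function(field, frame) {
  v <- frame_velocity(field, frame)
  sqrt(v$vx^2 + v$vy^2 + v$vz^2)
}

#' Trilinear interpolation of voxel volumes at world points
#'
#' Samples one or more scalar volumes at arbitrary world-mm points. Voxel
#' values are taken at voxel centers. Corners that are NA or excluded by
#' \code{mask} are omitted and the remaining trilinear weights renormalized
#' (\code{na_action = "omit"}, the default) so that wall-adjacent samples use
#' measured fluid data only; \code{"strict"} instead returns NA whenever any
#' corner is unusable. Points outside the grid return NA.
#'
#' @param x a 3-D array or a list of 3-D arrays sharing dimensions.
#' @param points n x 3 matrix of world coordinates (mm).
#' @param affine 4x4 index-to-world map.
#' @param mask optional logical 3-D array of usable voxels.
#' @param na_action "omit" or "strict".
#' @return numeric vector (length n) or matrix (n x length(x)) of samples.
#' @export
trilinear_sample <- function(x, points, affine, mask = NULL, na_action = c("omit", "strict")) {
  na_action <- match.arg(na_action)
  arrs <- if (is.list(x)) x else list(x)
  dm <- dim(arrs[[1L]])
  points <- matrix(points, ncol = 3L)
  n <- nrow(points)
  ijk <- world_to_index(points, affine)
  eps <- 1e-9
  inside <- ijk[, 1] >= -eps & ijk[, 1] <= dm[1] - 1 + eps &
            ijk[, 2] >= -eps & ijk[, 2] <= dm[2] - 1 + eps &
            ijk[, 3] >= -eps & ijk[, 3] <= dm[3] - 1 + eps
  i0 <- pmin(pmax(floor(ijk), 0), matrix(rep(dm - 2L, each = n), ncol = 3L))
  fr <- ijk - i0
  vals <- matrix(NA_real_, n, length(arrs))
  num <- matrix(0, n, length(arrs))
  den <- rep(0, n)
  anybad <- rep(FALSE, n)
  for (corner in 0:7) {
    b <- c(corner %% 2, (corner %/% 2) %% 2, corner %/% 4)
    w <- (if (b[1] == 1) fr[, 1] else 1 - fr[, 1]) *
         (if (b[2] == 1) fr[, 2] else 1 - fr[, 2]) *
         (if (b[3] == 1) fr[, 3] else 1 - fr[, 3])
    ci <- cbind(i0[, 1] + b[1] + 1L, i0[, 2] + b[2] + 1L, i0[, 3] + b[3] + 1L)
    ok <- inside
    ci_ok <- ci[ok, , drop = FALSE]
    usable <- rep(TRUE, sum(ok))
    if (!is.null(mask)) usable <- usable & mask[ci_ok]
    vc <- lapply(arrs, function(a) a[ci_ok])
    usable <- usable & Reduce(`&`, lapply(vc, is.finite))
    wk <- w[ok]
    contrib <- wk * usable
    den[ok] <- den[ok] + ifelse(usable, wk, 0)
    anyb <- rep(FALSE, n)
    anyb[ok] <- !usable & wk > eps
    anybad <- anybad | anyb
    for (j in seq_along(arrs)) {
      vj <- vc[[j]]
      vj[!usable] <- 0
      num[ok, j] <- num[ok, j] + wk * ifelse(usable, vj, 0)
    }
  }
  good <- inside & den > 1e-12
  if (na_action == "strict") good <- good & !anybad
  for (j in seq_along(arrs)) vals[good, j] <- num[good, j] / den[good]
  if (!is.list(x)) vals[, 1L] else vals
}

# Point-in-polygon (even-odd rule) for in-plane bounds; pts n x 2, poly m x 2.
point_in_polygon <- function(pts, poly) {
  n <- nrow(pts); m <- nrow(poly)
  inside <- rep(FALSE, n)
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & is.finite(crosses))
    j <- i
  }
  inside
}

#' Sample a voxel field on a bounded cross-section plane
#'
#' Lays a regular 2-D grid of pitch \code{resolution} over the plane's bounds
#' and interpolates the field trilinearly at each sample point. Each in-bounds
#' sample carries an area weight dA = resolution^2 (mm^2); samples falling
#' outside the fluid labels (or outside the grid) are flagged invalid and get
#' zero area weight — they are excluded, never zero-filled.
#'
#' @param x a 3-D scalar array or list of 3-D arrays (e.g. a vorticity field)
#'   on the same grid as \code{field}.
#' @param field a \code{velocity_field} or \code{segmented_geometry} supplying
#'   the grid (spacing and affine).
#' @param plane a \code{cross_section_plane}.
#' @param resolution in-plane sample pitch in mm.
#' @param mask optional logical 3-D array; a sample is valid only if its
#'   nearest voxel is in the mask (typically the sac or fluid mask).
#' @return list with \code{points} (n x 3 world mm), \code{uv} (n x 2 in-plane
#'   mm), \code{values} (vector or matrix), \code{dA} (mm^2, zero when
#'   invalid), \code{valid} (logical).
#' @export
plane_sample <- function(x, field, plane, resolution = 0.25, mask = NULL) {
  if (!inherits(plane, "cross_section_plane")) stop("plane must be a cross_section_plane")
  if (!is.finite(resolution) || resolution <= 0) stop("resolution must be > 0")
  basis <- plane_basis(plane$normal)
  if (!is.null(plane$radius)) {
    r <- plane$radius
    m <- ceiling(r / resolution)
    s <- (seq(-m, m - 1L) + 0.5) * resolution
    uv <- as.matrix(expand.grid(u = s, v = s))
    keep <- uv[, 1]^2 + uv[, 2]^2 <= r^2
  } else {
    rng_u <- range(plane$polygon[, 1]); rng_v <- range(plane$polygon[, 2])
    su <- seq(rng_u[1] + resolution / 2, rng_u[2], by = resolution)
    sv <- seq(rng_v[1] + resolution / 2, rng_v[2], by = resolution)
    uv <- as.matrix(expand.grid(u = su, v = sv))
    keep <- point_in_polygon(uv, plane$polygon)
  }
  uv <- uv[keep, , drop = FALSE]
  if (nrow(uv) == 0L) stop("plane bounds contain no sample points at this resolution")
  pts <- sweep(uv[, 1, drop = FALSE] %*% rbind(basis$e1) +
               uv[, 2, drop = FALSE] %*% rbind(basis$e2), 2L, plane$origin, `+`)
  vals <- trilinear_sample(x, pts, field$affine, mask = mask)
  valid <- if (is.matrix(vals)) apply(is.finite(vals), 1L, all) else is.finite(vals)
  if (!is.null(mask)) {
    dm <- dim(mask)
    nn <- round(world_to_index(pts, field$affine)) + 1
    inb <- nn[, 1] >= 1 & nn[, 1] <= dm[1] & nn[, 2] >= 1 & nn[, 2] <= dm[2] &
           nn[, 3] >= 1 & nn[, 3] <= dm[3]
    near <- rep(FALSE, nrow(pts))
    near[inb] <- mask[nn[inb, , drop = FALSE]]
    valid <- valid & near
  }
  if (!any(valid)) stop("cross-section plane misses all fluid voxels (empty section)")
  list(points = pts, uv = uv, values = vals,
       dA = ifelse(valid, resolution^2, 0), valid = valid)
}

#' Average a per-frame series over one cardiac cycle
#'
#' Trapezoidal quadrature with periodic closure: the interval from the last
#' frame back to the first (wrapping across the cycle length T) is included,
#' and the integral is divided by T. The cycle is periodic by construction of
#' the pulsatile pump, so the wrap interval uses the first frame's value as
#' the continuation of the last. A constant series returns exactly that
#' constant for any frame count; a single frame returns its value.
#'
#' @param y numeric per-frame values.
#' @param times frame midpoints in s, strictly increasing, within [0, T].
#' @param period cycle length T in s.
#' @return the cycle average of \code{y}.
#' @export
time_integrate <- function(y, times, period) {
  n <- length(y)
  if (n == 0L) stop("empty series")
  if (length(times) != n) stop("times and series lengths differ")
  if (n > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times < 0) || any(times > period)) stop("times must lie within [0, period]")
  if (n == 1L) return(y[1L])
  dt <- diff(times)
  total <- sum(dt * (y[-n] + y[-1L]) / 2)
  wrap <- period - times[n] + times[1L]
  total <- total + wrap * (y[n] + y[1L]) / 2
  total / period
}
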