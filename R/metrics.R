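# Scalar hemodynamic metrics of the aneurysm sac and pre/post flow-diverter
# comparison. All intra-aneurysmal averages are restricted to sac-labeled
# voxels, excluding the parent artery.

#' Frame index of the systolic peak
#'
#' Returns the frame maximizing the mean velocity magnitude over all fluid
#' voxels (sac and parent artery); ties are broken by the earliest frame.
#' Spatial metrics are conventionally evaluated at this frame, where the
#' hemodynamic parameters reach their maxima.
#'
#' @param field a \code{velocity_field}.
#' @param geom a \code{segmented_geometry}.
#' @return 1-based frame index.
#' @export
systolic_peak_frame <- function(field, geom) {
  mask <- fluid_mask(geom)
  if (!any(mask)) stop("no fluid voxels in segmentation")
  means <- vapply(seq_len(n_frames(field)), function(fr) {
    mean(velocity_magnitude(field, fr)[mask])
  }, numeric(1))
  which.max(means)  # which.max returns the first maximum: earliest-frame tie-break
}

#' Average intra-aneurysmal velocity
#'
#' Arithmetic mean of the velocity magnitude over sac-labeled voxels only
#' (parent artery excluded), in m/s. Evaluated at the systolic peak this is
#' the sac-averaged velocity U reported per case.
#'
#' @inheritParams systolic_peak_frame
#' @param frame 1-based frame index.
#' @export
average_sac_velocity <- function(field, geom, frame) {
  sm <- sac_mask(geom)
  if (!any(sm)) stop("sac mask is empty: no aneurysm voxels labeled")
  mean(velocity_magnitude(field, frame)[sm])
}

#' Intra-aneurysmal kinetic energy of one frame
#'
#' The kinetic-energy measure E = sum over the N sac voxels of the squared
#' velocity magnitude, in m^2/s^2. It is a sum, not a mean, so its absolute
#' value scales with the sampling resolution; only relative changes between
#' acquisitions on the same grid are comparable.
#'
#' @inheritParams average_sac_velocity
#' @export
kinetic_energy <- function(field, geom, frame) {
  sm <- sac_mask(geom)
  if (!any(sm)) stop("sac mask is empty: no aneurysm voxels labeled")
  sum(velocity_magnitude(field, frame)[sm]^2)
}

#' Mean kinetic energy over the cardiac cycle
#'
#' Cycle average (periodic trapezoidal rule) of the per-frame intra-aneurysmal
#' kinetic energies.
#'
#' @inheritParams systolic_peak_frame
#' @return list with \code{E_mean} and the per-frame series \code{E_per_frame}.
#' @export
mean_kinetic_energy <- function(field, geom) {
  e <- vapply(seq_len(n_frames(field)), function(fr) kinetic_energy(field, geom, fr),
              numeric(1))
  list(E_mean = time_integrate(e, field$times, field$period), E_per_frame = e)
}

#' Planar recirculation of one frame
#'
#' Integrates the wall-normal vorticity component over a bounded cross-section
#' plane: R = sum over valid plane samples of (omega . n) dA, in mm^2/s
#' (vorticity in 1/s, area in mm^2). Samples outside the fluid labels carry
#' zero area weight. R is signed; it flips sign with the plane normal.
#'
#' @inheritParams average_sac_velocity
#' @param plane a \code{cross_section_plane} through the sac (commonly its
#'   central cross-section).
#' @param resolution in-plane sample pitch in mm.
#' @param region which labels bound the integration: \code{"sac"} (default,
#'   intra-aneurysmal) or \code{"fluid"}.
#' @export
recirculation <- function(field, geom, plane, frame, resolution = 0.25,
                          region = c("sac", "fluid")) {
  region <- match.arg(region)
  mask <- if (region == "sac") sac_mask(geom) else fluid_mask(geom)
  w <- vorticity(field, geom, frame)
  ps <- plane_sample(w, field, plane, resolution = resolution, mask = mask)
  wn <- ps$values %*% plane$normal
  wn[!ps$valid] <- 0
  sum(wn * ps$dA)
}

#' Mean recirculation over the cardiac cycle
#'
#' Cycle average of the absolute instantaneous recirculation,
#' R_m = (1/T) integral of |R(t)| dt. Per-frame values keep their sign; only
#' the cycle mean takes the absolute value, so R_m is invariant to flipping
#' the plane normal.
#'
#' @inheritParams recirculation
#' @return list with \code{R_mean} and signed \code{R_per_frame}.
#' @export
mean_recirculation <- function(field, geom, plane, resolution = 0.25,
                               region = c("sac", "fluid")) {
  region <- match.arg(region)
  r <- vapply(seq_len(n_frames(field)), function(fr) {
    recirculation(field, geom, plane, fr, resolution = resolution, region = region)
  }, numeric(1))
  list(R_mean = time_integrate(abs(r), field$times, field$period), R_per_frame = r)
}

#' Wall shear stress on the wall surface
#'
#' Estimates the wall shear rate at each wall triangle centroid from the
#' tangential velocity sampled along the inward normal, assuming no slip at
#' the wall, and multiplies by the dynamic viscosity. The default estimator
#' uses two inward samples at distances d and 2d with the one-sided quadratic
#' derivative (4 u_t(d) - u_t(2d)) / (2d), which is exact for linear and
#' parabolic near-wall profiles; \code{estimator = "linear"} uses the
#' single-point secant u_t(d)/d. Elements whose inward samples leave the fluid
#' mask are returned as NA and excluded from any maximum.
#'
#' @param field a \code{velocity_field}.
#' @param geom a \code{segmented_geometry} carrying a wall \code{surface}.
#' @param props \code{fluid_properties} (viscosity used).
#' @param frame 1-based frame index.
#' @param d inward sampling distance in mm; default one voxel diagonal.
#' @param estimator "quadratic" (two-point, default) or "linear" (one-point).
#' @return numeric vector of WSS magnitudes in Pa, one per wall triangle
#'   (NA where invalid), with attribute \code{"valid"}.
#' @export
wall_shear_stress <- function(field, geom, props, frame,
                              d = NULL, estimator = c("quadratic", "linear")) {
  estimator <- match.arg(estimator)
  if (is.null(geom$surface)) stop("segmented_geometry carries no wall surface")
  if (is.null(d)) d <- sqrt(sum(field$spacing^2))
  mask <- fluid_mask(geom)
  fg <- mesh_face_geometry(geom$surface)
  v <- frame_velocity(field, frame)
  comp <- list(v$vx, v$vy, v$vz)
  p1 <- fg$centroids - d * fg$normals
  u1 <- trilinear_sample(comp, p1, field$affine, mask = mask)
  valid <- nearest_in_mask(p1, field$affine, mask) & apply(is.finite(u1), 1L, all)
  tang <- function(u) u - rowSums(u * fg$normals) * fg$normals
  d_m <- d / 1000
  if (estimator == "quadratic") {
    p2 <- fg$centroids - 2 * d * fg$normals
    u2 <- trilinear_sample(comp, p2, field$affine, mask = mask)
    valid <- valid & nearest_in_mask(p2, field$affine, mask) & apply(is.finite(u2), 1L, all)
    g <- (4 * tang(u1) - tang(u2)) / (2 * d_m)
  } else {
    g <- tang(u1) / d_m
  }
  wss <- props$viscosity * sqrt(rowSums(g^2))
  wss[!valid] <- NA_real_
  attr(wss, "valid") <- valid
  wss
}

# TRUE where the voxel nearest to each point belongs to the mask.
nearest_in_mask <- function(points, affine, mask) {
  dm <- dim(mask)
  nn <- round(world_to_index(points, affine)) + 1
  ok <- nn[, 1] >= 1 & nn[, 1] <= dm[1] & nn[, 2] >= 1 & nn[, 2] <= dm[2] &
        nn[, 3] >= 1 & nn[, 3] <= dm[3]
  res <- rep(FALSE, nrow(points))
  res[ok] <- mask[nn[ok, , drop = FALSE]]
  res
}

#' Identify sac-adjacent wall elements
#'
#' A wall triangle is sac-adjacent when its centroid lies nearer to a
#' sac-labeled voxel than to any parent-artery voxel (searched within a small
#' neighborhood of the centroid). The WSS normalization maximum is taken over
#' these elements.
#'
#' @param geom a \code{segmented_geometry} with a wall surface.
#' @param search_radius neighborhood half-width in voxels.
#' @return logical vector, one entry per wall triangle.
#' @export
sac_adjacent_elements <- function(geom, search_radius = 2L) {
  if (is.null(geom$surface)) stop("segmented_geometry carries no wall surface")
  fg <- mesh_face_geometry(geom$surface)
  pts <- fg$centroids
  dm <- dim(geom$labels)
  base <- round(world_to_index(pts, geom$affine))
  offs <- as.matrix(expand.grid(-search_radius:search_radius,
                                -search_radius:search_radius,
                                -search_radius:search_radius))
  best_sac <- rep(Inf, nrow(pts)); best_par <- rep(Inf, nrow(pts))
  for (r in seq_len(nrow(offs))) {
    idx <- sweep(base, 2L, offs[r, ], `+`)
    inb <- idx[, 1] >= 0 & idx[, 1] <= dm[1] - 1 & idx[, 2] >= 0 &
           idx[, 2] <= dm[2] - 1 & idx[, 3] >= 0 & idx[, 3] <= dm[3] - 1
    if (!any(inb)) next
    lin <- idx[inb, , drop = FALSE] + 1
    lab <- geom$labels[lin]
    wpos <- index_to_world(idx[inb, , drop = FALSE], geom$affine)
    dist <- sqrt(rowSums((wpos - pts[inb, , drop = FALSE])^2))
    sacv <- lab == LABELS[["sac"]]
    parv <- lab == LABELS[["parent_artery"]]
    bs <- best_sac[inb]; bp <- best_par[inb]
    bs[sacv] <- pmin(bs[sacv], dist[sacv])
    bp[parv] <- pmin(bp[parv], dist[parv])
    best_sac[inb] <- bs; best_par[inb] <- bp
  }
  best_sac < best_par
}

#' Normalized wall shear stress
#'
#' Divides each element's WSS magnitude by the maximum WSS over the aneurysm
#' sac (the sac-adjacent wall elements when \code{sac_elements} is given,
#' otherwise all valid elements). Sac-adjacent values therefore lie in [0, 1]
#' with the maximum exactly 1; parent-artery elements can exceed 1 when their
#' stress tops the sac maximum. An all-zero WSS field returns all zeros with a
#' warning rather than dividing by zero.
#'
#' @param wss numeric WSS magnitudes in Pa (NA allowed for invalid elements).
#' @param sac_elements optional logical vector marking sac-adjacent elements.
#' @return dimensionless nWSS vector, NA where \code{wss} is NA.
#' @export
normalized_wss <- function(wss, sac_elements = NULL) {
  vals <- wss
  if (!is.null(sac_elements)) {
    if (length(sac_elements) != length(wss)) stop("sac_elements length mismatch")
    vals <- wss[sac_elements]
  }
  if (all(is.na(vals))) stop("no valid wall elements to normalize against")
  m <- max(vals, na.rm = TRUE)
  if (m == 0) {
    warning("all wall shear stresses are zero; nWSS set to zero")
    return(wss * 0)
  }
  wss / m
}

#' Classify nWSS values into high / mid / low regions
#'
#' Thresholds follow the reporting convention for shear distributions:
#' high when nWSS >= \code{high_thresh} (default 0.75), low when
#' nWSS <= \code{low_thresh} (default 0.25), boundaries inclusive.
#'
#' @param nwss dimensionless nWSS values.
#' @param high_thresh,low_thresh classification thresholds.
#' @return factor with levels \code{low}, \code{mid}, \code{high} (NA kept).
#' @export
classify_nwss <- function(nwss, high_thresh = 0.75, low_thresh = 0.25) {
  out <- rep(NA_character_, length(nwss))
  out[!is.na(nwss) & nwss >= high_thresh] <- "high"
  out[!is.na(nwss) & nwss <= low_thresh] <- "low"
  out[!is.na(nwss) & nwss > low_thresh & nwss < high_thresh] <- "mid"
  factor(out, levels = c("low", "mid", "high"))
}

#' Relative reduction of a hemodynamic parameter, in percent
#'
#' 100 * (pre - post) / pre. The reporting layer rounds to integer percent
#' with halves away from zero (see \code{\link{round_half_away}}); this
#' function returns the unrounded value. Invariant under common rescaling of
#' both arguments, hence unit-independent.
#'
#' @param pre pre-treatment value, must be > 0.
#' @param post post-treatment value.
#' @export
relative_reduction <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    stop("pre-treatment value must be strictly positive")
  100 * (pre - post) / pre
}

#' Round half away from zero
#'
#' Integer rounding where .5 moves away from zero (the convention that
#' reproduces the published integer percent tables), unlike R's banker
#' rounding.
#' @param x numeric.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Bundle of per-case hemodynamic metrics
#'
#' Thin constructor for the scalar metric set of one case at one treatment
#' state; usually produced by \code{\link{case_metrics}} but can be filled by
#' hand (e.g. from published tables).
#'
#' @param U_peak average sac velocity at the systolic peak, m/s.
#' @param E_mean cycle-mean intra-aneurysmal kinetic energy, m^2/s^2.
#' @param R_mean mean recirculation, mm^2/s.
#' @param E_per_frame,R_per_frame optional per-frame series.
#' @param WSS optional per-element wall shear stresses, Pa.
#' @param nWSS optional normalized stresses.
#' @param peak_frame optional systolic peak frame index.
#' @param extra optional named list of additional fields (plane, N, ...).
#' @export
hemodynamic_metrics <- function(U_peak, E_mean, R_mean,
                                E_per_frame = NULL, R_per_frame = NULL,
                                WSS = NULL, nWSS = NULL, peak_frame = NULL,
                                extra = list()) {
  structure(c(list(U_peak = U_peak, E_mean = E_mean, R_mean = R_mean,
                   E_per_frame = E_per_frame, R_per_frame = R_per_frame,
                   WSS = WSS, nWSS = nWSS, peak_frame = peak_frame), extra),
            class = "hemodynamic_metrics")
}

#' @export
print.hemodynamic_metrics <- function(x, ...) {
  cat("hemodynamic_metrics\n")
  cat(sprintf("  U (systolic peak): %.4g m/s\n", x$U_peak))
  cat(sprintf("  E (cycle mean):    %.4g m^2/s^2\n", x$E_mean))
  cat(sprintf("  R_m:               %.4g mm^2/s\n", x$R_mean))
  if (!is.null(x$WSS))
    cat(sprintf("  WSS max:           %.4g Pa (%d valid elements)\n",
                max(x$WSS, na.rm = TRUE), sum(!is.na(x$WSS))))
  if (!is.null(x$peak_frame)) cat(sprintf("  peak frame:        %d\n", x$peak_frame))
  invisible(x)
}

metric_triple <- function(x, side) {
  if (inherits(x, "hemodynamic_metrics")) {
    trip <- c(U = x$U_peak, E = x$E_mean, R = x$R_mean)
  } else {
    trip <- as.numeric(x)
    if (length(trip) != 3L)
      stop(sprintf("%s side must be a hemodynamic_metrics object or a (U, E, R) triple", side))
    names(trip) <- c("U", "E", "R")
  }
  missing_m <- names(trip)[!is.finite(trip)]
  if (length(missing_m) > 0)
    stop(sprintf("%s side is missing metric(s): %s", side, paste(missing_m, collapse = ", ")))
  trip
}

#' Pre/post treatment comparison report
#'
#' Computes the relative reductions delta_U, delta_E, delta_R (percent) from a
#' pre- and a post-treatment metric set. Either side may be a full
#' \code{hemodynamic_metrics} object or a bare (U, E, R) triple, so published
#' per-case tables can be fed directly.
#'
#' @param pre,post \code{hemodynamic_metrics} or numeric (U, E, R) triples.
#' @param case_id case label.
#' @param method provenance tag, e.g. \code{"simulated"} or \code{"measured"}.
#' @return a \code{comparison_report} with unrounded \code{delta} and
#'   integer-rounded \code{delta_int} components.
#' @export
compare_pre_post <- function(pre, post, case_id = "case", method = "") {
  pt <- metric_triple(pre, "pre")
  qt <- metric_triple(post, "post")
  delta <- vapply(c("U", "E", "R"), function(k) relative_reduction(pt[[k]], qt[[k]]),
                  numeric(1))
  names(delta) <- c("delta_U", "delta_E", "delta_R")
  structure(list(case_id = case_id, method = method, pre = pt, post = qt,
                 delta = delta, delta_int = round_half_away(delta)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %s%s\n", x$case_id,
              if (nzchar(x$method)) paste0(" (", x$method, ")") else ""))
  cat(sprintf("  pre  U=%.4g E=%.4g R=%.4g\n", x$pre[1], x$pre[2], x$pre[3]))
  cat(sprintf("  post U=%.4g E=%.4g R=%.4g\n", x$post[1], x$post[2], x$post[3]))
  cat(sprintf("  delta U=%d%% E=%d%% R=%d%%\n",
              x$delta_int[1], x$delta_int[2], x$delta_int[3]))
  invisible(x)
}
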