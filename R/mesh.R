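# Triangle surface meshes: container, STL input/output, voxel-boundary
# extraction, and the analytic cylinder wall used by the tube phantom.

#' Construct a triangle surface mesh
#'
#' @param vertices n x 3 matrix of vertex coordinates in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices; the winding
#'   order defines the normal (right-hand rule).
#' @param kind optional per-face character labels (e.g. "lateral"/"cap" for
#'   the analytic cylinder).
#' @export
triangle_mesh <- function(vertices, faces, kind = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (any(faces < 1L) || any(faces > nrow(vertices))) stop("face indices out of range")
  if (!is.null(kind) && length(kind) != nrow(faces)) stop("kind must have one label per face")
  structure(list(vertices = vertices, faces = faces, kind = kind), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

# Per-face (un-normalized) normals: cross(v2-v1, v3-v1), length = 2*area.
face_cross <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  a <- v2 - v1; b <- v3 - v1
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a \code{triangle_mesh}.
#' @export
mesh_area <- function(mesh) sum(sqrt(rowSums(face_cross(mesh)^2))) / 2

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Positive when face normals point outward (divergence-theorem convention).
#' @param mesh a \code{triangle_mesh}.
#' @export
mesh_signed_volume <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cr <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
              v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
              v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(rowSums(v1 * cr)) / 6
}

#' Face centroids and outward unit normals
#' @param mesh a \code{triangle_mesh}.
#' @return list with \code{centroids} (m x 3 mm), \code{normals} (m x 3 unit),
#'   \code{areas} (mm^2).
#' @export
mesh_face_geometry <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- NA_real_
  list(centroids = (v1 + v2 + v3) / 3, normals = cr / len, areas = len / 2)
}

#' Weld duplicate vertices of a triangle soup
#'
#' Merges vertices closer than \code{tol} (by coordinate rounding) so that
#' STL triangle soups become connected meshes; drops degenerate faces.
#' @param mesh a \code{triangle_mesh}.
#' @param tol coordinate tolerance in mm.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  key <- apply(round(mesh$vertices / tol), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- mesh$vertices[first, , drop = FALSE]
  newf <- matrix(map[mesh$faces], ncol = 3L)
  degen <- newf[, 1] == newf[, 2] | newf[, 2] == newf[, 3] | newf[, 1] == newf[, 3]
  kind <- mesh$kind
  if (!is.null(kind)) kind <- kind[!degen]
  triangle_mesh(newv, newf[!degen, , drop = FALSE], kind)
}

#' Re-orient a closed mesh so that normals point outward
#'
#' Applies the signed-volume convention: if the enclosed signed volume is
#' negative, every face winding is flipped. Edges not shared by exactly two
#' faces are counted and reported in the \code{"nonmanifold_edges"} attribute.
#' @param mesh a welded \code{triangle_mesh}.
#' @export
orient_outward <- function(mesh) {
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  ed <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  nm <- sum(cnt != 2L)
  if (nm > 0)
    warning(sprintf("%d non-manifold or boundary edge(s) remain after welding", nm))
  attr(mesh, "nonmanifold_edges") <- nm
  mesh
}

#' Extract the closed boundary surface of a voxel mask
#'
#' Emits two triangles (outward winding) for every voxel face separating a
#' masked voxel from an unmasked one or from the grid exterior. The result is
#' watertight by construction and encloses all masked voxel centers.
#'
#' @param mask logical 3-D array.
#' @param spacing voxel edge lengths in mm.
#' @param affine 4x4 index-to-world map (voxel centers).
#' @export
mask_surface <- function(mask, spacing, affine = NULL) {
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  verts <- list(); faces <- list(); off <- 0L
  for (d in seq_len(6L)) {
    dvec <- dirs[d, ]
    axis <- which(dvec != 0)
    nb <- shift_array(mask, axis, as.integer(dvec[axis]), fill = FALSE)
    expose <- which(mask & !nb, arr.ind = TRUE)
    if (nrow(expose) == 0L) next
    # face center in index space: voxel center + dvec/2; corners span the
    # two axes orthogonal to `axis`.
    oax <- setdiff(1:3, axis)
    corner_off <- rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5))
    # The counter-clockwise corner cycle above gives a right-hand normal along
    # +axis for x and z faces but -axis for y faces (e1 x e3 = -e2); reverse
    # whenever that default disagrees with the outward direction dvec.
    default_positive <- axis != 2L
    if ((dvec[axis] > 0) != default_positive) corner_off <- corner_off[c(1, 4, 3, 2), ]
    base <- expose - 1  # 0-based centers
    for (cnr in 1:4) {
      ci <- base
      ci[, axis] <- ci[, axis] + dvec[axis] / 2
      ci[, oax[1]] <- ci[, oax[1]] + corner_off[cnr, 1]
      ci[, oax[2]] <- ci[, oax[2]] + corner_off[cnr, 2]
      verts[[length(verts) + 1L]] <- index_to_world(ci, affine)
    }
    nfc <- nrow(expose)
    i1 <- off + seq_len(nfc)
    i2 <- i1 + nfc; i3 <- i2 + nfc; i4 <- i3 + nfc
    faces[[length(faces) + 1L]] <- rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
    off <- off + 4L * nfc
  }
  if (off == 0L) stop("mask is empty")
  mesh <- triangle_mesh(do.call(rbind, verts), do.call(rbind, faces))
  mesh <- weld_vertices(mesh, tol = 1e-6)
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Analytic capped-cylinder wall mesh
#'
#' Lateral surface plus end caps of a cylinder of radius \code{radius} whose
#' axis runs along +x from \code{x0} to \code{x1} at (y, z) = (cy, cz).
#' Face labels distinguish \code{"lateral"} from \code{"cap"} elements.
#'
#' @param radius cylinder radius (mm).
#' @param x0,x1 axial extent (mm).
#' @param cy,cz axis position (mm).
#' @param n_theta angular segments.
#' @param n_axial axial segments.
#' @export
cylinder_mesh <- function(radius, x0, x1, cy = 0, cz = 0, n_theta = 48L, n_axial = 24L) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  xs <- seq(x0, x1, length.out = n_axial + 1L)
  ring <- cbind(cos(theta), sin(theta)) * radius
  verts <- do.call(rbind, lapply(xs, function(x) cbind(x, cy + ring[, 1], cz + ring[, 2])))
  idx <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  lat <- list()
  for (i in seq_len(n_axial)) {
    j <- seq_len(n_theta)
    # outward winding: normals point away from the axis
    lat[[i]] <- rbind(cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j)),
                      cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)))
  }
  nv <- nrow(verts)
  verts <- rbind(verts, c(x0, cy, cz), c(x1, cy, cz))
  c0 <- nv + 1L; c1 <- nv + 2L
  j <- seq_len(n_theta)
  cap0 <- cbind(rep(c0, n_theta), idx(1L, j + 1L), idx(1L, j))           # normal -x
  cap1 <- cbind(rep(c1, n_theta), idx(n_axial + 1L, j), idx(n_axial + 1L, j + 1L))  # normal +x
  faces <- rbind(do.call(rbind, lat), cap0, cap1)
  kind <- c(rep("lateral", 2L * n_theta * n_axial), rep("cap", 2L * n_theta))
  triangle_mesh(verts, faces, kind)
}

#' Read a triangulated wall surface from an STL file
#'
#' Accepts ASCII and binary STL. The triangle soup is welded into a connected
#' mesh, normals are recomputed and re-oriented outward by the signed-volume
#' convention (stored facet normals are not trusted), and any remaining
#' non-manifold edges are reported via a warning and the
#' \code{"nonmanifold_edges"} attribute.
#'
#' @param path STL file path.
#' @return a \code{triangle_mesh} with outward-facing windings.
#' @export
read_stl_surface <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  close(con)
  if (length(head) < 80L) stop("STL file too short or empty: ", path)
  txt <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt) && {
    body <- tryCatch(readLines(path, n = 50L, warn = FALSE), error = function(e) "")
    any(grepl("facet", body))
  }
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L) stop("STL file contains no facets: ", path)
  nf <- nrow(tri) / 3L
  mesh <- triangle_mesh(tri, matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE))
  orient_outward(weld_vertices(mesh))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  do.call(rbind, nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(nf) || is.na(nf) || nf <= 0L) stop("malformed binary STL: ", path)
  rec <- readBin(con, "raw", nf * 50L)
  if (length(rec) < nf * 50L) stop("truncated binary STL: ", path)
  m <- matrix(rec, nrow = 50L)
  tri <- matrix(NA_real_, nf * 3L, 3L)
  for (v in 1:3) {
    start <- 12L + (v - 1L) * 12L  # skip normal (12 bytes)
    for (k in 1:3) {
      bytes <- m[start + (k - 1L) * 4L + 1:4, , drop = FALSE]
      tri[seq(v, by = 3L, length.out = nf), k] <-
        readBin(as.raw(bytes), "double", nf, size = 4L, endian = "little")
    }
  }
  # interleaved as v1,v2,v3 per facet
  tri
}

#' Write a triangle mesh as ASCII STL
#'
#' Deterministic byte output for a fixed mesh (fixed numeric formatting).
#' @param mesh a \code{triangle_mesh}.
#' @param path output path.
#' @param name solid name written in the header.
#' @export
write_stl_surface <- function(mesh, path, name = "surface") {
  fg <- mesh_face_geometry(mesh)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  nrm <- fg$normals
  nrm[!is.finite(nrm)] <- 0
  out <- c(paste("solid", name),
           paste0("facet normal ", fmt(nrm), "\n",
                  " outer loop\n",
                  "  vertex ", fmt(v1), "\n",
                  "  vertex ", fmt(v2), "\n",
                  "  vertex ", fmt(v3), "\n",
                  " endloop\n",
                  "endfacet"),
           paste("endsolid", name))
  writeLines(out, path)
  invisible(path)
}
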