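# Readers and writers binding the pipeline to standard formats: per-component
# NIfTI velocity volumes, NIfTI label volumes, STL wall surfaces (mesh.R),
# and CSV/JSON comparison reports.

velocity_unit_scale <- function(units) {
  if (is.null(units) || length(units) != 1L || is.na(units))
    stop("velocity units must be declared explicitly (\"m/s\" or \"cm/s\"); refusing to guess")
  switch(units,
         "m/s" = 1,
         "cm/s" = 0.01,
         stop("unsupported velocity units: ", units, " (use \"m/s\" or \"cm/s\")"))
}

nifti_affine <- function(img) {
  x <- RNifti::xform(img)
  m <- matrix(as.numeric(x), 4, 4)
  m[4, ] <- c(0, 0, 0, 1)
  m
}

#' Read a 3-component velocity field from per-component NIfTI volumes
#'
#' Phase-contrast exports store one signed volume per encoding direction;
#' each file here is a 4-D NIfTI with frames on the fourth axis. The three
#' files must agree in shape and affine. Velocity units must be declared
#' (\code{"m/s"} or \code{"cm/s"}) and are converted to m/s in memory; there
#' is no silent default.
#'
#' @param path_x,path_y,path_z NIfTI files for the x/y/z velocity components.
#' @param times frame midpoints in s.
#' @param period cardiac cycle length in s.
#' @param units declared file units, \code{"m/s"} or \code{"cm/s"}.
#' @return a \code{velocity_field}.
#' @export
read_velocity_nifti <- function(path_x, path_y, path_z, times, period, units) {
  scale <- velocity_unit_scale(units)
  paths <- c(path_x, path_y, path_z)
  imgs <- lapply(paths, RNifti::readNifti)
  dims <- lapply(imgs, dim)
  affs <- lapply(imgs, nifti_affine)
  for (i in 2:3) {
    if (!identical(dims[[i]], dims[[1L]]))
      stop("velocity component shape mismatch in file: ", paths[i])
    if (max(abs(affs[[i]] - affs[[1L]])) > 1e-4)
      stop("velocity component affine mismatch in file: ", paths[i])
  }
  arrs <- lapply(imgs, function(im) {
    a <- as.array(im) * scale
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    a
  })
  spacing <- RNifti::pixdim(imgs[[1L]])[1:3]
  velocity_field(arrs[[1L]], arrs[[2L]], arrs[[3L]], spacing, times, period,
                 affine = affs[[1L]])
}

#' Write a velocity field as three per-component NIfTI volumes
#'
#' @param field a \code{velocity_field}.
#' @param path_x,path_y,path_z output NIfTI paths.
#' @param units units to write the samples in (\code{"m/s"} or \code{"cm/s"}).
#' @export
write_velocity_nifti <- function(field, path_x, path_y, path_z, units = "m/s") {
  scale <- velocity_unit_scale(units)
  dt <- if (length(field$times) > 1L) diff(field$times)[1L] else field$period
  paths <- c(path_x, path_y, path_z)
  comps <- list(field$vx, field$vy, field$vz)
  for (i in 1:3) {
    img <- RNifti::asNifti(comps[[i]] / scale)
    RNifti::pixdim(img) <- c(field$spacing, dt)
    RNifti::qform(img) <- structure(field$affine, code = 2L)
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Read a segmentation label volume from NIfTI
#'
#' Maps the integer codes found in the file onto the canonical classes
#' \code{outside}, \code{parent_artery}, \code{sac} via \code{label_map}.
#' Codes present in the file but absent from the map raise an error. The sac
#' voxel count N is recorded on the returned geometry.
#'
#' @param path NIfTI label volume (integer-valued).
#' @param label_map named integer vector with entries \code{outside},
#'   \code{parent_artery}, \code{sac} giving the file's codes.
#' @param surface optional \code{triangle_mesh} wall surface to attach.
#' @return a \code{segmented_geometry}.
#' @export
read_labels_nifti <- function(path, label_map = LABELS, surface = NULL) {
  needed <- c("outside", "parent_artery", "sac")
  if (!all(needed %in% names(label_map)))
    stop("label_map must name codes for: ", paste(needed, collapse = ", "))
  img <- RNifti::readNifti(path)
  raw <- as.array(img)
  if (max(abs(raw - round(raw))) > 1e-6)
    stop("label volume is not integer-valued: ", path)
  raw <- round(raw)
  codes <- sort(unique(as.vector(raw)))
  unknown <- setdiff(codes, as.integer(label_map[needed]))
  if (length(unknown) > 0)
    stop("label code(s) in file but not in label_map: ", paste(unknown, collapse = ", "))
  lab <- array(LABELS[["outside"]], dim(raw))
  lab[raw == label_map[["parent_artery"]]] <- LABELS[["parent_artery"]]
  lab[raw == label_map[["sac"]]] <- LABELS[["sac"]]
  segmented_geometry(lab, RNifti::pixdim(img)[1:3], nifti_affine(img), surface)
}

#' Write a segmentation label volume as NIfTI
#'
#' @param geom a \code{segmented_geometry}.
#' @param path output path.
#' @export
write_labels_nifti <- function(geom, path) {
  img <- RNifti::asNifti(geom$labels + 0L)
  RNifti::pixdim(img) <- geom$spacing
  RNifti::qform(img) <- structure(geom$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

report_row <- function(report) {
  data.frame(case = report$case_id, method = report$method,
             U_pre = signif(report$pre[["U"]], 3), E_pre = signif(report$pre[["E"]], 3),
             R_pre = signif(report$pre[["R"]], 3), U_post = signif(report$post[["U"]], 3),
             E_post = signif(report$post[["E"]], 3), R_post = signif(report$post[["R"]], 3),
             delta_U = as.integer(report$delta_int[["delta_U"]]),
             delta_E = as.integer(report$delta_int[["delta_E"]]),
             delta_R = as.integer(report$delta_int[["delta_R"]]),
             stringsAsFactors = FALSE)
}

#' Serialize comparison reports to CSV or JSON
#'
#' Columns are emitted in a stable order (case, method, the six pre/post
#' metrics, the three integer delta columns); metric values at 3 significant
#' figures, deltas as integer percent. Output bytes are deterministic for a
#' fixed report. The JSON variant embeds provenance (package version and,
#' when supplied, the seed).
#'
#' @param report a \code{comparison_report} or list of them.
#' @param path output file.
#' @param format \code{"csv"} or \code{"json"}.
#' @param seed optional integer recorded as provenance in JSON output.
#' @export
write_report <- function(report, path, format = c("csv", "json"), seed = NULL) {
  format <- match.arg(format)
  reports <- if (inherits(report, "comparison_report")) list(report) else report
  tab <- do.call(rbind, lapply(reports, report_row))
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(software = paste0("aneuflow ",
                                      as.character(utils::packageVersion("aneuflow"))),
                    rows = tab)
    if (!is.null(seed)) payload$seed <- as.integer(seed)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a serialized comparison report
#'
#' @param path CSV or JSON file produced by \code{\link{write_report}}.
#' @return data.frame in the writer's column order.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)$rows)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Describe a case's files on disk
#'
#' A case bundle points at the three velocity-component volumes, the label
#' volume, the wall surface, and the acquisition metadata needed to assemble
#' a \code{velocity_field} (declared units, frame times, cycle length).
#'
#' @param dir directory holding the files.
#' @param case_id case label.
#' @param method provenance tag (e.g. "simulated", "measured").
#' @param units declared velocity units of the NIfTI files.
#' @param times frame midpoints in s.
#' @param period cycle length in s.
#' @param label_map label codes used in the label volume.
#' @export
case_bundle <- function(dir, case_id = basename(dir), method = "simulated",
                        units = "m/s", times, period, label_map = LABELS) {
  paths <- list(vx = file.path(dir, "velocity_x.nii"),
                vy = file.path(dir, "velocity_y.nii"),
                vz = file.path(dir, "velocity_z.nii"),
                labels = file.path(dir, "labels.nii"),
                surface = file.path(dir, "wall.stl"))
  structure(list(dir = dir, paths = paths, case_id = case_id, method = method,
                 units = units, times = times, period = period,
                 label_map = label_map),
            class = "case_bundle")
}

#' Load the field and geometry of a case bundle
#'
#' @param bundle a \code{case_bundle} (or a directory containing
#'   \code{bundle.json} written by \code{\link{simulate_case}}).
#' @return list with \code{field} and \code{geom}.
#' @export
read_case_bundle <- function(bundle) {
  if (is.character(bundle)) bundle <- load_bundle_json(bundle)
  required <- unlist(bundle$paths[c("vx", "vy", "vz", "labels")])
  if (any(!file.exists(required)))
    stop("missing bundle file(s): ", paste(required[!file.exists(required)], collapse = ", "))
  field <- read_velocity_nifti(bundle$paths$vx, bundle$paths$vy, bundle$paths$vz,
                               times = bundle$times, period = bundle$period,
                               units = bundle$units)
  surface <- if (file.exists(bundle$paths$surface))
    read_stl_surface(bundle$paths$surface) else NULL
  lm <- bundle$label_map
  if (!is.null(names(lm))) lm <- unlist(lm)
  geom <- read_labels_nifti(bundle$paths$labels, label_map = lm, surface = surface)
  if (!identical(dim(geom$labels), dim(field$vx)[1:3]))
    stop("label volume shape does not match the velocity grid in bundle: ", bundle$dir)
  if (max(abs(geom$affine - field$affine)) > 1e-4)
    stop("label volume affine does not match the velocity grid in bundle: ", bundle$dir)
  list(field = field, geom = geom, bundle = bundle)
}

load_bundle_json <- function(dir) {
  path <- if (grepl("\\.json$", dir)) dir else file.path(dir, "bundle.json")
  if (!file.exists(path)) stop("no bundle.json found at ", path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- case_bundle(dirname(path), case_id = meta$case_id, method = meta$method,
                   units = meta$units, times = as.numeric(meta$times),
                   period = meta$period,
                   label_map = unlist(meta$label_map))
  b
}
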