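#' 3D image volume with grid geometry
#'
#' The common currency of all pipeline stages: a 3D scalar array tagged with a
#' physical unit, plus its grid geometry. Coordinates follow a fixed LPS world
#' frame with axis-aligned grids; voxel indices are 0-based and the world
#' coordinate of a voxel is the position of its centre, `origin + index *
#' spacing` per axis.
#'
#' @param values 3D numeric array.
#' @param spacing mm triplet, all strictly positive.
#' @param origin mm triplet: world position of the centre of voxel (0,0,0).
#' @param unit one of `"HU"`, `"rED"`, `"Gy"`, `"MR"` (arbitrary MR intensity).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0), unit = "HU") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be strictly positive", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite mm triplet", call. = FALSE)
  unit <- match.arg(unit, c("HU", "rED", "Gy", "MR"))
  if (unit == "rED" && any(values < 0, na.rm = TRUE))
    stop("rED-tagged volumes must be everywhere >= 0", call. = FALSE)
  storage.mode(values) <- "double"
  structure(
    list(values = values, spacing = spacing, origin = origin,
         unit = unit, frame = "LPS"),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels [%s], spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
    d[1], d[2], d[3], x$unit, x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid geometry of a volume
#'
#' @param x an `image_volume`, `structure_set`, or a geometry list.
#' @return list with `dims`, `spacing`, `origin`.
#' @export
grid_geometry <- function(x) {
  if (inherits(x, "image_volume"))
    return(list(dims = dim(x$values), spacing = x$spacing, origin = x$origin))
  if (inherits(x, "structure_set")) return(x$geometry)
  if (is.list(x) && all(c("dims", "spacing", "origin") %in% names(x)))
    return(list(dims = as.integer(x$dims), spacing = as.numeric(x$spacing),
                origin = as.numeric(x$origin)))
  stop("cannot extract a grid geometry from this object", call. = FALSE)
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- grid_geometry(a); gb <- grid_geometry(b)
  all(ga$dims == gb$dims) &&
    all(abs(ga$spacing - gb$spacing) <= tol) &&
    all(abs(ga$origin - gb$origin) <= tol)
}

#' Convert world coordinates (mm) to continuous voxel indices
#'
#' Indices are 0-based and satisfy `point = origin + index * spacing` per axis.
#' Out-of-grid points simply return out-of-range indices.
#'
#' @param vol an `image_volume` (or grid geometry).
#' @param points numeric mm triplet or an n x 3 matrix of points.
#' @return continuous index triplet (or n x 3 matrix).
#' @export
world_to_index <- function(vol, points) {
  g <- grid_geometry(vol)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sweep(sweep(points, 2, g$origin, "-"), 2, g$spacing, "/")
}

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @inheritParams world_to_index
#' @param index index triplet or n x 3 matrix (0-based, may be fractional).
#' @export
index_to_world <- function(vol, index) {
  g <- grid_geometry(vol)
  if (is.null(dim(index))) index <- matrix(index, ncol = 3)
  sweep(sweep(index, 2, g$spacing, "*"), 2, g$origin, "+")
}

#' Rigid spatial transform
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation mm triplet.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("translation must be a finite mm triplet", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Rotation about a grid axis
#'
#' Convenience constructor: right-handed rotation by `angle_deg` about the
#' given world axis, with an optional centre of rotation.
#'
#' @param axis 1, 2, or 3 (x/y/z).
#' @param angle_deg rotation angle in degrees.
#' @param translation extra mm translation applied after the rotation.
#' @param center mm triplet the rotation pivots about.
#' @export
axis_rotation <- function(axis, angle_deg, translation = c(0, 0, 0),
                          center = c(0, 0, 0)) {
  th <- angle_deg * pi / 180
  c2 <- cos(th); s2 <- sin(th)
  R <- diag(3)
  ax <- setdiff(1:3, axis)
  R[ax[1], ax[1]] <- c2; R[ax[2], ax[2]] <- c2
  R[ax[1], ax[2]] <- -s2; R[ax[2], ax[1]] <- s2
  rigid_transform(R, translation + center - R %*% center)
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#' @param a,b `rigid_transform` objects.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x a `rigid_transform`.
#' @export
invert_transform <- function(x) {
  rigid_transform(t(x$rotation), -as.numeric(t(x$rotation) %*% x$translation))
}

#' Apply a rigid transform to points
#' @param x a `rigid_transform`.
#' @param points mm triplet or n x 3 matrix.
#' @export
apply_transform <- function(x, points) {
  drop1 <- is.null(dim(points))
  if (drop1) points <- matrix(points, ncol = 3)
  out <- points %*% t(x$rotation)
  out <- sweep(out, 2, x$translation, "+")
  if (drop1) drop(out) else out
}

is_identity_transform <- function(x, tol = 0) {
  max(abs(x$rotation - diag(3))) <= tol && max(abs(x$translation)) <= tol
}

default_fill_value <- function(unit) {
  switch(unit, HU = -1000, rED = 0.001, Gy = 0, MR = 0)
}

#' Read a volume from a NIfTI file
#'
#' Grid geometry is taken bit-exactly from the sform (or, failing that, qform)
#' header matrix, which must be axis-aligned; the stored matrix is interpreted
#' directly in the package's LPS world frame.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param unit unit tag to attach (`"HU"`, `"rED"`, `"Gy"`, `"MR"`).
#' @export
read_volume <- function(path, unit = "HU") {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable volume file: ", path,
                                           call. = FALSE))
  m <- RNifti::xform(img, useQuaternionFirst = FALSE)
  rot <- m[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6)
    stop("header error: only axis-aligned volumes are supported",
         call. = FALSE)
  spacing <- diag(rot)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("header error: non-positive or missing voxel spacing", call. = FALSE)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(img)[1:3])
  image_volume(vals, spacing = spacing, origin = m[1:3, 4], unit = unit)
}

#' Write a volume to a NIfTI file
#'
#' @param vol an `image_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$values, datatype = "double")
  m <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  attr(m, "code") <- 2L
  RNifti::sform(img) <- m
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto a target grid through a rigid transform
#'
#' `transform` maps source-volume world coordinates into target-grid world
#' coordinates (it moves the image); internally the inverse is used to pull
#' values back from the source. Output voxels that map outside the source
#' support take a unit-dependent fill value (-1000 HU, 0.001 rED, 0 Gy, 0 MR).
#'
#' @param vol an `image_volume`, or a logical 3D array (mask) together with
#'   `geometry`.
#' @param target target grid: an `image_volume`, `structure_set`, or geometry
#'   list.
#' @param transform a `rigid_transform` (default identity).
#' @param mode `"linear"` (intensities) or `"nearest"` (masks / labels).
#' @param geometry grid geometry of `vol` when `vol` is a bare mask array.
#' @return an `image_volume` on the target grid, or a logical mask when the
#'   input was a mask.
#' @export
resample_to_grid <- function(vol, target, transform = rigid_transform(),
                             mode = c("linear", "nearest"), geometry = NULL) {
  mode <- match.arg(mode)
  is_mask <- is.logical(vol)
  if (is_mask) {
    if (mode != "nearest")
      stop("usage error: boolean masks must be resampled with mode = \"nearest\"",
           call. = FALSE)
    if (is.null(geometry))
      stop("`geometry` is required when resampling a bare mask array",
           call. = FALSE)
    src_g <- grid_geometry(geometry)
    vals <- array(as.double(vol), dim = dim(vol))
    unit <- "MR"
    fill <- 0
  } else {
    stopifnot(inherits(vol, "image_volume"))
    src_g <- grid_geometry(vol)
    vals <- vol$values
    unit <- vol$unit
    fill <- default_fill_value(unit)
  }
  tg <- grid_geometry(target)
  inv <- invert_transform(transform)
  out <- cpp_resample(as.vector(vals), as.integer(src_g$dims), src_g$origin,
                      src_g$spacing, as.integer(tg$dims), tg$origin,
                      tg$spacing, inv$rotation, inv$translation,
                      if (mode == "nearest") 0L else 1L, fill)
  arr <- array(out, dim = tg$dims)
  if (is_mask) return(arr > 0.5)
  image_volume(arr, spacing = tg$spacing, origin = tg$origin, unit = unit)
}

#' Named ROI masks on a reference grid
#'
#' @param geometry grid geometry the masks live on (list or `image_volume`).
#' @param rois named list; each element is `list(role =, mask =)` with role in
#'   `target`, `oar`, `bone`, `air`, `body` and `mask` a logical array on the
#'   reference grid.
#' @export
structure_set <- function(geometry, rois) {
  g <- grid_geometry(geometry)
  if (is.null(names(rois)) || any(names(rois) == ""))
    stop("every ROI must be named", call. = FALSE)
  roles <- c("target", "oar", "bone", "air", "body")
  for (nm in names(rois)) {
    r <- rois[[nm]]
    if (!is.list(r) || !all(c("role", "mask") %in% names(r)))
      stop("ROI `", nm, "` must be list(role=, mask=)", call. = FALSE)
    if (!r$role %in% roles)
      stop("ROI `", nm, "` has unknown role `", r$role, "`", call. = FALSE)
    if (!is.logical(r$mask) || !all(dim(r$mask) == g$dims))
      stop("mask of ROI `", nm,
           "` must be a logical array on the reference grid", call. = FALSE)
  }
  body <- vapply(rois, function(r) r$role == "body", logical(1))
  if (sum(body) != 1L) stop("exactly one body ROI is required", call. = FALSE)
  if (!any(rois[[which(body)]]$mask))
    stop("body mask must be non-empty", call. = FALSE)
  structure(list(geometry = g, rois = rois), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROIs on %d x %d x %d grid\n",
              length(x$rois), x$geometry$dims[1], x$geometry$dims[2],
              x$geometry$dims[3]))
  for (nm in names(x$rois))
    cat(sprintf("  %-12s %-7s %d voxels\n", nm, x$rois[[nm]]$role,
                sum(x$rois[[nm]]$mask)))
  invisible(x)
}

#' @rdname structure_set
#' @param x a `structure_set`.
#' @param name ROI name.
#' @export
roi_mask <- function(x, name) {
  if (!name %in% names(x$rois))
    stop("no ROI named `", name, "`", call. = FALSE)
  x$rois[[name]]$mask
}

#' @rdname structure_set
#' @export
roi_names <- function(x) names(x$rois)

#' @rdname structure_set
#' @export
roi_roles <- function(x) vapply(x$rois, function(r) r$role, character(1))

#' Propagate all masks of a structure set onto another grid
#'
#' Nearest-neighbour resampling through a rigid transform, the standard way a
#' planning system copies contours between co-registered image sets.
#'
#' @param structures a `structure_set`.
#' @param target target grid geometry.
#' @param transform `rigid_transform` mapping structure-set world coordinates
#'   into target world coordinates.
#' @export
propagate_structures <- function(structures, target,
                                 transform = rigid_transform()) {
  tg <- grid_geometry(target)
  rois <- lapply(structures$rois, function(r) {
    list(role = r$role,
         mask = resample_to_grid(r$mask, tg, transform, mode = "nearest",
                                 geometry = structures$geometry))
  })
  structure_set(tg, rois)
}

#' Write / read a structure set as a JSON manifest plus NIfTI masks
#'
#' The manifest stores the grid geometry and one `{name, role, mask_file}`
#' record per ROI; masks are written as uint8 NIfTI volumes next to it.
#'
#' @param structures a `structure_set`.
#' @param dir output directory (created if needed).
#' @export
write_structure_set <- function(structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- structures$geometry
  recs <- lapply(names(structures$rois), function(nm) {
    fn <- paste0("mask_", nm, ".nii.gz")
    vol <- image_volume(array(as.double(structures$rois[[nm]]$mask),
                              dim = g$dims),
                        spacing = g$spacing, origin = g$origin, unit = "MR")
    write_volume(vol, file.path(dir, fn))
    list(name = nm, role = structures$rois[[nm]]$role, mask_file = fn)
  })
  manifest <- list(geometry = list(dims = g$dims, spacing = g$spacing,
                                   origin = g$origin),
                   rois = recs)
  jsonlite::write_json(manifest, file.path(dir, "structures.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_structure_set
#' @export
read_structure_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "structures.json"),
                                  simplifyVector = TRUE)
  g <- list(dims = as.integer(manifest$geometry$dims),
            spacing = as.numeric(manifest$geometry$spacing),
            origin = as.numeric(manifest$geometry$origin))
  recs <- manifest$rois
  rois <- list()
  for (i in seq_len(nrow(recs))) {
    vol <- read_volume(file.path(dir, recs$mask_file[i]), unit = "MR")
    rois[[recs$name[i]]] <- list(role = recs$role[i],
                                 mask = vol$values > 0.5)
  }
  structure_set(g, rois)
}
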