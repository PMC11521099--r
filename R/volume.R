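#' 3D intensity volumes
#'
#' A `mri_volume` is a plain 3D numeric array carrying voxel spacing (mm per
#' axis) and, once [normalize_volume()] has been applied, the normalization
#' interval its intensities live in. Axes are ordered (x, y, z) in a
#' RAS-like layout: axis 1 runs left-to-right (sagittal index), axis 2
#' posterior-to-anterior (coronal index), axis 3 inferior-to-superior
#' (axial index).
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3 voxel size in mm per axis.
#' @param range optional numeric `c(lo, hi)` normalization interval; `NULL`
#'   for raw (unnormalized) volumes.
#' @return A `mri_volume` object.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), range = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array, got rank ",
         if (is.array(data)) length(dim(data)) else 1L, call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1", call. = FALSE)
  storage.mode(data) <- "double"
  structure(data,
            spacing = as.numeric(spacing),
            intensity_range = if (is.null(range)) NULL else as.numeric(range),
            class = c("mri_volume", "array"))
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x)
  rng <- attr(x, "intensity_range")
  cat(sprintf("<mri_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(attr(x, "spacing"), digits = 3), collapse = " x ")))
  cat(sprintf("  intensities in [%.4g, %.4g]%s\n", min(x), max(x),
              if (is.null(rng)) " (raw)"
              else sprintf(", normalized to [%g, %g]", rng[1], rng[2])))
  invisible(x)
}

volume_data <- function(v) {
  a <- unclass(v)
  attr(a, "spacing") <- NULL
  attr(a, "intensity_range") <- NULL
  a
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 image, canonicalizes its orientation to RAS and
#' returns the raw (unnormalized) intensities as a [as_volume()] object.
#'
#' @param path path to a `.nii` or `.nii.gz` file with exactly 3 spatial
#'   dimensions.
#' @return A `mri_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L) {
    stop("expected a 3D image, found rank ", nd, " in ", path, call. = FALSE)
  }
  # canonical RAS-like layout so slice axes mean the same thing for all
  # inputs; images without xform metadata are taken as already canonical
  suppressWarnings(try(RNifti::orientation(img) <- "RAS", silent = TRUE))
  sp <- RNifti::pixdim(img)
  as_volume(array(as.numeric(img), dim = dim(img)), spacing = sp[seq_len(3)])
}

#' Write a volume as NIfTI
#'
#' @param v a `mri_volume`.
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "mri_volume"))
  img <- RNifti::asNifti(volume_data(v), pixdim = attr(v, "spacing"))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Min-max intensity normalization
#'
#' Rescales intensities so the volume minimum maps to `range[1]` and the
#' maximum to `range[2]`. A constant volume maps every voxel to the interval
#' midpoint. The default interval (-1, 1) matches the tanh output layer of
#' the reconstruction autoencoder; use (0, 1) when comparing against
#' metrics reported on a unit scale.
#'
#' @param v a `mri_volume`.
#' @param range numeric `c(lo, hi)` with `lo < hi`.
#' @return A normalized `mri_volume` carrying `range` as metadata.
#' @export
normalize_volume <- function(v, range = c(-1, 1)) {
  stopifnot(inherits(v, "mri_volume"))
  if (length(range) != 2L || !(range[1] < range[2])) {
    stop("`range` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  a <- volume_data(v)
  lo <- min(a); hi <- max(a)
  out <- if (hi > lo) {
    range[1] + (a - lo) * (range[2] - range[1]) / (hi - lo)
  } else {
    array(mean(range), dim = dim(a))
  }
  as_volume(out, spacing = attr(v, "spacing"), range = range)
}

#' Flatten a volume to a 1D vector
#'
#' Flattening uses a fixed last-axis-fastest order (C/row-major over the
#' (x, y, z) axes): voxel (i, j, k) of an (m, a, b) volume lands at flat
#' position `(i-1)*a*b + (j-1)*b + k` (1-based). A 128x128x128 volume
#' flattens to 2,097,152 values. The result remembers the origin shape so
#' [unflatten_volume()] is an exact inverse.
#'
#' @param v a `mri_volume`.
#' @return A `flat_volume`: numeric vector with `origin_shape`, `order`,
#'   `spacing` and `intensity_range` attributes.
#' @export
flatten_volume <- function(v) {
  stopifnot(inherits(v, "mri_volume"))
  a <- volume_data(v)
  structure(as.vector(aperm(a, c(3L, 2L, 1L))),
            origin_shape = dim(a),
            order = "last-axis-fastest",
            spacing = attr(v, "spacing"),
            intensity_range = attr(v, "intensity_range"),
            class = "flat_volume")
}

#' Rebuild a volume from a flattened vector
#'
#' @param f a `flat_volume`, or a bare numeric vector together with `shape`.
#' @param shape origin shape, required when `f` has no `origin_shape`.
#' @return A `mri_volume`; exact inverse of [flatten_volume()].
#' @export
unflatten_volume <- function(f, shape = attr(f, "origin_shape")) {
  if (is.null(shape)) stop("origin shape unknown; pass `shape`", call. = FALSE)
  if (length(f) != prod(shape)) {
    stop(sprintf("length %d does not match shape %s (needs %d)",
                 length(f), paste(shape, collapse = "x"), prod(shape)),
         call. = FALSE)
  }
  a <- aperm(array(as.numeric(f), dim = rev(shape)), c(3L, 2L, 1L))
  as_volume(a,
            spacing = attr(f, "spacing") %||% c(1, 1, 1),
            range = attr(f, "intensity_range"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a 2D slice from a volume
#'
#' In the package's RAS-like axis convention, `sagittal` slices fix axis 1,
#' `coronal` axis 2 and `axial` axis 3. `index` is 1-based.
#'
#' @param v a `mri_volume`.
#' @param axis one of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param index 1-based slice position along the chosen axis.
#' @return An `mri_slice`: a numeric matrix with `axis` and `index`
#'   attributes.
#' @export
extract_slice <- function(v, axis = c("axial", "coronal", "sagittal"), index) {
  stopifnot(inherits(v, "mri_volume"))
  axis <- match.arg(axis)
  dim_i <- switch(axis, sagittal = 1L, coronal = 2L, axial = 3L)
  extent <- dim(v)[dim_i]
  if (length(index) != 1L || index < 1L || index > extent) {
    stop(sprintf("slice index %s out of range [1, %d] on %s axis",
                 format(index), extent, axis), call. = FALSE)
  }
  a <- volume_data(v)
  s <- switch(axis,
              sagittal = a[index, , ],
              coronal  = a[, index, ],
              axial    = a[, , index])
  as_slice(s, axis = axis, index = as.integer(index),
           range = attr(v, "intensity_range"))
}

#' Construct a 2D slice object
#'
#' @param data numeric matrix.
#' @param axis anatomical axis label.
#' @param index 1-based slice position.
#' @param range optional normalization interval.
#' @return An `mri_slice`.
#' @export
as_slice <- function(data, axis = "axial", index = 1L, range = NULL) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (length(data) < 1L) stop("slice must be non-empty", call. = FALSE)
  storage.mode(data) <- "double"
  structure(data, axis = axis, index = as.integer(index),
            intensity_range = if (is.null(range)) NULL else as.numeric(range),
            class = c("mri_slice", "matrix", "array"))
}

slice_data <- function(s) {
  a <- unclass(s)
  attr(a, "axis") <- NULL
  attr(a, "index") <- NULL
  attr(a, "intensity_range") <- NULL
  a
}

#' @export
print.mri_slice <- function(x, ...) {
  cat(sprintf("<mri_slice> %d x %d (%s axis, index %d)\n",
              nrow(x), ncol(x), attr(x, "axis"), attr(x, "index")))
  invisible(x)
}
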