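# Grid-level domain types and NIfTI I/O.
#
# Internal arrays are ordered (x, y, z), matching the NIfTI header spacing
# order; every module uses 0-based half-open voxel boxes. Volumes are
# reoriented to the canonical RAS orientation on read so that mirroring and
# axis transposition are well defined.

#' CT volume with spatial metadata
#'
#' @param data 3D numeric array of Hounsfield-like intensities, axes (x,y,z).
#' @param spacing Per-axis voxel size in mm; all strictly positive.
#' @param origin Physical coordinate (mm) of the centre of voxel (0,0,0).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- validate_grid(data, spacing, origin)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "ct_volume")
}

#' Integer label mask on a CT grid
#'
#' Values are restricted to 0 (background), 1 (kidney), 2 (tumor).
#'
#' @inheritParams ct_volume
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- validate_grid(data, spacing, origin)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1, 2)))
    stopf("label mask values must lie in {0,1,2}; found %s",
          paste(utils::head(setdiff(vals, 0:2), 5), collapse = ", "))
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "label_mask")
}

validate_grid <- function(data, spacing, origin) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("data must be a 3D array, got %s axes",
          if (is.array(data)) length(dim(data)) else "no")
  if (any(dim(data) < 1L)) stopf("each grid extent must be >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be three strictly positive values")
  if (length(origin) != 3L) stopf("origin must have length 3")
  data
}

is_grid <- function(x) inherits(x, c("ct_volume", "label_mask"))

grid_dim <- function(x) dim(x$data)

#' Check that two grids share extents and spacing
#' @param vol,mask Two grid objects.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_same_grid <- function(vol, mask) {
  if (!identical(grid_dim(vol), grid_dim(mask)))
    stopf("grids differ in extent: %s vs %s",
          paste(grid_dim(vol), collapse = "x"),
          paste(grid_dim(mask), collapse = "x"))
  if (max(abs(vol$spacing - mask$spacing)) > 1e-6)
    stopf("grids differ in spacing")
  invisible(TRUE)
}

#' Read a 3D NIfTI volume
#'
#' The image is reoriented to canonical RAS; spacing is taken from the header
#' and the origin from the translation of the stored transform.
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D image.
#' @param kind `"image"` for a [ct_volume()], `"mask"` for a [label_mask()].
#' @return A `ct_volume` or `label_mask`.
#' @export
read_volume <- function(path, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stopf("expected a 3D image, got %dD: %s", length(dim(img)), path)
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  spacing <- RNifti::pixdim(img)
  if (any(spacing <= 0)) stopf("non-positive voxel spacing in header: %s", path)
  origin <- RNifti::xform(img)[1:3, 4]
  arr <- array(as.numeric(img), dim(img))
  if (kind == "mask") label_mask(round(arr), spacing, origin)
  else ct_volume(arr, spacing, origin)
}

#' Write a volume or mask as NIfTI
#'
#' Label masks are written with an integer datatype so labels round-trip
#' losslessly; images are written as 32-bit float.
#'
#' @param vol A `ct_volume` or `label_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_grid(vol))
  dtype <- if (inherits(vol, "label_mask")) "int16" else "float"
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  aff <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("ct_volume %s @ (%s) mm, range [%.1f, %.1f]\n",
              paste(grid_dim(x), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$data, levels = 0:2,
                      labels = c("background", "kidney", "tumor")))
  cat(sprintf("label_mask %s @ (%s) mm; %s\n",
              paste(grid_dim(x), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = ", "),
              paste(names(tab), as.integer(tab), sep = "=", collapse = " ")))
  invisible(x)
}
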