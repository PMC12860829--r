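#' 3D scalar volume with voxel spacing and brain mask
#'
#' The unit of imaging data throughout the package: a 3D intensity grid
#' (arbitrary units), millimetre voxel spacing along each axis, and a logical
#' brain mask of the same shape. Voxel indices are treated as 0-based grid
#' coordinates internally; world coordinates are ignored (phantom volumes are
#' born aligned).
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, mm per voxel along each axis (positive).
#' @param mask Logical array of the same shape, or `NULL` for the default
#'   mask of finite, nonzero voxels.
#' @return An object of class `pf_volume` with fields `data`, `spacing`,
#'   `mask`.
#' @export
volume3d <- function(data, spacing = c(2, 2, 2), mask = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values")
  if (is.null(mask)) {
    mask <- is.finite(data) & data != 0
  }
  if (!identical(dim(mask), dim(data)))
    stop("`mask` and `data` must share one shape")
  storage.mode(mask) <- "logical"
  structure(list(data = data, spacing = spacing, mask = mask),
            class = "pf_volume")
}

#' @export
print.pf_volume <- function(x, ...) {
  cat(sprintf("<pf_volume> %s voxels, spacing %s mm, %d masked\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' @export
dim.pf_volume <- function(x) dim(x$data)

#' Read a NIfTI-1 volume
#'
#' Grid and spacing come from the header. The default mask keeps finite,
#' nonzero voxels; a companion mask file (nonzero = in mask) overrides it.
#'
#' @param path Path to a NIfTI-1 file holding a 3D image.
#' @param mask_path Optional companion NIfTI mask file.
#' @return A [volume3d()] object.
#' @export
read_volume <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L) stop("not a 3D image: ", path)
  arr <- array(as.numeric(arr), dim(arr))  # plain array, no header attrs
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(spacing <= 0)) stop("non-positive voxel spacing in header")
  if (is.null(mask_path)) {
    mask <- is.finite(arr) & arr != 0
  } else {
    m <- as.array(RNifti::readNifti(mask_path))
    if (!identical(dim(m)[1:3], dim(arr))) stop("mask shape mismatch")
    mask <- array(m != 0, dim(arr))
  }
  arr[!is.finite(arr)] <- 0
  volume3d(arr, spacing, mask)
}

#' Write a volume as NIfTI-1
#'
#' The grid is stored at double precision so a read/write round trip is
#' bit-identical.
#'
#' @param volume A [volume3d()] (or any list with `data` and `spacing`).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
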