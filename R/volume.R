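#' Create a voxel volume
#'
#' A `voxel_volume` is a scalar field (relative stopping-power density, or
#' dose in Gy) sampled on a regular 3-D grid.  Coordinates are millimetres
#' and voxel-center based: the world position of 0-based index `(i,j,k)` is
#' `origin + c(i,j,k) * spacing`.
#'
#' @param values numeric 3-D array (or vector reshaped by `dim`).
#' @param spacing numeric length-3, mm per axis (> 0).
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   center.  Default centers the grid on the world origin.
#' @param dim integer length-3, required when `values` is not an array.
#' @return an object of class `voxel_volume` with fields `values`,
#'   `spacing`, `origin`.
#' @export
voxel_volume <- function(values, spacing, origin = NULL, dim = NULL) {
  if (is.null(dim)) {
    dim <- base::dim(values)
    if (is.null(dim) || length(dim) != 3L)
      stop("`values` must be a 3-D array or `dim` must be given")
  } else {
    values <- array(values, dim = dim)
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0 on all axes")
  if (any(!is.finite(values))) stop("values must be finite")
  if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' Voxel volume in cc
#' @param vol a `voxel_volume` or a list with a `spacing` field.
#' @return volume of one voxel in cubic centimetres.
#' @export
voxel_cc <- function(vol) prod(vol$spacing) / 1000

#' World coordinates of all voxel centers
#'
#' @param vol a `voxel_volume`.
#' @return an `n x 3` matrix of mm coordinates, rows in R array order
#'   (first axis fastest).
#' @export
grid_points <- function(vol) {
  d <- dim(vol$values)
  ax <- lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

#' World coordinates of the voxels in a mask
#' @param vol a `voxel_volume` providing the grid.
#' @param mask logical array with the grid's dimensions.
#' @return `sum(mask) x 3` matrix of mm coordinates.
#' @export
mask_points <- function(vol, mask) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' Trilinear interpolation of a volume at arbitrary points
#'
#' Points outside the grid (beyond half a voxel past the border centers)
#' evaluate to 0; the half-voxel border shell clamps to the nearest face.
#'
#' @param vol a `voxel_volume`.
#' @param pts `n x 3` matrix of mm coordinates.
#' @return numeric vector of length `n`.
#' @export
interp_volume <- function(vol, pts) {
  cpp_trilinear(as.numeric(vol$values), dim(vol$values),
                vol$spacing, vol$origin, as.matrix(pts))
}

#' Write / read a volume in NIfTI format
#'
#' Thin wrappers around \pkg{RNifti}; spacing is stored in the header
#' (`pixdim`) and the origin in the qform translation.
#'
#' @param vol a `voxel_volume` (or a logical mask array plus `like`).
#' @param path file path, conventionally ending in `.nii` or `.nii.gz`.
#' @return `read_volume` returns a `voxel_volume`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3])
}
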