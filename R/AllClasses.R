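#' @include dmrisynth-package.R
NULL

## Central containers. All voxel grids are stored as dense arrays with a voxel
## spacing (mm per axis) and a 4x4 voxel-to-world affine. Multi-channel fields
## keep the channel dimension last: 9 channels for (log-)tensor fields
## (row-major flattened 3x3) and K = (L+1)(L+2)/2 channels for ODF fields.

setClass("GridVolume",
  representation("VIRTUAL",
    data = "array",
    spacing = "numeric",
    affine = "matrix"))

validGrid <- function(object, ndim, nchan = NULL) {
  d <- dim(object@data)
  if (length(d) != ndim)
    return(sprintf("data must be a %dD array, got %dD", ndim, length(d)))
  if (!is.null(nchan) && d[4] != nchan)
    return(sprintf("channel count must be %d, got %d", nchan, d[4]))
  if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values (mm)")
  if (!all(dim(object@affine) == c(4, 4)))
    return("affine must be a 4x4 matrix")
  TRUE
}

#' Scalar structural volume
#'
#' A 3D scalar image (e.g., a T1-weighted volume) with intensities normalized
#' to the unit interval. This is the real-valued domain of the synthesis task.
#'
#' @slot data 3D numeric array in `[0, 1]`.
#' @slot spacing voxel size in mm per axis.
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("StructuralVolume", contains = "GridVolume")

setValidity("StructuralVolume", function(object) {
  msg <- validGrid(object, 3)
  if (!isTRUE(msg)) return(msg)
  rng <- range(object@data)
  if (!all(is.finite(rng))) return("data contains non-finite values")
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
    return("structural intensities must lie in [0, 1]")
  TRUE
})

#' Diffusion tensor field
#'
#' A 3D grid of 3x3 symmetric positive-definite diffusion tensors stored as 9
#' row-major flattened channels. Diffusivities are expressed in um^2/ms so
#' that typical white-matter mean diffusivity is around 0.7.
#'
#' @slot data 4D array, last dimension of size 9.
#' @slot spacing voxel size in mm per axis.
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("TensorField", contains = "GridVolume")

setValidity("TensorField", function(object) validGrid(object, 4, 9))

#' Log-domain tensor field
#'
#' The image of a [TensorField] under the matrix logarithm: a grid of
#' symmetric (not necessarily positive) 3x3 matrices in the tangent space at
#' the identity. This is the space in which networks, interpolation, and
#' losses operate; any element maps back to a valid SPD tensor via the
#' matrix exponential.
#'
#' @slot data 4D array, last dimension of size 9.
#' @slot spacing voxel size in mm per axis.
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("LogTensorField", contains = "GridVolume")

setValidity("LogTensorField", function(object) validGrid(object, 4, 9))

#' ODF coefficient field
#'
#' A 3D grid of square-root ODF spherical-harmonic coefficient vectors. With
#' `space = "sphere"` each voxel is a unit-norm point on the coefficient
#' sphere; with `space = "tangent"` each voxel is a tangent vector at the
#' uniform distribution u = (1, 0, ..., 0) (first coefficient orthogonal
#' component, as produced by the sphere log map).
#'
#' @slot data 4D array, last dimension of size (L+1)(L+2)/2.
#' @slot spacing voxel size in mm per axis.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot shOrder even spherical-harmonic order L.
#' @slot space `"sphere"` or `"tangent"`.
#' @export
setClass("OdfField", contains = "GridVolume",
  representation(shOrder = "integer", space = "character"))

setValidity("OdfField", function(object) {
  L <- object@shOrder
  if (length(L) != 1 || L < 0 || L %% 2 != 0)
    return("shOrder must be a single even non-negative integer")
  msg <- validGrid(object, 4, (L + 1) * (L + 2) / 2)
  if (!isTRUE(msg)) return(msg)
  if (!object@space %in% c("sphere", "tangent"))
    return('space must be "sphere" or "tangent"')
  TRUE
})

#' Streamline tractogram
#'
#' A collection of streamlines (polylines in world mm) together with the
#' parameters that produced them.
#'
#' @slot streamlines list of n x 3 numeric matrices (points in mm).
#' @slot provenance list recording field id, seeding and tracking parameters.
#' @export
setClass("Tractogram",
  representation(streamlines = "list", provenance = "list"))

setValidity("Tractogram", function(object) {
  ok <- vapply(object@streamlines, function(s)
    is.matrix(s) && ncol(s) == 3 && nrow(s) >= 2, logical(1))
  if (!all(ok)) return("streamlines must be matrices with 3 columns and >= 2 rows")
  TRUE
})

defaultAffine <- function(spacing) {
  a <- diag(c(spacing, 1))
  a
}

#' Construct grid volumes
#'
#' Constructors for the package's voxel-grid containers. If `affine` is
#' missing, a diagonal affine mapping voxel index i to world `i * spacing`
#' is used.
#'
#' @param data numeric array (3D for structural data, 4D with trailing channel
#'   dimension for tensor/ODF data).
#' @param spacing voxel size in mm, length 1 (isotropic) or 3.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return An object of the corresponding class.
#' @examples
#' v <- structuralVolume(array(0.5, c(4, 4, 4)), spacing = 0.7)
#' gridDim(v)
#' @export
structuralVolume <- function(data, spacing = 1, affine = NULL) {
  spacing <- rep(spacing, length.out = 3)
  new("StructuralVolume", data = data, spacing = spacing,
      affine = if (is.null(affine)) defaultAffine(spacing) else affine)
}

#' @rdname structuralVolume
#' @export
tensorField <- function(data, spacing = 1, affine = NULL) {
  spacing <- rep(spacing, length.out = 3)
  new("TensorField", data = data, spacing = spacing,
      affine = if (is.null(affine)) defaultAffine(spacing) else affine)
}

#' @rdname structuralVolume
#' @export
logTensorField <- function(data, spacing = 1, affine = NULL) {
  spacing <- rep(spacing, length.out = 3)
  new("LogTensorField", data = data, spacing = spacing,
      affine = if (is.null(affine)) defaultAffine(spacing) else affine)
}

#' @rdname structuralVolume
#' @param shOrder even spherical-harmonic order.
#' @param space `"sphere"` (unit-norm coefficients) or `"tangent"`.
#' @export
odfField <- function(data, spacing = 1, shOrder = 4L, space = "sphere",
                     affine = NULL) {
  spacing <- rep(spacing, length.out = 3)
  new("OdfField", data = data, spacing = spacing,
      affine = if (is.null(affine)) defaultAffine(spacing) else affine,
      shOrder = as.integer(shOrder), space = space)
}

#' @rdname structuralVolume
#' @param streamlines list of n x 3 matrices of points in world mm.
#' @param provenance list of tracking metadata.
#' @export
tractogram <- function(streamlines, provenance = list()) {
  new("Tractogram", streamlines = streamlines, provenance = provenance)
}
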