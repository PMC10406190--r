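#' @include AllClasses.R
NULL

#' Grid accessors
#'
#' Accessor generics for the voxel-grid containers: the raw array, the voxel
#' spacing (mm), the voxel-to-world affine, the spatial grid dimensions and
#' the channel count.
#'
#' @param x a grid volume object.
#' @return `volData`: the underlying array; `voxelSpacing`: numeric length 3;
#'   `voxelAffine`: 4x4 matrix; `gridDim`: integer length 3; `nChannels`:
#'   integer (1 for scalar volumes).
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname grid-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname grid-accessors
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))

#' @rdname grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname grid-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname grid-accessors
#' @export
setMethod("volData", "GridVolume", function(x) x@data)

#' @rdname grid-accessors
#' @export
setMethod("voxelSpacing", "GridVolume", function(x) x@spacing)

#' @rdname grid-accessors
#' @export
setMethod("voxelAffine", "GridVolume", function(x) x@affine)

#' @rdname grid-accessors
#' @export
setMethod("gridDim", "GridVolume", function(x) dim(x@data)[1:3])

#' @rdname grid-accessors
#' @export
setMethod("nChannels", "GridVolume", function(x) {
  d <- dim(x@data)
  if (length(d) == 3) 1L else d[4]
})

#' @rdname grid-accessors
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' @rdname grid-accessors
#' @export
setMethod("streamlines", "Tractogram", function(x) x@streamlines)

setMethod("show", "GridVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %s voxels", class(object), paste(d[1:3], collapse = " x ")))
  if (length(d) == 4) cat(sprintf(", %d channels", d[4]))
  cat(sprintf(", spacing %s mm\n",
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  if (is(object, "OdfField"))
    cat(sprintf("  SH order %d (%d coefficients), space: %s\n",
                object@shOrder, dim(object@data)[4], object@space))
  invisible(object)
})

setMethod("show", "Tractogram", function(object) {
  n <- length(object@streamlines)
  cat(sprintf("Tractogram: %d streamlines", n))
  if (n > 0) {
    lens <- vapply(object@streamlines, polylineLength, numeric(1))
    cat(sprintf(", length %.1f +/- %.1f mm", mean(lens), stats::sd(lens)))
  }
  cat("\n")
  invisible(object)
})

# internal: matrix view (nvox, C) of a field, and its inverse
fieldMatrix <- function(x) {
  d <- dim(x@data)
  if (length(d) == 3) matrix(x@data, ncol = 1L)
  else matrix(x@data, nrow = prod(d[1:3]), ncol = d[4])
}

matrixToArray <- function(m, dims) {
  if (ncol(m) == 1L) array(m, dims) else array(m, c(dims, ncol(m)))
}

polylineLength <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}
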