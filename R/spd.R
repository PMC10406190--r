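#' @include AllGenerics.R
NULL

## Log-Euclidean framework for 3x3 SPD diffusion tensors. A tensor
## M = U diag(lambda) U' is mapped to the tangent space at the identity by
## log(M) = U diag(log lambda) U'; any symmetric matrix maps back to an SPD
## tensor through exp. All Euclidean processing (interpolation, networks,
## losses) happens on the log side, which is what guarantees validity.

checkSymmetric <- function(M, tol = NULL) {
  if (any(!is.finite(M))) stop("matrix contains non-finite entries")
  if (is.null(tol)) tol <- 1e-6 * max(1, norm(M, "F"))
  asym <- max(abs(M - t(M)))
  if (asym > tol)
    stop(sprintf("matrix is not symmetric (max asymmetry %.3g > tol %.3g)",
                 asym, tol))
  (M + t(M)) / 2
}

#' Matrix logarithm and exponential of diffusion tensors
#'
#' `tensorLog` maps a symmetric positive-definite tensor to the tangent space
#' at the identity by applying the scalar logarithm to its eigenvalues;
#' eigenvalues are clamped at `eigFloor` first so that near-singular
#' background tensors remain finite. `tensorExp` is the inverse map and
#' returns a symmetric positive-definite matrix for *every* symmetric input --
#' the validity guarantee the whole synthesis pipeline rests on.
#'
#' @param M,S 3x3 symmetric numeric matrices (`M` should be SPD up to the
#'   eigenvalue floor; `S` is any symmetric matrix).
#' @param eigFloor positive lower clamp applied to eigenvalues before the log.
#' @return A 3x3 symmetric matrix.
#' @examples
#' tensorLog(diag(3))            # zero matrix
#' tensorExp(matrix(0, 3, 3))    # identity
#' @export
tensorLog <- function(M, eigFloor = 1e-8) {
  stopifnot(eigFloor > 0)
  M <- checkSymmetric(M)
  e <- eigen(M, symmetric = TRUE)
  S <- e$vectors %*% diag(log(pmax(e$values, eigFloor))) %*% t(e$vectors)
  (S + t(S)) / 2
}

#' @rdname tensorLog
#' @export
tensorExp <- function(S) {
  S <- checkSymmetric(S)
  e <- eigen(S, symmetric = TRUE)
  M <- e$vectors %*% diag(exp(e$values)) %*% t(e$vectors)
  (M + t(M)) / 2
}

#' Log-Euclidean geodesic distance between two tensors
#'
#' The Frobenius norm of the difference of the matrix logarithms,
#' `||log(P1) - log(P2)||_F`. This is the geodesic distance of the
#' log-Euclidean metric on the SPD manifold.
#'
#' @param P1,P2 3x3 SPD matrices.
#' @param eigFloor eigenvalue clamp passed to [tensorLog()].
#' @return Non-negative scalar.
#' @export
tensorGeodesic <- function(P1, P2, eigFloor = 1e-8) {
  for (P in list(P1, P2)) {
    chk <- isSPD(P)
    if (!chk$spd)
      stop(sprintf("input is not SPD (min eigenvalue %.3g)", chk$minEigenvalue))
  }
  norm(tensorLog(P1, eigFloor) - tensorLog(P2, eigFloor), "F")
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' FA = sqrt(1/2) * sqrt(((l1-l2)^2 + (l2-l3)^2 + (l1-l3)^2) /
#' (l1^2 + l2^2 + l3^2)), in `[0, 1]`. Vectorized over eigenvalue triples;
#' the all-zero tensor is assigned FA 0 so that background voxels do not
#' poison masked means.
#'
#' @param l1,l2,l3 eigenvalues (non-negative, any order), vectors allowed.
#' @return FA values in `[0, 1]`.
#' @examples
#' fractionalAnisotropy(3, 2, 1)
#' fractionalAnisotropy(1, 1, 1)  # 0, isotropic
#' @export
fractionalAnisotropy <- function(l1, l2, l3) {
  num <- (l1 - l2)^2 + (l2 - l3)^2 + (l1 - l3)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(0.5) * sqrt(num / den)
  fa[den == 0] <- 0
  pmin(pmax(fa, 0), 1)
}

#' Principal diffusion direction of a tensor
#'
#' The unit eigenvector of the largest eigenvalue, sign-normalized so that its
#' first nonzero component is positive. When the two largest eigenvalues are
#' nearly equal (relative gap below `degeneracyTol`) the direction is
#' physically undefined and `NULL` is returned with attribute handling left
#' to the caller.
#'
#' @param M 3x3 SPD matrix.
#' @param degeneracyTol relative eigenvalue gap below which the direction is
#'   declared undefined.
#' @return A unit 3-vector, or `NULL` when degenerate.
#' @export
principalDirection <- function(M, degeneracyTol = 1e-6) {
  M <- checkSymmetric(M)
  e <- eigen(M, symmetric = TRUE)
  l <- e$values
  if (l[1] <= 0 || (l[1] - l[2]) / l[1] < degeneracyTol) return(NULL)
  signNormalize(e$vectors[, 1])
}

signNormalize <- function(v) {
  nz <- which(abs(v) > 0)
  if (length(nz) && v[nz[1]] < 0) v <- -v
  v
}

#' Test symmetric positive-definiteness
#'
#' A matrix passes when its asymmetry is within `symTol` and the minimum
#' eigenvalue of its symmetric part exceeds `eigTol` (strict positivity by
#' default, which is the mathematical definition used when counting invalid
#' synthesized tensors).
#'
#' @param M 3x3 numeric matrix with finite entries.
#' @param symTol absolute asymmetry tolerance; default `1e-6 * ||M||_F`.
#' @param eigTol eigenvalue threshold (default 0).
#' @return List with elements `spd` (logical) and `minEigenvalue`.
#' @export
isSPD <- function(M, symTol = NULL, eigTol = 0) {
  if (any(!is.finite(M))) stop("matrix contains non-finite entries")
  if (is.null(symTol)) symTol <- 1e-6 * max(1, norm(M, "F"))
  sym <- max(abs(M - t(M))) <= symTol
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(spd = sym && min(ev) > eigTol, minEigenvalue = min(ev))
}

#' Pack and unpack 9-channel tensor fields
#'
#' `packChannels` returns the 4D array view of a (log-)tensor field with the
#' 3x3 matrix at each voxel flattened row-major into 9 channels (the layout
#' networks consume). `unpackChannels` builds a field back from such an
#' array; with `symmetrize = TRUE` each voxel matrix is replaced by its
#' symmetric part `(S + S')/2`, which makes a subsequent [tensorExp()] legal
#' for any network output.
#'
#' @param field a [TensorField] or [LogTensorField].
#' @param volume 4D array with 9 channels in the last dimension.
#' @param symmetrize average each voxel matrix with its transpose.
#' @param log logical; build a [LogTensorField] (default) or [TensorField].
#' @param spacing,affine grid geometry for the rebuilt field.
#' @return `packChannels`: a 4D array; `unpackChannels`: a field object.
#' @export
packChannels <- function(field) {
  stopifnot(is(field, "TensorField") || is(field, "LogTensorField"))
  field@data
}

#' @rdname packChannels
#' @export
unpackChannels <- function(volume, symmetrize = FALSE, log = TRUE,
                           spacing = 1, affine = NULL) {
  d <- dim(volume)
  if (length(d) != 4 || d[4] != 9)
    stop("expected a 4D array with 9 channels in the last dimension")
  if (symmetrize) {
    m <- matrix(volume, ncol = 9)
    # row-major layout: entries (1..9) = (11,12,13,21,22,23,31,32,33)
    m <- symmetrizeRows(m)
    volume <- array(m, d)
  }
  if (log) logTensorField(volume, spacing, affine)
  else tensorField(volume, spacing, affine)
}

# symmetrize row-major flattened 3x3 rows: average off-diagonal pairs
symmetrizeRows <- function(m) {
  pairs <- list(c(2, 4), c(3, 7), c(6, 8))
  for (p in pairs) {
    avg <- (m[, p[1]] + m[, p[2]]) / 2
    m[, p[1]] <- avg
    m[, p[2]] <- avg
  }
  m
}

#' Field-level log/exp maps
#'
#' Vectorized maps between [TensorField] and [LogTensorField] applying
#' [tensorLog()]/[tensorExp()] at every voxel (computed in compiled code).
#'
#' @param field input field.
#' @param eigFloor eigenvalue clamp for the log map.
#' @return The mapped field.
#' @export
fieldLog <- function(field, eigFloor = 1e-8) {
  stopifnot(is(field, "TensorField"))
  m <- cpp_sym_func_field(fieldMatrix(field), 0L, eigFloor)
  logTensorField(matrixToArray(m, gridDim(field)), field@spacing, field@affine)
}

#' @rdname fieldLog
#' @export
fieldExp <- function(field) {
  stopifnot(is(field, "LogTensorField"))
  m <- cpp_sym_func_field(fieldMatrix(field), 1L, 0)
  tensorField(matrixToArray(m, gridDim(field)), field@spacing, field@affine)
}

# internal: eigenvalues (desc) and eigenvectors for every voxel
fieldEigen <- function(field) {
  cpp_sym_eig_field(fieldMatrix(field))
}

#' Voxelwise anisotropy and direction maps
#'
#' `faMap` computes fractional anisotropy at every voxel of a tensor field
#' (for a [LogTensorField] the eigenvalues are exponentiated first, i.e., the
#' FA of the exp-mapped tensors). `directionMap` returns the sign-normalized
#' principal direction per voxel, with NA rows where the direction is
#' degenerate.
#'
#' @param field a [TensorField] or [LogTensorField].
#' @param degeneracyTol relative eigenvalue gap for degeneracy flagging.
#' @return `faMap`: 3D array of FA values; `directionMap`: (nvox, 3) matrix.
#' @export
faMap <- function(field) {
  e <- fieldEigen(field)
  v <- e$values
  if (is(field, "LogTensorField")) v <- exp(v)
  array(fractionalAnisotropy(v[, 1], v[, 2], v[, 3]), gridDim(field))
}

#' @rdname faMap
#' @export
directionMap <- function(field, degeneracyTol = 1e-6) {
  e <- fieldEigen(field)
  v <- e$values
  if (is(field, "LogTensorField")) v <- exp(v)
  dirs <- e$vectors[, 1:3, drop = FALSE]
  # sign normalization: first nonzero component positive
  s <- sign(dirs[, 1])
  s[s == 0] <- sign(dirs[s == 0, 2])
  s[s == 0] <- sign(dirs[s == 0, 3])
  s[s == 0] <- 1
  dirs <- dirs * s
  deg <- v[, 1] <= 0 | (v[, 1] - v[, 2]) / pmax(v[, 1], .Machine$double.eps) < degeneracyTol
  dirs[deg, ] <- NA_real_
  dirs
}

#' Validity sweep over a tensor field
#'
#' Counts voxels that fail the SPD test (strict positivity of the minimum
#' eigenvalue of the symmetric part, plus symmetry of the stored matrix).
#'
#' @param field a [TensorField].
#' @param eigTol eigenvalue threshold (default 0: strict positivity).
#' @return List with `nInvalid`, `nVoxels` and the vector of minimum
#'   eigenvalues.
#' @export
fieldValidity <- function(field, eigTol = 0) {
  m <- fieldMatrix(field)
  asym <- pmax(abs(m[, 2] - m[, 4]), abs(m[, 3] - m[, 7]), abs(m[, 6] - m[, 8]))
  nrm <- sqrt(rowSums(m^2))
  e <- cpp_sym_eig_field(m)
  minev <- e$values[, 3]
  bad <- minev <= eigTol | asym > 1e-6 * pmax(1, nrm)
  list(nInvalid = sum(bad), nVoxels = nrow(m), minEigenvalues = minev)
}

#' Resample a log-domain tensor field
#'
#' Channel-wise trilinear interpolation onto a new grid spacing, performed in
#' the log domain where linear interpolation is geodesically meaningful (the
#' determinant of the exp-mapped midpoint of two tensors is the geometric
#' mean of their determinants, so no swelling occurs). Grids share the same
#' physical center.
#'
#' @param field a [LogTensorField] (or tangent-space [OdfField]).
#' @param targetSpacing new voxel size in mm (length 1 or 3).
#' @param targetDim optional explicit output grid size; by default the number
#'   of voxels that covers the same physical extent.
#' @return The resampled field of the same class.
#' @export
resampleLogField <- function(field, targetSpacing, targetDim = NULL) {
  targetSpacing <- rep(targetSpacing, length.out = 3)
  if (any(targetSpacing <= 0)) stop("target spacing must be strictly positive")
  tangent <- is(field, "OdfField")
  if (!tangent && !is(field, "LogTensorField"))
    stop("resampling is defined on log/tangent-domain fields only")
  if (tangent && field@space != "tangent")
    stop("ODF fields must be in tangent space for resampling")
  dims <- gridDim(field)
  if (is.null(targetDim))
    targetDim <- pmax(1L, as.integer(round(dims * field@spacing / targetSpacing)))
  m <- cpp_resample3(fieldMatrix(field), as.integer(dims), field@spacing,
                     as.integer(targetDim), targetSpacing, 1L)
  arr <- matrixToArray(m, targetDim)
  if (tangent)
    odfField(arr, targetSpacing, field@shOrder, "tangent")
  else
    logTensorField(arr, targetSpacing)
}
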