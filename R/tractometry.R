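#' @include spd.R odf.R
NULL

#' Deterministic peak-following streamline tractography
#'
#' Propagates streamlines bidirectionally through a diffusion field: along
#' the trilinearly interpolated (log-domain) principal tensor direction for
#' DT, or along the discrete ODF maximum of the nearest voxel that is best
#' aligned with the incoming direction for ODF. Seeds are jittered uniformly
#' within each seed-mask voxel by a seeded RNG. Propagation stops on leaving
#' the tracking mask or the grid, on exceeding the maximum angle between
#' steps, or on an undefined direction; the length filter is applied last.
#'
#' @param field a [TensorField] or sphere-space [OdfField].
#' @param seedMask logical 3D array of seed voxels.
#' @param trackMask logical 3D array within which propagation is allowed
#'   (default: the seed mask).
#' @param seedsPerVoxel seeds per mask voxel.
#' @param step step size in mm.
#' @param maxAngle maximum angle between consecutive steps, degrees.
#' @param minLen,maxLen retained streamline length bounds in mm.
#' @param seed RNG seed for seed-point jitter.
#' @param degeneracyTol relative eigenvalue gap below which a tensor
#'   direction is undefined.
#' @param sphereVertices tessellation size for ODF peak extraction.
#' @param maxPeaks ODF maxima retained per voxel.
#' @return A [Tractogram] (streamline points in world mm, diagonal-affine
#'   grid frame).
#' @export
track <- function(field, seedMask, trackMask = seedMask, seedsPerVoxel = 2L,
                  step = 0.5, maxAngle = 60, minLen = 10, maxLen = 300,
                  seed = 1L, degeneracyTol = 0.05, sphereVertices = 724L,
                  maxPeaks = 3L) {
  dims <- gridDim(field)
  sp <- voxelSpacing(field)
  if (!any(seedMask)) stop("empty seed mask")
  stopifnot(identical(dim(seedMask), as.integer(dims)) || identical(dim(seedMask), dims))
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  vox <- which(seedMask) - 1L
  vi <- cbind(vox %% dims[1],
              (vox %/% dims[1]) %% dims[2],
              vox %/% (dims[1] * dims[2]))
  vi <- vi[rep(seq_len(nrow(vi)), each = seedsPerVoxel), , drop = FALSE]
  jitter <- matrix(runif(length(vi), -0.5, 0.5), nrow(vi), 3)
  seeds <- sweep(vi + jitter, 2, sp, "*")
  if (is(field, "TensorField")) {
    m <- fieldMatrix(fieldLog(field))
    mode <- 0L
  } else {
    stopifnot(is(field, "OdfField"), field@space == "sphere")
    basis <- shBasis(field@shOrder, sphereTessellation(sphereVertices))
    m <- odfPeakField(field, trackMask, basis, maxPeaks)
    mode <- 1L
  }
  lines <- cpp_track(m, as.integer(dims), sp, as.integer(as.vector(trackMask)),
                     seeds, mode, step, maxAngle, minLen, maxLen, degeneracyTol)
  tractogram(lines, provenance = list(
    fieldClass = class(field)[1], seedsPerVoxel = seedsPerVoxel, step = step,
    maxAngle = maxAngle, minLen = minLen, maxLen = maxLen, seed = seed))
}

# per-voxel ODF peak directions (up to maxPeaks, strongest first), NA-padded
odfPeakField <- function(field, mask, basis, maxPeaks = 3L) {
  dims <- gridDim(field)
  m <- fieldMatrix(field)
  out <- matrix(NA_real_, nrow(m), 3 * maxPeaks)
  sel <- which(as.vector(mask))
  for (i in sel) {
    pk <- odfPeaks(m[i, ], basis, maxPeaks = maxPeaks)
    if (nrow(pk) == 0) next
    for (k in seq_len(nrow(pk)))
      out[i, (3 * k - 2):(3 * k)] <- pk[k, ]
  }
  out
}

#' Streamline density mask and summary statistics
#'
#' `densityMask` marks every voxel visited by at least one streamline point;
#' `streamlineStats` summarizes per-streamline arc lengths and, when a grid
#' is supplied, the occupied volume in voxels.
#'
#' @param t a [Tractogram].
#' @param grid a grid volume (or list with `dims` and `spacing`) defining the
#'   voxel raster.
#' @return `densityMask`: logical 3D array; `streamlineStats`: list with
#'   `n`, `lengthMean`, `lengthSd`, `volumeVoxels`.
#' @export
densityMask <- function(t, grid) {
  if (is(grid, "GridVolume")) grid <- list(dims = gridDim(grid), spacing = voxelSpacing(grid))
  dims <- grid$dims
  sp <- grid$spacing
  mask <- array(FALSE, dims)
  for (s in streamlines(t)) {
    v <- round(sweep(s, 2, sp, "/"))
    keep <- v[, 1] >= 0 & v[, 1] < dims[1] & v[, 2] >= 0 & v[, 2] < dims[2] &
      v[, 3] >= 0 & v[, 3] < dims[3]
    v <- v[keep, , drop = FALSE]
    if (nrow(v)) mask[v + 1] <- TRUE
  }
  mask
}

#' @rdname densityMask
#' @export
streamlineStats <- function(t, grid = NULL) {
  lens <- vapply(streamlines(t), polylineLength, numeric(1))
  out <- list(n = length(lens),
              lengthMean = if (length(lens)) mean(lens) else NA_real_,
              lengthSd = if (length(lens) > 1) stats::sd(lens) else NA_real_)
  if (!is.null(grid)) out$volumeVoxels <- sum(densityMask(t, grid))
  out
}

#' Bundle agreement statistics
#'
#' Overlap OL = |B intersect A| / |A|, overreach
#' OR = (|B union A| - |B intersect A|) / |A| and Dice
#' 2|A intersect B| / (|A| + |B|) between two binary bundle masks, with A as
#' the reference.
#'
#' @param A,B logical arrays on the same grid; `A` must be non-empty.
#' @return List with `dice`, `ol`, `or`.
#' @export
bundleAgreement <- function(A, B) {
  stopifnot(identical(dim(A), dim(B)))
  nA <- sum(A)
  if (nA == 0) stop("reference mask A is empty")
  nB <- sum(B)
  inter <- sum(A & B)
  uni <- nA + nB - inter
  list(dice = 2 * inter / (nA + nB), ol = inter / nA, or = (uni - inter) / nA)
}

## ---- TRK streamline file I/O ----------------------------------------------
## TrackVis TRK v2. Points are stored in the format's "voxmm" convention
## (voxel index plus half-voxel, times voxel size); the voxel-to-world
## affine is stored in the header and applied on read.

#' Read and write TRK streamline files
#'
#' Minimal TrackVis TRK (version 2) reader/writer. Streamline points are
#' converted between the package's world-mm convention (voxel center i at
#' `affine %*% i`) and the format's voxel-mm convention using the stored
#' affine and voxel size.
#'
#' @param t a [Tractogram].
#' @param path file path.
#' @param spacing voxel size recorded in the header.
#' @param affine 4x4 voxel-to-world matrix recorded in the header.
#' @param dims grid dimensions recorded in the header.
#' @return `readTrk`: a [Tractogram]; `writeTrk`: the path, invisibly.
#' @export
writeTrk <- function(t, path, spacing = c(1, 1, 1), dims = c(0L, 0L, 0L),
                     affine = diag(c(spacing, 1))) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(dims), con, size = 2)
  writeBin(as.numeric(spacing), con, size = 4)
  writeBin(numeric(3), con, size = 4)                   # origin
  writeBin(0L, con, size = 2)                           # n_scalars
  writeBin(raw(200), con)                               # scalar names
  writeBin(0L, con, size = 2)                           # n_properties
  writeBin(raw(200), con)                               # property names
  writeBin(as.numeric(t(affine)), con, size = 4)        # vox_to_ras
  writeBin(raw(444), con)                               # reserved
  writeBin(c(charToRaw("LPS"), as.raw(0)), con)         # voxel_order
  writeBin(raw(4), con)                                 # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4)
  writeBin(raw(2), con)                                 # pad1
  writeBin(raw(6), con)                                 # invert/swap flags
  writeBin(length(streamlines(t)), con, size = 4)       # n_count
  writeBin(2L, con, size = 4)                           # version
  writeBin(1000L, con, size = 4)                        # hdr_size
  inv <- solve(affine)
  for (s in streamlines(t)) {
    vox <- cbind(s, 1) %*% t(inv)                       # world -> voxel
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, spacing, "*")
    writeBin(nrow(s), con, size = 4)
    writeBin(as.numeric(t(voxmm)), con, size = 4)
  }
  invisible(path)
}

#' @rdname writeTrk
#' @export
readTrk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 5))
  invisible(readBin(con, raw(), 1))
  if (magic != "TRACK") stop("not a TRK file")
  dims <- readBin(con, integer(), 3, size = 2)
  spacing <- readBin(con, numeric(), 3, size = 4)
  invisible(readBin(con, numeric(), 3, size = 4))
  nScalars <- readBin(con, integer(), 1, size = 2)
  invisible(readBin(con, raw(), 200))
  nProps <- readBin(con, integer(), 1, size = 2)
  invisible(readBin(con, raw(), 200))
  affine <- matrix(readBin(con, numeric(), 16, size = 4), 4, 4, byrow = TRUE)
  invisible(readBin(con, raw(), 444 + 4 + 4 + 24 + 2 + 6))
  nCount <- readBin(con, integer(), 1, size = 4)
  version <- readBin(con, integer(), 1, size = 4)
  hdrSize <- readBin(con, integer(), 1, size = 4)
  if (hdrSize != 1000) stop("unsupported TRK header size")
  if (all(affine == 0)) affine <- diag(c(spacing, 1))
  lines <- vector("list", nCount)
  for (i in seq_len(nCount)) {
    np <- readBin(con, integer(), 1, size = 4)
    pts <- matrix(readBin(con, numeric(), np * (3 + nScalars), size = 4),
                  ncol = 3 + nScalars, byrow = TRUE)
    if (nProps > 0) invisible(readBin(con, numeric(), nProps, size = 4))
    voxmm <- pts[, 1:3, drop = FALSE]
    vox <- sweep(voxmm, 2, spacing, "/") - 0.5
    world <- cbind(vox, 1) %*% t(affine)
    lines[[i]] <- world[, 1:3, drop = FALSE]
  }
  tractogram(lines, provenance = list(source = path, dims = dims,
                                      spacing = spacing))
}
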