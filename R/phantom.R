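#' @include spd.R odf.R
NULL

## Synthetic fiber phantoms: paired high-resolution structural volumes and
## ground-truth DT/ODF fields with known bundle geometry, standing in for
## real paired acquisitions. Tensors are axially symmetric with eigenvalues
## solved to hit a target FA at a given mean diffusivity; structural
## intensity is a deterministic function of tissue class and local
## anisotropy (plus smooth bias and noise), so the structural-to-diffusion
## mapping is learnable by construction.

#' Fiber bundle description
#'
#' A tube of radius `radius` mm around a centerline, filled with axially
#' symmetric tensors oriented along the local tangent.
#'
#' @param centerline n x 3 matrix of points (mm, in the volume-centered
#'   frame) ordered along the bundle.
#' @param radius tube radius in mm.
#' @param faTarget fractional anisotropy of the bundle tensors, in `[0, 1)`.
#' @param meanDiffusivity mean diffusivity in um^2/ms.
#' @return A bundle description list.
#' @export
bundleSpec <- function(centerline, radius = 3, faTarget = 0.8,
                       meanDiffusivity = 0.7) {
  stopifnot(is.matrix(centerline), ncol(centerline) == 3, radius > 0,
            faTarget >= 0, faTarget <= 1, meanDiffusivity > 0)
  list(centerline = centerline, radius = radius, faTarget = faTarget,
       meanDiffusivity = meanDiffusivity)
}

#' @rdname bundleSpec
#' @param axis one of `"x"`, `"y"`, `"z"`: direction of a straight bundle
#'   spanning the whole grid.
#' @param offset 2-vector, mm offset of the bundle axis from the volume
#'   center in the two transverse directions.
#' @param extent length of the bundle in mm.
#' @param ... passed to [bundleSpec()].
#' @export
straightBundle <- function(axis = "z", offset = c(0, 0), extent = 40, ...) {
  t <- seq(-extent / 2, extent / 2, length.out = 129)
  cl <- switch(axis,
    x = cbind(t, offset[1], offset[2]),
    y = cbind(offset[1], t, offset[2]),
    z = cbind(offset[1], offset[2], t),
    stop("axis must be x, y or z"))
  bundleSpec(cl, ...)
}

#' @rdname bundleSpec
#' @param bendRadius radius of a 90-degree circular arc (in the x-z plane)
#'   in mm.
#' @export
arcBundle <- function(bendRadius = 12, offset = c(0, 0), ...) {
  a <- seq(0, pi / 2, length.out = 129)
  cl <- cbind(bendRadius * cos(a) - bendRadius / 2 + offset[1], offset[2],
              bendRadius * sin(a) - bendRadius / 2)
  bundleSpec(cl, ...)
}

#' Phantom specification
#'
#' The study conditions of the synthetic data: grid size, the 0.7 mm
#' high-resolution / 1.25 mm low-resolution gap, bundle geometry, background
#' tissue, structural noise and the RNG seed. Identical spec and seed give
#' bit-identical phantoms.
#'
#' @param gridShape HR voxels per axis.
#' @param hrSpacing,lrSpacing voxel sizes in mm (HR strictly finer).
#' @param bundles list of [bundleSpec()] descriptions.
#' @param background list with `gmFa`, `gmMd`, `csfFa`, `csfMd`, `csfRadius`
#'   (mm, 0 disables the CSF ball) and `csfCenter` (mm offset).
#' @param structuralNoiseSd Gaussian noise SD on structural intensities.
#' @param shOrder spherical-harmonic order of the phantom ODFs.
#' @param odfSharpening fraction of the isotropic floor subtracted from the
#'   Gaussian ODF before the square-root fit (emulating the sharpened
#'   constant-solid-angle reconstructions used for fiber ODFs; 0 keeps the
#'   blunt Gaussian ODF).
#' @param seed integer RNG seed.
#' @return A phantom specification list.
#' @export
phantomSpec <- function(gridShape = c(48L, 48L, 48L), hrSpacing = 0.7,
                        lrSpacing = 1.25,
                        bundles = list(straightBundle("z")),
                        background = list(gmFa = 0.1, gmMd = 0.8,
                                          csfFa = 0.02, csfMd = 2.5,
                                          csfRadius = 0, csfCenter = c(0, 0, 0)),
                        structuralNoiseSd = 0.02, shOrder = 4L,
                        odfSharpening = 0.85, seed = 1L) {
  stopifnot(hrSpacing < lrSpacing, all(gridShape >= 8))
  for (b in bundles) stopifnot(b$faTarget >= 0, b$faTarget <= 1)
  list(gridShape = as.integer(rep(gridShape, length.out = 3)),
       hrSpacing = hrSpacing, lrSpacing = lrSpacing, bundles = bundles,
       background = background, structuralNoiseSd = structuralNoiseSd,
       shOrder = as.integer(shOrder), odfSharpening = odfSharpening,
       seed = as.integer(seed))
}

# eigenvalues of an axially symmetric tensor with given FA and MD:
# lambda1 = md (1 + 2 d), lambda23 = md (1 - d) with d = f / sqrt(3 - 2 f^2)
axialEigenvalues <- function(fa, md) {
  if (any(fa >= 1)) stop("faTarget must be < 1 for a positive-definite tensor")
  d <- fa / sqrt(3 - 2 * fa^2)
  list(l1 = md * (1 + 2 * d), l23 = md * (1 - d))
}

# 9 row-major channels of (l1 - l23) t t' + l23 I for axis rows t
axialTensorRows <- function(axes, l1, l23) {
  out <- matrix(0, nrow(axes), 9)
  k <- 1L
  for (i in 1:3) for (j in 1:3) {
    out[, k] <- (l1 - l23) * axes[, i] * axes[, j] + if (i == j) l23 else 0
    k <- k + 1L
  }
  out
}

# Gaussian single-fiber ODF samples: p(u) propto (u' D^-1 u)^(-3/2)
gaussianOdfSamples <- function(axes, l1, l23, dirs) {
  G <- axes %*% t(dirs)               # (nvox, ndir) cosines with the axis
  inv23 <- 1 / l23
  (inv23 + (1 / l1 - inv23) * G^2)^(-1.5)
}

#' Generate a paired structural + diffusion phantom
#'
#' Builds the high-resolution structural volume, the ground-truth tensor
#' field, the ground-truth ODF field and a tissue label map from a
#' [phantomSpec()]. Voxels inside a single bundle carry an axially symmetric
#' tensor along the local bundle tangent; voxels inside two bundles carry
#' the log-Euclidean mean tensor and a two-peak ODF (equal mixture of the
#' two single-fiber ODFs, square-root fitted). Background voxels are mildly
#' anisotropic with random orientation.
#'
#' @param spec a [phantomSpec()].
#' @param odf compute the ODF field (set `FALSE` to skip for DT-only work).
#' @return List with `structural` ([StructuralVolume]), `tensors`
#'   ([TensorField]), `odfs` (sphere-space [OdfField] or `NULL`),
#'   `tissue` (integer 3D array: 0 background, 1 CSF, 1+k bundle k) and
#'   `bundleMasks` (list of logical arrays).
#' @export
makePhantom <- function(spec, odf = TRUE) {
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(spec$seed)

  dims <- spec$gridShape
  sp <- rep(spec$hrSpacing, 3)
  nvox <- prod(dims)
  ext <- dims * sp
  # voxel centers in the volume-centered frame
  cx <- ((seq_len(dims[1]) - 1) + 0.5) * sp[1] - ext[1] / 2
  cy <- ((seq_len(dims[2]) - 1) + 0.5) * sp[2] - ext[2] / 2
  cz <- ((seq_len(dims[3]) - 1) + 0.5) * sp[3] - ext[3] / 2
  X <- rep(cx, times = dims[2] * dims[3])
  Y <- rep(rep(cy, each = dims[1]), times = dims[3])
  Z <- rep(cz, each = dims[1] * dims[2])

  nb <- length(spec$bundles)
  bundleMasks <- vector("list", nb)
  bundleAxes <- vector("list", nb)
  for (k in seq_len(nb)) {
    b <- spec$bundles[[k]]
    cl <- b$centerline
    tang <- rbind(cl[2, ] - cl[1, ], cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])
    tang <- tang / sqrt(rowSums(tang^2))
    mind2 <- rep(Inf, nvox)
    near <- integer(nvox)
    for (i in seq_len(nrow(cl))) {
      d2 <- (X - cl[i, 1])^2 + (Y - cl[i, 2])^2 + (Z - cl[i, 3])^2
      upd <- d2 < mind2
      mind2[upd] <- d2[upd]
      near[upd] <- i
    }
    inside <- mind2 <= b$radius^2
    bundleMasks[[k]] <- array(inside, dims)
    ax <- matrix(NA_real_, nvox, 3)
    ax[inside, ] <- tang[near[inside], , drop = FALSE]
    bundleAxes[[k]] <- ax
  }

  nInside <- Reduce(`+`, lapply(bundleMasks, as.vector), rep(0L, nvox))
  bg <- spec$background
  csf <- rep(FALSE, nvox)
  if (!is.null(bg$csfRadius) && bg$csfRadius > 0) {
    cc <- bg$csfCenter
    csf <- ((X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2) <= bg$csfRadius^2
    csf <- csf & nInside == 0
  }

  # --- tensors ---------------------------------------------------------------
  gmAxes <- matrix(rnorm(3 * nvox), nvox, 3)
  gmAxes <- gmAxes / sqrt(rowSums(gmAxes^2))
  egm <- axialEigenvalues(bg$gmFa, bg$gmMd)
  tens <- axialTensorRows(gmAxes, egm$l1, egm$l23)
  if (any(csf)) {
    ecsf <- axialEigenvalues(bg$csfFa, bg$csfMd)
    tens[csf, ] <- axialTensorRows(gmAxes[csf, , drop = FALSE], ecsf$l1, ecsf$l23)
  }
  for (k in seq_len(nb)) {
    b <- spec$bundles[[k]]
    e <- axialEigenvalues(b$faTarget, b$meanDiffusivity)
    sel <- as.vector(bundleMasks[[k]]) & nInside == 1
    if (any(sel))
      tens[sel, ] <- axialTensorRows(bundleAxes[[k]][sel, , drop = FALSE], e$l1, e$l23)
  }
  cross <- nInside >= 2
  if (any(cross)) {
    idx <- which(cross)
    logAcc <- matrix(0, length(idx), 9)
    cnt <- numeric(length(idx))
    for (k in seq_len(nb)) {
      sel <- as.vector(bundleMasks[[k]])[idx]
      if (!any(sel)) next
      b <- spec$bundles[[k]]
      e <- axialEigenvalues(b$faTarget, b$meanDiffusivity)
      la <- axialTensorRows(bundleAxes[[k]][idx[sel], , drop = FALSE],
                            log(e$l1), log(e$l23))
      # log of an axially symmetric tensor is axially symmetric with logged
      # eigenvalues, so the log map has this closed form
      logAcc[sel, ] <- logAcc[sel, ] + la
      cnt[sel] <- cnt[sel] + 1
    }
    tens[idx, ] <- cpp_sym_func_field(logAcc / cnt, 1L, 0)
  }
  tensors <- tensorField(array(tens, c(dims, 9)), sp)

  # --- ODFs ------------------------------------------------------------------
  odfs <- NULL
  if (odf) {
    fitDirs <- sphereTessellation(180L)
    fitBasis <- shBasis(spec$shOrder, fitDirs)
    qrB <- qr(fitBasis$B)
    coef <- matrix(0, nvox, fitBasis$K)
    blocks <- split(seq_len(nvox), ceiling(seq_len(nvox) / 20000))
    compSamples <- function(vsel) {
      s <- matrix(0, length(vsel), nrow(fitDirs))
      wsum <- numeric(length(vsel))
      for (k in seq_len(nb)) {
        inb <- as.vector(bundleMasks[[k]])[vsel]
        if (!any(inb)) next
        b <- spec$bundles[[k]]
        e <- axialEigenvalues(b$faTarget, b$meanDiffusivity)
        s[inb, ] <- s[inb, ] + gaussianOdfSamples(
          bundleAxes[[k]][vsel[inb], , drop = FALSE], e$l1, e$l23, fitDirs)
        wsum[inb] <- wsum[inb] + 1
      }
      none <- wsum == 0
      if (any(none)) {
        isCsf <- csf[vsel] & none
        notCsf <- none & !isCsf
        if (any(notCsf))
          s[notCsf, ] <- gaussianOdfSamples(gmAxes[vsel[notCsf], , drop = FALSE],
                                            egm$l1, egm$l23, fitDirs)
        if (any(isCsf)) {
          ecsf <- axialEigenvalues(bg$csfFa, bg$csfMd)
          s[isCsf, ] <- gaussianOdfSamples(gmAxes[vsel[isCsf], , drop = FALSE],
                                           ecsf$l1, ecsf$l23, fitDirs)
        }
        wsum[none] <- 1
      }
      s / wsum
    }
    sharpen <- spec$odfSharpening
    if (is.null(sharpen)) sharpen <- 0.85
    for (blk in blocks) {
      s <- compSamples(blk)
      if (sharpen > 0) s <- s - sharpen * apply(s, 1, min)
      cf <- t(qr.coef(qrB, t(sqrt(s))))
      cf <- cf / sqrt(rowSums(cf^2))
      flip <- cf[, 1] < 0
      cf[flip, ] <- -cf[flip, ]
      coef[blk, ] <- cf
    }
    odfs <- odfField(array(coef, c(dims, fitBasis$K)), sp, spec$shOrder, "sphere")
  }

  # --- tissue + structural ---------------------------------------------------
  tissue <- integer(nvox)
  tissue[csf] <- 1L
  for (k in rev(seq_len(nb)))
    tissue[as.vector(bundleMasks[[k]])] <- 1L + k
  localFa <- numeric(nvox)
  for (k in seq_len(nb)) {
    inb <- as.vector(bundleMasks[[k]])
    localFa[inb] <- localFa[inb] + spec$bundles[[k]]$faTarget
  }
  localFa[nInside > 0] <- localFa[nInside > 0] / nInside[nInside > 0]
  base <- rep(0.45, nvox)
  base[csf] <- 0.12
  wm <- nInside > 0
  base[wm] <- 0.55 + 0.35 * localFa[wm]
  bias <- 1 + 0.05 * sin(2 * pi * X / ext[1] + 0.7) *
    sin(2 * pi * Y / ext[2] + 1.1) * sin(2 * pi * Z / ext[3] + 1.9)
  intens <- base * bias + rnorm(nvox, sd = spec$structuralNoiseSd)
  intens <- pmin(pmax(intens, 0), 1)

  list(structural = structuralVolume(array(intens, dims), sp),
       tensors = tensors, odfs = odfs,
       tissue = array(tissue, dims), bundleMasks = bundleMasks)
}

#' Degrade a field to low resolution
#'
#' Simulates the acquisition resolution gap: the field is mapped to its
#' log/tangent domain, anti-aliased (Gaussian smoothing matched to the
#' resolution ratio) and trilinearly resampled to the coarser grid there,
#' then mapped back. Outputs are therefore guaranteed valid (SPD tensors /
#' unit-norm ODFs).
#'
#' @param field a [TensorField], [OdfField] (sphere space) or
#'   [StructuralVolume].
#' @param lrSpacing target voxel size in mm (coarser than the input).
#' @param antialias apply the Gaussian pre-filter.
#' @return The degraded field of the same class.
#' @export
degradeToLR <- function(field, lrSpacing, antialias = TRUE) {
  lrSpacing <- rep(lrSpacing, length.out = 3)
  if (any(lrSpacing <= field@spacing))
    stop("lrSpacing must be coarser than the field spacing")
  dims <- gridDim(field)
  ratio <- lrSpacing / field@spacing
  sigma <- if (antialias) 0.5 * sqrt(ratio^2 - 1) else rep(0, 3)
  outDim <- pmax(1L, as.integer(round(dims * field@spacing / lrSpacing)))
  degrade <- function(m) {
    if (any(sigma > 0)) m <- cpp_smooth3(m, as.integer(dims), sigma)
    cpp_resample3(m, as.integer(dims), field@spacing, outDim, lrSpacing, 1L)
  }
  if (is(field, "StructuralVolume")) {
    m <- degrade(fieldMatrix(field))
    return(structuralVolume(array(pmin(pmax(m, 0), 1), outDim), lrSpacing))
  }
  if (is(field, "TensorField")) {
    lf <- fieldLog(field)
    m <- degrade(fieldMatrix(lf))
    return(fieldExp(logTensorField(matrixToArray(m, outDim), lrSpacing)))
  }
  if (is(field, "OdfField")) {
    stopifnot(field@space == "sphere")
    tf <- odfFieldLog(field)
    m <- degrade(fieldMatrix(tf))
    return(odfFieldExp(odfField(matrixToArray(m, outDim), lrSpacing,
                                field@shOrder, "tangent")))
  }
  stop("unsupported field type")
}

#' Paired patch decomposition
#'
#' Decomposes a high-resolution volume and a low-resolution field covering
#' the same physical extent into spatially corresponding patch pairs. The
#' HR/LR patch sizes preserve the physical extent relation (e.g., 32 voxels
#' at 0.7 mm versus 18 voxels at 1.25 mm). Offsets are 0-based; the LR
#' offset of each pair is chosen so that the patch centers coincide in the
#' volume-centered world frame (within one LR voxel).
#'
#' @param xHr HR volume ([StructuralVolume] or grid volume on the HR grid).
#' @param yLr LR field (log/tangent domain).
#' @param hrPatch,lrPatch patch sizes in voxels.
#' @param stride HR stride between patch starts (default half patch).
#' @return List with matrices `hrStarts`, `lrStarts` (n x 3, 0-based), the
#'   patch sizes, and the world-frame patch centers `hrCenters`,
#'   `lrCenters`.
#' @export
extractPatches <- function(xHr, yLr, hrPatch = 32L, lrPatch = 18L,
                           stride = hrPatch %/% 2L) {
  dH <- gridDim(xHr)
  dL <- gridDim(yLr)
  spH <- voxelSpacing(xHr)
  spL <- voxelSpacing(yLr)
  if (any(dH < hrPatch) || any(dL < lrPatch))
    stop("volume smaller than one patch")
  starts1 <- function(n, p, s) {
    v <- unique(c(seq(0L, n - p, by = s), n - p))
    as.integer(v)
  }
  sx <- starts1(dH[1], hrPatch, stride)
  sy <- starts1(dH[2], hrPatch, stride)
  sz <- starts1(dH[3], hrPatch, stride)
  hrStarts <- as.matrix(expand.grid(sx, sy, sz))
  colnames(hrStarts) <- NULL
  # centered world frame shared by both grids
  hrCenters <- sweep(sweep(hrStarts + hrPatch / 2, 2, spH, "*"), 2, dH * spH / 2)
  lrStarts <- round(sweep(sweep(hrCenters, 2, dL * spL / 2, "+"), 2, spL, "/") - lrPatch / 2)
  lrStarts <- pmin(pmax(lrStarts, 0), matrix(rep(dL - lrPatch, each = nrow(lrStarts)), ncol = 3))
  storage.mode(lrStarts) <- "integer"
  lrCenters <- sweep(sweep(lrStarts + lrPatch / 2, 2, spL, "*"), 2, dL * spL / 2)
  list(hrStarts = hrStarts, lrStarts = lrStarts,
       hrPatch = as.integer(hrPatch), lrPatch = as.integer(lrPatch),
       hrCenters = hrCenters, lrCenters = lrCenters)
}

#' Extract or reassemble raw patches
#'
#' `patchArray` cuts a patch out of a 3D or 4D array at a 0-based offset;
#' `reassemblePatches` writes patches back at their offsets (later patches
#' overwrite earlier ones where they overlap), inverting `patchArray` for
#' unmodified patches.
#'
#' @param arr 3D or 4D array.
#' @param start 0-based voxel offset (length 3).
#' @param size patch size in voxels.
#' @param patches list of patch arrays.
#' @param starts matrix of 0-based offsets.
#' @param dims output spatial dimensions.
#' @return `patchArray`: the patch array; `reassemblePatches`: the
#'   reassembled array.
#' @export
patchArray <- function(arr, start, size) {
  ix <- (start[1] + 1):(start[1] + size)
  iy <- (start[2] + 1):(start[2] + size)
  iz <- (start[3] + 1):(start[3] + size)
  if (length(dim(arr)) == 3) arr[ix, iy, iz, drop = FALSE]
  else arr[ix, iy, iz, , drop = FALSE]
}

#' @rdname patchArray
#' @export
reassemblePatches <- function(patches, starts, dims) {
  d4 <- length(dim(patches[[1]])) == 4
  out <- if (d4) array(0, c(dims, dim(patches[[1]])[4])) else array(0, dims)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    s <- starts[i, ]
    size <- dim(p)[1]
    ix <- (s[1] + 1):(s[1] + size)
    iy <- (s[2] + 1):(s[2] + size)
    iz <- (s[3] + 1):(s[3] + size)
    if (d4) out[ix, iy, iz, ] <- p else out[ix, iy, iz] <- p
  }
  out
}
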