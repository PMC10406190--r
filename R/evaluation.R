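#' @include spd.R odf.R
NULL

#' Absolute cosine similarity between directions
#'
#' `|a . b| / (||a|| ||b||)`, in `[0, 1]`: fiber directions are axes, so the
#' sign of either vector is irrelevant. Zero vectors yield `NA` (the voxel is
#' excluded from means).
#'
#' @param a,b 3-vectors (or matrices of row vectors).
#' @return Similarity value(s) in `[0, 1]`, `NA` for zero vectors.
#' @export
cosineSimilarity <- function(a, b) {
  if (is.matrix(a)) {
    num <- abs(rowSums(a * b))
    den <- sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))
    out <- ifelse(den > 0, pmin(num / den, 1), NA_real_)
    return(out)
  }
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(NA_real_)
  min(abs(sum(a * b)) / den, 1)
}

# per-voxel principal directions of an ODF field restricted to given voxels
odfDirections <- function(field, voxels, basis, degeneracyRatio = 1.05) {
  m <- fieldMatrix(field)[voxels, , drop = FALSE]
  A2 <- (m %*% t(basis$B))^2
  mx <- apply(A2, 1, max)
  mn <- rowMeans(A2)
  best <- max.col(A2, ties.method = "first")
  dirs <- basis$directions[best, , drop = FALSE]
  dirs <- dirs * ifelse(dirs[, 1] < 0 | (dirs[, 1] == 0 & dirs[, 2] < 0), -1, 1)
  deg <- mx <= 0 | mx / pmax(mn, .Machine$double.xmin) < degeneracyRatio
  dirs[deg, ] <- NA_real_
  dirs
}

#' Compare a generated diffusion field with a reference
#'
#' Computes the evaluation metrics between a generated and a reference field
#' on anisotropy masks derived from the *reference* (FA or GFA at the given
#' thresholds): the mean absolute cosine similarity of principal directions
#' (largest-eigenvalue eigenvector for DT; discrete amplitude argmax on the
#' tessellation for ODF), the mean squared error of FA/GFA, the mean
#' geodesic distance (log-Euclidean for DT, sphere tangent distance for
#' ODF), and the invalid-voxel count of the generated field (non-SPD
#' tensors / unit-norm violations). Voxels where either field has an
#' undefined direction are excluded from the cosine mean and counted.
#'
#' @param gen,ref two [TensorField]s or two sphere-space [OdfField]s on the
#'   same grid.
#' @param thresholds anisotropy mask thresholds.
#' @param sphereVertices tessellation size for ODF peak extraction.
#' @return An `evalReport` list: per-mask metrics under `masks`, plus
#'   `invalidCount`.
#' @export
evaluateFields <- function(gen, ref, thresholds = c(0.2, 0.5),
                           sphereVertices = 724L) {
  if (!identical(gridDim(gen), gridDim(ref)))
    stop("generated and reference fields must share the same grid")
  isDt <- is(ref, "TensorField")
  if (isDt) {
    stopifnot(is(gen, "TensorField"))
    aniso <- as.vector(faMap(ref))
    anisoGen <- as.vector(faMap(gen))
    dirRef <- directionMap(ref)
    dirGen <- directionMap(gen)
    dLog <- fieldMatrix(fieldLog(gen)) - fieldMatrix(fieldLog(ref))
    geo <- sqrt(rowSums(dLog^2))
    invalid <- fieldValidity(gen)$nInvalid
  } else {
    stopifnot(is(gen, "OdfField"), gen@space == "sphere", ref@space == "sphere")
    basis <- shBasis(ref@shOrder, sphereTessellation(sphereVertices))
    aniso <- as.vector(gfaMap(ref))
    anisoGen <- as.vector(gfaMap(gen))
    tg <- fieldMatrix(odfFieldLog(gen))
    tr <- fieldMatrix(odfFieldLog(ref))
    geo <- sqrt(rowSums((tg - tr)^2))
    invalid <- odfFieldValidity(gen)$nInvalid
    dirRef <- dirGen <- NULL
  }
  out <- list(modality = if (isDt) "dt" else "odf", invalidCount = invalid,
              masks = list())
  for (th in thresholds) {
    sel <- which(aniso >= th)
    if (isDt) {
      dr <- dirRef[sel, , drop = FALSE]
      dg <- dirGen[sel, , drop = FALSE]
    } else {
      basis <- shBasis(ref@shOrder, sphereTessellation(sphereVertices))
      dr <- odfDirections(ref, sel, basis)
      dg <- odfDirections(gen, sel, basis)
    }
    cs <- cosineSimilarity(dr, dg)
    ok <- !is.na(cs)
    out$masks[[sprintf("aniso%.1f", th)]] <- list(
      threshold = th,
      nVoxels = length(sel),
      nDegenerate = sum(!ok),
      cosineSimilarityMean = if (any(ok)) mean(cs[ok]) else NA_real_,
      anisotropyMse = if (length(sel)) mean((anisoGen[sel] - aniso[sel])^2) else NA_real_,
      geodesicMean = if (length(sel)) mean(geo[sel]) else NA_real_)
  }
  class(out) <- c("evalReport", "list")
  out
}

#' @export
print.evalReport <- function(x, ...) {
  cat(sprintf("Diffusion synthesis evaluation (%s), %d invalid voxels\n",
              toupper(x$modality), x$invalidCount))
  for (nm in names(x$masks)) {
    m <- x$masks[[nm]]
    cat(sprintf("  mask %s >= %.1f: n=%d  cosine=%.4f  %s MSE=%.4f  geodesic=%.4f\n",
                if (x$modality == "dt") "FA" else "GFA", m$threshold,
                m$nVoxels, m$cosineSimilarityMean,
                if (x$modality == "dt") "FA" else "GFA",
                m$anisotropyMse, m$geodesicMean))
  }
  invisible(x)
}
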