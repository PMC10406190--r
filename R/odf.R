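#' @include AllGenerics.R
NULL

## Square-root ODF framework. An ODF p(s) on the sphere is represented by the
## spherical-harmonic coefficients c of its square root psi = sqrt(p); the
## unit-mass constraint on p becomes ||c|| = 1, so each voxel is a point on
## the coefficient sphere S^{K-1}. The uniform distribution corresponds to
## u = (1, 0, ..., 0); log/exp maps at u give a flat tangent space in which
## networks and losses operate, and the exp map enforces unit norm (validity)
## for any tangent input.

#' Real symmetric spherical-harmonic basis
#'
#' Evaluates the real, antipodally symmetric (even-order) spherical-harmonic
#' basis at the given unit directions, in (degree, order) lexicographic
#' ordering: for each even degree k = 0, 2, ..., L, orders m = -k..k, with
#' sine terms for m < 0, the zonal term for m = 0 and cosine terms for m > 0
#' (orthonormal real basis with Condon-Shortley phase). K = (L+1)(L+2)/2
#' functions in total; the first basis function is the constant 1/sqrt(4*pi).
#'
#' @param L even non-negative spherical-harmonic order.
#' @param directions n x 3 matrix of unit vectors.
#' @return List with elements `B` (n x K matrix of basis values), `L`, `K`
#'   and `directions`.
#' @examples
#' b <- shBasis(4, sphereTessellation(724))
#' b$K  # 15
#' @export
shBasis <- function(L, directions) {
  if (L < 0 || L %% 2 != 0) stop("spherical-harmonic order L must be even and >= 0")
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  theta <- acos(pmin(pmax(directions[, 3], -1), 1))
  phi <- atan2(directions[, 2], directions[, 1])
  ct <- cos(theta)
  K <- as.integer((L + 1) * (L + 2) / 2)
  B <- matrix(0, nrow(directions), K)
  col <- 1L
  for (k in seq(0, L, by = 2)) {
    P <- pracma::legendre(k, ct)  # (k+1) x n, rows m = 0..k, CS phase included
    if (k == 0) P <- matrix(P, nrow = 1)
    for (m in -k:k) {
      am <- abs(m)
      N <- sqrt((2 * k + 1) / (4 * pi) * factorial(k - am) / factorial(k + am))
      Bcol <- if (m < 0) {
        sqrt(2) * N * P[am + 1, ] * sin(am * phi)
      } else if (m == 0) {
        N * P[1, ]
      } else {
        sqrt(2) * N * P[am + 1, ] * cos(am * phi)
      }
      B[, col] <- Bcol
      col <- col + 1L
    }
  }
  list(B = B, L = as.integer(L), K = K, directions = directions,
       name = "real-symmetric-lex")
}

#' Antipodally symmetric sphere tessellation
#'
#' A deterministic set of `n` unit vectors closed under point reflection,
#' built from a Fibonacci spiral on the upper hemisphere joined with its
#' antipodes (n must be even). Used for ODF amplitude evaluation, peak
#' extraction and validity checks; the default 724-vertex sphere gives a
#' vertex spacing of roughly 7-8 degrees.
#'
#' @param n even number of vertices.
#' @return n x 3 matrix of unit vectors where vertex i + n/2 is the antipode
#'   of vertex i.
#' @export
sphereTessellation <- function(n = 724L) {
  if (n %% 2 != 0) stop("n must be even for an antipodally symmetric set")
  m <- n / 2
  i <- seq_len(m)
  z <- (i - 0.5) / m           # upper hemisphere z in (0, 1)
  phi <- i * pi * (3 - sqrt(5))  # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  upper <- cbind(r * cos(phi), r * sin(phi), z)
  rbind(upper, -upper)
}

odfU <- function(K) c(1, numeric(K - 1))

#' Sphere logarithm and exponential maps at the uniform distribution
#'
#' `odfLog` maps a unit-norm coefficient vector c to the tangent plane at
#' u = (1, 0, ..., 0): `v = (c - u cos(Psi)) / ||c - u cos(Psi)|| * Psi` with
#' `Psi = arccos(<u, c>)`; its norm is the geodesic angle to u and it is
#' orthogonal to u. `odfExp` is the inverse: `u cos(Psi) + v/||v|| sin(Psi)`
#' with `Psi = ||v||`, which has unit norm for every tangent input -- the
#' ODF validity guarantee. Any component of `v` along u is projected out
#' first.
#'
#' @param c unit-norm coefficient vector.
#' @param v tangent vector at u.
#' @return `odfLog`: tangent vector; `odfExp`: unit-norm coefficient vector.
#' @export
odfLog <- function(c) {
  K <- length(c)
  if (abs(sqrt(sum(c^2)) - 1) > 1e-6) stop("coefficients must have unit norm")
  ca <- min(max(c[1], -1), 1)
  if (ca <= -1 + 1e-12) stop("log map undefined at the antipode of u")
  psi <- acos(ca)
  w <- c
  w[1] <- w[1] - ca
  nw <- sqrt(sum(w^2))
  if (nw < 1e-14 || psi < 1e-14) return(numeric(K))
  w / nw * psi
}

#' @rdname odfLog
#' @export
odfExp <- function(v) {
  K <- length(v)
  v[1] <- 0  # project onto the tangent plane at u
  psi <- sqrt(sum(v^2))
  u <- odfU(K)
  if (psi < 1e-14) return(u)
  out <- u * cos(psi) + v / psi * sin(psi)
  out / sqrt(sum(out^2))
}

#' Geodesic distance between two square-root ODFs
#'
#' The Euclidean distance between the tangent-plane projections at u:
#' `||log_u(c) - log_u(c')||`. For c' = u this reduces to the geodesic angle
#' `arccos(<u, c>)`.
#'
#' @param c1,c2 unit-norm coefficient vectors.
#' @return Non-negative scalar.
#' @export
odfGeodesic <- function(c1, c2) {
  sqrt(sum((odfLog(c1) - odfLog(c2))^2))
}

#' Generalized fractional anisotropy from square-root coefficients
#'
#' GFA = sqrt(1 - c1^2 / sum(ci^2)), the normalized distance of the ODF from
#' the uniform distribution (0 at u, 1 when the isotropic component
#' vanishes). Vectorized: `c` may be a matrix with one coefficient vector per
#' row.
#'
#' @param c coefficient vector, or matrix of row vectors.
#' @return GFA value(s) in `[0, 1]`.
#' @export
gfa <- function(c) {
  if (is.matrix(c)) {
    ss <- rowSums(c^2)
    out <- sqrt(pmax(0, 1 - c[, 1]^2 / ss))
    out[ss == 0] <- 0
    return(out)
  }
  ss <- sum(c^2)
  if (ss == 0) return(0)
  sqrt(max(0, 1 - c[1]^2 / ss))
}

#' Least-squares square-root ODF fit
#'
#' Fits the square root of sampled ODF values in the spherical-harmonic basis
#' and renormalizes the coefficients to unit norm. The uniform ODF maps to
#' u = (1, 0, ..., 0).
#'
#' @param samples non-negative ODF values, one per basis direction (vector) or
#'   one row per voxel (matrix).
#' @param basis a basis from [shBasis()] evaluated at the sample directions.
#' @return Unit-norm coefficient vector (or matrix of row vectors).
#' @export
sqrtOdfFit <- function(samples, basis) {
  m <- if (is.matrix(samples)) samples else matrix(samples, nrow = 1)
  if (ncol(m) != nrow(basis$B))
    stop("one sample per basis direction required")
  if (any(m < 0)) stop("ODF samples must be non-negative")
  qrB <- qr(basis$B)
  if (qrB$rank < basis$K)
    stop("rank-deficient design: directions do not determine the basis coefficients")
  cf <- t(qr.coef(qrB, t(sqrt(m))))
  nrm <- sqrt(rowSums(cf^2))
  if (any(nrm == 0)) stop("degenerate fit (all-zero samples)")
  cf <- cf / nrm
  flip <- cf[, 1] < 0
  cf[flip, ] <- -cf[flip, ]
  if (is.matrix(samples)) cf else cf[1, ]
}

#' Principal direction and peaks of an ODF
#'
#' `odfPrincipalDirection` returns the vertex of the tessellation maximizing
#' the reconstructed ODF amplitude (psi squared), sign-normalized; `NULL` is
#' returned when the maximum-to-mean amplitude ratio is below
#' `degeneracyRatio` (no meaningful maximum, e.g., the uniform ODF).
#' `odfPeaks` extracts up to `maxPeaks` local maxima (one representative per
#' antipodal pair, strongest first) whose amplitude exceeds
#' `relThreshold` times the global maximum.
#'
#' @param c unit-norm coefficient vector.
#' @param basis a basis from [shBasis()] evaluated at an antipodally
#'   symmetric tessellation (see [sphereTessellation()]).
#' @param degeneracyRatio max/mean squared-amplitude ratio below which the
#'   direction is undefined.
#' @param maxPeaks maximum number of peaks to return.
#' @param relThreshold relative amplitude threshold for secondary peaks.
#' @param minSeparation minimal angular separation between peaks (degrees).
#' @return `odfPrincipalDirection`: unit 3-vector or `NULL`;
#'   `odfPeaks`: matrix of peak directions (possibly 0 rows) with amplitudes
#'   as attribute `"amplitude"`.
#' @export
odfPrincipalDirection <- function(c, basis, degeneracyRatio = 1.05) {
  a2 <- as.vector(basis$B %*% c)^2
  mx <- max(a2)
  if (mx <= 0 || mx / mean(a2) < degeneracyRatio) return(NULL)
  signNormalize(basis$directions[which.max(a2), ])
}

#' @rdname odfPrincipalDirection
#' @export
odfPeaks <- function(c, basis, maxPeaks = 3L, relThreshold = 0.25,
                     minSeparation = 25) {
  amp <- as.vector(basis$B %*% c)
  a2 <- amp^2
  nb <- sphereNeighbors(basis$directions)
  isMax <- vapply(seq_len(nrow(nb)), function(i) all(a2[i] >= a2[nb[i, ]]),
                  logical(1))
  cand <- which(isMax & a2 >= relThreshold * max(a2))
  if (!length(cand)) return(structure(matrix(0, 0, 3), amplitude = numeric(0)))
  cand <- cand[order(a2[cand], decreasing = TRUE)]
  dirs <- basis$directions[cand, , drop = FALSE]
  keep <- integer(0)
  cosSep <- cos(minSeparation * pi / 180)
  for (i in seq_len(nrow(dirs))) {
    if (length(keep) &&
        any(abs(dirs[keep, , drop = FALSE] %*% dirs[i, ]) > cosSep)) next
    keep <- c(keep, i)
    if (length(keep) >= maxPeaks) break
  }
  out <- dirs[keep, , drop = FALSE]
  out <- t(apply(out, 1, signNormalize))
  structure(out, amplitude = a2[cand[keep]])
}

# cached k-nearest neighbors on a tessellation (by angular proximity)
sphereNeighborCache <- new.env(parent = emptyenv())

sphereNeighbors <- function(directions, k = 8L) {
  key <- sprintf("n%d_k%d_%0.6f", nrow(directions), k, sum(directions[1, ]))
  if (!is.null(sphereNeighborCache[[key]])) return(sphereNeighborCache[[key]])
  G <- abs(tcrossprod(directions))  # antipodal-aware proximity
  diag(G) <- -Inf
  nb <- t(apply(G, 1, function(r) order(r, decreasing = TRUE)[seq_len(k)]))
  sphereNeighborCache[[key]] <- nb
  nb
}

#' Validity check for ODF coefficients
#'
#' Checks the two constraints of the square-root parameter space: unit norm
#' of the coefficient vector (within `tol`) and non-negativity of the
#' reconstructed amplitude over the tessellation. Non-negativity is reported
#' as a diagnostic (minimum amplitude), not enforced; validity counting uses
#' the unit-norm constraint.
#'
#' @param c coefficient vector or matrix of row vectors.
#' @param basis a basis from [shBasis()].
#' @param tol unit-norm tolerance.
#' @return List with `unitNormOk` (logical vector) and `minAmplitude`
#'   (numeric vector).
#' @export
odfValidity <- function(c, basis, tol = 1e-6) {
  m <- if (is.matrix(c)) c else matrix(c, nrow = 1)
  nrm <- sqrt(rowSums(m^2))
  amp <- m %*% t(basis$B)
  list(unitNormOk = abs(nrm - 1) <= tol,
       minAmplitude = apply(amp, 1, min))
}

## ---- field-level maps ------------------------------------------------------

#' Field-level sphere log/exp maps
#'
#' Vectorized [odfLog()]/[odfExp()] over every voxel of an [OdfField],
#' converting between `space = "sphere"` (unit-norm coefficients) and
#' `space = "tangent"` (tangent vectors at the uniform distribution u). The
#' exp map projects out any component along u first and always produces
#' unit-norm voxels.
#'
#' @param field an [OdfField].
#' @return The mapped [OdfField] in the other space.
#' @export
odfFieldLog <- function(field) {
  stopifnot(is(field, "OdfField"), field@space == "sphere")
  m <- fieldMatrix(field)
  nrm <- sqrt(rowSums(m^2))
  bad <- abs(nrm - 1) > 1e-6
  if (any(bad))
    stop(sprintf("%d voxels violate the unit-norm constraint", sum(bad)))
  ca <- pmin(pmax(m[, 1], -1), 1)
  if (any(ca <= -1 + 1e-12)) stop("log map undefined at the antipode of u")
  psi <- acos(ca)
  w <- m
  w[, 1] <- w[, 1] - ca
  nw <- sqrt(rowSums(w^2))
  scl <- ifelse(nw < 1e-14 | psi < 1e-14, 0, psi / pmax(nw, 1e-300))
  v <- w * scl
  odfField(matrixToArray(v, gridDim(field)), field@spacing, field@shOrder,
           "tangent", field@affine)
}

#' @rdname odfFieldLog
#' @export
odfFieldExp <- function(field) {
  stopifnot(is(field, "OdfField"), field@space == "tangent")
  v <- fieldMatrix(field)
  v[, 1] <- 0
  psi <- sqrt(rowSums(v^2))
  K <- ncol(v)
  scl <- ifelse(psi < 1e-14, 0, sin(psi) / pmax(psi, 1e-300))
  out <- v * scl
  out[, 1] <- cos(psi)
  out <- out / sqrt(rowSums(out^2))
  odfField(matrixToArray(out, gridDim(field)), field@spacing, field@shOrder,
           "sphere", field@affine)
}

#' Voxelwise GFA of an ODF field
#'
#' For sphere-space fields, the GFA of each coefficient vector; for
#' tangent-space fields, the GFA of the exp-mapped voxels (which reduces to
#' `|sin(||v||)|`).
#'
#' @param field an [OdfField].
#' @return 3D array of GFA values in `[0, 1]`.
#' @export
gfaMap <- function(field) {
  stopifnot(is(field, "OdfField"))
  m <- fieldMatrix(field)
  if (field@space == "sphere") {
    vals <- gfa(m)
  } else {
    v <- m
    v[, 1] <- 0
    vals <- abs(sin(sqrt(rowSums(v^2))))
  }
  array(vals, gridDim(field))
}

#' Validity sweep over an ODF field
#'
#' Counts voxels violating the unit-norm constraint and reports the minimum
#' reconstructed amplitude per voxel as a non-negativity diagnostic.
#'
#' @param field a sphere-space [OdfField].
#' @param basis optional basis for the amplitude diagnostic (skipped if
#'   `NULL`).
#' @param tol unit-norm tolerance.
#' @return List with `nInvalid`, `nVoxels`, `norms` and (if a basis is given)
#'   `minAmplitudes`.
#' @export
odfFieldValidity <- function(field, basis = NULL, tol = 1e-6) {
  stopifnot(is(field, "OdfField"), field@space == "sphere")
  m <- fieldMatrix(field)
  nrm <- sqrt(rowSums(m^2))
  out <- list(nInvalid = sum(abs(nrm - 1) > tol), nVoxels = nrow(m), norms = nrm)
  if (!is.null(basis))
    out$minAmplitudes <- apply(m %*% t(basis$B), 1, min)
  out
}
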