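# Shared fixtures built in code at test time.

randomSpd <- function(cond = 10) {
  # random SPD 3x3 with bounded condition number
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  d <- exp(runif(3, -0.5 * log(cond), 0.5 * log(cond)))
  Q %*% diag(d) %*% t(Q)
}

randomRotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

randomSymmetric <- function(scale = 1) {
  S <- matrix(rnorm(9, sd = scale), 3)
  (S + t(S)) / 2
}

# small straight-bundle phantom reused across tests (computed once per run)
smallPhantomCache <- new.env()

smallPhantom <- function(grid = 24, odf = TRUE) {
  key <- sprintf("g%d_o%d", grid, odf)
  if (is.null(smallPhantomCache[[key]])) {
    smallPhantomCache[[key]] <- makePhantom(
      phantomSpec(gridShape = rep(grid, 3),
                  bundles = list(straightBundle("z", radius = 3.5,
                                                extent = grid * 0.7)),
                  seed = 42L),
      odf = odf)
  }
  smallPhantomCache[[key]]
}

unitVec <- function(v) v / sqrt(sum(v^2))
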