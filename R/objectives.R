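#' @include AllGenerics.R
NULL

#' Loss weights
#'
#' The weighting of the cycle-consistency and prior terms plus the anisotropy
#' weight floor. Defaults follow the full-scale training setup: prior weights
#' 10 (structural) and 0.5 (diffusion), cycle weights 5 (structural) and 0.25
#' (diffusion).
#'
#' @param cycX,cycY cycle-consistency weights for the structural and
#'   diffusion cycles.
#' @param priorX,priorY paired-prior weights for the structural and diffusion
#'   terms.
#' @param anisoFloor lower bound of the anisotropy weights in `[0, 1)`;
#'   isotropic tissue is down-weighted but never zero-weighted.
#' @return A named list of weights.
#' @export
lossWeights <- function(cycX = 5, cycY = 0.25, priorX = 10, priorY = 0.5,
                        anisoFloor = 0.05) {
  stopifnot(cycX >= 0, cycY >= 0, priorX >= 0, priorY >= 0,
            anisoFloor >= 0, anisoFloor < 1)
  list(cycX = cycX, cycY = cycY, priorX = priorX, priorY = priorY,
       anisoFloor = anisoFloor)
}

#' Least-squares adversarial losses
#'
#' The LSGAN objectives: the discriminator minimizes
#' `0.5 mean((D(real) - 1)^2) + 0.5 mean(D(fake)^2)` and the generator
#' minimizes `0.5 mean((D(fake) - 1)^2)`. For the diffusion branch the
#' "fake" inputs are downsampled synthesized volumes F(G_Y(x)) and the
#' "real" inputs are log-mapped LR volumes, both in the log/tangent domain.
#'
#' @param realScores,fakeScores discriminator scores (finite numerics).
#' @return Non-negative scalar loss.
#' @export
lsganDiscriminatorLoss <- function(realScores, fakeScores) {
  if (any(!is.finite(realScores)) || any(!is.finite(fakeScores)))
    stop("non-finite discriminator scores: training diverged")
  0.5 * mean((realScores - 1)^2) + 0.5 * mean(fakeScores^2)
}

#' @rdname lsganDiscriminatorLoss
#' @export
lsganGeneratorLoss <- function(fakeScores) {
  if (any(!is.finite(fakeScores)))
    stop("non-finite discriminator scores: training diverged")
  0.5 * mean((fakeScores - 1)^2)
}

#' Anisotropy weights of a target diffusion volume
#'
#' Per-voxel weights `max(FA, floor)` (tensor fields) or `max(GFA, floor)`
#' (ODF fields), computed on the *target* (real-data) volume. High-anisotropy
#' voxels carry fiber-tract information but are under-represented, so the
#' diffusion reconstruction errors in the cycle and prior losses are weighted
#' by the target anisotropy to keep the generated anisotropy distribution
#' faithful.
#'
#' @param target a [TensorField], [LogTensorField] or [OdfField].
#' @param floor weight floor in `[0, 1)`.
#' @return 3D array of weights in `[floor, 1]`.
#' @export
anisotropyWeights <- function(target, floor = 0.05) {
  a <- if (is(target, "OdfField")) gfaMap(target) else faMap(target)
  pmax(a, floor)
}

# mean absolute error, optionally anisotropy-weighted per voxel
# (weights broadcast over channels; weighted form is mean(w * |e|))
wMeanAbs <- function(a, b, w = NULL) {
  e <- abs(a - b)
  if (is.null(w)) return(mean(e))
  mean(as.vector(e) * rep(as.vector(w), length.out = length(e)))
}

asChanMatrix <- function(x) {
  d <- dim(x)
  if (length(d) == 3) matrix(x, ncol = 1) else matrix(x, prod(d[1:3]), d[4])
}

#' Three-term cycle-consistency loss
#'
#' `cycX * mean|G_X(G_Y(x)) - x|` (forward structural cycle) plus
#' `0.5 * cycY * wmean|G_Y(G_X(up(y))) - up(y)|` (backward HR diffusion
#' cycle) plus `0.5 * cycY * wmean|F(G_Y(G_X(up(y)))) - y|` (backward LR
#' diffusion cycle), with l1 voxel errors; the diffusion terms are weighted
#' per voxel by the anisotropy of the corresponding real volume. All
#' diffusion quantities are in the log/tangent domain.
#'
#' @param x HR structural array.
#' @param yUp HR-grid upsampled log/tangent diffusion array.
#' @param yLr LR-grid log/tangent diffusion array.
#' @param GX,GY,F functions mapping arrays to arrays (the two generators and
#'   the downsampler, e.g., closures over [netApply()]).
#' @param weights a [lossWeights()] list.
#' @param wHr,wLr optional per-voxel anisotropy weight arrays for the HR and
#'   LR diffusion terms.
#' @return Non-negative scalar.
#' @export
cycleLoss <- function(x, yUp, yLr, GX, GY, F, weights = lossWeights(),
                      wHr = NULL, wLr = NULL) {
  gyx <- GY(x)
  fwd <- weights$cycX * wMeanAbs(GX(gyx), x)
  gxy <- GX(yUp)
  rec <- GY(gxy)
  bwdHr <- 0.5 * weights$cycY * wMeanAbs(rec, yUp, wHr)
  bwdLr <- 0.5 * weights$cycY * wMeanAbs(F(rec), yLr, wLr)
  fwd + bwdHr + bwdLr
}

#' Paired prior loss
#'
#' For aligned paired volumes (x_i, y_i):
#' `priorY * wmean|G_Y(x_i) - up(y_i)| + priorX * mean|G_X(up(y_i)) - x_i|`.
#' The prior anchors the unpaired adversarial training to plausible
#' solutions using a limited number of paired subjects.
#'
#' @param x HR structural array of a paired subject.
#' @param yUp its aligned upsampled log/tangent diffusion array.
#' @param GX,GY generator functions.
#' @param weights a [lossWeights()] list.
#' @param w optional per-voxel anisotropy weights for the diffusion term.
#' @return Non-negative scalar.
#' @export
priorLoss <- function(x, yUp, GX, GY, weights = lossWeights(), w = NULL) {
  if (!identical(dim(x)[1:3], dim(yUp)[1:3]))
    stop("prior loss requires aligned paired volumes on the same grid")
  weights$priorY * wMeanAbs(GY(x), yUp, w) +
    weights$priorX * wMeanAbs(GX(yUp), x)
}

#' Full mini-max objective
#'
#' Assembles the loss of each player on a batch: the generator side minimizes
#' the adversarial generator terms plus cycle and prior losses; each
#' discriminator minimizes its own LSGAN objective against detached fakes.
#' This compositional form is used for logging and testing; the training
#' loop computes the same quantities with cached activations for
#' backpropagation, keeping gradients of the two players isolated.
#'
#' @param batch list with elements `x`, `yUp`, `yLr`, `pairedX`, `pairedYUp`,
#'   and optional weight arrays `wHr`, `wLr`, `wPrior`.
#' @param models list with functions `GX`, `GY`, `F`, `DX`, `DY` (the
#'   discriminators map arrays to scalar scores).
#' @param weights a [lossWeights()] list.
#' @return List with components `generator`, `discX`, `discY` and the
#'   individual terms.
#' @export
fullObjective <- function(batch, models, weights = lossWeights()) {
  fakeY <- models$F(models$GY(batch$x))
  fakeX <- models$GX(batch$yUp)
  advY <- lsganGeneratorLoss(models$DY(fakeY))
  advX <- lsganGeneratorLoss(models$DX(fakeX))
  cyc <- cycleLoss(batch$x, batch$yUp, batch$yLr, models$GX, models$GY,
                   models$F, weights, batch$wHr, batch$wLr)
  pri <- priorLoss(batch$pairedX, batch$pairedYUp, models$GX, models$GY,
                   weights, batch$wPrior)
  dY <- lsganDiscriminatorLoss(models$DY(batch$yLr), models$DY(fakeY))
  dX <- lsganDiscriminatorLoss(models$DX(batch$x), models$DX(fakeX))
  list(generator = advX + advY + cyc + pri,
       adversarialX = advX, adversarialY = advY, cycle = cyc, prior = pri,
       discX = dX, discY = dY)
}
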