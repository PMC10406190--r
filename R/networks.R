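#' @include nnet.R
NULL

#' Generator specification
#'
#' Describes an encoder-decoder generator with skip connections (3D U-Net
#' topology). The final activation is chosen per modality: `"sigmoid"` bounds
#' structural outputs to `[0, 1]`, `"hardtanh"` bounds log-tensor outputs to
#' `[-a, a]` (with `a` covering the data's log-eigenvalue dynamic range plus
#' margin), `"tanh"` bounds ODF tangent outputs to `[-1, 1]` scaled by
#' `activationBound`, and `"linear"` leaves outputs unbounded (used by the
#' no-manifold baseline).
#'
#' @param inChannels,outChannels channel counts (1 structural, 9 log-tensor,
#'   K ODF tangent).
#' @param finalActivation one of `"sigmoid"`, `"hardtanh"`, `"tanh"`,
#'   `"linear"`.
#' @param depth number of pooling levels.
#' @param baseWidth feature maps at the first level (doubled per level).
#' @param convsPerBlock convolutions per encoder/decoder block.
#' @param activationBound saturation bound `a` for hardtanh/tanh outputs.
#' @param instanceNorm apply per-channel instance normalization after each
#'   block convolution (the final output convolution is never normalized).
#' @return A generator specification list.
#' @export
generatorSpec <- function(inChannels, outChannels,
                          finalActivation = c("sigmoid", "hardtanh", "tanh", "linear"),
                          depth = 2L, baseWidth = 8L, convsPerBlock = 2L,
                          activationBound = 3, instanceNorm = TRUE) {
  finalActivation <- match.arg(finalActivation)
  stopifnot(inChannels >= 1, outChannels >= 1, depth >= 1, baseWidth >= 1)
  list(inChannels = as.integer(inChannels), outChannels = as.integer(outChannels),
       finalActivation = finalActivation, depth = as.integer(depth),
       baseWidth = as.integer(baseWidth), convsPerBlock = as.integer(convsPerBlock),
       activationBound = activationBound, instanceNorm = isTRUE(instanceNorm))
}

#' Build networks from specifications
#'
#' `buildGenerator`, `buildDiscriminator` and `buildDownsampler` instantiate
#' networks with freshly initialized weights (He initialization; the learned
#' correction of the downsampler starts at zero so it initially equals plain
#' trilinear resampling). Initialization is driven by the current RNG state,
#' so wrap in `set.seed()` for reproducibility.
#'
#' @param spec the corresponding specification list.
#' @return A network object (environment of class `dmrisynthNet`).
#' @export
buildGenerator <- function(spec) {
  newNet("unet", spec, unetInit(spec))
}

#' Discriminator specification
#'
#' A strided 3D convolutional critic producing one scalar score per input
#' volume (pairs of unit- and stride-2 convolutions over the given feature
#' widths, followed by a linear score map averaged over remaining voxels).
#'
#' @param inChannels input channels (1 structural HR; 9 or 15 diffusion LR).
#' @param widths feature maps per stage.
#' @return A discriminator specification list.
#' @export
discriminatorSpec <- function(inChannels, widths = c(32L, 64L, 128L, 256L)) {
  stopifnot(inChannels >= 1, length(widths) >= 1)
  list(inChannels = as.integer(inChannels), widths = as.integer(widths))
}

#' @rdname buildGenerator
#' @export
buildDiscriminator <- function(spec) {
  newNet("disc", spec, discInit(spec))
}

#' Residual downsampler specification
#'
#' The learned map F from the high-resolution grid to the low-resolution grid:
#' a fixed trilinear resampling plus a learned 3-layer convolutional residual
#' correction on the LR grid. With the correction zeroed (its initial state)
#' F is exactly trilinear resampling.
#'
#' @param channels number of channels (9 for DT, K for ODF).
#' @param hrSpacing,lrSpacing grid spacings in mm (defaults 0.7 and 1.25).
#' @param lrDim output grid size (e.g., 18^3 for 32^3 input at 0.7 to 1.25 mm).
#' @param hidden width of the residual stack.
#' @return A downsampler specification list.
#' @export
downsamplerSpec <- function(channels, hrSpacing = 0.7, lrSpacing = 1.25,
                            lrDim = c(18L, 18L, 18L), hidden = 8L) {
  list(channels = as.integer(channels),
       hrSpacing = rep(hrSpacing, length.out = 3),
       lrSpacing = rep(lrSpacing, length.out = 3),
       lrDim = as.integer(rep(lrDim, length.out = 3)),
       hidden = as.integer(hidden))
}

#' @rdname buildGenerator
#' @export
buildDownsampler <- function(spec) {
  newNet("resdown", spec, downInit(spec))
}

#' Apply a network to a volume array
#'
#' Runs a forward pass on a single 3D (scalar) or 4D (multi-channel) array and
#' returns the output array (or the scalar score for discriminators). This is
#' the inference-side entry point; training uses the cached forward/backward
#' machinery internally.
#'
#' @param net a built network.
#' @param x input array.
#' @return Output array of matching spatial shape (generators), LR-grid array
#'   (downsampler) or scalar (discriminators).
#' @export
netApply <- function(net, x) {
  d <- dim(x)
  dims <- d[1:3]
  m <- if (length(d) == 3) matrix(x, ncol = 1) else matrix(x, prod(dims), d[4])
  out <- netForward(net, m, dims, keep = FALSE)
  if (net$kind == "disc") return(out$y)
  matrixToArray(out$y, out$dims)
}

#' Map a raw generator output to a valid diffusion field
#'
#' The decoding step that turns network outputs in the log/tangent domain into
#' manifold-valid diffusion data: 9-channel outputs are symmetrized and
#' exp-mapped to SPD tensors; K-channel ODF tangent outputs are projected onto
#' the tangent plane at the uniform distribution u (the component along u is
#' removed) and exp-mapped to unit-norm coefficients. Holds for *any* weight
#' state, which is the architectural validity guarantee.
#'
#' @param out 4D array produced by a diffusion generator.
#' @param modality `"dt"` or `"odf"`.
#' @param spacing,affine grid geometry of the result.
#' @param shOrder spherical-harmonic order for ODF outputs.
#' @return A [TensorField] or sphere-space [OdfField].
#' @export
decodeDiffusion <- function(out, modality = c("dt", "odf"), spacing = 1,
                            affine = NULL, shOrder = 4L) {
  modality <- match.arg(modality)
  if (modality == "dt") {
    lf <- unpackChannels(out, symmetrize = TRUE, log = TRUE, spacing = spacing,
                         affine = affine)
    fieldExp(lf)
  } else {
    tf <- odfField(out, spacing, shOrder, "tangent", affine)
    odfFieldExp(tf)
  }
}
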