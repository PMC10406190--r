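#' @include AllClasses.R
NULL

sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read and write typed NIfTI volumes
#'
#' Volumes are stored as NIfTI-1 files; multi-channel diffusion types (9 or
#' K channels in the 4th dimension) additionally require a JSON sidecar
#' recording the channel semantics, because an SPD-domain and a log-domain
#' tensor field are indistinguishable by shape: `{"space": "spd" | "log"}`
#' for tensor fields and `{"space": "sphere" | "tangent", "sh_order": L,
#' "basis": name}` for ODF fields. Scalar 3D volumes are read as
#' [StructuralVolume] and need no sidecar. Affine and spacing round-trip
#' through the NIfTI header.
#'
#' @param vol a grid volume object.
#' @param path NIfTI file path (`.nii` or `.nii.gz`); the sidecar lives next
#'   to it with extension `.json`.
#' @return `readVolume`: a typed volume; `writeVolume`: `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  attr(img, "pixdim")[1:3] <- vol@spacing
  img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
  RNifti::writeNifti(img, path)
  sc <- NULL
  if (is(vol, "TensorField")) sc <- list(space = "spd")
  if (is(vol, "LogTensorField")) sc <- list(space = "log")
  if (is(vol, "OdfField"))
    sc <- list(space = vol@space, sh_order = vol@shOrder,
               basis = "real-symmetric-lex")
  if (!is.null(sc))
    jsonlite::write_json(sc, sidecarPath(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  d <- dim(arr)
  if (length(d) == 3)
    return(structuralVolume(arr, spacing, affine))
  if (length(d) != 4) stop("expected a 3D or 4D NIfTI volume")
  scp <- sidecarPath(path)
  if (!file.exists(scp))
    stop(sprintf("multi-channel volume requires a sidecar JSON at %s", scp))
  sc <- jsonlite::read_json(scp, simplifyVector = TRUE)
  if (d[4] == 9 && sc$space %in% c("spd", "log")) {
    if (sc$space == "log") return(logTensorField(arr, spacing, affine))
    return(tensorField(arr, spacing, affine))
  }
  if (!is.null(sc$sh_order)) {
    if (!sc$space %in% c("sphere", "tangent"))
      stop(sprintf("unknown sidecar space '%s'", sc$space))
    return(odfField(arr, spacing, as.integer(sc$sh_order), sc$space, affine))
  }
  stop(sprintf("unknown sidecar space '%s' for a %d-channel volume",
               sc$space, d[4]))
}

#' Run manifest
#'
#' Records what produced a set of artifacts: configuration snapshot, seeds,
#' package version, input/output paths and their MD5 hashes. Every CLI
#' subcommand writes one next to its outputs.
#'
#' @param path output JSON path.
#' @param command subcommand name.
#' @param config configuration list.
#' @param seed integer seed(s).
#' @param inputs,outputs file paths.
#' @return The manifest list, invisibly.
#' @export
writeManifest <- function(path, command, config = list(), seed = NULL,
                          inputs = character(), outputs = character()) {
  hash <- function(f) unname(tools::md5sum(f[file.exists(f)]))
  manifest <- list(
    command = command,
    version = as.character(utils::packageVersion("dmrisynth")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    inputs = list(paths = inputs, md5 = hash(inputs)),
    outputs = list(paths = outputs, md5 = hash(outputs)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
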