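## ---- configuration ----

configFields <- c("wavelength", "na", "G", "Nbgd", "psfSigmaX", "psfSigmaY",
                  "P", "dx", "dy", "dt", "shutter", "nFrames", "nSub",
                  "Dx", "Dy", "cameraKind", "segmentation", "initialPosition")

#' Convert a scene configuration to/from a plain list
#'
#' @param config a [SceneConfig-class]
#' @return named list mirroring the slot names
#' @export
sceneConfigToList <- function(config) {
  out <- lapply(configFields, function(f) slot(config, f))
  names(out) <- configFields
  out
}

#' @rdname sceneConfigToList
#' @param x named list (unknown names are an error; missing names fall back
#'   to the [sceneConfig()] defaults)
#' @export
sceneConfigFromList <- function(x) {
  bad <- setdiff(names(x), configFields)
  if (length(bad))
    stop(sprintf("unknown configuration field(s): %s",
                 paste(bad, collapse = ", ")))
  do.call(sceneConfig, x)
}

#' Read or write a scene configuration as JSON
#'
#' @param config a [SceneConfig-class]
#' @param file path to a JSON document
#' @export
writeSceneConfig <- function(config, file) {
  jsonlite::write_json(sceneConfigToList(config), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname writeSceneConfig
#' @return for the reader, a validated [SceneConfig-class]
#' @export
readSceneConfig <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  sceneConfigFromList(x)
}

## FNV-1a hash over the canonical (name-sorted) JSON of a list; gives a
## config hash that is stable under field reordering
canonicalHash <- function(x) {
  if (is.list(x)) x <- x[order(names(x))]
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  # 32-bit arithmetic via 16-bit halves (doubles lose no precision this way)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## ---- frame stacks ----

#' Write a frame stack to disk
#'
#' Two formats: a lossless R serialization (`.rds`) holding frames, config
#' and ground truth; or a multi-page TIFF (`.tif`/`.tiff`) with a JSON
#' sidecar (`<file>.json`) carrying the config, truth and the affine scaling
#' used to map counts into the TIFF sample range. Ideal-camera counts are
#' stored as 16-bit samples (exact round-trip for counts below 65536); sCMOS
#' frames, which are real-valued, are stored as 32-bit samples after affine
#' rescaling and round-trip to about 2^-32 relative precision.
#'
#' @param stack a [FrameStack-class]
#' @param file output path ending in `.rds`, `.tif` or `.tiff`
#' @return `file`, invisibly
#' @export
writeFrameStack <- function(stack, file) {
  if (grepl("\\.rds$", file, ignore.case = TRUE)) {
    saveRDS(list(frames = frames(stack),
                 config = sceneConfigToList(sceneConfigOf(stack)),
                 origins = windowOrigins(stack),
                 truth = truePositions(stack)), file)
    return(invisible(file))
  }
  if (!grepl("\\.tiff?$", file, ignore.case = TRUE))
    stop("'file' must end in .rds, .tif or .tiff")
  fr <- frames(stack)
  cfg <- sceneConfigOf(stack)
  ideal <- cfg@cameraKind == "ideal"
  if (ideal) {
    if (max(fr) > 65535) stop("counts exceed the 16-bit TIFF range")
    offset <- 0; scale <- 65535
    bits <- 16L
  } else {
    offset <- min(fr)
    scale <- max(max(fr) - offset, 1)
    bits <- 32L
  }
  pages <- lapply(seq_len(dim(fr)[1]),
                  function(t) (fr[t, , ] - offset) / scale)
  tiff::writeTIFF(pages, file, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  meta <- list(config = sceneConfigToList(cfg), offset = offset,
               scale = scale, bits = bits,
               origins = as.data.frame(windowOrigins(stack)),
               truth = if (is.null(truePositions(stack))) NULL
                       else as.data.frame(truePositions(stack)),
               hash = canonicalHash(sceneConfigToList(cfg)))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname writeFrameStack
#' @return for the reader, the reconstructed [FrameStack-class]
#' @export
readFrameStack <- function(file) {
  if (grepl("\\.rds$", file, ignore.case = TRUE)) {
    x <- readRDS(file)
    return(frameStack(x$frames, sceneConfigFromList(x$config), x$truth,
                      x$origins))
  }
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  cfg <- sceneConfigFromList(as.list(meta$config))
  pages <- tiff::readTIFF(file, all = TRUE)
  N <- length(pages)
  fr <- array(0, c(N, cfg@P, cfg@P))
  for (t in seq_len(N)) fr[t, , ] <- pages[[t]] * meta$scale + meta$offset
  if (cfg@cameraKind == "ideal") fr <- round(fr)
  truth <- if (is.null(meta$truth)) NULL else
    unname(as.matrix(meta$truth))
  origins <- if (is.null(meta$origins)) NULL else
    unname(as.matrix(meta$origins))
  frameStack(fr, cfg, truth, origins)
}

## ---- trajectories ----

#' Write or read ground-truth frame positions as CSV
#'
#' Columns: `frame`, `t_s`, `x_nm`, `y_nm`.
#'
#' @param trajectory a [Trajectory-class]
#' @param file CSV path
#' @export
writeTrajectoryCsv <- function(trajectory, file) {
  fp <- framePositions(trajectory)
  df <- data.frame(frame = seq_len(nrow(fp)), t_s = trajectory@frameTimes,
                   x_nm = fp[, 1], y_nm = fp[, 2])
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTrajectoryCsv
#' @return for the reader, a data.frame with the four columns
#' @export
readTrajectoryCsv <- function(file) read.csv(file)

## ---- camera maps ----

#' Write or read camera calibration maps
#'
#' `.rds` is lossless; `.tif` stores two pages (variance then gain) with an
#' affine-scale JSON sidecar.
#'
#' @param maps a [CameraMaps-class]
#' @param file path ending in `.rds`, `.tif` or `.tiff`
#' @export
writeCameraMaps <- function(maps, file) {
  if (grepl("\\.rds$", file, ignore.case = TRUE)) {
    saveRDS(list(readoutVariance = readoutVariance(maps),
                 gain = gainMap(maps)), file)
    return(invisible(file))
  }
  rv <- readoutVariance(maps)
  g <- gainMap(maps)
  sc <- c(max(rv), max(g))
  tiff::writeTIFF(list(rv / sc[1], g / sc[2]), file, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(scale = sc), paste0(file, ".json"),
                       digits = NA)
  invisible(file)
}

#' @rdname writeCameraMaps
#' @return for the reader, a [CameraMaps-class]
#' @export
readCameraMaps <- function(file) {
  if (grepl("\\.rds$", file, ignore.case = TRUE)) {
    x <- readRDS(file)
    return(cameraMaps(x$readoutVariance, x$gain))
  }
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file, all = TRUE)
  cameraMaps(pages[[1]] * meta$scale[1], pages[[2]] * meta$scale[2])
}

## ---- run manifests ----

#' Write a run manifest
#'
#' Records what produced a set of outputs: the configuration hash (stable
#' under field reordering), master seed, package version, per-stage file
#' paths and a timestamp.
#'
#' @param configList plain-list configuration (see [sceneConfigToList()])
#' @param seed master seed used
#' @param files named list/character of output paths
#' @param file manifest path (JSON)
#' @export
writeManifest <- function(configList, seed, files, file) {
  jsonlite::write_json(
    list(configHash = canonicalHash(configList), seed = seed,
         version = as.character(utils::packageVersion("sptEM")),
         files = as.list(files),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
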