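#' Read and write movie stacks as multi-page TIFF
#'
#' Movies are stored as 16-bit grayscale multi-page TIFF, with a JSON
#' sidecar (same path with extension \code{.json}) carrying the frame rate,
#' pixel size, seed and a hash of the generating configuration so that
#' calibration survives the round trip.
#'
#' @param stack a [MovieStack-class].
#' @param path TIFF file path.
#' @param config optional [SceneConfig-class] recorded in the sidecar.
#' @return \code{writeMovie} returns \code{path} invisibly;
#'   \code{readMovie} returns a [MovieStack-class].
#' @export
writeMovie <- function(stack, path, config = NULL) {
  stopifnot(is(stack, "MovieStack"))
  fr <- lapply(seq_len(nFrames(stack)), function(f) stack@frames[, , f])
  # tiff expects row-major matrices; transpose so x stays the flow axis
  tiff::writeTIFF(lapply(fr, t), path, bits.per.sample = 16L,
                  compression = "none")
  side <- list(frame_rate_fps = frameRate(stack),
               pixel_size_um = pixelSize(stack))
  if (!is.null(config)) {
    side$seed <- config@seed
    side$config_hash <- sum(utf8ToInt(paste(
      capture.output(str(configToList(config))), collapse = "")))
  }
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMovie
#' @export
readMovie <- function(path) {
  fr <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar))
    stop("calibration sidecar not found: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  arr <- array(0, dim = c(ncol(fr[[1]]), nrow(fr[[1]]), length(fr)))
  for (f in seq_along(fr)) arr[, , f] <- t(fr[[f]])
  new("MovieStack", frames = arr, frame_rate_fps = side$frame_rate_fps,
      pixel_size_um = side$pixel_size_um)
}

#' Read and write ground-truth track tables
#'
#' CSV with header \code{cell_id,parent_id,frame,t_min,x_um,y_um,length_um,
#' theta_deg,pivot_frac,bound}; the per-cell event log is written alongside
#' with suffix \code{_events.csv}.
#'
#' @param truth a [TruthTable-class].
#' @param path CSV path for the tracks table.
#' @return \code{writeTruth} returns \code{path} invisibly;
#'   \code{readTruth} returns the tracks data.frame (with the events table
#'   attached as attribute \code{events} when present).
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "TruthTable"))
  write.csv(truthTracks(truth), path, row.names = FALSE)
  write.csv(truthEvents(truth),
            paste0(tools::file_path_sans_ext(path), "_events.csv"),
            row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  tracks <- read.csv(path)
  evp <- paste0(tools::file_path_sans_ext(path), "_events.csv")
  if (file.exists(evp)) attr(tracks, "events") <- read.csv(evp)
  tracks
}

#' Serialize a scene configuration
#'
#' Converts a [SceneConfig-class] to/from a plain named list so that a
#' configuration round-trips unchanged through YAML or JSON files (the CLI's
#' config format).
#'
#' @param config a [SceneConfig-class].
#' @return \code{configToList}: a named list; \code{configFromList}: a
#'   [SceneConfig-class].
#' @export
configToList <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out$gr_schedule <- as.list(config@gr_schedule@coef)
  out
}

#' @rdname configToList
#' @param x a named list as produced by \code{configToList} (or parsed from
#'   YAML/JSON).
#' @export
configFromList <- function(x) {
  gs <- x$gr_schedule
  x$gr_schedule <- gompertzParams(gs$y0, gs$A, gs$k, gs$t_i)
  x$image_shape <- as.integer(unlist(x$image_shape))
  x$initial_length_um <- as.numeric(unlist(x$initial_length_um))
  x$illumination_coeffs <- unlist(x$illumination_coeffs)
  do.call(sceneConfig, x)
}

#' @importFrom utils capture.output str
NULL
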