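#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))
#' @rdname accessors
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))
#' @rdname accessors
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))
#' @rdname accessors
#' @export
setGeneric("truthTracks", function(x) standardGeneric("truthTracks"))
#' @rdname accessors
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))
#' @rdname accessors
#' @export
setGeneric("sceneSeed", function(x) standardGeneric("sceneSeed"))
#' @rdname gompertz
#' @export
setGeneric("transitionTime", function(object) standardGeneric("transitionTime"))

#' Accessors for BacFlow containers
#'
#' Read-only accessors for the slots of [MovieStack-class],
#' [TruthTable-class], [SegmentationStack-class] and [TrajectorySet-class].
#'
#' @param x a BacFlow container object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("frames", "MovieStack", function(x) x@frames)
#' @rdname accessors
setMethod("frameRate", "MovieStack", function(x) x@frame_rate_fps)
#' @rdname accessors
setMethod("pixelSize", "MovieStack", function(x) x@pixel_size_um)
#' @rdname accessors
setMethod("nFrames", "MovieStack", function(x) dim(x@frames)[3L])
#' @rdname accessors
setMethod("frameRate", "SegmentationStack", function(x) x@frame_rate_fps)
#' @rdname accessors
setMethod("pixelSize", "SegmentationStack", function(x) x@pixel_size_um)
#' @rdname accessors
setMethod("nFrames", "SegmentationStack", function(x) length(x@labels))
#' @rdname accessors
setMethod("observations", "SegmentationStack", function(x) x@observations)
#' @rdname accessors
setMethod("frameLabels", "SegmentationStack", function(x) x@labels)
#' @rdname accessors
setMethod("observations", "TrajectorySet", function(x) x@observations)
#' @rdname accessors
setMethod("lineage", "TrajectorySet", function(x) x@lineage)
#' @rdname accessors
setMethod("truthTracks", "TruthTable", function(x) x@tracks)
#' @rdname accessors
setMethod("truthEvents", "TruthTable", function(x) x@events)
#' @rdname accessors
setMethod("sceneSeed", "SceneConfig", function(x) x@seed)

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("MovieStack: %d frames of %d x %d px, %.4g fps, %.3g um/px\n",
              d[3L], d[1L], d[2L], object@frame_rate_fps,
              object@pixel_size_um))
})

setMethod("show", "TruthTable", function(object) {
  cat(sprintf("TruthTable: %d cells, %d bound-cell frame records\n",
              nrow(object@events), nrow(object@tracks)))
})

setMethod("show", "SegmentationStack", function(object) {
  cat(sprintf("SegmentationStack: %d frames, %d gated observations\n",
              length(object@labels), nrow(object@observations)))
})

setMethod("show", "TrajectorySet", function(object) {
  fate <- table(object@lineage$fate)
  cat(sprintf("TrajectorySet: %d trajectories (%s)\n",
              nrow(object@lineage),
              paste(names(fate), as.integer(fate), sep = "=",
                    collapse = ", ")))
})

setMethod("show", "GompertzFit", function(object) {
  if (object@degenerate) {
    cat("GompertzFit: degenerate (no sigmoidal rise; t_i undefined)\n")
  } else {
    co <- object@coef
    cat(sprintf(
      "GompertzFit: y0=%.4g, A=%.4g, k=%.4g /min, t_i=%.4g min (rsd %.3g)\n",
      co[["y0"]], co[["A"]], co[["k"]], co[["t_i"]], object@residual))
  }
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf(
    "BindingFit: N0=%.4g at t0=%.4g min, T_half=%.4g min, net rate=%.4g /min\n",
    object@N0, object@t0, object@T_half, object@net_rate))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %.4g min at %.4g fps, %d x %d px (%.3g um/px), seed %d\n",
    object@duration_min, object@frame_rate_fps, object@image_shape[1L],
    object@image_shape[2L], object@pixel_size_um, object@seed))
})
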