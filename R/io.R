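# io: plain-text and TIFF interchange. Every CSV starts with a schema
# line "# hemoflow <kind> <major>.<minor>"; readers reject unknown kinds
# and major versions. Image stacks are multi-page grayscale TIFFs with a
# YAML sidecar carrying frame rate and pixel size.

SCHEMA_VERSION <- "1.0"

writeSchemaCSV <- function(df, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hemoflow %s %s", kind, SCHEMA_VERSION), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
}

readSchemaCSV <- function(path, kind, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^# hemoflow (\\S+) (\\d+)\\.(\\d+)", first))[[1]]
  if (length(m)) {
    if (m[2] != kind)
      stop("expected a '", kind, "' file, found '", m[2], "': ", path)
    if (as.integer(m[3]) != as.integer(strsplit(SCHEMA_VERSION, ".",
                                                fixed = TRUE)[[1]][1]))
      stop("unsupported ", kind, " schema major version ", m[3], ": ", path)
  }
  df <- tryCatch(read.csv(path, comment.char = "#"),
                 error = function(e) stop("malformed CSV '", path, "': ",
                                          conditionMessage(e)))
  miss <- setdiff(columns, names(df))
  if (length(miss))
    stop("malformed ", kind, " CSV '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  intCols <- c("particle_id", "frame", "segment_id", "track_id",
               "area_px2", "n_points", "n_trajectories")
  for (cc in setdiff(names(df), "region")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "NA")
    if (length(bad))
      stop("malformed ", kind, " CSV '", path, "': non-numeric value in ",
           "column '", cc, "' at line ", bad[1] + 2L)
    df[[cc]] <- if (cc %in% intCols) as.integer(v) else v
  }
  df
}

#' Write / read ground truth
#'
#' Lossless CSV round trip of a [GroundTruth-class]: particle paths as
#' columns particle_id, frame, x_um, y_um, segment_id, region (plus
#' diameter_um), with frame rate and duration in a YAML sidecar
#' (\code{<path>.yaml}).
#'
#' @param truth a [GroundTruth-class].
#' @param path CSV file path.
#' @return \code{writeGroundTruth} returns \code{path} invisibly;
#'   \code{readGroundTruth} returns the [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
  writeSchemaCSV(particlePaths(truth), path, "ground_truth")
  yaml::write_yaml(list(frame_rate_fps = truth@frameRate,
                        duration_s = truth@duration,
                        schema = SCHEMA_VERSION),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeGroundTruth
#' @param frameRate,duration metadata used when no sidecar file exists.
#' @export
readGroundTruth <- function(path, frameRate = NULL, duration = NULL) {
  df <- readSchemaCSV(path, "ground_truth",
                      c("particle_id", "frame", "x_um", "y_um",
                        "segment_id", "region"))
  df$region <- as.character(df$region)
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    frameRate <- frameRate %||% meta$frame_rate_fps
    duration <- duration %||% meta$duration_s
  }
  if (is.null(frameRate))
    stop("frame rate unknown: no sidecar '", side, "' and none supplied")
  if (is.null(duration))
    duration <- if (nrow(df)) max(df$frame) / frameRate else 0
  new("GroundTruth", paths = df, frameRate = frameRate, duration = duration)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an image stack
#'
#' Multi-page grayscale TIFF (one page per frame, values clipped to
#' [0, 1]) plus a YAML sidecar with frame rate and pixel size.
#'
#' @param stack an [ImageStack-class].
#' @param path TIFF file path.
#' @param bitDepth 8 or 16 bits per sample.
#' @return \code{writeImageStack} returns \code{path} invisibly;
#'   \code{readImageStack} returns the [ImageStack-class].
#' @export
writeImageStack <- function(stack, path, bitDepth = 16L) {
  pages <- lapply(seq_len(nFrames(stack)), function(i)
    pmin(pmax(getFrame(stack, i), 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitDepth))
  yaml::write_yaml(list(frame_rate_fps = frameRate(stack),
                        pixel_size_um_per_px = pixelSize(stack),
                        n_frames = nFrames(stack),
                        schema = SCHEMA_VERSION),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeImageStack
#' @param frameRate,pixelSize metadata used when no sidecar file exists.
#' @export
readImageStack <- function(path, frameRate = NULL, pixelSize = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    frameRate <- frameRate %||% meta$frame_rate_fps
    pixelSize <- pixelSize %||% meta$pixel_size_um_per_px
  }
  if (is.null(frameRate) || is.null(pixelSize))
    stop("frame rate / pixel size unknown: no sidecar '", side,
         "' and none supplied")
  ImageStack(pages, frameRate, pixelSize)
}

#' Write / read per-frame detections
#'
#' CSV schema: frame, x_px, y_px, brightness, area_px2, diameter_px,
#' orientation_rad.
#'
#' @param detections detections data.frame (see [detectParticles()]).
#' @param path CSV file path.
#' @return The path (write) or the detections data.frame (read).
#' @export
writeDetections <- function(detections, path) {
  writeSchemaCSV(detections, path, "detections")
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  readSchemaCSV(path, "detections",
                c("frame", "x_px", "y_px", "brightness", "area_px2",
                  "diameter_px", "orientation_rad"))
}

#' Write / read a TrackSet
#'
#' Trajectories CSV (track_id, frame, x_px, y_px and photometric features)
#' with pixel size, frame rate and stuck-flagged ids in a YAML sidecar.
#'
#' @param trackset a [TrackSet-class].
#' @param path CSV file path.
#' @return The path (write) or the [TrackSet-class] (read).
#' @export
writeTracks <- function(trackset, path) {
  writeSchemaCSV(trackset@tracks, path, "tracks")
  yaml::write_yaml(list(pixel_size_um_per_px = trackset@pixelSize,
                        frame_rate_fps = trackset@frameRate,
                        flagged = as.integer(trackset@flagged),
                        schema = SCHEMA_VERSION),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeTracks
#' @param pixelSize,frameRate metadata used when no sidecar file exists.
#' @export
readTracks <- function(path, pixelSize = NULL, frameRate = NULL) {
  df <- readSchemaCSV(path, "tracks", c("track_id", "frame", "x_px", "y_px"))
  flagged <- integer()
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    pixelSize <- pixelSize %||% meta$pixel_size_um_per_px
    frameRate <- frameRate %||% meta$frame_rate_fps
    flagged <- as.integer(meta$flagged)
  }
  if (is.null(pixelSize) || is.null(frameRate))
    stop("pixel size / frame rate unknown: no sidecar '", side,
         "' and none supplied")
  new("TrackSet", tracks = df, pixelSize = pixelSize, frameRate = frameRate,
      flagged = flagged)
}
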