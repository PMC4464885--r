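# File formats: one 16-bit multi-page TIFF per channel (page = frame)
# plus a JSON metadata sidecar, CSV tables, YAML configuration.
#
# All coordinates in files are 0-based (row, col) with origin top-left;
# all frame windows are half-open [start, end).

TIFF_SCALE <- 65535

#' Construct a plate image stack from channel arrays
#'
#' @param images named list of `nrow x ncol x n_frames` arrays; names
#'   must be the three canonical channels `donor_ex_donor_em`,
#'   `donor_ex_acceptor_em`, `acceptor_ex_acceptor_em`.
#' @param frame_times frame acquisition times in seconds.
#' @param application_frame 0-based ligand-application frame index.
#' @param background_mode `"paper"` or `"agar"`.
#' @return an object of class `plate_stack`.
#' @export
plate_stack <- function(images, frame_times, application_frame,
                        background_mode = "paper") {
  if (!setequal(names(images), CHANNELS))
    stop("images must be named with the canonical channels: ",
         paste(CHANNELS, collapse = ", "))
  images <- images[CHANNELS]
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1 || length(dims[[1]]) != 3)
    stop("all channels must be arrays of identical (nrow, ncol, n_frames)")
  if (dims[[1]][3] != length(frame_times))
    stop("frame_times length must equal the frame count")
  if (application_frame < 0 || application_frame >= dims[[1]][3])
    stop("application_frame outside the frame range")
  if (any(vapply(images, function(a) any(a < 0), logical(1))))
    stop("pixel values must be nonnegative")
  structure(list(images = images, channels = CHANNELS,
                 frame_times = frame_times,
                 application_frame = as.integer(application_frame),
                 background_mode = background_mode),
            class = "plate_stack")
}

stack_paths <- function(dir, run_name) {
  c(stats::setNames(
      file.path(dir, paste0(run_name, "_", CHANNELS, ".tif")), CHANNELS),
    metadata = file.path(dir, paste0(run_name, "_metadata.json")))
}

#' Write a plate image stack to TIFF files plus a metadata sidecar
#'
#' Writes one 16-bit multi-page TIFF per channel
#' (`<run>_<channel>.tif`, one page per time frame) and
#' `<run>_metadata.json` recording channel names, frame times, the
#' application frame and the background mode. Pixel values must be
#' nonnegative integers up to 65535 (camera counts); the round trip
#' through [read_stack()] is then lossless.
#'
#' @param stack a `plate_stack`.
#' @param dir output directory (created if missing).
#' @param run_name file-name prefix.
#' @return named character vector of written paths.
#' @export
write_stack <- function(stack, dir, run_name = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stack_paths(dir, run_name)
  for (ch in CHANNELS) {
    arr <- stack$images[[ch]]
    if (any(arr < 0) || any(arr != round(arr)) || any(arr > TIFF_SCALE))
      stop("stack pixels must be integer counts in [0, ", TIFF_SCALE,
           "] for lossless 16-bit storage; render with quantizing noise ",
           "or round first")
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(f) arr[, , f] / TIFF_SCALE)
    tiff::writeTIFF(pages, paths[[ch]], bits.per.sample = 16L)
  }
  meta <- list(run_name = run_name, channels = as.list(CHANNELS),
               n_frames = dim(stack$images[[1]])[3],
               frame_times = stack$frame_times,
               application_frame = stack$application_frame,
               background_mode = stack$background_mode,
               pixel_scale = TIFF_SCALE)
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       digits = NA)
  paths
}

#' Read a plate image stack written by [write_stack()]
#'
#' @param dir directory holding the files.
#' @param run_name file-name prefix used at write time.
#' @return a `plate_stack`.
#' @export
read_stack <- function(dir, run_name = "run") {
  paths <- stack_paths(dir, run_name)
  if (!file.exists(paths[["metadata"]]))
    stop("metadata sidecar not found: expected file ", paths[["metadata"]])
  meta <- jsonlite::read_json(paths[["metadata"]], simplifyVector = TRUE)
  if (!identical(sort(unlist(meta$channels)), sort(CHANNELS)))
    stop("unknown channel names in metadata: ",
         paste(unlist(meta$channels), collapse = ", "))
  images <- list()
  for (ch in CHANNELS) {
    if (!file.exists(paths[[ch]])) stop("missing channel file ", paths[[ch]])
    pages <- tiff::readTIFF(paths[[ch]], all = TRUE)
    dims <- unique(lapply(pages, dim))
    if (length(dims) != 1) stop("inconsistent page sizes in ", paths[[ch]])
    if (length(pages) != meta$n_frames)
      stop("channel ", ch, " has ", length(pages), " pages, expected ",
           meta$n_frames)
    arr <- array(0, c(dims[[1]], length(pages)))
    for (f in seq_along(pages))
      arr[, , f] <- round(pages[[f]] * meta$pixel_scale)
    images[[ch]] <- arr
  }
  structure(list(images = images, channels = CHANNELS,
                 frame_times = meta$frame_times,
                 application_frame = meta$application_frame,
                 background_mode = meta$background_mode),
            class = "plate_stack")
}

#' Write / read a colony map (label TIFF + records CSV)
#'
#' The label image is stored as a 16-bit TIFF (pixel value = colony id),
#' the records as CSV with 0-based centroid coordinates.
#'
#' @param colony_map a `colony_map`.
#' @param dir output directory.
#' @param run_name file-name prefix.
#' @return named character vector of written paths.
#' @export
write_colony_map <- function(colony_map, dir, run_name = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labels = file.path(dir, paste0(run_name, "_labels.tif")),
             colonies = file.path(dir, paste0(run_name, "_colonies.csv")))
  if (max(colony_map$label_image) > TIFF_SCALE)
    stop("too many labels for 16-bit storage")
  tiff::writeTIFF(colony_map$label_image / TIFF_SCALE, paths[["labels"]],
                  bits.per.sample = 16L)
  write.csv(colony_map$records, paths[["colonies"]], row.names = FALSE)
  paths
}

#' @rdname write_colony_map
#' @param dir directory holding the files.
#' @export
read_colony_map <- function(dir, run_name = "run") {
  paths <- c(labels = file.path(dir, paste0(run_name, "_labels.tif")),
             colonies = file.path(dir, paste0(run_name, "_colonies.csv")))
  for (p in paths) if (!file.exists(p)) stop("missing file ", p)
  lab <- round(tiff::readTIFF(paths[["labels"]]) * TIFF_SCALE)
  storage.mode(lab) <- "integer"
  records <- read.csv(paths[["colonies"]])
  records$touches_border <- as.logical(records$touches_border)
  structure(list(label_image = lab, records = records),
            class = "colony_map")
}

#' Write colony traces as a long-format CSV
#'
#' Columns: `colony_id, frame, time_s, channel, intensity` (frame is
#' 0-based; intensities are background-corrected).
#'
#' @param traces a `colony_traces`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_traces <- function(traces, path) {
  n <- length(traces$colony_ids)
  nt <- length(traces$frame_times)
  chs <- dimnames(traces$intensity)[[2]]
  df <- expand.grid(colony_id = traces$colony_ids,
                    channel = chs, frame = seq_len(nt) - 1L,
                    stringsAsFactors = FALSE)
  df$time_s <- traces$frame_times[df$frame + 1L]
  df$intensity <- as.vector(traces$intensity)
  df <- df[, c("colony_id", "frame", "time_s", "channel", "intensity")]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
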