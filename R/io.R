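#' Write a movie as one multi-page 16-bit TIFF per channel
#'
#' @param movie A `ccp_movie`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix>_<channel>.tif`.
#' @param max_value Intensity mapped to the top of the 16-bit range.
#' @return Named character vector of file paths, invisibly.
#' @export
write_movie_tiff <- function(movie, dir, prefix = "movie",
                             max_value = 65535) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (ch in names(movie$channels)) {
    arr <- movie$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(f)
      pmin(pmax(arr[, , f] / max_value, 0), 1))
    path <- file.path(dir, paste0(prefix, "_", ch, ".tif"))
    tiff::writeTIFF(pages, path, bits.per.sample = 16,
                    compression = "none")
    paths[ch] <- path
  }
  invisible(paths)
}

#' Read a multi-channel movie from per-channel TIFF stacks
#'
#' @param paths Named character vector of TIFF paths (names are channel
#'   labels; first is the master).
#' @param frame_interval Frame interval, seconds.
#' @param pixel_size_um Specimen-plane pixel size, micrometres.
#' @param max_value Intensity of the top of the 16-bit range.
#' @return A `ccp_movie` (without ground truth).
#' @export
read_movie_tiff <- function(paths, frame_interval = 2,
                            pixel_size_um = 0.0645, max_value = 65535) {
  if (is.null(names(paths)))
    names(paths) <- paste0("channel", seq_along(paths))
  channels <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
    for (f in seq_along(pages)) {
      pg <- pages[[f]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]
      arr[, , f] <- pg * max_value
    }
    arr
  })
  structure(list(channels = channels, frame_interval = frame_interval,
                 pixel_size_um = pixel_size_um, spec = NULL, truth = NULL),
            class = "ccp_movie")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  yaml::read_yaml(path)
}

write_csv_quiet <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
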