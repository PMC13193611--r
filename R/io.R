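# File formats: multi-page TIFF movies (16-bit grayscale, one page per
# frame), tracking/annotation CSVs, YAML run configuration.

#' Read a single-cell movie from a multi-page TIFF
#'
#' Page order is frame order. Pixels are returned as floats in `[0, 1]`
#' (16-bit samples are scaled by 1/65535 by the TIFF reader).
#'
#' @param path TIFF file path.
#' @return A list with `movie` (T x H x W array) and `meta` (`n_frames`,
#'   `height`, `width`, `path`).
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("empty TIFF: ", path)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent page shapes in ", path)
  }
  Tn <- length(pages)
  movie <- array(0, dim = c(Tn, dims[1, 1], dims[2, 1]))
  for (t in seq_len(Tn)) movie[t, , ] <- pages[[t]]
  list(movie = movie,
       meta = list(n_frames = Tn, height = dims[1, 1], width = dims[2, 1],
                   path = path))
}

#' Write a movie to a 16-bit multi-page TIFF
#'
#' Intensities must already be in `[0, 1]`; they are stored with fixed
#' 16-bit scaling (values quantized to 1/65535 steps).
#'
#' @param movie T x H x W array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(length(dim(movie)) == 3, min(movie) >= 0, max(movie) <= 1)
  pages <- lapply(seq_len(dim(movie)[1]), function(t) movie[t, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read division-event annotations
#'
#' Expects a CSV with header `cell_id,event_frame` (0-based frame indices).
#' Frames are grouped per cell, sorted, and de-duplicated with a warning.
#'
#' @param path CSV path.
#' @param n_frames Optional named vector of movie lengths per cell used to
#'   populate `n_frames` in the returned timelines (and validate events).
#' @param frame_interval_min Minutes per frame recorded in the timelines.
#' @return Named list of [division_timeline()] objects.
#' @export
read_annotations <- function(path, n_frames = NULL, frame_interval_min = 15) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "event_frame") %in% names(df))) {
    stop("annotation CSV must have columns cell_id,event_frame")
  }
  if (nrow(df) && any(df$event_frame != as.integer(df$event_frame))) {
    stop("non-integer event frames in ", path)
  }
  out <- list()
  for (id in unique(df$cell_id)) {
    fr <- sort(df$event_frame[df$cell_id == id])
    if (anyDuplicated(fr)) {
      warning("duplicate annotation rows for cell ", id, "; de-duplicated")
      fr <- unique(fr)
    }
    nf <- if (!is.null(n_frames) && id %in% names(n_frames)) {
      n_frames[[id]]
    } else if (length(fr)) max(fr) + 1L else 1L
    out[[id]] <- division_timeline(id, fr, nf, frame_interval_min)
  }
  out
}

#' Read tracking centroids
#'
#' CSV with header `cell_id,frame,centroid_row,centroid_col` (0-based frames,
#' 1-based pixel coordinates).
#'
#' @param path CSV path.
#' @return Data frame sorted by cell and frame.
#' @export
read_tracking <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "centroid_row", "centroid_col")
  if (!all(need %in% names(df))) {
    stop("tracking CSV must have columns ", paste(need, collapse = ","))
  }
  df[order(df$cell_id, df$frame), , drop = FALSE]
}

#' Default run configuration
#'
#' The full set of tunables of the pipeline, serializable to YAML. Every
#' artifact written by [run_pipeline()] embeds this configuration and a hash
#' of it, so outputs are reproducible from config + seed alone.
#'
#' @param seed Master seed.
#' @param ... Overrides for any default field (nested lists are merged
#'   shallowly).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    version = 1L,
    seed = as.integer(seed),
    frame_interval_min = 15,
    simulate = list(n_cells = 40L, n_eval = 20L, n_negative = 10L,
                    rls_mean = 24, rls_sd = 4, base_cycle_frames = 6,
                    late_life_slowdown = 2.5, cycle_noise_sd = 1),
    preprocess = list(source_crop_size = 224L, target_size = 64L,
                      half_window = 5L, positive_span = 1L,
                      train_frac = 0.8, padding = "edge-replicate"),
    mae = list(epochs = 30L, mask_ratio = 0.75, batch_size = 32L,
               max_crops = 2000L),
    detector = list(epochs = 20L, batch_size = 32L, threshold = 0.5,
                    encoder_mode = "frozen", n_val_negatives = 30L),
    evaluate = list(tolerance = 1L, max_gap = 5L, sg_window = 11L,
                    sg_polyorder = 2L, pct_bin = 2)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read or write a run configuration as YAML
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = cfg$seed %||% 1L),
                        cfg[setdiff(names(cfg), c("seed", "version"))]))
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  # order-stable structural hash; no digest dependency
  s <- paste(utils::capture.output(utils::str(config, digits.d = 10)),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}
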