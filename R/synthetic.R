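# Synthetic mother-machine movies: a bright elliptical mother cell fixed in a
# trap, buds that emerge at scheduled frames on the channel-facing side, grow
# for a few frames and are flushed away. Every downstream stage (preprocessing,
# pretraining, detection, evaluation) is testable against the known schedules.

#' Division-schedule parameters
#'
#' Statistical description of a mother cell's division timeline: how many
#' divisions she completes (replicative lifespan, RLS), how long a young
#' cell cycle is, and how much cycles lengthen toward the end of life.
#' Defaults emulate wild-type aging at a 15-minute frame interval: a mean RLS
#' of 24 divisions, young cycles of ~6 frames (~90 min), and a 2.5-fold
#' late-life slowdown applied as a linear ramp across the lifespan.
#'
#' @param rls_mean,rls_sd Mean and SD of the per-cell division count.
#' @param base_cycle_frames Expected young-cell inter-division gap, frames.
#' @param late_life_slowdown Multiplicative factor (>= 1) by which the
#'   expected gap grows from the first to the last cycle.
#' @param cycle_noise_sd SD of additive Gaussian noise on each gap, frames.
#' @return A list of class `"schedule_params"`.
#' @export
schedule_params <- function(rls_mean = 24, rls_sd = 4, base_cycle_frames = 6,
                            late_life_slowdown = 2.5, cycle_noise_sd = 1) {
  stopifnot(rls_mean >= 1, rls_sd >= 0, base_cycle_frames >= 1,
            late_life_slowdown >= 1, cycle_noise_sd >= 0)
  structure(as.list(environment()), class = "schedule_params")
}

#' Appearance parameters of one synthetic trapped cell
#'
#' @param cell_id Identifier string.
#' @param image_size Square frame side, pixels.
#' @param mother_center `(row, col)` of the mother body.
#' @param mother_radii `(r_row, r_col)` ellipse radii, pixels.
#' @param mother_intensity,background_intensity Intensities in `[0, 1]`.
#' @param noise_sigma Per-pixel Gaussian noise SD.
#' @param jitter_sigma Per-frame SD of the mother-center displacement, pixels.
#' @param bud_growth_frames Frames from bud emergence to flushing.
#' @param bud_max_radius Bud radius reached just before flushing, pixels;
#'   must be smaller than the smallest mother radius.
#' @param illumination_scale Maximal per-frame multiplicative illumination
#'   shift (1 = constant illumination).
#' @param rng_seed Integer seed for the rendering noise streams.
#' @return A list of class `"synthetic_cell_spec"`.
#' @export
synthetic_cell_spec <- function(cell_id = "cell_001", image_size = 64L,
                                mother_center = c(40, 32),
                                mother_radii = c(10, 8),
                                mother_intensity = 0.85,
                                background_intensity = 0.15,
                                noise_sigma = 0.05, jitter_sigma = 0.5,
                                bud_growth_frames = 4L, bud_max_radius = 5,
                                illumination_scale = 1.0, rng_seed = 1L) {
  stopifnot(bud_max_radius < min(mother_radii),
            bud_growth_frames >= 1, illumination_scale > 0,
            mother_intensity >= 0, mother_intensity <= 1,
            background_intensity >= 0, background_intensity <= 1)
  max_jit <- 3 * jitter_sigma
  if (mother_center[1] - mother_radii[1] - max_jit < 1 ||
      mother_center[1] + mother_radii[1] + max_jit > image_size ||
      mother_center[2] - mother_radii[2] - max_jit < 1 ||
      mother_center[2] + mother_radii[2] + max_jit > image_size) {
    stop("mother ellipse (plus maximal jitter) must fit inside the image")
  }
  structure(as.list(environment()), class = "synthetic_cell_spec")
}

#' Construct a division timeline
#'
#' @param cell_id Identifier.
#' @param event_frames Strictly increasing 0-based frame indices of bud
#'   emergence; the timeline length is the cell's replicative lifespan.
#' @param n_frames Total movie length in frames.
#' @param frame_interval_min Minutes between frames (default 15).
#' @return A list of class `"division_timeline"`.
#' @export
division_timeline <- function(cell_id, event_frames, n_frames,
                              frame_interval_min = 15) {
  event_frames <- as.integer(event_frames)
  if (length(event_frames)) {
    stopifnot(all(diff(event_frames) > 0),
              all(event_frames >= 0), all(event_frames < n_frames))
  }
  structure(list(cell_id = cell_id, event_frames = event_frames,
                 n_frames = as.integer(n_frames),
                 frame_interval_min = frame_interval_min),
            class = "division_timeline")
}

#' @export
print.division_timeline <- function(x, ...) {
  cat(sprintf("<division_timeline> cell %s: RLS %d over %d frames (%g min/frame)\n",
              x$cell_id, length(x$event_frames), x$n_frames,
              x$frame_interval_min))
  if (length(x$event_frames)) {
    cat("  events:", paste(x$event_frames, collapse = " "), "\n")
  }
  invisible(x)
}

#' Sample a division schedule
#'
#' Draws a replicative lifespan from `N(rls_mean, rls_sd)` (rounded, floored
#' at 1) and inter-division gaps whose expectation ramps linearly from
#' `base_cycle_frames` for the first cycle to `base_cycle_frames *
#' late_life_slowdown` for the last, emulating progressive late-life
#' cell-cycle lengthening. Gaps get additive Gaussian noise and are floored
#' at 1 frame; frame 0 is never an event. Deterministic given `seed`.
#'
#' @param params A [schedule_params()] object.
#' @param seed Integer seed.
#' @param cell_id Identifier for the resulting timeline.
#' @param tail_frames Event-free frames appended after the last division.
#' @return A [division_timeline()].
#' @export
sample_division_schedule <- function(params, seed, cell_id = "cell",
                                     tail_frames = 10L) {
  stopifnot(inherits(params, "schedule_params"))
  rls <- gaps <- NULL
  withr::with_seed(seed, {
    rls <- max(1L, as.integer(round(stats::rnorm(1, params$rls_mean, params$rls_sd))))
    ramp <- if (rls > 1) {
      1 + (params$late_life_slowdown - 1) * (seq_len(rls) - 1) / (rls - 1)
    } else rep(1, rls)
    mu <- params$base_cycle_frames * ramp
    gaps <- pmax(1L, as.integer(round(mu + stats::rnorm(rls, 0, params$cycle_noise_sd))))
  })
  if (any(gaps < 1)) stop("schedule produced a zero-length cell cycle")
  events <- cumsum(gaps)
  division_timeline(cell_id, events, n_frames = events[rls] + tail_frames + 1L)
}

.ellipse_mask <- function(size, center, radii) {
  r <- matrix(seq_len(size), size, size)
  c <- t(r)
  ((r - center[1]) / radii[1])^2 + ((c - center[2]) / radii[2])^2 <= 1
}

.disk_mask <- function(size, center, radius) {
  r <- matrix(seq_len(size), size, size)
  c <- t(r)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

#' Render a synthetic single-cell movie
#'
#' Draws the mother body in every frame (with per-frame center jitter and
#' illumination shifts), and at each scheduled division a bud disk emerging
#' on the channel-facing side of the mother, growing linearly to
#' `bud_max_radius` over `bud_growth_frames` frames before being flushed
#' away. Per-pixel Gaussian noise is added and intensities are clipped to
#' `[0, 1]`. Deterministic given `spec$rng_seed`.
#'
#' @param spec A [synthetic_cell_spec()].
#' @param timeline A [division_timeline()].
#' @param overlap One of `"error"`, `"truncate"`: what to do when consecutive
#'   events are closer than `bud_growth_frames` (a new bud truncates the
#'   previous episode under `"truncate"`).
#' @return A list with `movie` (T x H x W array in `[0, 1]`), `bud_pixel_log`
#'   (T x H x W logical array of rendered bud pixels), `timeline`, `spec`.
#' @export
render_cell_movie <- function(spec, timeline, overlap = c("truncate", "error")) {
  stopifnot(inherits(spec, "synthetic_cell_spec"),
            inherits(timeline, "division_timeline"))
  overlap <- match.arg(overlap)
  Tn <- timeline$n_frames
  stopifnot(Tn >= 1)
  ev <- timeline$event_frames
  if (length(ev) > 1 && any(diff(ev) < spec$bud_growth_frames) &&
      overlap == "error") {
    stop("overlapping bud episodes (inter-event gap < bud_growth_frames)")
  }
  size <- spec$image_size
  movie <- array(0, dim = c(Tn, size, size))
  budlog <- array(FALSE, dim = c(Tn, size, size))

  # owner of each frame's bud episode: the most recent event within growth
  # range; a new event truncates the previous episode
  bud_owner <- rep(NA_integer_, Tn)
  for (e in ev) {
    span <- e:min(Tn - 1L, e + spec$bud_growth_frames - 1L)
    bud_owner[span + 1L] <- e
  }

  withr::with_seed(spec$rng_seed, {
    jit <- matrix(stats::rnorm(2 * Tn, 0, spec$jitter_sigma), Tn, 2)
    jit <- pmin(pmax(jit, -3 * spec$jitter_sigma), 3 * spec$jitter_sigma)
    illum <- if (spec$illumination_scale == 1) rep(1, Tn) else {
      exp(stats::runif(Tn, -log(spec$illumination_scale),
                       log(spec$illumination_scale)))
    }
    ang <- stats::rnorm(length(ev), -pi / 2, pi / 18)  # distal side, small jitter
    names(ang) <- as.character(ev)
    noise <- if (spec$noise_sigma > 0) {
      stats::rnorm(Tn * size * size, 0, spec$noise_sigma)
    } else numeric(Tn * size * size)
    dim(noise) <- c(Tn, size, size)

    for (t in seq_len(Tn) - 1L) {
      center <- spec$mother_center + jit[t + 1L, ]
      frame <- matrix(spec$background_intensity, size, size)
      frame[.ellipse_mask(size, center, spec$mother_radii)] <- spec$mother_intensity
      own <- bud_owner[t + 1L]
      if (!is.na(own)) {
        age <- t - own + 1L  # 1..bud_growth_frames
        brad <- spec$bud_max_radius * age / spec$bud_growth_frames
        a <- ang[[as.character(own)]]
        # bud center sits just outside the mother boundary along direction a
        edge <- 1 / sqrt((cos(a) / spec$mother_radii[1])^2 +
                         (sin(a) / spec$mother_radii[2])^2)
        bud_center <- center + (edge + brad) * c(cos(a), sin(a))
        bmask <- .disk_mask(size, bud_center, brad)
        frame[bmask] <- spec$mother_intensity
        budlog[t + 1L, , ][bmask] <- TRUE
      }
      frame <- frame * illum[t + 1L] + noise[t + 1L, , ]
      movie[t + 1L, , ] <- pmin(pmax(frame, 0), 1)
    }
  })
  list(movie = movie, bud_pixel_log = budlog, timeline = timeline, spec = spec)
}

#' Simulate a cohort of mother cells
#'
#' @param n_cells Number of cells.
#' @param params A [schedule_params()].
#' @param spec_template A [synthetic_cell_spec()] reused for every cell
#'   (per-cell seeds and ids are derived from `seed`).
#' @param seed Integer master seed.
#' @return List of [render_cell_movie()] results, one per cell.
#' @export
simulate_cells <- function(n_cells, params = schedule_params(),
                           spec_template = synthetic_cell_spec(),
                           seed = 1L) {
  lapply(seq_len(n_cells), function(i) {
    id <- sprintf("cell_%03d", i)
    tl <- sample_division_schedule(params, seed = seed * 10000L + i, cell_id = id)
    sp <- spec_template
    sp$cell_id <- id
    sp$rng_seed <- seed * 10000L + 5000L + i
    render_cell_movie(sp, tl)
  })
}

#' Write a synthetic fixture dataset to disk
#'
#' One 16-bit multi-page TIFF per cell (one page per frame), a pooled
#' annotation CSV (`cell_id,event_frame`, 0-based frames), and a manifest CSV
#' (`cell_id,tiff_path,n_frames,rls`).
#'
#' @param n_cells Number of cells to simulate.
#' @param params,spec_template,seed Passed to [simulate_cells()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The manifest as a data frame (invisibly also written to disk).
#' @export
write_fixture_dataset <- function(n_cells, params = schedule_params(),
                                  spec_template = synthetic_cell_spec(),
                                  out_dir, seed = 1L, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stop("out_dir exists and is not empty; pass overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- simulate_cells(n_cells, params, spec_template, seed)
  ann <- data.frame(cell_id = character(0), event_frame = integer(0))
  man <- data.frame(cell_id = character(0), tiff_path = character(0),
                    n_frames = integer(0), rls = integer(0))
  for (cl in cells) {
    id <- cl$timeline$cell_id
    path <- file.path(out_dir, paste0(id, ".tif"))
    write_movie(cl$movie, path)
    if (length(cl$timeline$event_frames)) {
      ann <- rbind(ann, data.frame(cell_id = id,
                                   event_frame = cl$timeline$event_frames))
    }
    man <- rbind(man, data.frame(cell_id = id, tiff_path = path,
                                 n_frames = cl$timeline$n_frames,
                                 rls = length(cl$timeline$event_frames)))
  }
  utils::write.csv(ann, file.path(out_dir, "annotations.csv"), row.names = FALSE)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  man
}
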