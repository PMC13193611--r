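# Synthetic movie generator: schedules, rendering, fixture round trips.

test_that("noiseless arithmetic schedules are exact and slowdown ramps gaps", {
  p0 <- schedule_params(rls_mean = 3, rls_sd = 0, base_cycle_frames = 10,
                        late_life_slowdown = 1, cycle_noise_sd = 0)
  tl <- sample_division_schedule(p0, seed = 7)
  expect_identical(tl$event_frames, c(10L, 20L, 30L))
  expect_equal(compute_rls(tl), 3)

  p2 <- schedule_params(rls_mean = 3, rls_sd = 0, base_cycle_frames = 10,
                        late_life_slowdown = 2, cycle_noise_sd = 0)
  tl2 <- sample_division_schedule(p2, seed = 7)
  gaps <- diff(c(0L, tl2$event_frames))
  expect_true(all(diff(gaps) > 0))
  expect_gte(gaps[length(gaps)], gaps[1])
})

test_that("schedules are deterministic in the seed and vary across seeds", {
  p <- schedule_params(rls_mean = 20)
  a <- sample_division_schedule(p, seed = 11)
  b <- sample_division_schedule(p, seed = 11)
  expect_identical(a$event_frames, b$event_frames)
  c_ <- sample_division_schedule(p, seed = 12)
  expect_false(identical(a$event_frames, c_$event_frames))
  # frame 0 is never an event; events strictly increasing and in range
  for (s in 1:20) {
    tl <- sample_division_schedule(p, seed = s)
    expect_true(all(tl$event_frames >= 1))
    expect_true(all(diff(tl$event_frames) > 0))
    expect_true(all(tl$event_frames < tl$n_frames))
  }
})

test_that("sampled lifespans concentrate around the configured mean", {
  p <- schedule_params(rls_mean = 24, rls_sd = 4)
  rls <- vapply(1:200, function(s) {
    compute_rls(sample_division_schedule(p, seed = 1000 + s))
  }, integer(1))
  se <- sd(rls) / sqrt(length(rls))
  expect_lt(abs(mean(rls) - 24), 3 * se)
})

test_that("rendering is deterministic and bud episodes track the schedule", {
  spec <- synthetic_cell_spec(rng_seed = 5)
  tl <- division_timeline("c", c(8L, 20L), n_frames = 30L)
  a <- render_cell_movie(spec, tl)
  b <- render_cell_movie(spec, tl)
  expect_identical(a$movie, b$movie)
  expect_true(all(a$movie >= 0 & a$movie <= 1))

  # bud pixels present exactly on frames e .. e + growth - 1
  budded <- which(apply(a$bud_pixel_log, 1, any)) - 1L
  expected <- sort(c(8:11, 20:23))
  expect_identical(budded, expected)

  # event-free timeline -> empty bud log, mother still present everywhere
  tl0 <- division_timeline("c0", integer(0), n_frames = 10L)
  z <- render_cell_movie(spec, tl0)
  expect_false(any(z$bud_pixel_log))
  expect_true(all(apply(z$movie, 1, max) > 0.5))
})

test_that("overlapping bud episodes are truncated or rejected as configured", {
  spec <- synthetic_cell_spec(rng_seed = 2, bud_growth_frames = 6L)
  tl <- division_timeline("c", c(5L, 8L), n_frames = 20L)
  expect_error(render_cell_movie(spec, tl, overlap = "error"), "overlap")
  r <- render_cell_movie(spec, tl, overlap = "truncate")
  # one bud episode per event even though they overlap
  budded <- which(apply(r$bud_pixel_log, 1, any)) - 1L
  expect_identical(budded, 5:13)
})

test_that("invalid cell specs are rejected", {
  expect_error(synthetic_cell_spec(bud_max_radius = 9, mother_radii = c(10, 8)))
  expect_error(synthetic_cell_spec(mother_center = c(5, 32)), "fit inside")
})

test_that("fixture datasets round-trip through the readers", {
  dir <- withr::local_tempdir()
  man <- write_fixture_dataset(5, schedule_params(rls_mean = 5, rls_sd = 1),
                               out_dir = dir, seed = 3)
  expect_equal(nrow(man), 5)
  expect_true(all(file.exists(man$tiff_path)))

  ann <- read.csv(file.path(dir, "annotations.csv"))
  counts <- table(ann$cell_id)
  expect_equal(as.integer(counts[man$cell_id]), man$rls)

  # page t equals rendered frame t up to 16-bit quantization
  cells <- simulate_cells(5, schedule_params(rls_mean = 5, rls_sd = 1), seed = 3)
  rd <- read_movie(man$tiff_path[2])
  expect_equal(rd$meta$n_frames, man$n_frames[2])
  expect_lt(max(abs(rd$movie - cells[[2]]$movie)), 1 / 65535 + 1e-9)

  # deterministic manifests; refusal to clobber
  expect_error(write_fixture_dataset(5, out_dir = dir, seed = 3), "overwrite")
  dir2 <- withr::local_tempdir()
  man2 <- write_fixture_dataset(5, schedule_params(rls_mean = 5, rls_sd = 1),
                                out_dir = dir2, seed = 3)
  expect_identical(man$rls, man2$rls)
  tls <- read_annotations(file.path(dir, "annotations.csv"))
  expect_identical(sort(names(tls)), sort(unique(ann$cell_id)))
  expect_identical(tls[[man$cell_id[1]]]$event_frames,
                   sort(ann$event_frame[ann$cell_id == man$cell_id[1]]))
})
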