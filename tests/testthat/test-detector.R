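# Temporal detector mechanics: softmax head, balanced batching, embedding
# determinism, window handling.

tiny_mae <- function(seed = 1) {
  # untrained tiny model: sufficient for mechanical properties
  cfg <- mae_config(image_size = 16L, patch_size = 4L, encoder_dim = 16L,
                    encoder_depth = 1L, encoder_heads = 2L, decoder_dim = 8L,
                    decoder_depth = 1L, decoder_heads = 2L, epochs = 1L,
                    seed = seed)
  p <- withr::with_seed(seed, budcall:::init_mae_params(cfg))
  structure(list(params = p, final_params = p, ema_params = p, config = cfg,
                 norm_stats = list(mean = 0.5, sd = 0.25),
                 log = data.frame(), best_checkpoint = 1L),
            class = "bud_mae")
}

test_that("classify_stack emits a normalized probability pair for the center frame", {
  mae <- tiny_mae()
  cfg <- detector_config(temporal_dim = 16L, temporal_heads = 2L)
  tp <- withr::with_seed(2, budcall:::init_temporal_params(16L, cfg))
  E <- matrix(rnorm(11 * 16), 11, 16)
  pr <- classify_stack(tp, E, cfg)
  expect_named(pr, c("non_budding", "budding"))
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_identical(pr, classify_stack(tp, E, cfg))  # deterministic
  expect_error(classify_stack(tp, E[1:9, ], cfg), "window")

  # temporal embeddings make the model order-aware even at initialization
  pr_rev <- classify_stack(tp, E[11:1, ], cfg)
  expect_false(isTRUE(all.equal(pr, pr_rev)))
})

test_that("frame embeddings are deterministic, sized, and input-sensitive", {
  mae <- tiny_mae()
  crop <- matrix(rnorm(16 * 16), 16, 16)
  e1 <- embed_frame(mae, crop)
  expect_length(e1, 16)
  expect_identical(e1, embed_frame(mae, crop))
  crop2 <- crop
  crop2[4:8, 4:8] <- crop2[4:8, 4:8] + 2
  expect_false(isTRUE(all.equal(e1, embed_frame(mae, crop2))))
})

test_that("encoder latents cover every visible token plus CLS", {
  mae <- tiny_mae()
  crop <- matrix(rnorm(16 * 16), 16, 16)
  lat_full <- mae_encode(mae, crop)          # all 16 patches + CLS
  expect_equal(dim(lat_full), c(17, 16))
  lat_masked <- mae_encode(mae, crop, keep = c(0L, 3L, 7L, 9L))
  expect_equal(dim(lat_masked), c(5, 16))
  expect_true(all(is.finite(lat_masked)))
})

test_that("balanced batches are exactly half positive at every step", {
  labels <- c(rep(1L, 6), rep(0L, 100))
  batches <- balanced_batches(labels, 8, seed = 3)
  for (b in batches) {
    expect_length(b, 8)
    expect_equal(sum(labels[b]), 4)
  }
  # every majority-class sample appears at least once per epoch
  negs <- unlist(batches)
  expect_true(all(which(labels == 0L) %in% negs))
  # determinism
  expect_identical(batches, balanced_batches(labels, 8, seed = 3))
  expect_false(identical(batches, balanced_batches(labels, 8, seed = 4)))
  expect_error(balanced_batches(rep(0L, 10), 8), "each class")
  expect_error(balanced_batches(labels, 7))
})

test_that("predict_timeline returns one probability per frame", {
  mae <- tiny_mae()
  cfg <- detector_config(temporal_dim = 16L, temporal_heads = 2L)
  det <- untrained_baseline(mae, cfg, seed = 5)
  crops <- array(rnorm(30 * 16 * 16), dim = c(30, 16, 16))
  pr <- predict_timeline(det, crops)
  expect_length(pr, 30)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_identical(pr, predict_timeline(det, crops))
  expect_error(predict_timeline(det, array(0, c(0, 16, 16))), "empty")

  # baseline predictions survive post-processing invariants
  tl <- collapse_runs(binarize(pr, 0.5))
  expect_true(all(diff(tl$event_frames) > 0))
  expect_equal(compute_rls(tl), length(tl$event_frames))

  # identical baseline for identical seeds
  det2 <- untrained_baseline(mae, cfg, seed = 5)
  expect_identical(predict_timeline(det2, crops), pr)
})

test_that("predict.bud_detector applies stored normalization to raw movies", {
  mae <- tiny_mae()
  cfg <- detector_config(temporal_dim = 16L, temporal_heads = 2L)
  det <- untrained_baseline(mae, cfg, seed = 5)
  raw <- array(runif(20 * 16 * 16), dim = c(20, 16, 16))
  norm <- budcall:::movie_to_crops(raw, det$norm_stats, 16L)
  expect_equal(predict(det, raw, normalized = FALSE),
               predict(det, norm))
  tl <- predict(det, norm, type = "timeline")
  expect_s3_class(tl, "division_timeline")
})
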