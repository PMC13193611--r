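# MAE building blocks: patch grids, masking plans, shuffle/unshuffle,
# reconstruction loss, learning-rate schedule, EMA.

test_that("patchify and unpatchify are exact inverses", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  seq <- patchify(img, 8)
  expect_equal(dim(seq$patches), c(64, 64))
  expect_identical(unpatchify(seq), img)

  const <- matrix(3.2, 16, 16)
  sc <- patchify(const, 4)
  expect_true(all(apply(sc$patches, 1, function(r) all(r == sc$patches[1, ]))))

  for (p in c(2, 4, 16, 32)) {
    x <- matrix(rnorm(64 * 64), 64, 64)
    expect_identical(unpatchify(patchify(x, p)), x)
  }
  expect_error(patchify(matrix(0, 63, 64), 8), "divisible")
})

test_that("random masking keeps the exact visible count and stores a valid restore order", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  seq <- patchify(img, 8)
  set.seed(1)
  m <- random_masking(seq, 0.75)
  expect_equal(m$plan$n_visible, 16)
  expect_equal(nrow(m$visible), 16)
  expect_length(m$plan$masked, 48)
  # shuffle then restore is the identity permutation
  expect_identical(m$plan$shuffle_perm[m$plan$restore_indices + 1L],
                   0:(64 - 1))

  m0 <- random_masking(seq, 0)
  expect_equal(m0$plan$n_visible, 64)
  expect_length(m0$plan$masked, 0)

  for (P in c(9, 16, 64)) {
    sq <- patchify(matrix(0, sqrt(P) * 4, sqrt(P) * 4), 4)
    for (ratio in c(0, 0.3, 0.5, 0.9)) {
      pl <- random_masking(sq, ratio)$plan
      expect_equal(pl$n_visible, P - floor(ratio * P))
      expect_identical(sort(c(pl$keep, pl$masked)), 0:(P - 1))
      expect_identical(pl$shuffle_perm[pl$restore_indices + 1L], 0:(P - 1))
    }
  }
})

test_that("each patch is masked at the nominal frequency", {
  seq <- patchify(matrix(0, 32, 32), 4)  # P = 64
  P <- 64
  set.seed(42)
  n_draws <- 10000
  hits <- numeric(P)
  for (i in seq_len(n_draws)) {
    masked <- random_masking(seq, 0.75)$plan$masked + 1L
    hits[masked] <- hits[masked] + 1
  }
  freq <- hits / n_draws
  se <- sqrt(0.75 * 0.25 / n_draws)
  expect_true(all(abs(freq - 0.75) < 3 * se + 0.005))
})

test_that("decoded tokens unshuffle to their original grid positions (stub decoder)", {
  # shuffle -> drop masked -> append mask tokens -> unshuffle, with an
  # identity decoder: every visible patch must land at its original index
  # and every masked slot must contain the mask token
  set.seed(3)
  img <- matrix(rnorm(64 * 64), 64, 64)
  seq <- patchify(img, 8)
  P <- nrow(seq$patches)
  m <- random_masking(seq, 0.75)
  shuffled <- seq$patches[m$plan$shuffle_perm + 1L, , drop = FALSE]
  visible <- shuffled[seq_len(m$plan$n_visible), , drop = FALSE]
  mask_token <- rep(-999, ncol(seq$patches))
  decoded <- rbind(visible,
                   matrix(mask_token, P - m$plan$n_visible, ncol(seq$patches),
                          byrow = TRUE))
  restored <- decoded[m$plan$restore_indices + 1L, , drop = FALSE]
  vis_idx <- m$plan$shuffle_perm[seq_len(m$plan$n_visible)] + 1L
  for (i in seq_len(P)) {
    if (i %in% vis_idx) {
      expect_identical(restored[i, ], seq$patches[i, ])
    } else {
      expect_identical(restored[i, ], mask_token)
    }
  }
})

test_that("reconstruction loss scores masked patches only (or all on request)", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  seq <- patchify(img, 8)
  set.seed(2)
  plan <- random_masking(seq, 0.75)$plan

  expect_equal(reconstruction_loss(img, img, plan, 8), 0)
  expect_equal(reconstruction_loss(img + 1, img, plan, 8), 1.0)

  # corrupt a visible patch only: masked-only loss stays zero
  vis_patch <- plan$keep[1]
  corrupted <- patchify(img, 8)
  corrupted$patches[vis_patch + 1L, ] <- corrupted$patches[vis_patch + 1L, ] + 5
  cimg <- unpatchify(corrupted)
  expect_equal(reconstruction_loss(cimg, img, plan, 8), 0)
  expect_gt(reconstruction_loss(cimg, img, plan, 8, loss_on = "all"), 0)

  # invariant to the order the mask was drawn in: only the masked set matters
  plan2 <- plan
  plan2$masked <- rev(plan$masked)
  expect_equal(reconstruction_loss(cimg, img, plan2, 8),
               reconstruction_loss(cimg, img, plan, 8))
  expect_error(reconstruction_loss(matrix(0, 8, 8), img, plan, 8), "mismatch")
})

test_that("the learning-rate schedule hits its closed-form boundary values", {
  cfg <- list(base_lr = 1e-3, warmup_steps = 100, cycle_steps = 400,
              min_lr = 0)
  expect_equal(lr_at(0, cfg), 0)
  expect_equal(lr_at(50, cfg), 5e-4)
  expect_equal(lr_at(100, cfg), 1e-3)                 # warmup end = cosine peak
  expect_equal(lr_at(100 + 200, cfg), 5e-4)           # half cycle, min_lr = 0
  expect_equal(lr_at(100 + 400, cfg), 1e-3)           # restart boundary
  expect_equal(lr_at(100 + 3 * 400, cfg), 1e-3)
  cfg$min_lr <- 1e-5
  tc <- 123
  expect_equal(lr_at(100 + 400 + tc, cfg),
               1e-5 + 0.5 * (1e-3 - 1e-5) * (1 + cos(pi * tc / 400)))
})

test_that("EMA updates follow the geometric closed form", {
  w0 <- list(a = matrix(2, 2, 2), b = rep(-1, 3))
  cur <- list(a = matrix(5, 2, 2), b = rep(4, 3))
  expect_equal(ema_update(w0, cur, 0), cur)
  expect_equal(ema_update(w0, cur, 1), w0)

  decay <- 0.9
  ema <- w0
  for (k in 1:7) ema <- ema_update(ema, cur, decay)
  expect_equal(ema$a, cur$a + decay^7 * (w0$a - cur$a), tolerance = 1e-12)
  expect_equal(ema$b, cur$b + decay^7 * (w0$b - cur$b), tolerance = 1e-12)
  expect_error(ema_update(w0, list(a = matrix(1, 3, 3), b = rep(0, 3)), 0.5))
})

test_that("sinusoidal temporal table matches its definition", {
  tab <- temporal_positional_table(11, 64)
  expect_equal(dim(tab), c(11, 64))
  expect_true(all(tab >= -1 & tab <= 1))
  expect_equal(tab[1, seq(1, 63, by = 2)], rep(0, 32))  # sin(0)
  expect_equal(tab[1, seq(2, 64, by = 2)], rep(1, 32))  # cos(0)
  expect_equal(tab[4, 1], sin(3))
  expect_equal(tab[4, 2], cos(3))
  i <- 5  # 0-based pair index
  expect_equal(tab[3, 2 * i + 1], sin(2 / 10000^(2 * i / 64)))
  expect_equal(nrow(unique(round(tab, 12))), 11)  # all rows distinct
  expect_error(temporal_positional_table(11, 63), "even")
})
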