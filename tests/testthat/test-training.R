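# Training machinery: analytic gradients vs finite differences, gradient
# accumulation equivalence, optimizer/checkpoint bookkeeping, encoder modes.

# central finite differences against the analytic gradients; the core runs in
# single precision, so only components whose magnitude clears the fp32
# difference-quotient noise floor are compared, at a matching tolerance
fd_check <- function(f, params, grads, n_per = 3, h = 1e-2, tol = 3e-2,
                     gate = 2e-3) {
  set.seed(99)
  n_checked <- 0
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(n_per, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + h
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - h
      fd <- (f(p2) - f(p3)) / (2 * h)
      an <- grads[[nm]][i]
      if (abs(fd) + abs(an) > gate) {
        expect_lt(abs(fd - an) / (abs(fd) + abs(an)), tol)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 10)  # the check must actually exercise the model
}

test_that("MAE analytic gradients match finite differences", {
  cfg <- mae_config(image_size = 8L, patch_size = 4L, encoder_dim = 8L,
                    encoder_depth = 2L, encoder_heads = 2L, decoder_dim = 6L,
                    decoder_depth = 1L, decoder_heads = 2L, mask_ratio = 0.5)
  set.seed(21)
  params <- budcall:::init_mae_params(cfg)
  B <- 3L; P <- cfg$n_patches
  Xp <- array(rnorm(P * 16 * B), dim = c(P, 16, B))
  keep <- budcall:::draw_keep(P, 0.5, B)
  f <- function(pl) {
    budcall:::cpp_mae_batch(pl, Xp, keep, 2L, 1L, 2L, 2L,
                            FALSE, FALSE, FALSE)$loss
  }
  r <- budcall:::cpp_mae_batch(params, Xp, keep, 2L, 1L, 2L, 2L,
                               FALSE, TRUE, FALSE)
  fd_check(f, params, r$grads)
})

test_that("temporal-transformer gradients match finite differences", {
  tcfg <- detector_config(temporal_dim = 8L, temporal_depth = 2L,
                          temporal_heads = 2L)
  set.seed(22)
  tp <- budcall:::init_temporal_params(6L, tcfg)
  E <- array(rnorm(5 * 6 * 4), dim = c(5, 6, 4))
  tab <- temporal_positional_table(5, 8)
  y <- c(0L, 1L, 1L, 0L)
  f <- function(pl) {
    budcall:::cpp_temporal_batch(pl, E, tab, y, 2L, 2L, FALSE, FALSE)$loss
  }
  r <- budcall:::cpp_temporal_batch(tp, E, tab, y, 2L, 2L, TRUE, FALSE)
  fd_check(f, tp, r$grads, n_per = 4, gate = 3e-4, tol = 5e-2)
})

test_that("accumulated micro-batch gradients equal the single large batch", {
  cfg <- mae_config(image_size = 8L, patch_size = 4L, encoder_dim = 8L,
                    encoder_depth = 1L, encoder_heads = 2L, decoder_dim = 6L,
                    decoder_depth = 1L, decoder_heads = 2L, mask_ratio = 0.5)
  set.seed(23)
  params <- budcall:::init_mae_params(cfg)
  P <- cfg$n_patches
  B <- 8L; k <- 4L
  Xp <- array(rnorm(P * 16 * B), dim = c(P, 16, B))
  keep <- budcall:::draw_keep(P, 0.5, B)
  run <- function(idx) {
    budcall:::cpp_mae_batch(params, Xp[, , idx, drop = FALSE],
                            keep[, idx, drop = FALSE], 1L, 1L, 2L, 2L,
                            FALSE, TRUE, FALSE)
  }
  big <- run(1:B)
  acc <- NULL
  for (j in seq_len(k)) {
    idx <- ((j - 1) * (B / k) + 1):(j * (B / k))
    r <- run(idx)
    g <- budcall:::conform_grads(params, r$grads)
    acc <- if (is.null(acc)) lapply(g, `/`, k) else {
      budcall:::grads_add(acc, g, 1 / k)
    }
  }
  bigg <- budcall:::conform_grads(params, big$grads)
  for (nm in names(params)) {
    expect_equal(acc[[nm]], bigg[[nm]], tolerance = 1e-4)
  }
})

test_that("a short MAE run reduces reconstruction loss and logs its best epoch", {
  set.seed(24)
  cells <- simulate_cells(4, schedule_params(rls_mean = 6, rls_sd = 1), seed = 41)
  stats <- normalization_stats(cells[[1]]$movie)
  crops <- lapply(cells, function(x) budcall:::movie_to_crops(x$movie, stats))
  tr <- budcall:::abind3(crops[[1]], crops[[2]], crops[[3]])
  va <- crops[[4]]
  cfg <- mae_config(epochs = 3L, warmup_steps = 10L, cycle_steps = 60L,
                    seed = 7L)
  mae <- mae_pretrain(tr, va, cfg, norm_stats = stats)
  expect_s3_class(mae, "bud_mae")
  expect_equal(nrow(mae$log), 3)
  expect_lt(mae$log$val_loss[3], mae$log$val_loss[1])
  expect_equal(mae$best_checkpoint, which.min(mae$log$val_loss))

  # identical seed, identical training trajectory
  mae2 <- mae_pretrain(tr, va, cfg, norm_stats = stats)
  expect_equal(mae$log, mae2$log)
  expect_equal(mae$params, mae2$params)

  # reconstruction plumbing: output shaped, finite, loss consistent
  img <- va[1, , ]
  set.seed(5)
  rec <- mae_reconstruct(mae, img)
  expect_equal(dim(rec$recon), dim(img))
  expect_true(all(is.finite(rec$recon)))
  expect_equal(rec$loss,
               reconstruction_loss(rec$recon, img, rec$plan,
                                   mae$config$patch_size),
               tolerance = 1e-5)
  expect_error(mae_pretrain(tr, budcall:::abind3(va)[0, , , drop = FALSE], cfg),
               "empty")
})

test_that("both encoder modes train and the finetune mode moves encoder weights", {
  set.seed(25)
  cells <- simulate_cells(4, schedule_params(rls_mean = 5, rls_sd = 1,
                                             base_cycle_frames = 5),
                          seed = 52)
  stats <- normalization_stats(cells[[1]]$movie)
  ncell <- lapply(cells, function(x) {
    list(cell_id = x$timeline$cell_id,
         crops = budcall:::movie_to_crops(x$movie, stats),
         timeline = x$timeline)
  })
  # shrink the problem: trim movies to 40 frames (events inside)
  ncell <- lapply(ncell, function(cl) {
    keep <- cl$timeline$event_frames < 35L
    cl$crops <- cl$crops[1:40, , , drop = FALSE]
    cl$timeline <- division_timeline(cl$cell_id,
                                     cl$timeline$event_frames[keep], 40L)
    cl
  })
  mcfg <- mae_config(encoder_dim = 16L, encoder_depth = 1L, encoder_heads = 2L,
                     decoder_dim = 8L, decoder_depth = 1L, decoder_heads = 2L,
                     epochs = 1L, seed = 8L)
  tr_crops <- budcall:::abind3(ncell[[1]]$crops, ncell[[2]]$crops)
  mae <- mae_pretrain(tr_crops, ncell[[3]]$crops, mcfg, norm_stats = stats)

  for (mode in c("frozen", "finetune")) {
    dcfg <- detector_config(temporal_dim = 16L, temporal_heads = 2L,
                            epochs = 1L, batch_size = 8L,
                            encoder_mode = mode, seed = 9L)
    det <- train_detector(ncell[1:2], ncell[3:4], mae, dcfg)
    expect_s3_class(det, "bud_detector")
    expect_equal(det$config$encoder_mode, mode)
    expect_equal(nrow(det$log), 1)
    moved <- !isTRUE(all.equal(det$encoder_params$pe_W, mae$params$pe_W))
    expect_equal(moved, mode == "finetune")
  }

  # cell-exclusive split is enforced
  expect_error(train_detector(ncell[1:2], ncell[2:3], mae,
                              detector_config(temporal_dim = 16L,
                                              temporal_heads = 2L)),
               "cell-exclusive")
})

test_that("adam with decoupled weight decay shrinks unused weights", {
  params <- list(W = matrix(1, 2, 2), b = rep(1, 2))
  st <- budcall:::adam_init(params)
  zero_g <- list(W = matrix(0, 2, 2), b = rep(0, 2))
  r <- budcall:::adam_step(params, zero_g, st, lr = 0.1, weight_decay = 0.1)
  expect_lt(r$params$W[1], 1)     # matrices decay
  expect_equal(r$params$b, c(1, 1))  # biases exempt
})
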