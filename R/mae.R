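# Stage 1: self-supervised masked auto-encoder. Images are cut into patch
# tokens, a large random fraction is hidden, the visible tokens (plus a CLS
# token and learnable positional embeddings) are encoded, and a lightweight
# decoder with mask tokens reconstructs the hidden patches under an L2 loss.
# Training uses AdamW, warmup + cosine annealing with restarts, gradient
# accumulation, an EMA weight copy, and validation-loss checkpointing.

#' Cut an image into a patch-token sequence
#'
#' Square non-overlapping `p` x `p` patches in row-major grid order; each
#' patch is flattened to a length `p^2` vector. `unpatchify()` inverts it.
#'
#' @param image H x W matrix with H, W divisible by `p`.
#' @param p Patch side length, pixels.
#' @return List with `patches` (P x p^2 matrix), `grid` (rows, cols of the
#'   patch grid), `patch_size`.
#' @export
patchify <- function(image, p) {
  h <- nrow(image); w <- ncol(image)
  if (h %% p != 0 || w %% p != 0) {
    stop("image dimensions must be divisible by the patch size")
  }
  gr <- h %/% p; gc <- w %/% p
  patches <- matrix(0, gr * gc, p * p)
  k <- 1L
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      patches[k, ] <- as.numeric(image[((i - 1) * p + 1):(i * p),
                                       ((j - 1) * p + 1):(j * p)])
      k <- k + 1L
    }
  }
  list(patches = patches, grid = c(gr, gc), patch_size = p)
}

#' @rdname patchify
#' @param seq A patch sequence as returned by `patchify()`.
#' @export
unpatchify <- function(seq) {
  p <- seq$patch_size
  gr <- seq$grid[1]; gc <- seq$grid[2]
  image <- matrix(0, gr * p, gc * p)
  k <- 1L
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      image[((i - 1) * p + 1):(i * p), ((j - 1) * p + 1):(j * p)] <-
        matrix(seq$patches[k, ], p, p)
      k <- k + 1L
    }
  }
  image
}

#' Draw a random mask plan
#'
#' Uniformly shuffles the `P` patch positions and keeps the first
#' `P - floor(mask_ratio * P)` as visible. The stored shuffle permutation and
#' its inverse let decoded patches be unshuffled back to their original grid
#' positions.
#'
#' @param seq A [patchify()] patch sequence.
#' @param mask_ratio Fraction of patches to hide, in `[0, 1)`.
#' @return List with `visible` (n_visible x p^2 matrix) and `plan`: a list
#'   with `mask_ratio`, `shuffle_perm` (0-based permutation of patch
#'   indices), `n_visible`, `restore_indices` (0-based inverse permutation),
#'   `keep` (0-based indices of visible patches, sorted), `masked` (0-based
#'   indices of hidden patches).
#' @export
random_masking <- function(seq, mask_ratio) {
  stopifnot(mask_ratio >= 0, mask_ratio < 1)
  P <- nrow(seq$patches)
  perm <- sample.int(P)                      # caller controls the RNG state
  n_visible <- P - floor(mask_ratio * P)
  keep <- perm[seq_len(n_visible)]
  restore <- order(perm)
  plan <- list(mask_ratio = mask_ratio,
               shuffle_perm = perm - 1L,
               n_visible = as.integer(n_visible),
               restore_indices = restore - 1L,
               keep = sort(keep) - 1L,
               masked = sort(setdiff(seq_len(P), keep)) - 1L)
  list(visible = seq$patches[keep, , drop = FALSE], plan = plan)
}

#' Masked-patch reconstruction loss
#'
#' Mean squared pixel error between a reconstruction and its target,
#' averaged over masked patches only (the canonical masked auto-encoding
#' objective) or over all patches.
#'
#' @param pred,target H x W images (same shape).
#' @param plan Mask plan from [random_masking()] (ignored when
#'   `loss_on = "all"`).
#' @param patch_size Patch side used to delimit patches.
#' @param loss_on `"masked"` or `"all"`.
#' @return Non-negative scalar; 0 iff the images agree on the scored region.
#' @export
reconstruction_loss <- function(pred, target, plan, patch_size,
                                loss_on = c("masked", "all")) {
  loss_on <- match.arg(loss_on)
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  ps <- patchify(pred, patch_size)$patches
  ts <- patchify(target, patch_size)$patches
  idx <- if (loss_on == "masked") plan$masked + 1L else seq_len(nrow(ps))
  mean((ps[idx, , drop = FALSE] - ts[idx, , drop = FALSE])^2)
}

# crops (list of H x W matrices or T x H x W array) -> P x p^2 x N cube
crops_to_cube <- function(crops, p) {
  if (is.array(crops) && length(dim(crops)) == 3) {
    crops <- lapply(seq_len(dim(crops)[1]), function(t) crops[t, , ])
  }
  n <- length(crops)
  if (n == 0) stop("empty crop set")
  first <- patchify(crops[[1]], p)
  cube <- array(0, dim = c(nrow(first$patches), p * p, n))
  cube[, , 1] <- first$patches
  if (n > 1) {
    for (i in 2:n) cube[, , i] <- patchify(crops[[i]], p)$patches
  }
  attr(cube, "grid") <- first$grid
  cube
}

# draw a keep-index matrix (n_visible x B, 0-based) for a batch
draw_keep <- function(P, mask_ratio, B) {
  n_visible <- P - floor(mask_ratio * P)
  matrix(vapply(seq_len(B),
                function(b) sort(sample.int(P, n_visible)) - 1L,
                integer(n_visible)),
         nrow = n_visible)
}

mae_val_loss <- function(params, cfg, cube, keep) {
  n <- dim(cube)[3]
  bs <- 64L
  total <- 0
  for (s in seq(1L, n, by = bs)) {
    idx <- s:min(n, s + bs - 1L)
    r <- cpp_mae_batch(params, cube[, , idx, drop = FALSE],
                       keep[, idx, drop = FALSE],
                       cfg$encoder_depth, cfg$decoder_depth,
                       cfg$encoder_heads, cfg$decoder_heads,
                       cfg$loss_on == "all", FALSE, FALSE)
    total <- total + r$loss * length(idx)
  }
  total / n
}

#' Pretrain a masked auto-encoder on single-cell crops
#'
#' Trains the MAE end-to-end on normalized crops with AdamW, gradient
#' accumulation (`grad_accum_steps` micro-batches per optimizer step), a
#' warmup + cosine-restart learning-rate schedule, and an EMA weight copy.
#' Validation loss (on a fixed set of validation masks) is monitored every
#' epoch and the best-scoring weights are retained as the checkpoint.
#' Deterministic given `config$seed`.
#'
#' @param train_crops,val_crops Normalized crops: lists of H x W matrices or
#'   T x H x W arrays. Must come from disjoint cell sets.
#' @param config A [mae_config()].
#' @param norm_stats Optional normalization statistics to store with the
#'   model for inference parity.
#' @param verbose Print per-epoch losses.
#' @return An object of class `"bud_mae"`: `params` (best checkpoint),
#'   `final_params`, `ema_params`, `config`, `norm_stats`, and `log` (one row
#'   per epoch: train/validation/EMA-validation loss and learning rate) with
#'   `best_checkpoint` the argmin of validation loss.
#' @export
mae_pretrain <- function(train_crops, val_crops, config = mae_config(),
                         norm_stats = NULL, verbose = FALSE) {
  cfg <- config
  tr <- crops_to_cube(train_crops, cfg$patch_size)
  va <- crops_to_cube(val_crops, cfg$patch_size)
  n_tr <- dim(tr)[3]; n_va <- dim(va)[3]
  if (n_tr == 0 || n_va == 0) stop("empty training or validation set")
  P <- dim(tr)[1]

  out <- withr::with_seed(cfg$seed, {
    params <- init_mae_params(cfg)
    ema <- params
    opt <- adam_init(params)
    val_keep <- draw_keep(P, cfg$mask_ratio, n_va)  # fixed across epochs
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0), ema_val_loss = numeric(0),
                      lr = numeric(0))
    best <- list(loss = Inf, params = params, epoch = 0L)
    opt_step <- 0L
    acc <- NULL; n_acc <- 0L

    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n_tr)
      ep_loss <- 0; n_batches <- 0L
      for (s in seq(1L, n_tr, by = cfg$batch_size)) {
        idx <- perm[s:min(n_tr, s + cfg$batch_size - 1L)]
        keep <- draw_keep(P, cfg$mask_ratio, length(idx))
        r <- cpp_mae_batch(params, tr[, , idx, drop = FALSE], keep,
                           cfg$encoder_depth, cfg$decoder_depth,
                           cfg$encoder_heads, cfg$decoder_heads,
                           cfg$loss_on == "all", TRUE, FALSE)
        if (!is.finite(r$loss)) {
          stop(sprintf("NaN/Inf loss at epoch %d, step %d - aborting",
                       epoch, opt_step))
        }
        ep_loss <- ep_loss + r$loss; n_batches <- n_batches + 1L
        acc <- if (is.null(acc)) {
          lapply(conform_grads(params, r$grads), function(x) x / cfg$grad_accum_steps)
        } else {
          grads_add(acc, conform_grads(params, r$grads), 1 / cfg$grad_accum_steps)
        }
        n_acc <- n_acc + 1L
        if (n_acc == cfg$grad_accum_steps) {
          lr <- lr_at(opt_step, cfg)
          st <- adam_step(params, acc, opt, lr,
                          weight_decay = cfg$weight_decay)
          params <- st$params; opt <- st$state
          ema <- ema_update(ema, params, cfg$ema_decay)
          opt_step <- opt_step + 1L
          acc <- NULL; n_acc <- 0L
        }
      }
      if (n_acc > 0L) {  # flush a trailing partial accumulation group
        acc <- lapply(acc, function(x) x * cfg$grad_accum_steps / n_acc)
        lr <- lr_at(opt_step, cfg)
        st <- adam_step(params, acc, opt, lr, weight_decay = cfg$weight_decay)
        params <- st$params; opt <- st$state
        ema <- ema_update(ema, params, cfg$ema_decay)
        opt_step <- opt_step + 1L
        acc <- NULL; n_acc <- 0L
      }
      vl <- mae_val_loss(params, cfg, va, val_keep)
      evl <- mae_val_loss(ema, cfg, va, val_keep)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = ep_loss / n_batches,
                                   val_loss = vl, ema_val_loss = evl,
                                   lr = lr_at(opt_step - 1L, cfg)))
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = epoch)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f  ema-val %.5f",
                        epoch, ep_loss / n_batches, vl, evl))
      }
    }
    list(params = best$params, final_params = params, ema_params = ema,
         log = log, best_checkpoint = best$epoch)
  })

  structure(list(params = out$params, final_params = out$final_params,
                 ema_params = out$ema_params, config = cfg,
                 norm_stats = norm_stats, log = out$log,
                 best_checkpoint = out$best_checkpoint),
            class = "bud_mae")
}

#' Encode patch tokens with the MAE encoder
#'
#' Runs the encoder over the visible tokens of one image (all tokens when
#' `keep` is omitted) and returns the latent representation of every token
#' after the final layer norm. Row 1 is the CLS token latent.
#'
#' @param object A fitted [mae_pretrain()] model.
#' @param image Normalized H x W crop.
#' @param keep Optional 0-based indices of visible patches.
#' @param weights Which weight copy to use: best checkpoint, EMA, or final.
#' @return (n_visible + 1) x encoder_dim latent matrix.
#' @export
mae_encode <- function(object, image, keep = NULL,
                       weights = c("best", "ema", "final")) {
  weights <- match.arg(weights)
  cfg <- object$config
  pr <- switch(weights, best = object$params, ema = object$ema_params,
               final = object$final_params)
  seq <- patchify(image, cfg$patch_size)
  P <- nrow(seq$patches)
  if (is.null(keep)) keep <- seq_len(P) - 1L
  cube <- array(seq$patches, dim = c(P, cfg$patch_size^2, 1))
  lat <- cpp_encode(pr, cube, matrix(as.integer(keep), ncol = 1),
                    cfg$encoder_depth, cfg$encoder_heads)
  lat[, , 1]
}

#' Reconstruct an image through the masked auto-encoder
#'
#' Encodes the visible patches, inserts mask tokens at the hidden positions,
#' decodes, and unshuffles decoded patches back to their grid positions.
#'
#' @param object A fitted `"bud_mae"` model.
#' @param image Normalized H x W crop.
#' @param plan Optional mask plan from [random_masking()]; when omitted a
#'   fresh plan at the training mask ratio is drawn from the current RNG
#'   state.
#' @param weights Weight copy to use (see [mae_encode()]).
#' @return List with `recon` (H x W reconstruction), `plan`, and `loss`
#'   (masked-patch MSE against the input).
#' @export
mae_reconstruct <- function(object, image, plan = NULL,
                            weights = c("best", "ema", "final")) {
  weights <- match.arg(weights)
  cfg <- object$config
  pr <- switch(weights, best = object$params, ema = object$ema_params,
               final = object$final_params)
  seq <- patchify(image, cfg$patch_size)
  P <- nrow(seq$patches)
  if (is.null(plan)) plan <- random_masking(seq, cfg$mask_ratio)$plan
  cube <- array(seq$patches, dim = c(P, cfg$patch_size^2, 1))
  r <- cpp_mae_batch(pr, cube, matrix(as.integer(plan$keep), ncol = 1),
                     cfg$encoder_depth, cfg$decoder_depth,
                     cfg$encoder_heads, cfg$decoder_heads,
                     cfg$loss_on == "all", FALSE, TRUE)
  recon <- unpatchify(list(patches = r$recon[, , 1], grid = seq$grid,
                           patch_size = cfg$patch_size))
  list(recon = recon, plan = plan, loss = r$loss)
}

#' @export
print.bud_mae <- function(x, ...) {
  cfg <- x$config
  cat("Masked auto-encoder (vision transformer)\n")
  cat(sprintf("  input %dx%d, patch %d (%d tokens), mask ratio %.2f\n",
              cfg$image_size, cfg$image_size, cfg$patch_size, cfg$n_patches,
              cfg$mask_ratio))
  cat(sprintf("  encoder dim %d depth %d heads %d; decoder dim %d depth %d\n",
              cfg$encoder_dim, cfg$encoder_depth, cfg$encoder_heads,
              cfg$decoder_dim, cfg$decoder_depth))
  cat(sprintf("  trained %d epochs; best checkpoint at epoch %d (val loss %.5f)\n",
              nrow(x$log), x$best_checkpoint,
              min(x$log$val_loss)))
  invisible(x)
}

#' @export
summary.bud_mae <- function(object, ...) {
  print(object)
  cat("\nTraining log (last 5 epochs):\n")
  print(utils::tail(object$log, 5), row.names = FALSE)
  invisible(object$log)
}

#' @export
plot.bud_mae <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$train_loss, type = "l",
                 xlab = "epoch", ylab = "reconstruction loss",
                 ylim = range(c(x$log$train_loss, x$log$val_loss)), ...)
  graphics::lines(x$log$epoch, x$log$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' @export
predict.bud_mae <- function(object, image, ...) {
  mae_reconstruct(object, image, ...)
}
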