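# Stage 2: budding-event classifier. Each frame of an 11-frame window is
# embedded by the pretrained MAE encoder via its CLS token (no masking),
# sinusoidal temporal embeddings encode the slot order, a lightweight
# temporal transformer mixes the sequence, and a two-way softmax on the
# center slot gives the budding probability of the center frame.

#' Temporal-detector configuration
#'
#' @param window Temporal window length (odd; default 11 = center frame with
#'   five preceding and five subsequent frames).
#' @param temporal_dim,temporal_depth,temporal_heads Temporal transformer
#'   geometry.
#' @param threshold Probability threshold for calling a frame positive.
#' @param encoder_mode `"frozen"` (encoder fixed, frame embeddings cached
#'   once) or `"finetune"` (encoder updated at `encoder_lr_scale` times the
#'   head learning rate).
#' @param lr Head learning rate (AdamW).
#' @param encoder_lr_scale Encoder learning-rate multiplier under finetuning.
#' @param weight_decay Decoupled weight decay.
#' @param epochs,batch_size Training schedule; `batch_size` must be even so
#'   batches can be class-balanced.
#' @param encoder_weights Which MAE weight copy supplies the embeddings:
#'   `"best"` (validation-loss checkpoint), `"ema"`, or `"final"`.
#' @param frame_embedding Frame readout from the encoder: `"cls_mean"`
#'   (CLS-token output concatenated with the mean of the patch-token
#'   latents; the default), `"cls"`, or `"mean"`. The masked-reconstruction
#'   objective never constrains the CLS token directly, so with a frozen
#'   encoder its informativeness varies from pretraining run to pretraining
#'   run; mean-pooled patch latents are trained by the loss itself and keep
#'   the readout reliable, while the CLS component preserves whatever global
#'   summary that token learned.
#' @param seed Integer seed for init, batch order and resampling.
#' @return A list of class `"detector_config"`.
#' @export
detector_config <- function(window = 11L, temporal_dim = 64L,
                            temporal_depth = 2L, temporal_heads = 4L,
                            threshold = 0.5,
                            encoder_mode = c("frozen", "finetune"),
                            lr = 1e-3, encoder_lr_scale = 0.1,
                            weight_decay = 0.01, epochs = 8L,
                            batch_size = 32L,
                            encoder_weights = c("best", "ema", "final"),
                            frame_embedding = c("cls_mean", "cls", "mean"),
                            seed = 1L) {
  encoder_mode <- match.arg(encoder_mode)
  encoder_weights <- match.arg(encoder_weights)
  frame_embedding <- match.arg(frame_embedding)
  stopifnot(window %% 2 == 1, threshold > 0, threshold < 1,
            batch_size %% 2 == 0, temporal_dim %% temporal_heads == 0)
  structure(as.list(environment()), class = "detector_config")
}

#' Sinusoidal temporal position table
#'
#' Standard fixed sinusoid: entry `(t, 2i)` is `sin(t / 10000^(2i/d))` and
#' `(t, 2i+1)` is `cos(t / 10000^(2i/d))`, for 0-based `t` and `i`.
#'
#' @param T Number of positions (window length).
#' @param d Embedding dimension (even).
#' @return T x d matrix with entries in `[-1, 1]`.
#' @export
temporal_positional_table <- function(T, d) {
  if (d %% 2 != 0) stop("temporal embedding dimension must be even")
  tab <- matrix(0, T, d)
  pos <- seq_len(T) - 1
  for (i in seq_len(d / 2) - 1) {
    freq <- 1 / 10000^(2 * i / d)
    tab[, 2 * i + 1] <- sin(pos * freq)
    tab[, 2 * i + 2] <- cos(pos * freq)
  }
  tab
}

# Frame features for a stack of normalized crops (T x H x W array or list),
# batched through the encoder with full patch visibility. mode selects the
# readout: CLS row, mean over patch-token latents, or their concatenation.
encode_frame_features <- function(enc_params, mae_cfg, crops,
                                  mode = "cls_mean", chunk = 64L) {
  cube <- crops_to_cube(crops, mae_cfg$patch_size)
  P <- dim(cube)[1]
  n <- dim(cube)[3]
  keep_all <- matrix(rep(seq_len(P) - 1L, chunk), nrow = P)
  D <- mae_cfg$encoder_dim
  out <- matrix(0, n, if (mode == "cls_mean") 2L * D else D)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    lat <- cpp_encode(enc_params, cube[, , idx, drop = FALSE],
                      keep_all[, seq_along(idx), drop = FALSE],
                      mae_cfg$encoder_depth, mae_cfg$encoder_heads)
    cls <- t(lat[1, , , drop = TRUE])
    if (length(idx) == 1) cls <- matrix(lat[1, , 1], 1)
    if (mode == "cls") {
      out[idx, ] <- cls
    } else {
      mp <- t(apply(lat[-1, , , drop = FALSE], c(2, 3), mean))
      if (length(idx) == 1) mp <- matrix(mp, 1)
      out[idx, ] <- if (mode == "mean") mp else cbind(cls, mp)
    }
  }
  out
}

encode_cls_frames <- function(enc_params, mae_cfg, crops, chunk = 64L) {
  encode_frame_features(enc_params, mae_cfg, crops, mode = "cls", chunk = chunk)
}

frame_feature_dim <- function(mae_cfg, mode) {
  as.integer(mae_cfg$encoder_dim * if (mode == "cls_mean") 2L else 1L)
}

#' Embed one frame with the pretrained encoder
#'
#' Full-visibility encoding (no patch masking); the CLS-token output is the
#' frame embedding.
#'
#' @param object A fitted `"bud_mae"` model.
#' @param crop Normalized H x W crop.
#' @param weights MAE weight copy to use.
#' @return Numeric vector of length `encoder_dim`.
#' @export
embed_frame <- function(object, crop, weights = c("best", "ema", "final")) {
  weights <- match.arg(weights)
  pr <- switch(weights, best = object$params, ema = object$ema_params,
               final = object$final_params)
  as.numeric(encode_cls_frames(pr, object$config,
                               array(crop, c(1, dim(crop)))))
}

#' Classify one 11-frame stack of embeddings
#'
#' @param params Temporal-transformer parameter list.
#' @param stack_emb window x encoder_dim matrix of frame embeddings, in
#'   temporal order.
#' @param config A [detector_config()].
#' @return Named probability pair `(non_budding, budding)` summing to 1,
#'   attached to the center frame of the window.
#' @export
classify_stack <- function(params, stack_emb, config) {
  if (nrow(stack_emb) != config$window) stop("wrong window length")
  tab <- temporal_positional_table(config$window, config$temporal_dim)
  r <- cpp_temporal_batch(params,
                          array(stack_emb, c(dim(stack_emb), 1)), tab,
                          -1L, config$temporal_depth, config$temporal_heads,
                          FALSE, FALSE)
  stats::setNames(as.numeric(r$probs), c("non_budding", "budding"))
}

#' Class-balanced batch indices
#'
#' Splits sample indices into batches containing exactly `batch_size / 2`
#' positives and negatives. The majority class is shuffled and covered once
#' per epoch; the minority class is resampled with replacement. Deterministic
#' given `seed`.
#'
#' @param labels 0/1 vector over samples.
#' @param batch_size Even batch size.
#' @param seed Integer seed.
#' @return List of integer index vectors (each of length `batch_size`).
#' @export
balanced_batches <- function(labels, batch_size, seed = 1L) {
  stopifnot(batch_size %% 2 == 0)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) == 0 || length(neg) == 0) {
    stop("balanced batching needs at least one sample of each class")
  }
  half <- batch_size %/% 2
  withr::with_seed(seed, {
    maj <- if (length(neg) >= length(pos)) neg else pos
    mino <- if (length(neg) >= length(pos)) pos else neg
    maj <- sample(maj)
    n_batches <- ceiling(length(maj) / half)
    lapply(seq_len(n_batches), function(i) {
      m <- maj[((i - 1) * half + 1):min(i * half, length(maj))]
      if (length(m) < half) {  # pad the trailing batch from the majority pool
        m <- c(m, sample(maj, half - length(m), replace = TRUE))
      }
      k <- sample(mino, half, replace = TRUE)
      sample(c(m, k))  # shuffle within batch
    })
  })
}

# assemble a (window x D x B) cube of embedding windows
gather_windows <- function(E, windows, sel) {
  B <- length(sel)
  out <- array(0, dim = c(ncol(windows), ncol(E), B))
  for (b in seq_len(B)) out[, , b] <- E[windows[sel[b], ], ]
  out
}

#' Train the budding-event detector
#'
#' Embeds every frame of the training and validation cells with the
#' pretrained encoder, builds 11-frame windows (edge-replication padding at
#' movie boundaries, identical at inference), and trains the temporal
#' transformer with cross-entropy on class-balanced batches. The model is
#' selected by validation F1 at a ±1-frame tolerance. With
#' `encoder_mode = "finetune"` the encoder is updated jointly at a reduced
#' learning rate; with `"frozen"` frame embeddings are computed once and
#' cached.
#'
#' @param cells List of training cells; each element is a list with
#'   `cell_id`, `crops` (T x H x W normalized array), and `timeline`
#'   (a [division_timeline()]).
#' @param val_cells Held-out cells in the same format (cell-exclusive).
#' @param mae A fitted [mae_pretrain()] model.
#' @param config A [detector_config()].
#' @param positive_span Frames labeled positive from each annotated event
#'   (see [label_stacks()]).
#' @param negative_cells Optional list of event-free validation movies
#'   (T x H x W normalized crop arrays). When given, model selection becomes
#'   lexicographic: fewest spurious events on these movies first, highest
#'   validation F1 second. This anchors the checkpoint choice to the
#'   specificity that downstream lifespan counting needs; without it,
#'   checkpoints with near-identical F1 can differ sharply in their
#'   false-positive rate on quiet movies.
#' @param verbose Print per-epoch progress.
#' @return An object of class `"bud_detector"`.
#' @export
train_detector <- function(cells, val_cells, mae, config = detector_config(),
                           positive_span = 1L, negative_cells = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(mae, "bud_mae"))
  cfg <- config
  if (cfg$encoder_mode == "finetune") cfg$frame_embedding <- "cls"
  mcfg <- mae$config
  enc_params <- switch(cfg$encoder_weights, best = mae$params,
                       ema = mae$ema_params, final = mae$final_params)
  train_ids <- vapply(cells, function(x) x$cell_id, character(1))
  val_ids <- vapply(val_cells, function(x) x$cell_id, character(1))
  if (length(intersect(train_ids, val_ids))) {
    stop("cell-exclusive split violated: ",
         paste(intersect(train_ids, val_ids), collapse = ", "))
  }
  half <- (cfg$window - 1L) %/% 2L

  # per-cell embeddings, window index tables, labels
  prep_cell <- function(cl, ep) {
    Tn <- dim(cl$crops)[1]
    stacks <- label_stacks(build_stacks(Tn, half), cl$timeline, positive_span)
    windows <- t(vapply(stacks, function(s) s$frames + 1L, integer(cfg$window)))
    list(E = encode_frame_features(ep, mcfg, cl$crops, cfg$frame_embedding),
         windows = windows,
         labels = vapply(stacks, function(s) s$label, integer(1)),
         cell = cl)
  }
  tr <- lapply(cells, prep_cell, ep = enc_params)
  va <- lapply(val_cells, prep_cell, ep = enc_params)
  prep_neg <- function(crops, ep) {
    Tn <- dim(crops)[1]
    list(E = encode_frame_features(ep, mcfg, crops, cfg$frame_embedding),
         windows = t(vapply(build_stacks(Tn, half), function(s) s$frames + 1L,
                            integer(cfg$window))),
         crops = crops)
  }
  ng <- lapply(negative_cells, prep_neg, ep = enc_params)

  # flat sample table over training cells
  cell_of <- rep(seq_along(tr), vapply(tr, function(x) nrow(x$windows), integer(1)))
  row_of <- unlist(lapply(tr, function(x) seq_len(nrow(x$windows))))
  labels <- unlist(lapply(tr, function(x) x$labels))
  tab <- temporal_positional_table(cfg$window, cfg$temporal_dim)

  neg_events <- function(tp) {
    if (length(ng) == 0) return(0L)
    sum(vapply(ng, function(v) {
      pr <- cpp_temporal_batch(tp, gather_windows(v$E, v$windows,
                                                  seq_len(nrow(v$windows))),
                               tab, rep(-1L, nrow(v$windows)),
                               cfg$temporal_depth, cfg$temporal_heads,
                               FALSE, FALSE)$probs[, 2]
      compute_rls(collapse_runs(binarize(pr, cfg$threshold)))
    }, integer(1)))
  }

  val_f1 <- function(tp) {
    cnt <- c(tp_ = 0, fp = 0, fn = 0)
    for (v in va) {
      pr <- cpp_temporal_batch(tp, gather_windows(v$E, v$windows,
                                                  seq_len(nrow(v$windows))),
                               tab, rep(-1L, nrow(v$windows)),
                               cfg$temporal_depth, cfg$temporal_heads,
                               FALSE, FALSE)$probs[, 2]
      calls <- binarize(pr, cfg$threshold)
      pred_tl <- collapse_runs(calls, cell_id = v$cell$cell_id)
      rep_ <- match_events(v$cell$timeline, pred_tl, max_gap = 5L)
      sc <- detection_scores(rep_, tolerance = 1L)
      cnt <- cnt + c(sc$tp, sc$fp, sc$fn)
    }
    if (2 * cnt[1] + cnt[2] + cnt[3] == 0) return(0)
    unname(2 * cnt[1] / (2 * cnt[1] + cnt[2] + cnt[3]))
  }

  out <- withr::with_seed(cfg$seed, {
    tparams <- init_temporal_params(frame_feature_dim(mcfg, cfg$frame_embedding), cfg)
    topt <- adam_init(tparams)
    eopt <- if (cfg$encoder_mode == "finetune") adam_init(enc_params)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_f1 = numeric(0), val_neg_events = integer(0))
    best <- list(f1 = -Inf, neg = Inf, tparams = tparams,
                 eparams = enc_params, epoch = 0L)
    for (epoch in seq_len(cfg$epochs)) {
      batches <- balanced_batches(labels, cfg$batch_size,
                                  seed = cfg$seed * 1000L + epoch)
      ep_loss <- 0
      for (bi in batches) {
        if (cfg$encoder_mode == "finetune") {
          # recompute the batch's frame embeddings from the current encoder
          big <- array(0, dim = c(length(bi) * cfg$window,
                                  mcfg$image_size, mcfg$image_size))
          for (k in seq_along(bi)) {
            ci <- cell_of[bi[k]]
            fr <- tr[[ci]]$windows[row_of[bi[k]], ]
            big[((k - 1) * cfg$window + 1):(k * cfg$window), , ] <-
              tr[[ci]]$cell$crops[fr, , , drop = FALSE]
          }
          Eb <- encode_cls_frames(enc_params, mcfg, big)  # finetune path trains the CLS readout
          Ecube <- array(0, dim = c(cfg$window, mcfg$encoder_dim, length(bi)))
          for (k in seq_along(bi)) {
            Ecube[, , k] <- Eb[((k - 1) * cfg$window + 1):(k * cfg$window), ]
          }
          r <- cpp_temporal_batch(tparams, Ecube, tab,
                                  as.integer(labels[bi]), cfg$temporal_depth,
                                  cfg$temporal_heads, TRUE, TRUE)
          dE <- matrix(aperm(r$dE, c(1, 3, 2)),
                       nrow = length(bi) * cfg$window)
          gcube <- crops_to_cube(big, mcfg$patch_size)
          eg <- cpp_encode_cls_vjp(enc_params, gcube, dE,
                                   mcfg$encoder_depth, mcfg$encoder_heads)
          est <- adam_step(enc_params, conform_grads(enc_params, eg), eopt,
                           cfg$lr * cfg$encoder_lr_scale,
                           weight_decay = cfg$weight_decay)
          enc_params <- est$params; eopt <- est$state
        } else {
          Ecube <- array(0, dim = c(cfg$window,
                                    frame_feature_dim(mcfg, cfg$frame_embedding),
                                    length(bi)))
          for (k in seq_along(bi)) {
            i <- bi[k]
            Ecube[, , k] <- tr[[cell_of[i]]]$E[tr[[cell_of[i]]]$windows[row_of[i], ], ]
          }
          r <- cpp_temporal_batch(tparams, Ecube, tab,
                                  as.integer(labels[bi]), cfg$temporal_depth,
                                  cfg$temporal_heads, TRUE, FALSE)
        }
        if (!is.finite(r$loss)) stop("NaN/Inf detector loss - aborting")
        ep_loss <- ep_loss + r$loss
        st <- adam_step(tparams, conform_grads(tparams, r$grads), topt, cfg$lr,
                        weight_decay = cfg$weight_decay)
        tparams <- st$params; topt <- st$state
      }
      if (cfg$encoder_mode == "finetune") {
        # re-embed validation cells under the updated encoder
        va <- lapply(val_cells, prep_cell, ep = enc_params)
        ng <- lapply(negative_cells, prep_neg, ep = enc_params)
      }
      f1 <- val_f1(tparams)
      nev <- neg_events(tparams)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = ep_loss / length(batches),
                                   val_f1 = f1, val_neg_events = nev))
      if (nev < best$neg || (nev == best$neg && f1 > best$f1)) {
        best <- list(f1 = f1, neg = nev, tparams = tparams,
                     eparams = enc_params, epoch = epoch)
      }
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val F1(+/-1) %.3f  neg events %d",
                        epoch, ep_loss / length(batches), f1, nev))
      }
    }
    list(tparams = best$tparams, eparams = best$eparams, log = log,
         best_epoch = best$epoch)
  })

  structure(list(temporal_params = out$tparams,
                 encoder_params = out$eparams,
                 mae_config = mcfg, config = cfg,
                 norm_stats = mae$norm_stats,
                 log = out$log, best_epoch = out$best_epoch),
            class = "bud_detector")
}

#' Frame-wise budding probabilities for a whole movie
#'
#' Slides the 11-frame window over every frame (edge-replication padding at
#' the boundaries, identical to training) and returns one budding
#' probability per frame.
#'
#' @param object A fitted `"bud_detector"`.
#' @param crops T x H x W array of normalized crops (see `normalized`).
#' @param normalized Set `FALSE` when `crops` holds raw `[0, 1]` intensities;
#'   the detector's stored normalization statistics are then applied.
#' @return Numeric vector of length T with values in `[0, 1]`.
#' @export
predict_timeline <- function(object, crops, normalized = TRUE) {
  stopifnot(inherits(object, "bud_detector"))
  if (length(dim(crops)) != 3 || dim(crops)[1] < 1) stop("empty movie")
  cfg <- object$config
  if (!normalized) {
    if (is.null(object$norm_stats)) stop("detector carries no normalization stats")
    crops <- movie_to_crops(crops, object$norm_stats,
                            target = object$mae_config$image_size)
  }
  Tn <- dim(crops)[1]
  mode <- if (cfg$encoder_mode == "finetune") "cls" else cfg$frame_embedding
  E <- encode_frame_features(object$encoder_params, object$mae_config, crops,
                             mode)
  stacks <- build_stacks(Tn, (cfg$window - 1L) %/% 2L)
  windows <- t(vapply(stacks, function(s) s$frames + 1L, integer(cfg$window)))
  tab <- temporal_positional_table(cfg$window, cfg$temporal_dim)
  cpp_temporal_batch(object$temporal_params,
                     gather_windows(E, windows, seq_len(Tn)), tab,
                     rep(-1L, Tn), cfg$temporal_depth, cfg$temporal_heads,
                     FALSE, FALSE)$probs[, 2]
}

#' @export
predict.bud_detector <- function(object, crops, normalized = TRUE,
                                 type = c("prob", "timeline"), ...) {
  type <- match.arg(type)
  probs <- predict_timeline(object, crops, normalized)
  if (type == "prob") return(probs)
  collapse_runs(binarize(probs, object$config$threshold))
}

#' @export
print.bud_detector <- function(x, ...) {
  cat("Budding-event detector (temporal transformer over MAE embeddings)\n")
  cat(sprintf("  window %d, temporal dim %d depth %d heads %d, encoder %s\n",
              x$config$window, x$config$temporal_dim, x$config$temporal_depth,
              x$config$temporal_heads, x$config$encoder_mode))
  sel <- x$log$val_f1[match(x$best_epoch, x$log$epoch)]
  cat(sprintf("  trained %d epochs; selected epoch %d (val F1 +/-1 = %.3f)\n",
              nrow(x$log), x$best_epoch, if (length(sel)) sel else NA))
  invisible(x)
}

#' @export
summary.bud_detector <- function(object, ...) {
  print(object)
  cat("\nTraining log:\n")
  print(object$log, row.names = FALSE)
  invisible(object$log)
}

#' @export
plot.bud_detector <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x$log$epoch, x$log$train_loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy", main = "training loss", ...)
  graphics::plot(x$log$epoch, x$log$val_f1, type = "b", xlab = "epoch",
                 ylab = "validation F1 (+/-1 frame)", main = "model selection",
                 ylim = c(0, 1))
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
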