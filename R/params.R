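# Parameter containers and optimization utilities shared by the MAE and the
# temporal detector. Parameters are flat named lists of matrices/vectors whose
# names match the C++ core's lookup keys.

.init_block <- function(prefix, D, hidden, sd = 0.02) {
  w <- list()
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    w[[paste0(prefix, "_", nm)]] <- matrix(stats::rnorm(D * D, sd = sd), D, D)
  }
  w[[paste0(prefix, "_bq")]] <- numeric(D)
  w[[paste0(prefix, "_bk")]] <- numeric(D)
  w[[paste0(prefix, "_bv")]] <- numeric(D)
  w[[paste0(prefix, "_bo")]] <- numeric(D)
  w[[paste0(prefix, "_W1")]] <- matrix(stats::rnorm(D * hidden, sd = sd), D, hidden)
  w[[paste0(prefix, "_b1")]] <- numeric(hidden)
  w[[paste0(prefix, "_W2")]] <- matrix(stats::rnorm(hidden * D, sd = sd), hidden, D)
  w[[paste0(prefix, "_b2")]] <- numeric(D)
  w[[paste0(prefix, "_ln1g")]] <- rep(1, D)
  w[[paste0(prefix, "_ln1b")]] <- numeric(D)
  w[[paste0(prefix, "_ln2g")]] <- rep(1, D)
  w[[paste0(prefix, "_ln2b")]] <- numeric(D)
  w
}

.init_stack <- function(tag, depth, D, hidden, sd = 0.02) {
  w <- list()
  for (i in seq_len(depth) - 1L) {
    w <- c(w, .init_block(paste0(tag, i), D, hidden, sd))
  }
  w[[paste0(tag, "_lng")]] <- rep(1, D)
  w[[paste0(tag, "_lnb")]] <- numeric(D)
  w
}

#' Masked auto-encoder configuration
#'
#' Collects the architecture and optimization hyperparameters of the
#' self-supervised pretraining stage. Defaults are the "tiny" desk-scale
#' setting: 64x64 crops cut into 8x8 patches (64 tokens), a dim-128/depth-4
#' encoder and a dim-64/depth-2 decoder, mask ratio 0.75.
#'
#' @param image_size Input crop side length in pixels; must be divisible by
#'   `patch_size`.
#' @param patch_size Patch side length in pixels.
#' @param encoder_dim,encoder_depth,encoder_heads Encoder width, number of
#'   transformer blocks, and attention heads.
#' @param decoder_dim,decoder_depth,decoder_heads Decoder geometry.
#' @param mask_ratio Fraction of patches hidden from the encoder, in `[0, 1)`.
#' @param base_lr Peak learning rate reached at the end of warmup.
#' @param warmup_steps Optimizer steps of linear learning-rate ramp from 0.
#' @param cycle_steps Length of each cosine-annealing cycle (after warmup);
#'   the rate restarts at `base_lr` at every cycle boundary.
#' @param min_lr Floor of the cosine schedule.
#' @param ema_decay Exponential-moving-average decay for the secondary weight
#'   copy, in `[0, 1]`.
#' @param grad_accum_steps Micro-batches accumulated per optimizer step.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param batch_size Micro-batch size (images per forward/backward pass).
#' @param epochs Training epochs.
#' @param loss_on Compute the reconstruction loss on `"masked"` patches only
#'   (canonical masked auto-encoding) or on `"all"` patches.
#' @param seed Integer seed controlling weight init, shuffling and masking.
#' @return A list of class `"mae_config"`.
#' @export
mae_config <- function(image_size = 64L, patch_size = 8L,
                       encoder_dim = 128L, encoder_depth = 4L, encoder_heads = 4L,
                       decoder_dim = 64L, decoder_depth = 2L, decoder_heads = 4L,
                       mask_ratio = 0.75, base_lr = 1.5e-3, warmup_steps = 100L,
                       cycle_steps = 400L, min_lr = 1e-5, ema_decay = 0.999,
                       grad_accum_steps = 2L, weight_decay = 0.01,
                       batch_size = 32L, epochs = 30L,
                       loss_on = c("masked", "all"), seed = 1L) {
  loss_on <- match.arg(loss_on)
  stopifnot(image_size %% patch_size == 0,
            mask_ratio >= 0, mask_ratio < 1,
            ema_decay >= 0, ema_decay <= 1,
            base_lr > 0, warmup_steps >= 0, cycle_steps >= 1,
            grad_accum_steps >= 1, batch_size >= 1, epochs >= 1,
            encoder_dim %% encoder_heads == 0,
            decoder_dim %% decoder_heads == 0)
  cfg <- as.list(environment())
  cfg$n_patches <- as.integer((image_size / patch_size)^2)
  structure(cfg, class = "mae_config")
}

init_mae_params <- function(cfg) {
  pp <- cfg$patch_size^2
  P <- cfg$n_patches
  D <- cfg$encoder_dim
  Dd <- cfg$decoder_dim
  p <- list(
    pe_W = matrix(stats::rnorm(pp * D, sd = 0.02), pp, D),
    pe_b = numeric(D),
    cls  = matrix(stats::rnorm(D, sd = 0.02), 1, D),
    pos  = matrix(stats::rnorm((P + 1) * D, sd = 0.02), P + 1, D)
  )
  p <- c(p, .init_stack("e", cfg$encoder_depth, D, 2L * D))
  p$d_in_W <- matrix(stats::rnorm(D * Dd, sd = 0.02), D, Dd)
  p$d_in_b <- numeric(Dd)
  p$mask_tok <- matrix(stats::rnorm(Dd, sd = 0.02), 1, Dd)
  p$dpos <- matrix(stats::rnorm((P + 1) * Dd, sd = 0.02), P + 1, Dd)
  p <- c(p, .init_stack("d", cfg$decoder_depth, Dd, 2L * Dd))
  p$out_W <- matrix(stats::rnorm(Dd * pp, sd = 0.02), Dd, pp)
  p$out_b <- numeric(pp)
  p
}

init_temporal_params <- function(encoder_dim, cfg) {
  Td <- cfg$temporal_dim
  p <- list(
    t_in_W = matrix(stats::rnorm(encoder_dim * Td, sd = 0.02), encoder_dim, Td),
    t_in_b = numeric(Td)
  )
  p <- c(p, .init_stack("t", cfg$temporal_depth, Td, 2L * Td))
  p$head_W <- matrix(stats::rnorm(Td * 2, sd = 0.02), Td, 2)
  p$head_b <- numeric(2)
  p
}

# ---------------------------------------------------------------------------
# AdamW over named parameter lists

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    # decoupled weight decay; norm gains/biases (vectors) are exempt
    if (weight_decay > 0 && is.matrix(params[[nm]])) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

grads_zero <- function(params) lapply(params, function(x) x * 0)

# make gradient shapes match parameter shapes (the C++ core returns row
# vectors as 1 x D matrices)
conform_grads <- function(params, grads) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(dim(params[[nm]])) && !is.null(dim(g))) g <- as.numeric(g)
    out[[nm]] <- g
  }
  out
}

grads_add <- function(acc, g, scale = 1) {
  for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + scale * g[[nm]]
  acc
}

#' Exponential moving average of model weights
#'
#' Updates a secondary weight copy as `ema <- decay * ema + (1 - decay) *
#' current`, parameter by parameter. With `decay = 0` the EMA tracks the
#' current weights exactly; with `decay = 1` it never moves.
#'
#' @param ema_weights,current_weights Named lists of numeric arrays with
#'   identical structure.
#' @param decay Scalar in `[0, 1]`.
#' @return Updated EMA weight list.
#' @export
ema_update <- function(ema_weights, current_weights, decay) {
  stopifnot(decay >= 0, decay <= 1,
            identical(names(ema_weights), names(current_weights)))
  for (nm in names(ema_weights)) {
    stopifnot(identical(dim(ema_weights[[nm]]), dim(current_weights[[nm]])),
              length(ema_weights[[nm]]) == length(current_weights[[nm]]))
    ema_weights[[nm]] <- decay * ema_weights[[nm]] +
      (1 - decay) * current_weights[[nm]]
  }
  ema_weights
}

#' Warmup + cosine-annealing-with-restarts learning-rate schedule
#'
#' Linear ramp from 0 to `base_lr` over `warmup_steps`, then repeated cosine
#' cycles from `base_lr` down to `min_lr`, restarting at `base_lr` every
#' `cycle_steps` optimizer steps.
#'
#' @param step Optimizer step index (0-based).
#' @param config A list with `base_lr`, `warmup_steps`, `cycle_steps`,
#'   `min_lr` (e.g. a [mae_config()]).
#' @return Learning rate at `step`.
#' @export
lr_at <- function(step, config) {
  stopifnot(step >= 0)
  if (config$warmup_steps > 0 && step < config$warmup_steps) {
    return(config$base_lr * step / config$warmup_steps)
  }
  tc <- (step - config$warmup_steps) %% config$cycle_steps
  config$min_lr + 0.5 * (config$base_lr - config$min_lr) *
    (1 + cos(pi * tc / config$cycle_steps))
}
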