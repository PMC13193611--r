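# Evaluation: optimal one-to-one event matching (Hungarian algorithm),
# tolerance-window detection scores with early/late/unmatched breakdown,
# replicative-lifespan agreement, smoothed cell-cycle trajectories, and the
# untrained-model diagnostic baseline.

# Min-cost assignment via the Hungarian algorithm with potentials
# (O(n^2 m), n <= m). Returns, for each row, the assigned column (0 = none).
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(INF, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Match predicted to ground-truth division events
#'
#' Optimal one-to-one assignment between two sorted event timelines,
#' maximizing the number of pairs within `max_gap` frames and, among those,
#' minimizing the total absolute frame offset (Hungarian algorithm with a
#' large penalty on disallowed pairings). Equal-cost ties are resolved
#' deterministically in lexicographic pair order, i.e. toward the earlier
#' ground-truth event.
#'
#' @param gt,pred [division_timeline()] objects or sorted integer frame
#'   vectors; either may be empty.
#' @param max_gap Maximal |pred - gt| offset (frames) at which events may be
#'   paired.
#' @return A match report: `pairs` (data frame `gt_frame`, `pred_frame`,
#'   `signed_error = pred - gt`), `unmatched_gt`, `unmatched_pred`,
#'   `max_gap`, `n_gt`, `n_pred`.
#' @export
match_events <- function(gt, pred, max_gap = 5L) {
  g <- if (inherits(gt, "division_timeline")) gt$event_frames else as.integer(gt)
  p <- if (inherits(pred, "division_timeline")) pred$event_frames else as.integer(pred)
  n <- length(g); m <- length(p)
  empty <- data.frame(gt_frame = integer(0), pred_frame = integer(0),
                      signed_error = integer(0))
  if (n == 0 || m == 0) {
    return(list(pairs = empty, unmatched_gt = g, unmatched_pred = p,
                max_gap = max_gap, n_gt = n, n_pred = m))
  }
  BIG <- 1e9
  eps <- 1e-6  # lexicographic tie-break, far below any real cost difference
  cost <- outer(g, p, function(a, b) abs(b - a))
  allowed <- cost <= max_gap
  tie <- eps * outer(seq_len(n), seq_len(m), function(i, j) i * (m + 1) + j)
  cost <- ifelse(allowed, cost + tie, BIG)
  flip <- n > m
  assign <- if (flip) hungarian(t(cost)) else hungarian(cost)
  pairs <- empty
  matched_g <- logical(n); matched_p <- logical(m)
  rows <- if (flip) seq_len(m) else seq_len(n)
  for (r in rows) {
    cidx <- assign[r]
    if (cidx == 0) next
    i <- if (flip) cidx else r   # gt index
    j <- if (flip) r else cidx   # pred index
    if (abs(p[j] - g[i]) > max_gap) next
    pairs <- rbind(pairs, data.frame(gt_frame = g[i], pred_frame = p[j],
                                     signed_error = p[j] - g[i]))
    matched_g[i] <- TRUE; matched_p[j] <- TRUE
  }
  pairs <- pairs[order(pairs$gt_frame), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched_gt = g[!matched_g],
       unmatched_pred = p[!matched_p], max_gap = max_gap,
       n_gt = n, n_pred = m)
}

# pool several per-cell match reports into one
pool_reports <- function(reports) {
  list(pairs = do.call(rbind, lapply(reports, `[[`, "pairs")),
       unmatched_gt = unlist(lapply(reports, `[[`, "unmatched_gt")),
       unmatched_pred = unlist(lapply(reports, `[[`, "unmatched_pred")),
       max_gap = reports[[1]]$max_gap,
       n_gt = sum(vapply(reports, `[[`, integer(1), "n_gt")),
       n_pred = sum(vapply(reports, `[[`, integer(1), "n_pred")))
}

#' Tolerance-window detection scores from a match report
#'
#' A matched pair counts as a true positive when its absolute signed error
#' is within `tolerance` frames. Precision, recall and F1 follow from
#' `tp`, `fp = n_pred - tp`, `fn = n_gt - tp`. Exact/±1/±2 fractions and the
#' early/late/unmatched breakdown are reported over predictions by default
#' (with unmatched predictions as their own class) or over ground truth.
#'
#' @param report A [match_events()] report (possibly pooled over cells).
#' @param tolerance Frames.
#' @param denominator `"pred"` or `"gt"` for the fraction columns.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `fraction_exact`, `fraction_within_1`, `fraction_within_2`,
#'   `fraction_early`, `fraction_late`, `fraction_unmatched`,
#'   `mean_signed_error`, `undefined` (names of scores whose denominator was
#'   zero; those are `NA`, never silent `NaN`).
#' @export
detection_scores <- function(report, tolerance = 1L,
                             denominator = c("pred", "gt")) {
  denominator <- match.arg(denominator)
  err <- report$pairs$signed_error
  tp <- sum(abs(err) <= tolerance)
  fp <- report$n_pred - tp
  fn <- report$n_gt - tp
  undefined <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  # count form of the harmonic mean: defined whenever either side has events
  # (a detector that predicts nothing scores 0, not undefined)
  f1 <- div(2 * tp, 2 * tp + fp + fn, "f1")
  den <- if (denominator == "pred") report$n_pred else report$n_gt
  n_un <- if (denominator == "pred") length(report$unmatched_pred) else {
    length(report$unmatched_gt)
  }
  scores <- list(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    fraction_exact = div(sum(err == 0), den, "fraction_exact"),
    fraction_within_1 = div(sum(abs(err) <= 1), den, "fraction_within_1"),
    fraction_within_2 = div(sum(abs(err) <= 2), den, "fraction_within_2"),
    fraction_early = div(sum(err < 0), den, "fraction_early"),
    fraction_late = div(sum(err > 0), den, "fraction_late"),
    fraction_unmatched = div(n_un, den, "fraction_unmatched"),
    mean_signed_error = if (length(err)) mean(err) else NA_real_,
    tolerance = tolerance, denominator = denominator)
  scores$undefined <- undefined
  scores
}

#' Replicative-lifespan agreement
#'
#' Ordinary least-squares fit of predicted on ground-truth RLS with
#' `r_squared = 1 - SS_res / SS_tot`, plus the identity-line variant
#' (residuals about `pred = gt`) and the SD of the per-cell RLS error.
#'
#' @param records Data frame (or list of pairs) with columns `gt_rls`,
#'   `pred_rls`; at least 3 cells, non-constant ground truth.
#' @return List with `r_squared`, `r_squared_identity`, `error_sd`, `slope`,
#'   `intercept`, `n`, and the per-cell `records`.
#' @export
lifespan_agreement <- function(records) {
  if (!is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      data.frame(gt_rls = r[[1]], pred_rls = r[[2]])
    }))
  }
  if (nrow(records) < 3) stop("need at least 3 cells")
  if (stats::var(records$gt_rls) == 0) {
    stop("constant ground-truth RLS: R^2 undefined (SS_tot = 0)")
  }
  fit <- stats::lm(pred_rls ~ gt_rls, data = records)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((records$pred_rls - mean(records$pred_rls))^2)
  list(r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
       r_squared_identity = 1 - sum((records$pred_rls - records$gt_rls)^2) /
         sum((records$gt_rls - mean(records$gt_rls))^2),
       error_sd = stats::sd(records$pred_rls - records$gt_rls),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = nrow(records), records = records)
}

#' Savitzky-Golay-smoothed cell-cycle trajectory
#'
#' Bins cycle lengths on the percent-of-lifespan axis and smooths the binned
#' means with a Savitzky-Golay filter (which reproduces polynomials up to
#' the fit order exactly and returns a series of the same length).
#'
#' @param points Data frame with columns `pct_lifespan` and `gap_frames`
#'   (e.g. pooled [cell_cycle_lengths()] rows).
#' @param window Odd filter window length (bins).
#' @param polyorder Polynomial order, `< window`.
#' @param pct_bin Bin width on the percent axis.
#' @return Data frame with `pct` (bin centers), `gap_mean` (binned means),
#'   `gap_smooth` (filtered curve), `n` (points per bin).
#' @export
smooth_cycle_trajectory <- function(points, window = 11L, polyorder = 2L,
                                    pct_bin = 2) {
  stopifnot(window %% 2 == 1, polyorder < window)
  bin <- floor(points$pct_lifespan / pct_bin)
  agg <- stats::aggregate(points$gap_frames, by = list(bin = bin), FUN = mean)
  cnt <- as.integer(table(bin))
  if (nrow(agg) < window) {
    stop("too few occupied bins (", nrow(agg), ") for window ", window)
  }
  sm <- signal::sgolayfilt(agg$x, p = polyorder, n = window)
  data.frame(pct = (agg$bin + 0.5) * pct_bin, gap_mean = agg$x,
             gap_smooth = sm, n = cnt)
}

#' Untrained-detector diagnostic baseline
#'
#' Builds a detector whose temporal transformer is randomly initialized
#' (fixed seed) on top of the given encoder and runs it through exactly the
#' same prediction path as a trained model. It serves only as the diagnostic
#' control establishing that detection accuracy comes from learned
#' representations, not from the architecture or the post-processing.
#'
#' @param mae A fitted `"bud_mae"` model supplying the encoder.
#' @param config A [detector_config()].
#' @param seed Seed for the random head initialization.
#' @return An object of class `"bud_detector"` (untrained).
#' @export
untrained_baseline <- function(mae, config = detector_config(), seed = 1L) {
  stopifnot(inherits(mae, "bud_mae"))
  enc <- switch(config$encoder_weights, best = mae$params,
                ema = mae$ema_params, final = mae$final_params)
  if (config$encoder_mode == "finetune") config$frame_embedding <- "cls"
  tparams <- withr::with_seed(seed, {
    init_temporal_params(frame_feature_dim(mae$config,
                                           config$frame_embedding), config)
  })
  structure(list(temporal_params = tparams, encoder_params = enc,
                 mae_config = mae$config, config = config,
                 norm_stats = mae$norm_stats,
                 log = data.frame(epoch = integer(0), train_loss = numeric(0),
                                  val_f1 = numeric(0)),
                 best_epoch = 0L),
            class = "bud_detector")
}

#' Score predicted timelines against ground truth over a dataset
#'
#' Matches events cell by cell, pools the match reports, and reports
#' tolerance-window detection scores together with replicative-lifespan
#' agreement.
#'
#' @param gt_timelines,pred_timelines Named lists of [division_timeline()]
#'   objects with matching names.
#' @param tolerance Frames for the F1 tolerance window.
#' @param max_gap Maximal pairing offset for the Hungarian matching.
#' @param denominator See [detection_scores()].
#' @return List with `scores`, `lifespan`, `per_cell` (match reports), and
#'   `events` (long table `cell_id`, `source` in gt/pred, `frame` for raster
#'   plots).
#' @export
evaluate_dataset <- function(gt_timelines, pred_timelines, tolerance = 1L,
                             max_gap = 5L, denominator = "pred") {
  ids <- names(gt_timelines)
  stopifnot(!is.null(ids), all(ids %in% names(pred_timelines)))
  reports <- lapply(ids, function(id) {
    match_events(gt_timelines[[id]], pred_timelines[[id]], max_gap)
  })
  names(reports) <- ids
  pooled <- pool_reports(reports)
  rls <- data.frame(
    gt_rls = vapply(gt_timelines[ids], compute_rls, integer(1)),
    pred_rls = vapply(pred_timelines[ids], compute_rls, integer(1)))
  events <- do.call(rbind, lapply(ids, function(id) {
    rbind(
      if (compute_rls(gt_timelines[[id]]) > 0) {
        data.frame(cell_id = id, source = "gt",
                   frame = gt_timelines[[id]]$event_frames)
      },
      if (compute_rls(pred_timelines[[id]]) > 0) {
        data.frame(cell_id = id, source = "pred",
                   frame = pred_timelines[[id]]$event_frames)
      })
  }))
  list(scores = detection_scores(pooled, tolerance, denominator),
       lifespan = lifespan_agreement(rls),
       per_cell = reports, events = events)
}
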