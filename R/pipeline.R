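# End-to-end pipeline: simulate -> preprocess -> pretrain -> train ->
# predict -> evaluate, with every artifact traceable to config + seed.

#' Run the full division-detection pipeline on synthetic data
#'
#' Simulates a training pool and a held-out evaluation cohort of mother
#' cells, computes dataset normalization statistics on training cells only,
#' pretrains the masked auto-encoder on unlabeled training-cell crops,
#' trains the temporal detector on the (cell-exclusive) train/validation
#' split of the pool, predicts division timelines for the held-out cohort,
#' and scores them against the known schedules. Also runs the untrained
#' diagnostic baseline and an event-free negative-control cohort.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory for artifacts (predictions CSV, cycle
#'   series CSV, evaluation report YAML).
#' @param verbose Print per-stage progress.
#' @return List with `mae`, `detector`, `report` (held-out evaluation),
#'   `baseline_report` (untrained detector on the same cells),
#'   `negative_control` (fraction and count of event-free cells predicted
#'   event-free), `holdout` (per-cell truths/predictions), and `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  cfg <- config
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("stage %-10s %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    r
  }
  sp <- schedule_params(rls_mean = cfg$simulate$rls_mean,
                        rls_sd = cfg$simulate$rls_sd,
                        base_cycle_frames = cfg$simulate$base_cycle_frames,
                        late_life_slowdown = cfg$simulate$late_life_slowdown,
                        cycle_noise_sd = cfg$simulate$cycle_noise_sd)

  sim <- stage("simulate", {
    pool <- simulate_cells(cfg$simulate$n_cells, sp, seed = cfg$seed)
    holdout <- simulate_cells(cfg$simulate$n_eval, sp, seed = cfg$seed + 101L)
    for (i in seq_along(holdout)) {
      id <- sprintf("eval_%03d", i)
      holdout[[i]]$timeline$cell_id <- id
      holdout[[i]]$spec$cell_id <- id
    }
    list(pool = pool, holdout = holdout)
  })

  prep <- stage("preprocess", {
    ids <- vapply(sim$pool, function(x) x$timeline$cell_id, character(1))
    split <- split_by_cell(ids, cfg$preprocess$train_frac, seed = cfg$seed + 7L)
    train_raw <- sim$pool[ids %in% split$train_cells]
    val_raw <- sim$pool[ids %in% split$val_cells]
    stats <- normalization_stats(
      do.call(abind3, lapply(train_raw, function(x) x$movie)))
    norm_cell <- function(x) {
      list(cell_id = x$timeline$cell_id,
           crops = movie_to_crops(x$movie, stats, cfg$preprocess$target_size),
           timeline = x$timeline)
    }
    list(train = lapply(train_raw, norm_cell),
         val = lapply(val_raw, norm_cell),
         holdout = lapply(sim$holdout, norm_cell),
         stats = stats, split = split)
  })

  mae <- stage("pretrain", {
    pick_crops <- function(cells, n_max, seed) {
      all <- do.call(abind3, lapply(cells, function(x) x$crops))
      n <- dim(all)[1]
      idx <- withr::with_seed(seed, sample.int(n, min(n, n_max)))
      all[idx, , , drop = FALSE]
    }
    trc <- pick_crops(prep$train, cfg$mae$max_crops, cfg$seed + 11L)
    vac <- pick_crops(prep$val, max(64L, cfg$mae$max_crops %/% 4L),
                      cfg$seed + 12L)
    mc <- mae_config(image_size = cfg$preprocess$target_size,
                     mask_ratio = cfg$mae$mask_ratio,
                     batch_size = cfg$mae$batch_size,
                     epochs = cfg$mae$epochs, seed = cfg$seed + 13L)
    mae_pretrain(trc, vac, mc, norm_stats = prep$stats, verbose = verbose)
  })

  detector <- stage("train", {
    dc <- detector_config(threshold = cfg$detector$threshold,
                          encoder_mode = cfg$detector$encoder_mode,
                          epochs = cfg$detector$epochs,
                          batch_size = cfg$detector$batch_size,
                          seed = cfg$seed + 17L)
    # event-free movies for specificity-aware checkpoint selection
    # (independent renders; not the evaluation negative-control cohort)
    val_negs <- lapply(seq_len(cfg$detector$n_val_negatives), function(i) {
      spec <- synthetic_cell_spec(cell_id = sprintf("valneg_%03d", i),
                                  rng_seed = cfg$seed * 100L + 61L + i)
      mv <- render_cell_movie(spec, division_timeline(spec$cell_id,
                                                      integer(0), 120L))
      movie_to_crops(mv$movie, prep$stats, cfg$preprocess$target_size)
    })
    train_detector(prep$train, prep$val, mae, dc,
                   positive_span = cfg$preprocess$positive_span,
                   negative_cells = val_negs, verbose = verbose)
  })

  predictions <- stage("predict", {
    lapply(prep$holdout, function(cl) {
      probs <- predict_timeline(detector, cl$crops)
      tl <- collapse_runs(binarize(probs, cfg$detector$threshold),
                          cell_id = cl$cell_id,
                          frame_interval_min = cfg$frame_interval_min)
      list(cell_id = cl$cell_id, probs = probs, timeline = tl)
    })
  })

  report <- stage("evaluate", {
    gt <- lapply(prep$holdout, `[[`, "timeline")
    names(gt) <- vapply(prep$holdout, `[[`, character(1), "cell_id")
    pr <- lapply(predictions, `[[`, "timeline")
    names(pr) <- vapply(predictions, `[[`, character(1), "cell_id")
    evaluate_dataset(gt, pr, tolerance = cfg$evaluate$tolerance,
                     max_gap = cfg$evaluate$max_gap)
  })

  baseline_report <- stage("baseline", {
    naive <- untrained_baseline(mae, detector$config, seed = cfg$seed + 23L)
    gt <- lapply(prep$holdout, `[[`, "timeline")
    names(gt) <- vapply(prep$holdout, `[[`, character(1), "cell_id")
    pr <- lapply(prep$holdout, function(cl) {
      probs <- predict_timeline(naive, cl$crops)
      collapse_runs(binarize(probs, cfg$detector$threshold),
                    cell_id = cl$cell_id)
    })
    names(pr) <- names(gt)
    evaluate_dataset(gt, pr, tolerance = cfg$evaluate$tolerance,
                     max_gap = cfg$evaluate$max_gap)
  })

  negative <- stage("negcontrol", {
    n <- cfg$simulate$n_negative
    if (n == 0) return(NULL)
    zeros <- lapply(seq_len(n), function(i) {
      id <- sprintf("neg_%03d", i)
      spec <- synthetic_cell_spec(cell_id = id,
                                  rng_seed = cfg$seed * 100L + 31L + i)
      tl <- division_timeline(id, integer(0), n_frames = 120L)
      mv <- render_cell_movie(spec, tl)
      movie_to_crops(mv$movie, prep$stats, cfg$preprocess$target_size)
    })
    rls <- vapply(zeros, function(crops) {
      compute_rls(collapse_runs(binarize(predict_timeline(detector, crops),
                                         cfg$detector$threshold)))
    }, integer(1))
    list(n_cells = n, n_event_free = sum(rls == 0L),
         fraction_event_free = mean(rls == 0L), predicted_rls = rls)
  })

  result <- list(mae = mae, detector = detector, report = report,
                 baseline_report = baseline_report,
                 negative_control = negative,
                 holdout = list(cells = prep$holdout,
                                predictions = predictions),
                 norm_stats = prep$stats, split = prep$split,
                 config = cfg, config_hash = config_hash(cfg))

  if (!is.null(out_dir)) stage("write", write_artifacts(result, out_dir))
  result
}

# bind T x H x W arrays along the first axis
abind3 <- function(...) {
  arrs <- list(...)
  hw <- dim(arrs[[1]])[2:3]
  total <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, dim = c(total, hw))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  # per-frame probabilities and per-cell timelines for the held-out cohort
  probs <- do.call(rbind, lapply(result$holdout$predictions, function(p) {
    data.frame(cell_id = p$cell_id, frame = seq_along(p$probs) - 1L,
               prob_budding = p$probs)
  }))
  utils::write.csv(probs, file.path(out_dir, "probabilities.csv"),
                   row.names = FALSE)
  tls <- do.call(rbind, lapply(result$holdout$predictions, function(p) {
    data.frame(cell_id = p$cell_id, rls = compute_rls(p$timeline),
               event_frames = paste(p$timeline$event_frames, collapse = "|"),
               threshold = cfg$detector$threshold)
  }))
  utils::write.csv(tls, file.path(out_dir, "predicted_timelines.csv"),
                   row.names = FALSE)
  cycles <- do.call(rbind, lapply(result$holdout$predictions, function(p) {
    cc <- cell_cycle_lengths(p$timeline, cfg$frame_interval_min)
    if (nrow(cc)) cbind(data.frame(cell_id = p$cell_id), cc)
  }))
  if (!is.null(cycles)) {
    utils::write.csv(cycles, file.path(out_dir, "cycle_series.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(result$report$events, file.path(out_dir, "event_table.csv"),
                   row.names = FALSE)
  sc <- result$report$scores
  yaml::write_yaml(list(
    config = unclass(cfg), config_hash = result$config_hash,
    scores = sc[setdiff(names(sc), "undefined")],
    lifespan = result$report$lifespan[c("r_squared", "r_squared_identity",
                                        "error_sd", "slope", "intercept", "n")],
    baseline_f1 = result$baseline_report$scores$f1,
    negative_control = result$negative_control[c("n_cells", "n_event_free")]),
    file.path(out_dir, "report.yaml"))
  invisible(out_dir)
}
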