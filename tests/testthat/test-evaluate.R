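# Event matching, detection scores, lifespan agreement, SG smoothing.

# exhaustive one-to-one matcher: maximizes pairs within max_gap, then
# minimizes total |pred - gt| (oracle for the Hungarian implementation)
brute_match <- function(g, p, max_gap) {
  best <- list(npairs = -1L, cost = Inf)
  recur <- function(i, used, npairs, cost) {
    if (i > length(g)) {
      if (npairs > best$npairs ||
          (npairs == best$npairs && cost < best$cost)) {
        best <<- list(npairs = npairs, cost = cost)
      }
      return(invisible())
    }
    recur(i + 1L, used, npairs, cost)  # leave g[i] unmatched
    for (j in seq_along(p)) {
      if (!used[j] && abs(p[j] - g[i]) <= max_gap) {
        used[j] <- TRUE
        recur(i + 1L, used, npairs + 1L, cost + abs(p[j] - g[i]))
        used[j] <- FALSE
      }
    }
  }
  recur(1L, logical(length(p)), 0L, 0)
  best
}

test_that("match_events reproduces the worked example and handles empties", {
  r <- match_events(c(10L, 20L, 30L), c(11L, 19L, 40L), max_gap = 5)
  expect_equal(r$pairs$gt_frame, c(10, 20))
  expect_equal(r$pairs$pred_frame, c(11, 19))
  expect_equal(r$pairs$signed_error, c(1, -1))
  expect_equal(r$unmatched_gt, 30L)
  expect_equal(r$unmatched_pred, 40L)

  perfect <- match_events(c(5L, 9L), c(5L, 9L), 5)
  expect_true(all(perfect$pairs$signed_error == 0))
  expect_length(perfect$unmatched_gt, 0)

  none <- match_events(c(5L, 9L), integer(0), 5)
  expect_equal(none$unmatched_gt, c(5L, 9L))
  expect_equal(nrow(none$pairs), 0)
})

test_that("Hungarian matching equals exhaustive search on random instances", {
  set.seed(77)
  for (k in 1:120) {
    n <- sample(0:7, 1); m <- sample(0:7, 1)
    g <- sort(sample(0:40, n))
    p <- sort(sample(0:40, m))
    gap <- sample(1:6, 1)
    r <- match_events(g, p, gap)
    b <- brute_match(g, p, gap)
    expect_identical(nrow(r$pairs), b$npairs)
    expect_equal(sum(abs(r$pairs$signed_error)), b$cost)
    # bookkeeping invariants
    expect_equal(nrow(r$pairs) + length(r$unmatched_gt), n)
    expect_equal(nrow(r$pairs) + length(r$unmatched_pred), m)
    if (nrow(r$pairs)) expect_true(all(abs(r$pairs$signed_error) <= gap))
  }
})

test_that("detection scores satisfy the metric identities", {
  r <- match_events(c(10L, 20L, 30L), c(11L, 19L, 40L), max_gap = 5)
  s <- detection_scores(r, tolerance = 1)
  expect_equal(s$tp, 2); expect_equal(s$fp, 1); expect_equal(s$fn, 1)
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$recall, 2 / 3)
  expect_equal(s$f1, 2 / 3)
  expect_equal(s$mean_signed_error, 0)
  expect_equal(s$fraction_early, s$fraction_late)

  set.seed(13)
  for (k in 1:40) {
    g <- sort(sample(0:60, sample(2:10, 1)))
    p <- sort(sample(0:60, sample(2:10, 1)))
    r <- match_events(g, p, 5)
    s <- detection_scores(r, tolerance = 1)
    if (!is.na(s$f1) && s$precision + s$recall > 0) {
      expect_equal(s$f1, 2 * s$precision * s$recall / (s$precision + s$recall))
    }
    expect_lte(s$fraction_exact, s$fraction_within_1)
    expect_lte(s$fraction_within_1, s$fraction_within_2)
    # swapping gt and pred swaps precision/recall and negates the bias
    # (the bias negation is exact whenever the two directions settle on
    # mirrored pairings, which equal-cost ties need not; check it then)
    rs <- match_events(p, g, 5)
    ss <- detection_scores(rs, tolerance = 1)
    expect_equal(s$precision, ss$recall)
    expect_equal(s$recall, ss$precision)
    mirrored <- identical(
      sort(paste(r$pairs$gt_frame, r$pairs$pred_frame)),
      sort(paste(rs$pairs$pred_frame, rs$pairs$gt_frame)))
    if (!is.na(s$mean_signed_error) && mirrored) {
      expect_equal(s$mean_signed_error, -ss$mean_signed_error)
    }
  }
})

test_that("zero denominators are flagged, never silent NaN", {
  r <- match_events(integer(0), integer(0), 5)
  s <- detection_scores(r, 1)
  expect_true(all(c("precision", "recall") %in% s$undefined))
  expect_true(is.na(s$precision))
  expect_false(any(vapply(s[c("precision", "recall", "f1")],
                          is.nan, logical(1))))
})

test_that("perfect predictions score perfectly", {
  g <- c(3L, 9L, 20L)
  s <- detection_scores(match_events(g, g, 5), 1)
  expect_equal(s$precision, 1); expect_equal(s$recall, 1); expect_equal(s$f1, 1)
  expect_equal(s$fraction_exact, 1)
  expect_equal(s$fraction_unmatched, 0)
})

test_that("lifespan agreement matches a closed-form OLS oracle", {
  rec <- data.frame(gt_rls = c(10, 20, 30, 25), pred_rls = c(10, 20, 30, 25))
  a <- lifespan_agreement(rec)
  expect_equal(a$r_squared, 1)
  expect_equal(a$error_sd, 0)
  expect_equal(a$slope, 1)

  shifted <- data.frame(gt_rls = c(10, 20, 30), pred_rls = c(13, 23, 33))
  b <- lifespan_agreement(shifted)
  expect_equal(b$slope, 1)
  expect_equal(b$error_sd, 0)
  expect_equal(b$intercept, 3)

  set.seed(5)
  g <- rnorm(30, 24, 5); p <- g + rnorm(30)
  rec <- data.frame(gt_rls = g, pred_rls = p)
  o <- lifespan_agreement(rec)
  # normal-equations oracle
  X <- cbind(1, g)
  beta <- solve(t(X) %*% X, t(X) %*% p)
  res <- p - X %*% beta
  r2 <- 1 - sum(res^2) / sum((p - mean(p))^2)
  expect_equal(o$slope, beta[2], tolerance = 1e-10)
  expect_equal(o$r_squared, r2, tolerance = 1e-10)

  expect_error(lifespan_agreement(rec[1:2, ]), "at least 3")
  expect_error(lifespan_agreement(data.frame(gt_rls = c(5, 5, 5),
                                             pred_rls = c(4, 5, 6))),
               "constant")
})

test_that("SG smoothing reproduces low-order polynomials and preserves length", {
  pct <- seq(1, 99, by = 2)  # one point per 2% bin
  quad <- 5 + 0.02 * pct + 0.001 * pct^2
  pts <- data.frame(pct_lifespan = pct, gap_frames = quad)
  sm <- smooth_cycle_trajectory(pts, window = 11, polyorder = 2, pct_bin = 2)
  expect_equal(nrow(sm), length(pct))
  expect_equal(sm$gap_smooth, sm$gap_mean, tolerance = 1e-8)

  const <- data.frame(pct_lifespan = pct, gap_frames = rep(6, length(pct)))
  smc <- smooth_cycle_trajectory(const)
  expect_equal(smc$gap_smooth, rep(6, length(pct)), tolerance = 1e-10)

  expect_error(smooth_cycle_trajectory(pts[1:5, ], window = 11), "too few")
})
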