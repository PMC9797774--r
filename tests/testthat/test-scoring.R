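make_block_gt <- function() {
  gt <- matrix(0L, 9, 9); gt[4:6, 4:6] <- 1L
  gt
}

test_that("relaxed_iou matches direct cases and validates inputs", {
  gt <- make_block_gt()
  expect_equal(relaxed_iou(gt, gt), 1)
  expect_equal(relaxed_iou(gt, matrix(0L, 9, 9)), 0)  # empty prediction
  expect_warning(v <- relaxed_iou(matrix(0L, 5, 5), matrix(0L, 5, 5)),
                 "empty union")
  expect_equal(v, 1)
  expect_error(relaxed_iou(gt, matrix(0L, 5, 5)), "shape error")
  bad <- matrix(0L, 9, 9); bad[1, 1] <- 3L
  expect_error(relaxed_iou(gt, bad), "outside \\{0,1,2\\}")

  # block shifted right by one stays inside the tolerance envelope
  shifted <- matrix(0L, 9, 9); shifted[4:6, 5:7] <- 1L
  expect_equal(relaxed_iou(gt, shifted), oracle_score(gt, shifted))
})

test_that("class-2 dilation over adjacent class-1 pixels caps even a perfect prediction below 1", {
  # hemorrhagic precedence in the merged dilated envelope overwrites
  # ischemic labels on the contact band, so the intersection misses those
  # pixels even for the ground truth itself — a documented metric property
  gt <- matrix(0L, 9, 9)
  gt[4:6, 2:4] <- 1L
  gt[4:6, 5:7] <- 2L  # touching the class-1 block
  v <- relaxed_iou(gt, gt)
  expect_lt(v, 1)
  expect_equal(v, oracle_score(gt, gt))
  # with a gap of >= 2 pixels the same prediction is exact
  gt2 <- matrix(0L, 9, 9)
  gt2[4:6, 1:3] <- 1L
  gt2[4:6, 6:8] <- 2L
  expect_equal(relaxed_iou(gt2, gt2), 1)
})

test_that("relaxed_iou equals the verbatim-pseudocode double-loop oracle", {
  set.seed(51)
  for (rep in 1:100) {
    nr <- sample(4:64, 1); nc <- sample(4:64, 1)
    gt <- random_label_mask(nr, nc, p = c(0.8, 0.1, 0.1))
    pred <- if (rep %% 3 == 0) {
      # structured prediction: degraded copy of the truth
      degrade(gt, degradation_spec(shift = sample(-3:3, 2, replace = TRUE),
                                   seed = rep))
    } else {
      random_label_mask(nr, nc, p = c(0.8, 0.1, 0.1))
    }
    expect_equal(relaxed_iou(gt, pred), oracle_score(gt, pred))
  }
})

test_that("any prediction inside the eroded/dilated envelope scores exactly 1", {
  set.seed(52)
  for (rep in 1:100) {
    gt <- gen_phantom(32, 32, n_class1 = sample(0:2, 1), n_class2 = sample(0:2, 1),
                      radius_range = c(3, 6), seed = rep)
    env <- build_envelope(gt)
    if (!any(support(env$eroded))) next
    # random support between eroded and dilated, labels copied from dilated
    extra <- which(support(env$dilated) & !support(env$eroded))
    take <- extra[stats::runif(length(extra)) < 0.5]
    pred <- matrix(0L, 32, 32)
    pred[support(env$eroded)] <- env$dilated[support(env$eroded)]
    pred[take] <- env$dilated[take]
    expect_equal(relaxed_iou(gt, pred), 1)
  }
})

test_that("relaxed_iou stays in [0,1] and is monotone under envelope-consistent additions", {
  set.seed(53)
  for (rep in 1:60) {
    gt <- random_label_mask(10, 10)
    pred <- random_label_mask(10, 10)
    v <- relaxed_iou(gt, pred)
    expect_gte(v, 0); expect_lte(v, 1)
    # add one background pixel of pred whose dilated label it can match
    env <- build_envelope(gt)
    cand <- which(pred == 0L & support(env$dilated))
    if (length(cand)) {
      px <- cand[sample.int(length(cand), 1)]
      pred2 <- pred
      pred2[px] <- env$dilated[px]
      expect_gte(relaxed_iou(gt, pred2), v)
    }
  }
})

test_that("f1_score follows the harmonic-mean formula with the zero convention", {
  expect_equal(f1_score(10, 0, 0), 1)
  expect_equal(f1_score(0, 5, 5), 0)
  expect_equal(f1_score(60, 20, 20), 0.75)  # precision = recall = 0.75
  expect_equal(f1_score(0, 0, 0), 0)
  set.seed(54)
  for (rep in 1:25) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    p <- if (tp + fp > 0) tp / (tp + fp) else NA
    r <- if (tp + fn > 0) tp / (tp + fn) else NA
    expected <- if (is.na(p) || is.na(r) || p + r == 0) 0 else 2 * p * r / (p + r)
    expect_equal(f1_score(tp, fp, fn), expected)
  }
})

test_that("stage1_evaluate gates teams at the F1 threshold", {
  set.seed(55)
  ids <- sprintf("img%03d", 1:192)
  truth <- stats::setNames(sample(0:1, 192, replace = TRUE), ids)
  perfect <- stage1_evaluate(truth, truth)
  expect_equal(perfect$f1, 1)
  expect_true(perfect$qualified)

  flipped <- stage1_evaluate(truth, 1L - truth)
  expect_equal(flipped$f1, 0)
  expect_false(flipped$qualified)

  # 70 positives / 122 negatives; 10 positives and 10 negatives flipped
  truth2 <- stats::setNames(c(rep(1L, 70), rep(0L, 122)), ids)
  sub <- truth2
  sub[1:10] <- 0L          # 10 missed positives
  sub[71:80] <- 1L         # 10 false alarms
  res <- stage1_evaluate(truth2, sub)
  expect_equal(unname(res$counts[c("tp", "fp", "fn")]), c(60L, 10L, 10L))
  expect_equal(res$f1, 6 / 7)  # precision = recall = 6/7
  expect_true(res$qualified)

  expect_error(stage1_evaluate(truth, truth[-1]), "submission mismatch.*img001")
  bad <- truth; bad[1] <- 2L
  expect_error(stage1_evaluate(truth, bad), "invalid label")
})

test_that("rank_points reproduces the printed worked example and tie rules", {
  # exactly 10 of 36 teams with positive IoU: they get 36..27, the rest 26
  ious <- c(seq(0.95, 0.05, length.out = 10), rep(0, 26))
  names(ious) <- sprintf("t%02d", 1:36)
  pts <- rank_points(ious)
  expect_equal(unname(pts[1:10]), 36:27)
  expect_equal(unname(pts[11:36]), rep(26L, 26))

  # all distinct positive IoUs: points are exactly n..1
  set.seed(56)
  ious2 <- stats::setNames(sample(seq(0.01, 0.99, length.out = 36)), sprintf("t%02d", 1:36))
  pts2 <- rank_points(ious2)
  expect_setequal(unname(pts2), 1:36)
  expect_equal(sum(pts2), 36 * 37 / 2)

  # competition-style ties and the zero rule
  expect_equal(unname(rank_points(c(0.9, 0.9, 0.5, 0, 0))), c(5L, 5L, 3L, 2L, 2L))
  # no positive IoU at all: everyone gets 0
  expect_equal(unname(rank_points(c(0, 0, 0))), c(0L, 0L, 0L))
  expect_error(rank_points(c(0.5, 0.2), n_teams = 3), "expected 3 teams")

  for (rep in 1:50) {
    n <- sample(2:12, 1)
    ious <- sample(c(0, 0, round(stats::runif(4), 2)), n, replace = TRUE)
    expect_equal(unname(rank_points(ious)), oracle_rank_points(ious))
  }
})

test_that("leaderboard aggregation sums per-image points and respects bounds", {
  # one team strictly best everywhere, one strictly worst-positive everywhere
  n_teams <- 36; n_images <- 97
  iou <- matrix(0, n_teams, n_images,
                dimnames = list(sprintf("t%02d", 1:n_teams),
                                sprintf("img%02d", 1:n_images)))
  for (j in seq_len(n_images)) iou[, j] <- seq(1, 0.01, length.out = n_teams)
  board <- score_leaderboard(iou)
  expect_equal(unname(board$totals[1]), 36 * 97)   # always first
  expect_equal(unname(board$totals[36]), 97)       # always last positive
  expect_equal(board$totals, aggregate_points(board$points))

  # single image: totals equal that image's points vector
  one <- iou[, 1, drop = FALSE]
  expect_equal(aggregate_points(score_leaderboard(one)),
               rank_points(iou[, 1]))

  # permutation invariance over image order
  perm <- sample(n_images)
  expect_equal(score_leaderboard(iou[, perm])$totals, board$totals)

  bad <- iou; bad[1, 1] <- NA
  expect_error(score_leaderboard(bad), "incomplete leaderboard")
})

test_that("theoretical bounds follow the closed form", {
  expect_equal(unname(theoretical_bounds(36, 97)), c(3492L, 97L))
  expect_equal(unname(theoretical_bounds(1, 1)), c(1L, 1L))
  expect_equal(unname(theoretical_bounds(5, 10)), c(50L, 10L))
})
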