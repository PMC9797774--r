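#' Boundary-tolerant intersection-over-union between prediction and ground truth
#'
#' Lesion boundaries cannot be drawn with perfect precision even by expert
#' radiologists, so the metric relaxes the classical IoU by one 3x3
#' morphological step: the intersection is taken against the *dilated*
#' ground truth (a predicted pixel counts as correct if it matches the class
#' of the dilated envelope) while the union is taken against the *eroded*
#' ground truth (uncertain boundary pixels of the truth do not enlarge the
#' denominator). Any prediction whose support lies between the eroded and
#' dilated envelopes, with matching class labels, scores exactly 1.
#'
#' Concretely, with `E`/`D` the class-preserving eroded/dilated envelopes of
#' `gt` (see [build_envelope()]):
#' \deqn{IoU = \frac{|\{(i,j): D_{ij} = P_{ij} \ne 0\}|}{|\{(i,j): E_{ij} \ne 0 \lor P_{ij} \ne 0\}|}}
#'
#' When the union is empty — possible only when erosion removes the ground
#' truth entirely (thin lesions) *and* the prediction is all background —
#' both parties assert "nothing confidently present" and the score is
#' defined as 1, with a warning.
#'
#' @param gt ground-truth label mask (values 0/1/2).
#' @param predicted predicted label mask, same dimensions and value set.
#' @return a number in \[0, 1\].
#' @examples
#' gt <- matrix(0L, 9, 9); gt[3:7, 3:7] <- 1L
#' relaxed_iou(gt, gt)  # 1
#' @export
relaxed_iou <- function(gt, predicted) {
  assert_label_mask(gt, "ground truth")
  assert_label_mask(predicted, "prediction")
  assert_same_dim(gt, predicted)
  env <- build_envelope(gt)
  intersection_count <- sum(env$dilated == predicted & env$dilated != 0L)
  union_count <- sum(env$eroded != 0L | predicted != 0L)
  if (union_count == 0L) {
    warning("empty union: eroded ground truth and prediction are both empty; score defined as 1",
            call. = FALSE)
    return(1)
  }
  intersection_count / union_count
}

#' F1 score from image-level confusion counts
#'
#' Harmonic mean of precision and recall with "stroke present" (label 1) as
#' the positive class. Returns 0 whenever a denominator is 0 (no predicted
#' positives, no true positives), the standard convention.
#'
#' @param tp,fp,fn numbers of true-positive, false-positive and
#'   false-negative images (non-negative).
#' @return a number in \[0, 1\].
#' @export
f1_score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0 || tp + fn == 0) return(0)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Evaluate a stage-1 classification submission against the truth
#'
#' Stage 1 asks each team to label every image 0 (stroke absent) or
#' 1 (stroke present). The submission must cover exactly the truth's image
#' ids. Teams below the F1 threshold (default 0.75) are eliminated.
#'
#' @param truth named vector (names = image ids) of 0/1 reference labels, or
#'   a data frame with columns `image_id` and `label`.
#' @param submission same format as `truth`.
#' @param threshold qualification threshold on F1, default 0.75.
#' @return list with `counts` (tp, fp, fn, tn), `f1`, and `qualified`.
#' @export
stage1_evaluate <- function(truth, submission, threshold = 0.75) {
  truth <- as_label_map(truth, "truth")
  submission <- as_label_map(submission, "submission")
  missing_ids <- setdiff(names(truth), names(submission))
  extra_ids <- setdiff(names(submission), names(truth))
  if (length(missing_ids) || length(extra_ids))
    stop("submission mismatch: missing ids [",
         paste(utils::head(missing_ids, 10L), collapse = ", "),
         "], extra ids [", paste(utils::head(extra_ids, 10L), collapse = ", "), "]",
         call. = FALSE)
  sub <- submission[names(truth)]
  counts <- c(
    tp = sum(truth == 1L & sub == 1L),
    fp = sum(truth == 0L & sub == 1L),
    fn = sum(truth == 1L & sub == 0L),
    tn = sum(truth == 0L & sub == 0L)
  )
  f1 <- f1_score(counts[["tp"]], counts[["fp"]], counts[["fn"]])
  list(counts = counts, f1 = f1, qualified = f1 >= threshold)
}

as_label_map <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("image_id", "label") %in% names(x)))
      stop(what, " must have columns image_id and label", call. = FALSE)
    v <- x$label
    names(v) <- as.character(x$image_id)
    x <- v
  }
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop(what, " must be named by unique image ids", call. = FALSE)
  if (!all(x %in% c(0L, 1L)))
    stop("invalid label in ", what, ": labels must be 0 or 1", call. = FALSE)
  stats::setNames(as.integer(x), names(x))
}

#' Convert one image's IoU values into leaderboard points
#'
#' Teams with IoU > 0 are sorted in decreasing IoU order; the best receives
#' `n_teams` points, the next `n_teams - 1`, and so on. All teams with an
#' IoU of exactly 0 receive one point less than the lowest-ranked team with
#' a positive IoU. Two documented conventions complete the rule:
#' exact ties among positive IoUs share the best position's points
#' (competition-style "1224" ranking) and the count continues after the tie
#' block; and when no team has a positive IoU every team receives 0.
#' IoU equality means exact floating-point equality.
#'
#' @param ious named numeric vector of IoU values in \[0, 1\], one per team.
#' @param n_teams expected number of teams; must equal `length(ious)`.
#' @return named integer vector of points in the same team order.
#' @examples
#' rank_points(c(a = 0.9, b = 0.9, c = 0.5, d = 0, e = 0))  # 5 5 3 2 2
#' @export
rank_points <- function(ious, n_teams = length(ious)) {
  if (length(ious) != n_teams)
    stop("expected ", n_teams, " teams, got ", length(ious), call. = FALSE)
  if (any(ious < 0 | ious > 1)) stop("IoU values must lie in [0, 1]", call. = FALSE)
  if (is.null(names(ious))) names(ious) <- as.character(seq_along(ious))
  pts <- integer(n_teams)
  names(pts) <- names(ious)
  pos <- ious > 0
  if (!any(pos)) return(pts)  # no positive IoU: everyone gets 0
  r <- rank(-ious[pos], ties.method = "min")
  pts[pos] <- n_teams - as.integer(r) + 1L
  pts[!pos] <- min(pts[pos]) - 1L
  pts
}

#' Build a leaderboard from a team-by-image IoU matrix
#'
#' Applies [rank_points()] to every image (column) and accumulates per-team
#' totals: the overall score of a team is the sum of its per-image points.
#'
#' @param iou_matrix numeric matrix, rows = teams (rownames = team ids),
#'   columns = images (colnames = image ids), entries in \[0, 1\].
#' @return object of class `leaderboard`: list with `iou` (the input),
#'   `points` (integer matrix of the same shape) and `totals` (named integer
#'   vector, decreasing order not imposed).
#' @export
score_leaderboard <- function(iou_matrix) {
  if (!is.matrix(iou_matrix)) stop("iou_matrix must be a matrix", call. = FALSE)
  if (anyNA(iou_matrix))
    stop("incomplete leaderboard: IoU matrix has missing cells", call. = FALSE)
  if (is.null(rownames(iou_matrix)))
    rownames(iou_matrix) <- paste0("team", seq_len(nrow(iou_matrix)))
  pts <- apply(iou_matrix, 2L, rank_points, n_teams = nrow(iou_matrix))
  pts <- matrix(as.integer(pts), nrow(iou_matrix), ncol(iou_matrix),
                dimnames = dimnames(iou_matrix))
  structure(list(iou = iou_matrix, points = pts, totals = aggregate_points(pts)),
            class = "leaderboard")
}

#' Aggregate per-image points into team totals
#'
#' @param board a `leaderboard` object from [score_leaderboard()], or the
#'   points matrix itself (teams x images).
#' @return named integer vector of per-team totals.
#' @export
aggregate_points <- function(board) {
  pts <- if (inherits(board, "leaderboard")) board$points else board
  if (!is.matrix(pts)) stop("points must form a matrix", call. = FALSE)
  if (anyNA(pts)) stop("incomplete leaderboard: missing points cells", call. = FALSE)
  totals <- as.integer(rowSums(pts))
  names(totals) <- rownames(pts)
  totals
}

#' @export
print.leaderboard <- function(x, ...) {
  cat("leaderboard:", nrow(x$iou), "teams x", ncol(x$iou), "images\n")
  ord <- order(x$totals, decreasing = TRUE)
  print(data.frame(team = names(x$totals)[ord], total = x$totals[ord],
                   row.names = NULL))
  invisible(x)
}

#' Theoretical leaderboard score bounds
#'
#' A team ranked first on every image totals `n_teams * n_images` points; a
#' team holding the lowest positive IoU on every image totals `n_images`
#' (one point per image).
#'
#' @param n_teams,n_images positive counts.
#' @return named integer vector `c(max = ..., min = ...)`.
#' @examples
#' theoretical_bounds(36, 97)  # max 3492, min 97
#' @export
theoretical_bounds <- function(n_teams, n_images) {
  stopifnot(n_teams >= 1, n_images >= 1)
  c(max = as.integer(n_teams) * as.integer(n_images), min = as.integer(n_images))
}
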