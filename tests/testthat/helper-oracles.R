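# Independent brute-force oracles: explicit double loops following the
# scoring pseudocode pixel by pixel, sharing no code with the package
# implementation.

oracle_erode <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    all_one <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      v <- if (ii < 1 || ii > nr || jj < 1 || jj > nc) 0L else m[ii, jj]
      if (v != 1L) all_one <- FALSE
    }
    if (all_one) out[i, j] <- 1L
  }
  out
}

oracle_dilate <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    any_one <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && m[ii, jj] == 1L)
        any_one <- TRUE
    }
    if (any_one) out[i, j] <- 1L
  }
  out
}

# Verbatim double-loop transcription of the Score procedure, with class
# labels preserved in the merged envelopes (class 2 written last).
oracle_score <- function(gt, pred) {
  nr <- nrow(gt); nc <- ncol(gt)
  mask1 <- matrix(0L, nr, nc); mask2 <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (gt[i, j] == 1L) mask1[i, j] <- 1L
    if (gt[i, j] == 2L) mask2[i, j] <- 1L
  }
  erosion1 <- oracle_erode(mask1); dilation1 <- oracle_dilate(mask1)
  erosion2 <- oracle_erode(mask2); dilation2 <- oracle_dilate(mask2)
  erodedGT <- matrix(0L, nr, nc); dilatedGT <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (erosion1[i, j] == 1L) erodedGT[i, j] <- 1L
    if (erosion2[i, j] == 1L) erodedGT[i, j] <- 2L
    if (dilation1[i, j] == 1L) dilatedGT[i, j] <- 1L
    if (dilation2[i, j] == 1L) dilatedGT[i, j] <- 2L
  }
  intersection_count <- 0L; union_count <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (dilatedGT[i, j] == pred[i, j] && dilatedGT[i, j] != 0L)
      intersection_count <- intersection_count + 1L
    if (erodedGT[i, j] != 0L || pred[i, j] != 0L)
      union_count <- union_count + 1L
  }
  if (union_count == 0L) return(1)
  intersection_count / union_count
}

# Independent rank-to-points oracle: a team with positive IoU is scored by
# counting how many teams beat it strictly; zero-IoU teams get one point
# less than the worst positive team.
oracle_rank_points <- function(ious) {
  n <- length(ious)
  pts <- integer(n)
  if (!any(ious > 0)) return(pts)
  for (k in seq_len(n)) {
    if (ious[k] > 0) pts[k] <- n - sum(ious > ious[k])
  }
  pts[ious == 0] <- min(pts[ious > 0]) - 1L
  pts
}

random_label_mask <- function(nr, nc, p = c(0.7, 0.15, 0.15)) {
  matrix(sample(0:2, nr * nc, replace = TRUE, prob = p), nr, nc)
}

random_binary_mask <- function(nr, nc, p = 0.4) {
  matrix(as.integer(stats::runif(nr * nc) < p), nr, nc)
}

support <- function(m) m != 0L
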