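# Engineered competition: per image, team k's prediction keeps the first
# |E| - (k-1) pixels (column-major order) of the eroded ground-truth
# support, with the ground-truth labels. Eroded pixels always match the
# dilated envelope's class, so IoU(team k) = (|E| - k + 1)/|E|: strictly
# decreasing, distinct and positive across teams — team 1 is first and
# team n last-positive on every image.
build_nested_iou_matrix <- function(n_teams, n_images, seed, rows = 128L,
                                    cols = 128L, radius_range = c(8, 16)) {
  team_ids <- sprintf("team%02d", seq_len(n_teams))
  image_ids <- sprintf("img%03d", seq_len(n_images))
  iou <- matrix(NA_real_, n_teams, n_images,
                dimnames = list(team_ids, image_ids))
  for (i in seq_len(n_images)) {
    gt <- gen_phantom(rows, cols, n_class1 = 1, n_class2 = 1,
                      radius_range = radius_range, seed = seed + i)
    env <- build_envelope(gt)
    er_px <- which(env$eroded != 0L)
    stopifnot(length(er_px) >= n_teams)
    for (k in seq_len(n_teams)) {
      pred <- matrix(0L, rows, cols)
      keep <- er_px[seq_len(length(er_px) - k + 1L)]
      pred[keep] <- gt[keep]
      iou[k, i] <- relaxed_iou(gt, pred)
    }
  }
  iou
}
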