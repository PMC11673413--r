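# Independent brute-force oracles. Each reimplements a quantity from first
# principles, by enumeration or rasterization, and is deliberately slower
# and simpler than the package's implementation.

# IoU by rasterization on the unit grid: only exact for integer-coordinate
# boxes under the half-open convention, so oracle trials use integer boxes.
oracle_iou_raster <- function(a, b) {
  cells <- function(bx) {
    if (bx[3] <= bx[1] || bx[4] <= bx[2]) return(matrix(numeric(), 0, 2))
    as.matrix(expand.grid(x = seq(bx[1], bx[3] - 1), y = seq(bx[2], bx[4] - 1)))
  }
  ca <- cells(a); cb <- cells(b)
  if (!nrow(ca) && !nrow(cb)) return(0)
  key <- function(m) paste(m[, 1], m[, 2])
  inter <- length(intersect(key(ca), key(cb)))
  uni <- length(union(key(ca), key(cb)))
  if (uni == 0) 0 else inter / uni
}

# greedy NMS by repeated full rescan
oracle_nms <- function(boxes, scores, threshold) {
  alive <- seq_len(nrow(boxes))
  kept <- integer()
  while (length(alive)) {
    i <- alive[which.max(scores[alive])]
    kept <- c(kept, i)
    drop <- vapply(alive, function(j)
      j != i && iou(boxes[i, ], boxes[j, ]) > threshold, logical(1))
    alive <- setdiff(alive[!drop], i)
  }
  kept
}

# ROI align by direct evaluation of every bilinear sample in R
oracle_roi_align <- function(feature, stride, box, pooled, sampling = 2L) {
  H <- dim(feature)[1]; W <- dim(feature)[2]; C <- dim(feature)[3]
  interp <- function(f, y, x) {
    x <- min(max(x, 0), W - 1); y <- min(max(y, 0), H - 1)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- min(x0 + 1, W - 1); y1 <- min(y0 + 1, H - 1)
    dx <- x - x0; dy <- y - y0
    f[y0 + 1, x0 + 1] * (1 - dy) * (1 - dx) + f[y0 + 1, x1 + 1] * (1 - dy) * dx +
      f[y1 + 1, x0 + 1] * dy * (1 - dx) + f[y1 + 1, x1 + 1] * dy * dx
  }
  x0 <- box[1] / stride - 0.5; y0 <- box[2] / stride - 0.5
  x1 <- box[3] / stride - 0.5; y1 <- box[4] / stride - 0.5
  bw <- (x1 - x0) / pooled; bh <- (y1 - y0) / pooled
  out <- array(0, c(pooled, pooled, C))
  for (c in seq_len(C))
    for (pi in seq_len(pooled))
      for (pj in seq_len(pooled)) {
        acc <- 0
        for (si in seq_len(sampling))
          for (sj in seq_len(sampling))
            acc <- acc + interp(feature[, , c],
                                y0 + (pi - 1 + (si - 0.5) / sampling) * bh,
                                x0 + (pj - 1 + (sj - 0.5) / sampling) * bw)
        out[pi, pj, c] <- acc / sampling^2
      }
  out
}

# AP by explicit threshold enumeration: precision/recall recomputed from
# scratch at every distinct score, then the all-points envelope integral.
oracle_ap <- function(detections, ground_truth, iou_threshold = 0.5) {
  n_gt <- nrow(ground_truth)
  if (!nrow(detections)) return(0)
  match_at <- function(det) {
    det <- det[order(det$score, decreasing = TRUE), ]
    matched <- rep(FALSE, n_gt)
    tp <- 0
    for (i in seq_len(nrow(det))) {
      cand <- which(!matched & ground_truth$image_id == det$image_id[i])
      if (length(cand)) {
        ious <- vapply(cand, function(j)
          iou(unlist(det[i, c("x_min", "y_min", "x_max", "y_max")]),
              unlist(ground_truth[j, c("x_min", "y_min", "x_max", "y_max")])),
          numeric(1))
        if (max(ious) >= iou_threshold) {
          tp <- tp + 1
          matched[cand[which.max(ious)]] <- TRUE
        }
      }
    }
    c(tp = tp, n = nrow(det))
  }
  pts <- t(vapply(sort(unique(detections$score), decreasing = TRUE),
                  function(thr) match_at(detections[detections$score >= thr, ]),
                  numeric(2)))
  recall <- pts[, "tp"] / n_gt
  precision <- pts[, "tp"] / pts[, "n"]
  p_env <- rev(cummax(rev(precision)))
  r <- c(0, recall)
  sum((r[-1] - r[-length(r)]) * p_env)
}

# AUC as the normalized pairwise Mann-Whitney statistic, ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos)
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# direct evaluation of the four quadrant indicator functions
oracle_quadrant_indicators <- function(y_sag_anat, x_ax, g) {
  up_strict <- y_sag_anat > g$Y_mid
  outside <- x_ax < g$x_Rmid | x_ax > g$x_Lmid
  inside <- x_ax >= g$x_Rmid & x_ax <= g$x_Lmid
  c(outside_up = outside && up_strict,
    outside_down = outside && !up_strict,
    inside_up = inside && up_strict,
    inside_down = inside && !up_strict)
}
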