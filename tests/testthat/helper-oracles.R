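# Independent oracles used by the test suite. These deliberately re-derive
# results through different routes (brute force, enumeration, closed form)
# than the package implementation.

# Brute-force greedy NMS written as repeated scans over a data.frame.
oracle_nms <- function(detections, thr) {
  if (length(detections) == 0L) return(detections)
  df <- data.frame(
    i = seq_along(detections),
    conf = vapply(detections, function(d) d$confidence, 1),
    img = vapply(detections, function(d) as.character(d$image_id), ""))
  kept <- integer(0)
  while (nrow(df) > 0L) {
    top <- df[order(-df$conf, df$i)[1], ]
    kept <- c(kept, top$i)
    drop <- logical(nrow(df))
    for (r in seq_len(nrow(df))) {
      if (df$i[r] == top$i) { drop[r] <- TRUE; next }
      if (df$img[r] != top$img) next
      if (iou(detections[[top$i]]$bbox, detections[[df$i[r]]]$bbox) > thr) {
        drop[r] <- TRUE
      }
    }
    df <- df[!drop, , drop = FALSE]
  }
  detections[kept]
}

# Reference COCO-style AP/AR at a single IoU threshold, computed naively:
# detections sorted by confidence; each matched to the best remaining gt in
# its image; AP by direct 101-point interpolation scanning the full PR lists.
oracle_ap_ar_single <- function(gts, dets, thr, max_det = 100L) {
  n_gt <- length(gts)
  conf <- vapply(dets, function(d) d$confidence, 1)
  img <- vapply(dets, function(d) as.character(d$image_id), "")
  keep <- unlist(lapply(split(seq_along(dets), img), function(ix) {
    ix[order(-conf[ix])][seq_len(min(length(ix), max_det))]
  }), use.names = FALSE)
  keep <- keep[order(-conf[keep])]
  gt_img <- vapply(gts, function(g) as.character(g$image_id), "")
  taken <- rep(FALSE, n_gt)
  tp <- logical(length(keep))
  for (k in seq_along(keep)) {
    d <- dets[[keep[k]]]
    cand <- which(gt_img == as.character(d$image_id) & !taken)
    if (!length(cand)) next
    vals <- vapply(cand, function(g) iou(gts[[g]]$bbox, d$bbox), 1)
    b <- which.max(vals)
    if (vals[b] >= thr) {
      tp[k] <- TRUE
      taken[cand[b]] <- TRUE
    }
  }
  if (!length(keep)) return(c(ap = 0, ar = 0))
  ctp <- cumsum(tp)
  rec <- ctp / n_gt
  prec <- ctp / seq_along(ctp)
  # 101-point interpolation directly from its definition: at recall level r,
  # the interpolated precision is the best precision attained at any
  # operating point whose recall reaches r
  ap <- 0
  for (r in seq(0, 1, by = 0.01)) {
    ok <- rec >= r
    ap <- ap + (if (any(ok)) max(prec[ok]) else 0)
  }
  c(ap = ap / 101, ar = max(rec))
}

oracle_ap_ar <- function(gts, dets, grid = seq(0.5, 0.95, by = 0.05)) {
  per <- vapply(grid, function(t) oracle_ap_ar_single(gts, dets, t), numeric(2))
  c(AP = 100 * mean(per[1, ]), AR = 100 * mean(per[2, ]))
}

# Optimal one-to-one assignment total score (brute force over permutations,
# n <= 6): score = IoU when >= thr else 0.
oracle_assignment_total <- function(gt_boxes, det_boxes, thr = 0.75) {
  ng <- nrow(gt_boxes); nd <- nrow(det_boxes)
  M <- matrix(0, ng, nd)
  for (i in seq_len(ng)) for (j in seq_len(nd)) {
    v <- iou(gt_boxes[i, ], det_boxes[j, ])
    M[i, j] <- if (v >= thr) v else 0
  }
  k <- min(ng, nd)
  best <- 0
  gsub <- utils::combn(seq_len(ng), k)
  dperm <- perms(seq_len(nd))
  for (gc in seq_len(ncol(gsub))) {
    for (p in seq_len(nrow(dperm))) {
      tot <- sum(M[cbind(gsub[, gc], dperm[p, seq_len(k)])])
      if (tot > best) best <- tot
    }
  }
  best
}

perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# Exact two-sided signed-rank p-value by full 2^n enumeration.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  total <- 0
  lo <- 0
  hi <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    w <- sum(r[bits == 1L])
    total <- total + 1
    if (w <= W) lo <- lo + 1
    if (w >= W) hi <- hi + 1
  }
  min(1, 2 * min(lo / total, hi / total))
}

# Projection through an explicit 4x4 homogeneous matrix chain.
oracle_project <- function(points, cam) {
  pos <- synthretarget:::camera_position(cam)
  T1 <- diag(4); T1[1:3, 4] <- -pos
  f <- (cam$target - pos); f <- f / sqrt(sum(f^2))
  up <- c(0, 0, 1)
  r <- c(f[2] * up[3] - f[3] * up[2], f[3] * up[1] - f[1] * up[3],
         f[1] * up[2] - f[2] * up[1])
  r <- r / sqrt(sum(r^2))
  u <- c(r[2] * f[3] - r[3] * f[2], r[3] * f[1] - r[1] * f[3],
         r[1] * f[2] - r[2] * f[1])
  Rw <- rbind(c(r, 0), c(-u, 0), c(f, 0), c(0, 0, 0, 1))
  th <- cam$roll_deg * pi / 180
  Rr <- rbind(c(cos(th), -sin(th), 0, 0), c(sin(th), cos(th), 0, 0),
              c(0, 0, 1, 0), c(0, 0, 0, 1))
  M <- Rr %*% Rw %*% T1
  hp <- M %*% rbind(t(points), 1)
  z <- hp[3, ]
  cbind(x = cam$image_size[1] / 2 + cam$focal_px * hp[1, ] / z,
        y = cam$image_size[2] / 2 + cam$focal_px * hp[2, ] / z,
        depth = z)
}

# random detections for property tests
random_boxes <- function(n, span = 20) {
  cbind(runif(n, 0, span), runif(n, 0, span), runif(n, 1, 8), runif(n, 1, 8))
}

random_detections <- function(n, images = 1:2, span = 20) {
  lapply(seq_len(n), function(i) {
    b <- random_boxes(1, span)
    detection(sample(images, 1), as.numeric(b), runif(1))
  })
}
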