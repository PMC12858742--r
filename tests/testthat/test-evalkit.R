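test_that("IoU matches hand geometry", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 1, 1)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 2, 2)), 1 / 7)
  expect_equal(iou(c(0, 0, 0, 0), c(0, 0, 0, 0)), 0) # both empty, by convention
  expect_error(iou(c(0, 0, -1, 2), c(0, 0, 1, 1)), "non-negative")
  # pixel-enumeration oracle on integer boxes
  set.seed(1)
  for (i in 1:25) {
    a <- c(sample(0:10, 2, TRUE), sample(1:8, 2, TRUE))
    b <- c(sample(0:10, 2, TRUE), sample(1:8, 2, TRUE))
    grid <- expand.grid(x = 0:24, y = 0:24)
    inA <- grid$x >= a[1] & grid$x < a[1] + a[3] & grid$y >= a[2] & grid$y < a[2] + a[4]
    inB <- grid$x >= b[1] & grid$x < b[1] + b[3] & grid$y >= b[2] & grid$y < b[2] + b[4]
    expect_equal(iou(a, b), sum(inA & inB) / sum(inA | inB))
  }
})

test_that("confidence filtering keeps order and matches brute force", {
  set.seed(2)
  dets <- random_detections(30)
  expect_identical(filter_confidence(dets, 0), dets)
  hi <- filter_confidence(dets, 1)
  expect_length(hi, sum(vapply(dets, `[[`, 1, "confidence") >= 1))
  at2 <- filter_confidence(dets, 0.2)
  keep <- vapply(dets, function(d) d$confidence >= 0.2, TRUE)
  expect_identical(at2, dets[keep])
  expect_error(filter_confidence(dets, 1.5), "0, 1")
})

test_that("greedy NMS equals the brute-force oracle on random instances", {
  one <- random_detections(1)
  expect_identical(nms(one), one)
  # two identical boxes: only the higher-confidence one survives
  d2 <- list(detection(1, c(0, 0, 4, 4), 0.9), detection(1, c(0, 0, 4, 4), 0.8))
  expect_identical(nms(d2, 0.65), d2[1])
  set.seed(3)
  for (i in 1:20) {
    dets <- random_detections(50, images = 1:3, span = 12)
    got <- nms(dets, 0.65)
    want <- oracle_nms(dets, 0.65)
    expect_identical(got, want)
  }
  # order invariance up to the documented tie-break
  set.seed(4)
  dets <- random_detections(30, images = 1, span = 8)
  perm <- sample(length(dets))
  a <- nms(dets, 0.5)
  b <- nms(dets[perm], 0.5)
  keyfun <- function(l) sort(vapply(l, function(d) paste(round(d$bbox, 9), collapse = ","), ""))
  expect_identical(keyfun(a), keyfun(b))
})

test_that("per-person scoring applies the 0.75 rule and near-optimal matching", {
  cfg <- eval_config()
  gts <- list(coco_annotation(1, 1, c(0, 0, 10, 20)),
              coco_annotation(2, 1, c(30, 0, 10, 20)))
  # perfect detections score 1
  dets <- list(detection(1, c(0, 0, 10, 20), 0.9),
               detection(1, c(30, 0, 10, 20), 0.8))
  sc <- score_persons(gts, dets, cfg)
  expect_equal(sc$score, c(1, 1))
  # a single detection at IoU 0.5 scores 0 despite being matched
  half <- list(detection(1, c(5, 0, 10, 20), 0.9)) # IoU = 1/3
  sc2 <- score_persons(gts[1], half, cfg)
  expect_equal(sc2$matched_iou, 1 / 3)
  expect_equal(sc2$score, 0)
  # unmatched ground truths score 0
  sc3 <- score_persons(gts, list(), cfg)
  expect_equal(sc3$score, c(0, 0))
  # binary variant
  cfgb <- eval_config(score_mode = "binary")
  expect_equal(score_persons(gts, dets, cfgb)$score, c(1, 1))
  # greedy total equals optimal assignment (no threshold-straddling ties)
  set.seed(5)
  tries <- 0
  while (tries < 40) {
    ng <- sample(2:5, 1); nd <- sample(2:5, 1)
    gtb <- random_boxes(ng, span = 10)
    dtb <- gtb[sample(ng, nd, replace = TRUE), , drop = FALSE] +
      matrix(runif(nd * 4, -1.2, 1.2), nd)
    dtb[, 3:4] <- pmax(dtb[, 3:4], 1)
    ious <- as.numeric(synthretarget:::iou_matrix(gtb, dtb))
    if (any(abs(ious - 0.75) < 0.02)) next # skip threshold-straddling cases
    tries <- tries + 1
    gl <- lapply(seq_len(ng), function(i) coco_annotation(i, 1, gtb[i, ]))
    dl <- lapply(seq_len(nd), function(i) detection(1, dtb[i, ], runif(1)))
    got <- sum(score_persons(gl, dl, cfg)$score)
    want <- oracle_assignment_total(gtb, dtb, 0.75)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("improving a matched IoU never lowers any per-person score", {
  cfg <- eval_config()
  set.seed(6)
  for (i in 1:10) {
    gtb <- random_boxes(3, span = 10)
    gl <- lapply(1:3, function(k) coco_annotation(k, 1, gtb[k, ]))
    dl <- lapply(1:3, function(k) {
      detection(1, gtb[k, ] + c(runif(1, 0, 2), 0, 0, 0), 0.5 + 0.1 * k)
    })
    base <- score_persons(gl, dl, cfg)
    # move one detection exactly onto its ground truth
    dl2 <- dl
    dl2[[2]]$bbox <- gtb[2, ]
    better <- score_persons(gl, dl2, cfg)
    expect_true(all(better$score >= base$score - 1e-12))
  }
})

test_that("AP/AR equals the reference implementation on random instances", {
  cfg <- eval_config()
  gts <- list(coco_annotation(1, 1, c(0, 0, 10, 20)),
              coco_annotation(2, 2, c(5, 5, 8, 16)))
  # detections identical to ground truths: AP = AR = 100
  dets <- list(detection(1, c(0, 0, 10, 20), 1), detection(2, c(5, 5, 8, 16), 1))
  s <- ap_ar(gts, dets, cfg)
  expect_equal(s$AP, 100)
  expect_equal(s$AR, 100)
  # no detections: AP = AR = 0
  s0 <- ap_ar(gts, list(), cfg)
  expect_equal(s0$AP, 0)
  expect_equal(s0$AR, 0)
  # no ground truths: undefined, not zero
  su <- ap_ar(list(), dets, cfg)
  expect_true(is.na(su$AP))
  # 3-image toy set with one false positive and one miss
  gts3 <- list(coco_annotation(1, 1, c(0, 0, 10, 10)),
               coco_annotation(2, 2, c(0, 0, 10, 10)),
               coco_annotation(3, 3, c(0, 0, 10, 10)))
  dets3 <- list(detection(1, c(0, 0, 10, 10), 0.95),
                detection(2, c(0.5, 0, 10, 10), 0.9),
                detection(1, c(50, 50, 10, 10), 0.85)) # FP; image 3 missed
  s3 <- ap_ar(gts3, dets3, cfg)
  o3 <- oracle_ap_ar(gts3, dets3)
  expect_equal(s3$AP, unname(o3["AP"]), tolerance = 1e-6)
  expect_equal(s3$AR, unname(o3["AR"]), tolerance = 1e-6)
  # 100 randomised small instances
  set.seed(7)
  for (i in 1:100) {
    ng <- sample(1:6, 1); nd <- sample(0:8, 1)
    gtb <- random_boxes(ng, span = 15)
    gl <- lapply(seq_len(ng), function(k) coco_annotation(k, sample(1:2, 1), gtb[k, ]))
    dl <- if (nd > 0) lapply(seq_len(nd), function(k) {
      src <- gtb[sample(ng, 1), ]
      detection(sample(1:2, 1), pmax(src + runif(4, -2, 2), c(-99, -99, 0.5, 0.5)),
                runif(1))
    }) else list()
    got <- ap_ar(gl, dl, cfg)
    want <- oracle_ap_ar(gl, dl)
    expect_equal(got$AP, unname(want["AP"]), tolerance = 1e-6)
    expect_equal(got$AR, unname(want["AR"]), tolerance = 1e-6)
  }
})

test_that("OKS follows its closed form", {
  kp <- cbind(seq(10, 170, by = 10), seq(10, 170, by = 10), rep(2, 17))
  gt <- coco_annotation(1, 1, c(0, 0, 100, 100), keypoints = kp)
  expect_equal(oks(gt, kp[, 1:2]), 1)
  # one labelled keypoint displaced by d = s * k gives exp(-1/2)
  kp1 <- kp
  kp1[, 3] <- 0
  kp1[1, 3] <- 2
  gt1 <- coco_annotation(1, 1, c(0, 0, 100, 100), keypoints = kp1)
  s <- sqrt(gt1$area)
  k1 <- oks_constants()[["nose"]]
  pred <- kp1[, 1:2]
  pred[1, 1] <- pred[1, 1] + s * k1
  expect_equal(oks(gt1, pred), exp(-1 / 2), tolerance = 1e-12)
  # gross displacement drives OKS to ~0
  predfar <- kp[, 1:2] + 100 * s
  expect_lt(oks(gt, predfar), 1e-6)
  # no labelled keypoints: undefined
  kp0 <- kp; kp0[, 3] <- 0
  gt0 <- coco_annotation(1, 1, c(0, 0, 100, 100), keypoints = kp0)
  expect_true(is.na(oks(gt0, kp0[, 1:2])))
})

test_that("aspect log-ratios hit closed forms and integrate to one", {
  expect_equal(aspect_log_ratio(matrix(c(0, 0, 5, 5), 1))$values, 0)
  expect_equal(aspect_log_ratio(matrix(c(0, 0, 8, 4), 1))$values, log(2))
  expect_error(aspect_log_ratio(matrix(c(0, 0, -2, 4), 1)), "positive")
  set.seed(8)
  b <- random_boxes(500)
  d <- aspect_log_ratio(b)$density
  expect_equal(sum(d$density * d$width), 1, tolerance = 1e-6)
})
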