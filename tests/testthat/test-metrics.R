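# Voxel metrics, instance measurement, detection matching, summaries.

test_that("voxel metrics match their closed forms and degenerate conventions", {
  c1 <- structure(list(tp = 3, fp = 1, fn = 1), class = "voxel_confusion")
  expect_equal(dice(c1), 0.75)
  expect_equal(precision(c1), 0.75)
  expect_equal(vd(c1), 0)
  expect_equal(osr(c1), 0.25)
  expect_equal(usr(c1), 0.25)

  perfect <- structure(list(tp = 10, fp = 0, fn = 0),
                       class = "voxel_confusion")
  expect_equal(dice(perfect), 1)
  expect_equal(vd(perfect), 0)
  expect_equal(osr(perfect), 0)
  expect_equal(usr(perfect), 0)

  empty_pred <- structure(list(tp = 0, fp = 0, fn = 5),
                          class = "voxel_confusion")
  expect_equal(dice(empty_pred), 0)
  expect_equal(usr(empty_pred), 1)
  expect_equal(osr(empty_pred), 0)

  # perfect-negative convention
  nothing <- structure(list(tp = 0, fp = 0, fn = 0),
                       class = "voxel_confusion")
  expect_equal(dice(nothing), 1)
  expect_equal(vd(nothing), 0)
  expect_equal(osr(nothing), 0)
  # empty GT with false positives: OSR/USR undefined
  fp_only <- structure(list(tp = 0, fp = 3, fn = 0),
                       class = "voxel_confusion")
  expect_true(is.na(osr(fp_only)))
  expect_true(is.na(usr(fp_only)))
})

test_that("voxel confusion and metrics agree with brute force on random grids", {
  set.seed(101)
  for (rep in 1:100) {
    d <- sample(3:8, 3, replace = TRUE)
    pred <- array(rbinom(prod(d), 1, runif(1, 0.1, 0.7)), d)
    gt <- array(rbinom(prod(d), 1, runif(1, 0.1, 0.7)), d)
    got <- voxel_confusion(pred, gt)
    want <- oracle_confusion(pred, gt)
    expect_identical(got$tp, want$tp)
    expect_identical(got$fp, want$fp)
    expect_identical(got$fn, want$fn)
    # Eqs. evaluated directly from the counts
    den <- 2 * want$tp + want$fp + want$fn
    if (den > 0) expect_equal(dice(got), 2 * want$tp / den)
    gtn <- want$tp + want$fn
    if (gtn > 0) {
      expect_equal(osr(got), want$fp / gtn)
      expect_equal(usr(got), want$fn / gtn)
      # OSR + USR identity
      expect_equal(osr(got) + usr(got), (want$fp + want$fn) / gtn)
    }
  }
})

test_that("dice = 1 iff vd, osr, usr are all zero", {
  set.seed(7)
  for (rep in 1:50) {
    cf <- structure(list(tp = sample(0:20, 1), fp = sample(0:5, 1),
                         fn = sample(0:5, 1)), class = "voxel_confusion")
    if (cf$tp + cf$fp + cf$fn == 0) next
    if (dice(cf) == 1) {
      expect_equal(vd(cf), 0)
      expect_equal(osr(cf), 0)
      expect_equal(usr(cf), 0)
    } else {
      expect_true(vd(cf) > 0 || osr(cf) > 0 || usr(cf) > 0)
    }
  }
})

test_that("size categories honour the TNM boundaries", {
  expect_equal(size_category(4.0), "small")
  expect_equal(size_category(4.05), "medium")
  expect_equal(size_category(7.0), "medium")
  expect_equal(size_category(7.01), "large")
  expect_equal(size_subcategory(c(1.5, 2.0, 2.5, 3.5, 5)),
               c("<=2", "<=2", ">2-<=3", ">3-<=4", NA))
})

test_that("tumor diameter is the in-plane extent, not the height", {
  # single voxel at 1 mm: one-voxel extent convention
  idx <- matrix(c(5L, 5L, 5L), 1)
  expect_equal(tumor_diameter(idx, c(1, 1, 1)), 0.1)

  # axial disk of radius 15 voxels at 1 mm -> 3.0 cm
  co <- expand.grid(x = 1:41, y = 1:41)
  disk <- co[(co$x - 21)^2 + (co$y - 21)^2 <= 15^2, ]
  idx <- cbind(as.integer(disk$x), as.integer(disk$y), 7L)
  expect_equal(tumor_diameter(idx, c(1, 1, 1)), 3.0, tolerance = 0.02)

  # tall thin craniocaudal cylinder: diameter ignores the z extent
  cyl <- do.call(rbind, lapply(1:40, function(z)
    cbind(as.integer(disk$x[1:5]), as.integer(disk$y[1:5]), as.integer(z))))
  d_cyl <- tumor_diameter(cyl, c(1, 1, 1))
  d_slice <- tumor_diameter(cyl[cyl[, 3] == 1, , drop = FALSE], c(1, 1, 1))
  expect_equal(d_cyl, d_slice)
  expect_lt(d_cyl, 1.0)
  # the 3D Feret alternative does see the height
  expect_gt(tumor_diameter(cyl, c(1, 1, 1), mode = "feret3d"), 3.5)
})

test_that("instance components label 26-connected blobs and drop noise", {
  dims <- c(20L, 20L, 20L)
  arr <- array(0L, dims)
  arr[3:6, 3:6, 3:6] <- 1L            # 64 voxels
  arr[15:16, 15:16, 15:16] <- 1L      # 8 voxels
  arr[10, 1, 1] <- 1L                 # single-voxel noise
  inst <- instance_components(arr, spacing = c(1, 1, 1), min_voxels = 5L)
  expect_length(inst, 2L)
  expect_equal(sort(vapply(inst, function(i) i$n_voxels, 0L)), c(8L, 64L))
  expect_length(instance_components(array(0L, dims), spacing = c(1, 1, 1)), 0L)
  # diagonal touch merges under 26-connectivity
  arr2 <- array(0L, c(6L, 6L, 6L))
  arr2[1:2, 1:2, 1:2] <- 1L
  arr2[3, 3, 3] <- 1L
  inst2 <- instance_components(arr2, spacing = c(1, 1, 1), min_voxels = 1L)
  expect_length(inst2, 1L)
})

test_that("two overlapping cubes give IoU 32/96, detected at 0.25 not 0.35", {
  dims <- c(12L, 12L, 12L)
  gt_arr <- array(0L, dims); gt_arr[1:4, 1:4, 1:4] <- 1L
  pr_arr <- array(0L, dims); pr_arr[3:6, 1:4, 1:4] <- 1L
  gt <- instance_components(gt_arr, c(1, 1, 1), min_voxels = 1L)
  pr <- instance_components(pr_arr, c(1, 1, 1), min_voxels = 1L)
  det25 <- match_detections(gt, pr, dims, iou_threshold = 0.25)
  expect_equal(det25$matches$iou, 32 / 96)
  expect_equal(det25$detected_gt_ids, 1L)
  expect_length(det25$unmatched_pred_ids, 0L)
  det35 <- match_detections(gt, pr, dims, iou_threshold = 0.35)
  expect_length(det35$detected_gt_ids, 0L)
  expect_equal(det35$unmatched_pred_ids, 1L)
})

test_that("matching is one-to-one, greedy by IoU, and monotone in threshold", {
  dims <- c(16L, 16L, 16L)
  gt_arr <- array(0L, dims)
  gt_arr[2:5, 2:5, 2:5] <- 1L
  gt_arr[10:13, 10:13, 10:13] <- 1L
  pr_arr <- array(0L, dims)
  pr_arr[3:6, 2:5, 2:5] <- 1L     # overlaps gt 1
  pr_arr[10:12, 10:13, 10:13] <- 1L  # overlaps gt 2
  pr_arr[1:2, 14:16, 1:2] <- 1L   # pure FP
  gt <- instance_components(gt_arr, c(1, 1, 1), min_voxels = 1L)
  pr <- instance_components(pr_arr, c(1, 1, 1), min_voxels = 1L)
  prev <- Inf
  for (thr in c(0.05, 0.25, 0.5, 0.9)) {
    det <- match_detections(gt, pr, dims, iou_threshold = thr)
    expect_lte(length(det$detected_gt_ids), prev)
    prev <- length(det$detected_gt_ids)
    expect_equal(anyDuplicated(det$matches$pred_id), 0L)
    expect_equal(anyDuplicated(det$matches$gt_id), 0L)
    expect_true(all(det$matches$iou >= thr))
  }
  det <- match_detections(gt, pr, dims, iou_threshold = 0.25)
  expect_length(det$detected_gt_ids, 2L)
  expect_length(det$unmatched_pred_ids, 1L)
})

test_that("cohort summary reproduces a hand-computed table", {
  dims <- c(24L, 24L, 24L)
  # case 1: one small GT tumor, detected exactly; one small FP blob
  gt1 <- array(0L, dims); gt1[4:9, 4:9, 4:9] <- 2L
  pr1 <- gt1; pr1[16:19, 16:19, 16:19] <- 2L
  # case 2: one small GT tumor, missed entirely
  gt2 <- array(0L, dims); gt2[10:14, 10:14, 10:14] <- 2L
  pr2 <- array(0L, dims)
  sp <- c(1, 1, 1)
  cases <- list(
    evaluate_case(label_mask(pr1, sp), label_mask(gt1, sp)),
    evaluate_case(label_mask(pr2, sp), label_mask(gt2, sp)))
  rep <- summarize_evaluation(cases)
  small <- rep$per_category[rep$per_category$category == "small", ]
  expect_equal(small$n_gt, 2L)
  expect_equal(small$n_detected, 1L)
  expect_equal(small$sensitivity, 0.5)
  expect_equal(small$n_fp, 1L)
  expect_equal(small$fpc, 0.5)          # 1 FP over 2 patients
  expect_equal(small$dice_mean, 1)      # the one detected tumor is exact
  # 3 FPs over 2 patients -> FPC 1.5
  pr1b <- pr1
  pr1b[16:19, 1:4, 1:4] <- 2L
  pr1b[1:4, 16:19, 16:19] <- 2L
  cases_b <- list(
    evaluate_case(label_mask(pr1b, sp), label_mask(gt1, sp)),
    evaluate_case(label_mask(pr2, sp), label_mask(gt2, sp)))
  rep_b <- summarize_evaluation(cases_b)
  expect_equal(sum(rep_b$per_category$n_fp), 3L)
  expect_equal(sum(rep_b$per_category$fpc), 1.5)
  # undetected-as-zero mode pulls the mean down
  rep0 <- summarize_evaluation(cases, undetected_zero = TRUE)
  small0 <- rep0$per_category[rep0$per_category$category == "small", ]
  expect_equal(small0$dice_mean, 0.5)
})

test_that("evaluation CSV has the documented schema", {
  dims <- c(16L, 16L, 16L)
  gt <- array(0L, dims); gt[4:9, 4:9, 4:9] <- 2L
  sp <- c(1, 1, 1)
  rep <- summarize_evaluation(list(
    evaluate_case(label_mask(gt, sp), label_mask(gt, sp))))
  f <- tempfile(fileext = ".csv")
  out <- write_evaluation_csv(rep, f)
  expect_true(file.exists(f))
  got <- utils::read.csv(f)
  expect_identical(names(got),
                   c("case_id", "category", "n_gt", "n_detected", "n_fp",
                     "dice_mean", "dice_sd", "precision", "vd", "osr", "usr"))
})

test_that("paired Dice comparison behaves like a signed-rank test", {
  a <- seq(0.5, 0.9, length.out = 20)
  expect_equal(compare_dice(a, a), 1)
  expect_lt(compare_dice(a, a + 0.2), 0.01)
  # pairing invariance: permuting the pairs leaves p unchanged
  set.seed(5)
  b <- a + rnorm(20, 0.05, 0.05)
  p1 <- compare_dice(a, b)
  perm <- sample(20)
  expect_equal(compare_dice(a[perm], b[perm]), p1)
  expect_error(compare_dice(a, b[-1]), "equal length")
})
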