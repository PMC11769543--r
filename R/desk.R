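# A complete desk-scale experiment: CPU-sized cohorts, networks and
# training schedules that exercise the full dual-stage pipeline end to end.
# The paper-scale presets (six-stage tumor net, 192x128x128 patches) are
# configuration; this preset is sized for a single CPU.

#' Desk-scale training presets
#'
#' Stage one trains the pure-CNN backend (widths 8/16/32) on 32^3 patches
#' with AdamW; stage two trains a three-stage tumor net (widths 8/16/32,
#' attention gates on) on 24^3 patches of the expanded kidney-region VOIs
#' with nesterov SGD and polynomial learning-rate decay. Both use DiceCE.
#'
#' @param stage `"organ"` or `"tumor"`.
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @return A [train_config()].
#' @export
desk_train_config <- function(stage = c("tumor", "organ"), epochs = NULL,
                              seed = 1L) {
  stage <- match.arg(stage)
  if (stage == "organ") {
    train_config(stage = "organ", epochs = epochs %||% 10L,
                 patch_size = c(32L, 32L, 32L), batch_size = 2L,
                 patches_per_volume = 1L, lr = 3e-3, seed = seed)
  } else {
    train_config(stage = "tumor", epochs = epochs %||% 25L,
                 patch_size = c(24L, 24L, 24L), batch_size = 2L,
                 patches_per_volume = 1L, lr = 0.01, seed = seed)
  }
}

#' Desk-scale network configurations
#' @return A list with `organ` ([organ_net_config()], CNN backend) and
#'   `tumor` ([tumor_net_config()], three stages).
#' @export
desk_net_configs <- function() {
  list(organ = organ_net_config(backend = "cnn",
                                cnn_channels = c(8L, 16L, 32L),
                                cnn_blocks = c(1L, 1L, 1L)),
       tumor = tumor_net_config(n_stages = 3L, channels = c(8L, 16L, 32L),
                                residual_blocks = c(1L, 1L, 1L),
                                patch_size = c(24L, 24L, 24L),
                                batch_size = 2L))
}

#' Train both stages on an easy phantom cohort and segment held-out cases
#'
#' Simulates `n_train` + `n_test` easy desk phantoms (64^3 at 1 mm), freezes
#' pooled intensity statistics on the training cohort, trains stage one on
#' the kidney region and stage two on expanded VOI crops, then runs the
#' dual-stage pipeline on the held-out cases.
#'
#' @param n_train,n_test Cohort sizes.
#' @param seed Seed controlling simulation, initialization and sampling.
#' @param epochs_organ,epochs_tumor Training epochs per stage.
#' @param difficulty Passed to [generate_cohort()].
#' @return A list: `organ_net`, `tumor_net`, `stats`, `train_logs`,
#'   `test_cases` (preprocessed vol/mask pairs), `predictions`
#'   (list of `case_prediction`), `dice` (data.frame with per-case kidney
#'   and tumor Dice on the isotropic grid).
#' @export
run_desk_experiment <- function(n_train = 40L, n_test = 10L, seed = 1L,
                                epochs_organ = 10L, epochs_tumor = 25L,
                                difficulty = "easy") {
  cohort <- generate_cohort(n_train + n_test, difficulty = difficulty,
                            seed = seed, preset = "desk")
  stats <- compute_intensity_stats(
    lapply(cohort$cases[seq_len(n_train)], `[[`, "vol"))
  prep <- function(cs) {
    pre <- preprocess_case(cs$vol, stats, cs$mask)
    list(vol = pre$vol, mask = pre$mask)
  }
  train_cases <- lapply(cohort$cases[seq_len(n_train)], prep)
  test_raw <- cohort$cases[n_train + seq_len(n_test)]
  test_cases <- lapply(test_raw, prep)
  nets <- desk_net_configs()
  organ_net <- build_organ_net(nets$organ, seed = seed + 1L)
  organ_fit <- train_stage(organ_net, train_cases,
                           desk_train_config("organ", epochs_organ,
                                             seed = seed + 2L))
  crops <- voi_training_crops(train_cases,
                              min_extent = nets$tumor$patch_size)
  tumor_net <- build_tumor_net(nets$tumor, seed = seed + 3L)
  tumor_fit <- train_stage(tumor_net, crops,
                           desk_train_config("tumor", epochs_tumor,
                                             seed = seed + 4L))
  pcfg <- pipeline_config()
  # the pipeline preprocesses internally, so it gets the native-grid volume
  predictions <- lapply(test_raw, function(cs)
    run_dual_stage(cs$vol, organ_net, tumor_net, stats, pcfg))
  dice_rows <- lapply(seq_along(test_cases), function(i) {
    gt <- test_cases[[i]]$mask
    pr <- predictions[[i]]
    data.frame(
      case = i,
      kidney_dice = dice(voxel_confusion(pr$kidney_mask$data != 0,
                                         gt$data > 0)),
      tumor_dice = dice(voxel_confusion(pr$tumor_mask$data != 0,
                                        gt$data == 2L)))
  })
  list(organ_net = organ_net, tumor_net = tumor_net, stats = stats,
       train_logs = list(organ = organ_fit$log, tumor = tumor_fit$log),
       test_cases = test_cases, test_raw = test_raw,
       predictions = predictions, dice = do.call(rbind, dice_rows))
}

#' Compare single-stage and dual-stage false-positive behaviour
#'
#' Runs the trained stage-two network both inside stage-one VOIs (dual
#' stage) and over the whole volume (single stage) on a cohort containing
#' the bright spine decoy, then counts false-positive tumor instances per
#' patient in each mode.
#'
#' @param experiment A [run_desk_experiment()] result.
#' @param iou_threshold Object-wise detection threshold.
#' @return A list with `fpc_ds`, `fpc_ss`, `outside_voi_voxels` (dual-stage
#'   tumor voxels outside every VOI, zero by construction), and the per-mode
#'   evaluation reports.
#' @export
compare_ss_ds <- function(experiment, iou_threshold = 0.25) {
  pcfg <- pipeline_config()
  eval_mode <- function(preds) {
    cases <- lapply(seq_along(experiment$test_cases), function(i)
      evaluate_case(preds[[i]]$tumor_mask, experiment$test_cases[[i]]$mask,
                    iou_threshold = iou_threshold))
    summarize_evaluation(cases)
  }
  ds_preds <- experiment$predictions
  ss_preds <- lapply(experiment$test_raw, function(cs)
    run_single_stage(cs$vol, experiment$tumor_net, experiment$stats, pcfg))
  outside <- vapply(ds_preds, function(pr) {
    tum <- which(pr$tumor_mask$data != 0L, arr.ind = TRUE) - 1L
    if (nrow(tum) == 0L) return(0L)
    inside <- rep(FALSE, nrow(tum))
    for (v in pr$vois) {
      inside <- inside |
        (tum[, 1] >= v$start[1] & tum[, 1] < v$stop[1] &
           tum[, 2] >= v$start[2] & tum[, 2] < v$stop[2] &
           tum[, 3] >= v$start[3] & tum[, 3] < v$stop[3])
    }
    sum(!inside)
  }, 0L)
  ds_rep <- eval_mode(ds_preds)
  ss_rep <- eval_mode(ss_preds)
  list(fpc_ds = sum(ds_rep$per_category$n_fp) / ds_rep$n_patients,
       fpc_ss = sum(ss_rep$per_category$n_fp) / ss_rep$n_patients,
       outside_voi_voxels = sum(outside),
       ds_report = ds_rep, ss_report = ss_rep)
}
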