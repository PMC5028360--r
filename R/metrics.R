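#' Pixel confusion counts between a predicted and a ground-truth mask
#'
#' @param pred predicted binary mask.
#' @param gt ground-truth binary mask, same shape.
#' @return list with `tp`, `fp`, `fn`, `tn`, `gt_area`, `pred_area`.
#' @export
confusion_counts <- function(pred, gt) {
  pred <- binary_mask(pred); gt <- binary_mask(gt)
  if (!all(dim(pred) == dim(gt))) stop("confusion_counts: shape mismatch")
  tp <- sum(pred & gt)
  fp <- sum(pred & !gt)
  fn <- sum(!pred & gt)
  tn <- sum(!pred & !gt)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       gt_area = tp + fn, pred_area = tp + fp)
}

#' Overlap metrics for one mask pair
#'
#' Rates follow the conventions of the dermoscopy segmentation literature:
#' * `tdr` (true detection rate) = `tp / #GT`
#' * `fpr` = `fp / #GT` — note the denominator is the ground-truth area,
#'   not the background area; the standard fall-out `fp / (fp + tn)` is
#'   reported separately as `fallout`.
#' * `fnr` = `fn / #GT`, so `tdr + fnr = 1`.
#' * `tnr` = `tn / (tn + fp)` and `tpr` = `tp / (tp + fn)`, the standard
#'   confusion-matrix forms. (The source formulas for TNR/TPR as printed
#'   duplicate TDR and use complements — evident typesetting slips — so the
#'   standard definitions are used.)
#' * `ep` (error probability) = `(fallout + fnr) / (tpr + fallout + tnr +
#'   fnr)`, with all four terms the standard rates, so `ep` lies in `[0, 1]`.
#' * `dice` = `2 tp / (pred_area + gt_area)`.
#'
#' All returned rates are fractions in `[0, 1]`; [evaluate_batch()] reports
#' them in percent.
#'
#' @param pred predicted binary mask.
#' @param gt ground-truth binary mask (non-empty).
#' @param image_id optional label carried into reports.
#' @return object of class `"eval_record"`: list of rates plus `counts` and
#'   `image_id`.
#' @export
evaluate_masks <- function(pred, gt, image_id = NA_character_) {
  cc <- confusion_counts(pred, gt)
  if (cc$gt_area == 0) stop("evaluate_masks: ground truth empty")
  fallout <- if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else 0
  tnr <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else 0
  tpr <- cc$tp / cc$gt_area
  fnr <- cc$fn / cc$gt_area
  structure(list(
    tdr = cc$tp / cc$gt_area,
    fpr = cc$fp / cc$gt_area,
    fallout = fallout,
    fnr = fnr,
    tnr = tnr,
    tpr = tpr,
    ep = (fallout + fnr) / (tpr + fallout + tnr + fnr),
    dice = if (cc$pred_area + cc$gt_area > 0)
      2 * cc$tp / (cc$pred_area + cc$gt_area) else 0,
    counts = cc,
    image_id = image_id
  ), class = "eval_record")
}

#' @export
print.eval_record <- function(x, ...) {
  cat(sprintf("TDR %.2f%%  FPR %.2f%%  EP %.4f  DICE %.2f%%\n",
              100 * x$tdr, 100 * x$fpr, x$ep, 100 * x$dice))
  invisible(x)
}

#' Evaluate a batch of mask pairs
#'
#' @param pairs list of lists/length-3 lists with elements `pred`, `gt` and
#'   optionally `image_id`.
#' @return object of class `"eval_report"`: list with `records` (a
#'   data.frame in percent: columns image_id, tdr, fpr, fallout, fnr, tnr,
#'   tpr, ep, dice), `atdr`, `afpr`, `aep`, `mean_dice` (percent scale; `ep`
#'   is averaged on its natural scale times 100), and `failed` (character
#'   vector of pair ids that errored and were excluded from the averages).
#' @export
evaluate_batch <- function(pairs) {
  if (length(pairs) < 1L) stop("evaluate_batch: need at least one pair")
  rows <- list(); failed <- character()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    id <- if (!is.null(p$image_id)) p$image_id else sprintf("case_%03d", i)
    rec <- tryCatch(evaluate_masks(p$pred, p$gt, id), error = function(e) e)
    if (inherits(rec, "error")) {
      failed <- c(failed, id)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = id,
      tdr = 100 * rec$tdr, fpr = 100 * rec$fpr, fallout = 100 * rec$fallout,
      fnr = 100 * rec$fnr, tnr = 100 * rec$tnr, tpr = 100 * rec$tpr,
      ep = 100 * rec$ep, dice = 100 * rec$dice,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("evaluate_batch: every pair failed")
  records <- do.call(rbind, rows)
  structure(list(records = records,
                 atdr = mean(records$tdr),
                 afpr = mean(records$fpr),
                 aep = mean(records$ep),
                 mean_dice = mean(records$dice),
                 failed = failed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d image(s)%s\n", nrow(x$records),
              if (length(x$failed)) sprintf(" (%d failed)", length(x$failed)) else ""))
  cat(sprintf("  ATDR %.2f%%  AFPR %.2f%%  AEP %.4f  mean DICE %.2f%%\n",
              x$atdr, x$afpr, x$aep, x$mean_dice))
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row per image plus a footer row `AVERAGE` with ATDR / AFPR / AEP /
#' mean DICE.
#'
#' @param report [evaluate_batch()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  df <- report$records
  footer <- df[1, ]
  footer$image_id <- "AVERAGE"
  for (col in setdiff(names(df), "image_id")) footer[[col]] <- mean(df[[col]])
  utils::write.csv(rbind(df, footer), path, row.names = FALSE)
  invisible(path)
}
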