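#' Match predicted against ground-truth instances at an IoU threshold
#'
#' Candidate pairs are all (predicted, ground-truth) cells whose 3D
#' voxel-support IoU strictly exceeds `t`. A one-to-one matching is built
#' greedily in descending IoU order (ties broken by ascending predicted,
#' then ground-truth label); for `t >= 0.5` each instance admits at most
#' one candidate partner, so the greedy matching is the optimal one.
#'
#' @param pred,gt Label volumes of equal dimensions.
#' @param t IoU threshold in `[0, 1)`.
#' @return A list with `threshold`, counts `tp`, `fp`, `fn`, and
#'   `matches` (data frame of pred label, gt label, IoU).
#' @export
match_instances <- function(pred, gt, t) {
  pred <- as_label_volume(pred)
  gt <- as_label_volume(gt)
  if (!all(dim(pred) == dim(gt))) stop("volumes must share dimensions")
  if (t < 0 || t >= 1) stop("t must lie in [0, 1)")
  pl <- sort(setdiff(unique(as.vector(pred)), 0L))
  gl <- sort(setdiff(unique(as.vector(gt)), 0L))
  empty <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  if (!length(pl) || !length(gl)) {
    return(list(threshold = t, tp = 0L, fp = length(pl), fn = length(gl),
                matches = empty))
  }
  sp <- stats::setNames(tabulate(match(pred, pl), length(pl)), pl)
  sg <- stats::setNames(tabulate(match(gt, gl), length(gl)), gl)
  sel <- pred != 0L & gt != 0L
  cand <- empty
  if (any(sel)) {
    inter <- table(factor(pred[sel], levels = pl), factor(gt[sel], levels = gl))
    pos <- which(inter > 0, arr.ind = TRUE)
    if (nrow(pos)) {
      I <- inter[pos]
      p <- pl[pos[, 1]]; g <- gl[pos[, 2]]
      iou <- I / (sp[as.character(p)] + sg[as.character(g)] - I)
      keep <- iou > t
      cand <- data.frame(pred = p[keep], gt = g[keep], iou = iou[keep])
    }
  }
  cand <- cand[order(-cand$iou, cand$pred, cand$gt), , drop = FALSE]
  used_p <- integer(0); used_g <- integer(0)
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$pred[i] %in% used_p) && !(cand$gt[i] %in% used_g)) {
      take[i] <- TRUE
      used_p <- c(used_p, cand$pred[i])
      used_g <- c(used_g, cand$gt[i])
    }
  }
  matches <- cand[take, , drop = FALSE]
  rownames(matches) <- NULL
  tp <- nrow(matches)
  list(threshold = t, tp = tp, fp = length(pl) - tp, fn = length(gl) - tp,
       matches = matches)
}

#' Precision, recall, AP and mAP from per-threshold match results
#'
#' Applies the instance-level formulas `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)` and `AP = TP / (TP + FN + FP)` to each
#' result, reporting degenerate `0/0` ratios as 0. The mean average
#' precision averages AP over the thresholds 0.25, 0.5 and 0.75, which
#' must all be present.
#'
#' @param results A list of [match_instances()] results.
#' @return A list with `per_threshold` (data frame) and `map`.
#' @export
metric_report <- function(results) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(threshold = r$threshold, tp = r$tp, fp = r$fp, fn = r$fn,
               precision = safe(r$tp, r$tp + r$fp),
               recall = safe(r$tp, r$tp + r$fn),
               ap = safe(r$tp, r$tp + r$fn + r$fp))
  }))
  df <- df[order(df$threshold), , drop = FALSE]
  rownames(df) <- NULL
  map_t <- c(0.25, 0.5, 0.75)
  if (!all(map_t %in% df$threshold)) {
    stop("mAP requires results at thresholds 0.25, 0.5 and 0.75")
  }
  list(per_threshold = df, map = mean(df$ap[match(map_t, df$threshold)]))
}

#' One-call instance-level evaluation of a segmentation
#'
#' Convenience wrapper: runs [match_instances()] at each threshold and
#' summarizes with [metric_report()].
#'
#' @param pred,gt Label volumes of equal dimensions.
#' @param thresholds IoU thresholds; the default is the standard
#'   `{0.25, 0.5, 0.75}` grid over which mAP is averaged.
#' @return See [metric_report()].
#' @export
evaluate_segmentation <- function(pred, gt, thresholds = c(0.25, 0.5, 0.75)) {
  metric_report(lapply(thresholds, function(t) match_instances(pred, gt, t)))
}
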