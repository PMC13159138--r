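# instance areas and pairwise overlap counts between two label images
.overlap_table <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)))
    stop("predicted (", paste(dim(pred), collapse = "x"), ") and reference (",
         paste(dim(ref), collapse = "x"), ") mask shapes differ")
  p <- as.integer(pred); r <- as.integer(ref)
  pid <- sort(unique(p[p > 0L])); rid <- sort(unique(r[r > 0L]))
  parea <- tabulate(p, nbins = max(p, 1L))
  rarea <- tabulate(r, nbins = max(r, 1L))
  both <- p > 0L & r > 0L
  ov <- data.frame(pred_id = integer(), ref_id = integer(),
                   inter = integer(), iou = numeric())
  if (any(both)) {
    key <- paste(p[both], r[both])
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
    ov <- data.frame(pred_id = as.integer(parts[, 1L]),
                     ref_id = as.integer(parts[, 2L]),
                     inter = as.integer(cnt))
    ov$iou <- ov$inter /
      (parea[ov$pred_id] + rarea[ov$ref_id] - ov$inter)
  }
  list(pred_ids = pid, ref_ids = rid, overlaps = ov)
}

#' Binary-foreground Dice coefficient
#'
#' `2 |P & R| / (|P| + |R|)` over non-background pixels, irrespective of
#' instance labels. Two empty masks score 1.0 by convention.
#'
#' @param pred,ref integer label images, same shape.
#' @return Dice score in \[0, 1\].
#' @export
diceScore <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("mask shapes differ")
  p <- pred > 0; r <- ref > 0
  denom <- sum(p) + sum(r)
  if (denom == 0L) return(1.0)
  2 * sum(p & r) / denom
}

#' Match predicted to reference instances by IoU
#'
#' Candidate pairs are those with IoU strictly above `iou_threshold`. At
#' thresholds >= 0.5 the matching is provably one-to-one; below, pairs are
#' accepted greedily by descending IoU with each instance used at most once.
#' Unmatched predictions are false positives, unmatched references false
#' negatives.
#'
#' @param pred,ref integer label images.
#' @param iou_threshold matching threshold in (0, 1); default 0.5.
#' @return list: `matches` (data.frame `pred_id`, `ref_id`, `iou`), `fp_ids`,
#'   `fn_ids`, `n_pred`, `n_ref`.
#' @export
matchInstances <- function(pred, ref, iou_threshold = 0.5) {
  ot <- .overlap_table(pred, ref)
  cand <- ot$overlaps[ot$overlaps$iou > iou_threshold, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$pred_id, cand$ref_id), , drop = FALSE]
  keep <- logical(nrow(cand))
  used_p <- integer(); used_r <- integer()
  for (i in seq_len(nrow(cand))) {
    if (!(cand$pred_id[i] %in% used_p) && !(cand$ref_id[i] %in% used_r)) {
      keep[i] <- TRUE
      used_p <- c(used_p, cand$pred_id[i])
      used_r <- c(used_r, cand$ref_id[i])
    }
  }
  m <- cand[keep, c("pred_id", "ref_id", "iou"), drop = FALSE]
  rownames(m) <- NULL
  list(matches = m,
       fp_ids = setdiff(ot$pred_ids, m$pred_id),
       fn_ids = setdiff(ot$ref_ids, m$ref_id),
       n_pred = length(ot$pred_ids), n_ref = length(ot$ref_ids))
}

#' Panoptic Quality
#'
#' `PQ = sum(TP IoU) / (|TP| + |FP|/2 + |FN|/2)` with matching at IoU > 0.5;
#' also returns the segmentation-quality (mean TP IoU) and
#' recognition-quality factors with `PQ = SQ * RQ`. Two instance-free masks
#' score 1.0 by convention.
#'
#' @param pred,ref integer label images.
#' @return list: `pq`, `sq`, `rq`, `tp`, `fp`, `fn`.
#' @export
panopticQuality <- function(pred, ref) {
  mt <- matchInstances(pred, ref, 0.5)
  tp <- nrow(mt$matches); fp <- length(mt$fp_ids); fn <- length(mt$fn_ids)
  if (mt$n_pred == 0L && mt$n_ref == 0L)
    return(list(pq = 1.0, sq = 1.0, rq = 1.0, tp = 0L, fp = 0L, fn = 0L))
  denom <- tp + fp / 2 + fn / 2
  pq <- if (denom > 0) sum(mt$matches$iou) / denom else 0
  list(pq = pq,
       sq = if (tp) mean(mt$matches$iou) else 0,
       rq = if (denom > 0) tp / denom else 0,
       tp = tp, fp = fp, fn = fn)
}

#' SoftPQ: Panoptic Quality with partial credit for sub-threshold overlaps
#'
#' Pairs are matched greedily by descending IoU above `low_threshold`. Pairs
#' with IoU > `high_threshold` count as full true positives (credit = IoU);
#' pairs with `low_threshold < IoU <= high_threshold` contribute sublinear
#' partial credit `w * IoU` with `w = sqrt(IoU / high_threshold)`, their
#' unit of denominator mass split `w` toward the TP role and `1 - w` toward
#' the FP/FN penalty (so partial matches reduce the penalty a hard PQ would
#' charge). With `low = high = 0.5` the score reduces bit-exactly to PQ.
#'
#' @param pred,ref integer label images.
#' @param low_threshold minimum IoU for any credit; default 0.05.
#' @param high_threshold IoU at and below which credit is partial; default
#'   0.5.
#' @return SoftPQ score in \[0, 1\].
#' @export
softPQ <- function(pred, ref, low_threshold = 0.05, high_threshold = 0.5) {
  if (low_threshold <= 0 || low_threshold > high_threshold ||
      high_threshold > 0.5)
    stop("need 0 < low_threshold <= high_threshold <= 0.5")
  mt <- matchInstances(pred, ref, low_threshold)
  if (mt$n_pred == 0L && mt$n_ref == 0L) return(1.0)
  iou <- mt$matches$iou
  full <- iou > high_threshold
  w <- sqrt(iou[!full] / high_threshold)
  num <- sum(iou[full]) + sum(w * iou[!full])
  denom <- sum(full) + length(w) +  # each match carries unit mass
    length(mt$fp_ids) / 2 + length(mt$fn_ids) / 2
  if (denom <= 0) return(0)
  num / denom
}

#' Mean average precision over an IoU threshold sweep
#'
#' Label masks carry no detection confidences, so at each threshold tau the
#' average precision takes the score-free instance form
#' `AP = TP / (TP + FP + FN)` with matching at IoU > tau; mAP is the mean
#' over the threshold vector (default 0.50, 0.55, ..., 0.95). Two
#' instance-free masks score 1.0 by convention.
#'
#' @param pred,ref integer label images.
#' @param thresholds IoU thresholds; default `seq(0.5, 0.95, by = 0.05)`.
#' @return mAP in \[0, 1\].
#' @export
meanAveragePrecision <- function(pred, ref,
                                 thresholds = seq(0.5, 0.95, by = 0.05)) {
  ot <- .overlap_table(pred, ref)
  if (!length(ot$pred_ids) && !length(ot$ref_ids)) return(1.0)
  ap <- vapply(thresholds, function(tau) {
    mt <- matchInstances(pred, ref, tau)
    tp <- nrow(mt$matches)
    tp / (tp + length(mt$fp_ids) + length(mt$fn_ids))
  }, 0)
  mean(ap)
}

#' Evaluate a set of predicted/reference mask pairs
#'
#' Computes Dice, PQ, SoftPQ and mAP per image and summarizes each metric
#' with its mean and population standard deviation (a single pair reports
#' SD 0 with `sd_degenerate = TRUE`).
#'
#' @param pairs list of `list(pred = , ref = )` label-image pairs (named or
#'   unnamed elements in that order).
#' @param soft_low,soft_high SoftPQ thresholds.
#' @return data.frame of per-image scores (`image`, `dice`, `pq`, `soft_pq`,
#'   `map`) with a `summary` attribute holding `mean`, `sd` and
#'   `sd_degenerate`.
#' @export
evaluateSegSet <- function(pairs, soft_low = 0.05, soft_high = 0.5) {
  if (!length(pairs)) stop("need at least one mask pair")
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    pred <- pr$pred %||% pr[[1L]]
    ref <- pr$ref %||% pr[[2L]]
    nm <- names(pairs)[i]
    data.frame(image = if (is.null(names(pairs)) || !nzchar(nm))
                 as.character(i) else nm,
               dice = diceScore(pred, ref),
               pq = panopticQuality(pred, ref)$pq,
               soft_pq = softPQ(pred, ref, soft_low, soft_high),
               map = meanAveragePrecision(pred, ref))
  })
  scores <- do.call(rbind, rows)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  metrics <- c("dice", "pq", "soft_pq", "map")
  attr(scores, "summary") <- list(
    mean = vapply(scores[metrics], mean, 0),
    sd = vapply(scores[metrics], pop_sd, 0),
    sd_degenerate = nrow(scores) < 2L)
  scores
}
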