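#' Dice score and Jaccard index of two binary masks
#'
#' `dice = 2|A n B| / (|A| + |B|)`, `jaccard = |A n B| / |A u B|`; both are
#' missing when both masks are empty.
#'
#' @param pred_mask,true_mask Logical (or 0/1) matrices of identical shape.
#' @return One-row tibble with `dice` and `jaccard`.
#' @export
dice_jaccard <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask))) stop("mask shapes differ")
  a <- pred_mask > 0; b <- true_mask > 0
  inter <- sum(a & b); na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(tibble::tibble(dice = NA_real_, jaccard = NA_real_))
  tibble::tibble(dice = 2 * inter / (na + nb),
                 jaccard = inter / (na + nb - inter))
}

#' Pixel-wise confusion matrix of predicted versus true classes
#'
#' @param pred_lm,true_lm [label_map()]s (or integer matrices) of identical
#'   shape.
#' @return 10 x 10 integer matrix; rows are true classes, columns predicted,
#'   named by tissue class. Row sums equal the true class pixel counts.
#' @export
confusion_matrix <- function(pred_lm, true_lm) {
  p <- if (inherits(pred_lm, "label_map")) pred_lm$labels else pred_lm
  t_ <- if (inherits(true_lm, "label_map")) true_lm$labels else true_lm
  if (!identical(dim(p), dim(t_))) stop("label map shapes differ")
  nm <- tissue_classes()$name
  out <- table(factor(as.vector(t_), levels = 1:10),
               factor(as.vector(p), levels = 1:10))
  out <- matrix(as.integer(out), 10, 10, dimnames = list(true = nm, predicted = nm))
  out
}

#' Instance-level vessel detection metrics
#'
#' A true vessel is correctly detected (true positive) when a predicted
#' vessel covers more than `overlap_frac` (default 50%) of its pixels; since
#' disjoint predictions cannot each cover more than half of the same truth,
#' every truth has at most one qualifying prediction, and predictions are
#' matched one-to-one greedily by descending overlap (ties by true-vessel
#' size, then index). Unmatched predictions are false positives, unmatched
#' truths false negatives. Additionally, the percentage of true vessels
#' *merged* (their matching prediction also covers > 50% of another truth)
#' and *split* (covered by >= 2 predictions each over `split_frac`, none
#' over 50%) is reported relative to the total number of true vessels.
#'
#' @param pred_lm,true_lm Predicted and ground-truth [label_map()]s.
#' @param min_area_px Minimum vessel size applied to both maps before
#'   matching.
#' @param overlap_frac True-positive coverage threshold (fraction of the
#'   true vessel).
#' @param split_frac Minimum partial coverage for counting a fragment of a
#'   split.
#' @return One-row tibble of class `detection_report`: `n_true`, `n_pred`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, `merged_pct`,
#'   `split_pct`. Metrics are missing when the truth holds no vessels.
#' @export
detect_vessels <- function(pred_lm, true_lm, min_area_px = 40,
                           overlap_frac = 0.5, split_frac = 0.1) {
  tv <- label_vessels(true_lm, min_area_px)
  pv <- label_vessels(pred_lm, min_area_px)
  tid <- attr(tv, "id_matrix"); pid <- attr(pv, "id_matrix")
  n_true <- nrow(tv); n_pred <- nrow(pv)
  if (n_true == 0) {
    return(structure(tibble::tibble(n_true = 0L, n_pred = n_pred, tp = NA_integer_,
                                    fp = NA_integer_, fn = NA_integer_,
                                    precision = NA_real_, recall = NA_real_,
                                    f1 = NA_real_, merged_pct = NA_real_,
                                    split_pct = NA_real_),
                     class = c("detection_report", class(tibble::tibble()))))
  }
  ov <- if (n_pred > 0) cpp_overlap_table(tid, pid, n_true, n_pred)
        else matrix(0L, n_true, 0)
  cover <- ov / tv$n_px  # fraction of each truth covered by each prediction

  tp <- 0L; matched_pred <- logical(n_pred); matched_true <- logical(n_true)
  if (n_pred > 0) {
    qual <- which(cover > overlap_frac, arr.ind = TRUE)
    if (nrow(qual)) {
      o <- order(-ov[qual], -tv$n_px[qual[, 1]], qual[, 1])
      for (i in o) {
        ti <- qual[i, 1]; pj <- qual[i, 2]
        if (!matched_true[ti] && !matched_pred[pj]) {
          matched_true[ti] <- TRUE; matched_pred[pj] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- n_pred - sum(matched_pred)
  fn <- n_true - tp
  precision <- if (n_pred > 0) tp / n_pred else NA_real_
  recall <- tp / n_true
  f1 <- if (!is.na(precision) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else if (!is.na(precision)) 0 else NA_real_

  merged <- 0L; split <- 0L
  if (n_pred > 0) {
    covered_by <- cover > overlap_frac          # truth i covered >50% by pred j
    preds_merging <- colSums(covered_by) >= 2
    merged <- sum(covered_by[, preds_merging, drop = FALSE])
    partial <- cover > split_frac & !covered_by
    split <- sum(rowSums(partial) >= 2 & rowSums(covered_by) == 0)
  }
  structure(tibble::tibble(n_true = n_true, n_pred = n_pred, tp = tp,
                           fp = as.integer(fp), fn = as.integer(fn),
                           precision = precision, recall = recall, f1 = f1,
                           merged_pct = 100 * merged / n_true,
                           split_pct = 100 * split / n_true),
            class = c("detection_report", class(tibble::tibble())))
}
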