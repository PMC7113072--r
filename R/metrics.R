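#' Pixel-level F1 score between two binary masks
#'
#' `2TP / (2TP + FP + FN)` over pixels. Two empty masks are defined as perfect
#' agreement (1.0, with a warning), so that an all-negative prediction of an
#' all-negative truth does not read as failure.
#'
#' @param pred,gt Logical matrices of identical shape.
#' @return F1 in `[0, 1]`.
#' @export
pixel_f1 <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) abort_dim("`pred` and `gt` shapes differ.")
  pred <- pred > 0; gt <- gt > 0
  tp <- sum(pred & gt)
  fp <- sum(pred & !gt)
  fn <- sum(!pred & gt)
  if (tp + fp + fn == 0) {
    warn("both masks empty; pixel F1 defined as 1.")
    return(1)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Pixel-level ROC AUC of a probability map against a binary truth
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pixel pairs ranked concordantly, with 0.5 credit per
#' tied pair (midrank formulation).
#'
#' @param map A `probability_map` or numeric matrix of scores.
#' @param gt Logical matrix; must contain both classes.
#' @return AUC in `[0, 1]`.
#' @export
pixel_auc <- function(map, gt) {
  v <- if (inherits(map, "probability_map")) map$values else map
  if (!identical(dim(v), dim(gt))) abort_dim("`map` and `gt` shapes differ.")
  pos <- gt > 0
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("ground truth contains a single class; AUC undefined.",
          class = "histocompress_undefined_metric_error")
  }
  r <- rank(as.numeric(v))  # midranks handle ties with 0.5 credit
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Match predicted and ground-truth centres one-to-one
#'
#' Maximum-cardinality, minimum-total-distance assignment among pred-gt pairs
#' within `radius` px (Hungarian algorithm on a padded cost matrix where
#' out-of-radius pairs carry a prohibitive cost). Unmatched predictions are
#' false positives; unmatched ground truth, false negatives.
#'
#' @param pred,gt Tibbles/data frames with `row` and `col` columns.
#' @param radius Maximum centre-to-centre distance of a valid match, px.
#' @return A list of class `detection_match`: `tp`, `fp`, `fn`, and `pairs`
#'   (tibble `pred_index`, `gt_index`, `distance`).
#' @export
match_detections <- function(pred, gt, radius) {
  if (radius <= 0) abort_param("`radius` must be > 0.")
  np <- nrow(pred); ng <- nrow(gt)
  empty_pairs <- tibble(pred_index = integer(0), gt_index = integer(0),
                        distance = numeric(0))
  if (np == 0L || ng == 0L) {
    return(structure(list(tp = 0L, fp = np, fn = ng, pairs = empty_pairs),
                     class = "detection_match"))
  }
  d <- sqrt(outer(pred$row, gt$row, "-")^2 + outer(pred$col, gt$col, "-")^2)
  feasible <- d <= radius
  if (!any(feasible)) {
    return(structure(list(tp = 0L, fp = np, fn = ng, pairs = empty_pairs),
                     class = "detection_match"))
  }
  big <- min(np, ng) * radius + 1
  cost <- ifelse(feasible, d, big)
  # solve_LSAP needs nrow <= ncol; pad the smaller side with zero-cost slack
  n <- max(np, ng)
  padded <- matrix(big, n, n)
  padded[seq_len(np), seq_len(ng)] <- cost
  sol <- clue::solve_LSAP(padded)
  pi <- seq_len(np)
  gi <- as.integer(sol)[seq_len(np)]
  ok <- gi <= ng & feasible[cbind(pi, pmin(gi, ng))]
  pairs <- tibble(pred_index = pi[ok], gt_index = gi[ok],
                  distance = d[cbind(pi[ok], gi[ok])])
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = np - tp, fn = ng - tp, pairs = pairs),
            class = "detection_match")
}

#' Detection F1 from a match result
#'
#' `2 tp / (2 tp + fp + fn)`; an empty problem (no predictions and no ground
#' truth) is defined as 1.
#'
#' @param match A [match_detections()] result.
#' @return F1 in `[0, 1]`.
#' @export
detection_f1 <- function(match) {
  if (!inherits(match, "detection_match")) abort_param("`match` must come from match_detections().")
  denom <- 2 * match$tp + match$fp + match$fn
  if (denom == 0) return(1)
  2 * match$tp / denom
}
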