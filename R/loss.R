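#' Class-weighted soft Dice loss
#'
#' The training objective for the segmentation network. For predicted
#' probabilities \eqn{p_{ij} \in [0,1]} and one-hot ground truth
#' \eqn{g_{ij} \in \{0,1\}} over pixels \eqn{i} and classes \eqn{j},
#' \deqn{L(p,g) = 1 - \sum_j \frac{w_j}{\sum_l w_l} \cdot
#'   \frac{2\sum_i p_{ij} g_{ij}}{\sum_i p_{ij} + \sum_i g_{ij}}}
#' The per-class Dice terms are averaged with normalized class weights, so the
#' loss lies in \[0, 1\]: 0 for perfect agreement, 1 for total disagreement.
#' A class absent from both prediction and truth has an empty (0/0) Dice term;
#' it is defined as 1 (perfectly segmented nothing) so that absent classes do
#' not penalize the loss. During network training a smoothed variant with an
#' additive epsilon in numerator and denominator is used instead for gradient
#' stability; this function is the exact reference form.
#'
#' @param p Numeric array of predicted probabilities. If 3-dimensional, the
#'   third dimension indexes classes; a vector or matrix is treated as a
#'   single class (binary soft Dice).
#' @param g Ground truth of the same shape, values in \{0, 1\} (one-hot over
#'   the class dimension for multi-class input).
#' @param weights Positive per-class weights, recycled to the number of
#'   classes. Defaults to [default_class_weights()] when `p` has 10 class
#'   planes, all-ones otherwise.
#' @param ignore Optional logical/0-1 matrix marking pixels to exclude from
#'   all sums (unannotated space on partially annotated slides).
#' @return Loss value in \[0, 1\].
#' @export
#' @examples
#' dice_loss(c(1, 1), c(1, 0))  # 1/3
dice_loss <- function(p, g, weights = NULL, ignore = NULL) {
  p <- as.array(p); g <- as.array(g)
  if (!identical(dim(p), dim(g)) && !identical(length(p), length(g))) {
    stop("p and g must have identical shapes")
  }
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (!all(g %in% c(0, 1))) stop("g must be binary")
  nd <- length(dim(p))
  if (is.null(dim(p)) || nd < 3) {
    pc <- list(as.vector(p)); gc <- list(as.vector(g))
  } else {
    C <- dim(p)[nd]
    pm <- matrix(p, ncol = C); gm <- matrix(g, ncol = C)
    pc <- lapply(seq_len(C), function(j) pm[, j])
    gc <- lapply(seq_len(C), function(j) gm[, j])
  }
  C <- length(pc)
  if (is.null(weights)) {
    weights <- if (C == 10) default_class_weights() else rep(1, C)
  }
  weights <- rep_len(weights, C)
  if (any(weights <= 0)) stop("class weights must be positive")
  use <- if (is.null(ignore)) NULL else as.vector(ignore) > 0
  dice_j <- vapply(seq_len(C), function(j) {
    pj <- pc[[j]]; gj <- gc[[j]]
    if (!is.null(use)) { pj <- pj[use]; gj <- gj[use] }
    den <- sum(pj) + sum(gj)
    if (den == 0) 1 else 2 * sum(pj * gj) / den
  }, numeric(1))
  1 - sum(weights / sum(weights) * dice_j)
}
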