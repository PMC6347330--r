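# Objective reconstruction assessment: pairwise identification against all
# same-type distractors, and round-robin winning percentages between
# reconstruction conditions. The similarity judge is pixel-wise Pearson
# correlation; a hook allows plugging an alternative perceptual metric.

#' Pixel-wise Pearson correlation between two images
#'
#' Correlation over all `H * W * 3` vectorized pixel values. Undefined
#' (returned as `NA`) when either image is constant.
#'
#' @param a,b image arrays of identical dimensions.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
pixel_correlation <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("images must have identical dimensions", call. = FALSE)
  safe_cor(as.vector(a), as.vector(b))
}

#' Pairwise identification of reconstructions
#'
#' Each reconstruction is compared with every pair formed by its own
#' original and one other original from the same set (exhaustive pairing):
#' the trial is correct when the reconstruction's similarity to its own
#' original is strictly higher than to the distractor; exact ties count
#' 0.5. With `n` originals this yields `n - 1` comparisons per
#' reconstruction and `n * (n - 1)` in total. Chance is 50%.
#'
#' @param recons list of reconstructed image arrays.
#' @param originals list of original image arrays, aligned with `recons`.
#' @param similarity similarity function of two images (default
#'   [pixel_correlation()]).
#' @return object of class `identification_result`: data.frame `per_image`
#'   (`image`, `percent_correct`, `comparisons`), pooled accuracies
#'   `pooled_percent` (comparison-weighted) and `image_mean_percent`
#'   (image-weighted), and `n_comparisons`.
#' @export
pairwise_identification <- function(recons, originals,
                                    similarity = pixel_correlation) {
  if (length(recons) != length(originals))
    stop("reconstructions and originals must be aligned lists", call. = FALSE)
  n <- length(originals)
  if (n < 2L) stop("at least two originals are required", call. = FALSE)
  for (i in seq_len(n))
    if (!all(dim(recons[[i]]) == dim(originals[[i]])))
      stop("dimension mismatch between reconstruction and original ", i, call. = FALSE)
  # n x n similarity matrix: s[i, j] = sim(recon_i, original_j)
  s <- matrix(NA_real_, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      s[i, j] <- similarity(recons[[i]], originals[[j]])
  correct <- numeric(n)
  for (i in seq_len(n)) {
    own <- s[i, i]
    others <- s[i, -i]
    if (is.na(own)) { correct[i] <- NA_real_; next }
    wins <- sum(others < own, na.rm = TRUE) + 0.5 * sum(others == own, na.rm = TRUE)
    correct[i] <- 100 * wins / (n - 1L)
  }
  per_image <- data.frame(image = seq_len(n), percent_correct = correct,
                          comparisons = n - 1L)
  structure(list(per_image = per_image,
                 pooled_percent = mean(correct, na.rm = TRUE),
                 image_mean_percent = mean(correct, na.rm = TRUE),
                 n_comparisons = n * (n - 1L)),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat("<identification_result>", x$n_comparisons, "comparisons, pooled",
      sprintf("%.1f%%", x$pooled_percent), "correct\n")
  invisible(x)
}

#' Winning percentages across reconstruction conditions
#'
#' For every unordered pair of conditions (e.g. layer combinations DNN1,
#' DNN1-2, ..., DNN1-8: 8 conditions, 28 pairs) and every original image,
#' the condition whose reconstruction is more similar to the original wins;
#' ties score 0.5 each. A condition's winning percentage is its wins over
#' all its pairings and images; with no ties the mean across conditions is
#' exactly 50%.
#'
#' @param recons_by_condition named list: condition -> list of
#'   reconstructions aligned with `originals`.
#' @param originals list of original image arrays.
#' @param similarity similarity function (default [pixel_correlation()]).
#' @return object of class `tournament_result`: data.frame `percentages`
#'   (`condition`, `winning_percent`), and `n_pairs` (condition pairs).
#' @export
winning_percentage <- function(recons_by_condition, originals,
                               similarity = pixel_correlation) {
  conds <- names(recons_by_condition)
  if (length(conds) < 2L) stop("at least two conditions are required", call. = FALSE)
  n <- length(originals)
  for (cn in conds)
    if (length(recons_by_condition[[cn]]) != n)
      stop("condition '", cn, "' is missing reconstructions", call. = FALSE)
  # per condition x image similarity to the original
  s <- matrix(NA_real_, length(conds), n, dimnames = list(conds, NULL))
  for (ci in seq_along(conds))
    for (i in seq_len(n))
      s[ci, i] <- similarity(recons_by_condition[[conds[ci]]][[i]],
                             originals[[i]])
  pairs <- utils::combn(length(conds), 2L)
  wins <- stats::setNames(numeric(length(conds)), conds)
  games <- stats::setNames(numeric(length(conds)), conds)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    for (i in seq_len(n)) {
      sa <- s[a, i]; sb <- s[b, i]
      if (is.na(sa) || is.na(sb)) next
      wa <- if (sa > sb) 1 else if (sa < sb) 0 else 0.5
      wins[a] <- wins[a] + wa; wins[b] <- wins[b] + (1 - wa)
      games[a] <- games[a] + 1; games[b] <- games[b] + 1
    }
  }
  structure(list(percentages = data.frame(condition = conds,
                                          winning_percent = 100 * wins / games),
                 n_pairs = ncol(pairs)),
            class = "tournament_result")
}

#' @export
print.tournament_result <- function(x, ...) {
  cat("<tournament_result>", x$n_pairs, "condition pairs\n")
  print(x$percentages, row.names = FALSE)
  invisible(x)
}

#' Signed-rank test on paired per-image accuracies
#'
#' Thin convenience wrapper around [stats::wilcox.test()] for comparing two
#' conditions' per-image percent-correct values (non-core helper).
#'
#' @param x,y paired numeric vectors.
#' @param alternative passed to [stats::wilcox.test()].
#' @return the `htest` object.
#' @export
signed_rank_test <- function(x, y, alternative = "two.sided") {
  stats::wilcox.test(x, y, paired = TRUE, alternative = alternative,
                     exact = FALSE)
}
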