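#' Majority-vote gold standard from reader masks
#'
#' A voxel belongs to the gold standard iff at least `quorum` of the reader
#' masks mark it (default: 3 of 4 readers). Lower quorums are strictly more
#' permissive, so the result is monotone (non-increasing) in `quorum`.
#'
#' @param masks list of grid-compatible `binary_mask`s (one per reader).
#' @param quorum minimum number of agreeing readers (default 3).
#' @param role role of the output mask (default `"lesion"`).
#' @export
majority_vote <- function(masks, quorum = 3, role = "lesion") {
  if (quorum > length(masks)) stop("quorum exceeds the number of masks")
  if (quorum < 1) stop("quorum must be at least 1")
  votes <- array(0L, dim(masks[[1]]$data))
  for (m in masks) {
    stop_if_incompatible(masks[[1]], m)
    votes <- votes + m$data
  }
  binary_mask(votes >= quorum, masks[[1]]$spacing, masks[[1]]$origin,
              masks[[1]]$direction, role)
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A n B| / (|A| + |B|)`; 1 for identical nonempty masks, 0 for disjoint
#' ones. When both masks are empty the coefficient is undefined and `NA` is
#' returned (never silently 0).
#'
#' @param a,b grid-compatible `binary_mask`s.
#' @export
dice <- function(a, b) {
  stop_if_incompatible(a, b)
  na <- voxel_count(a)
  nb <- voxel_count(b)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a$data & b$data) / (na + nb)
}

#' Lesion-level detection metrics by overlap matching
#'
#' A gold-standard lesion counts as detected iff it overlaps, at least
#' partially (>= 1 voxel), with any predicted component; a predicted
#' component counts as correct iff it overlaps any gold-standard lesion.
#' Each lesion/component is counted once no matter how many partners it
#' overlaps. Sensitivity is detected / n_gs, PPV is correct / n_pred; a 0/0
#' ratio is reported as NA (undefined), never as 0. The voxelwise Dice
#' coefficient is computed on the binarised unions of the two label maps.
#'
#' @param pred predicted `labeled_components`.
#' @param gs gold-standard `labeled_components` on the same grid.
#' @return A `detection_metrics` object: `dsc`, `sensitivity`, `ppv`,
#'   `n_gs`, `n_pred`, `n_gs_detected`, `n_pred_correct` and the
#'   `match_pairs` data frame (pred_id, gs_id).
#' @export
match_lesions <- function(pred, gs) {
  stop_if_incompatible(pred, gs)
  both <- pred$labels > 0L & gs$labels > 0L
  pairs <- unique(data.frame(pred_id = pred$labels[both],
                             gs_id = gs$labels[both]))
  pairs <- pairs[order(pairs$pred_id, pairs$gs_id), , drop = FALSE]
  rownames(pairs) <- NULL
  n_gs <- n_components(gs)
  n_pred <- n_components(pred)
  n_gs_detected <- length(unique(pairs$gs_id))
  n_pred_correct <- length(unique(pairs$pred_id))
  sens <- if (n_gs > 0) n_gs_detected / n_gs else NA_real_
  ppv <- if (n_pred > 0) n_pred_correct / n_pred else NA_real_
  dsc <- dice(components_mask(pred), components_mask(gs))
  structure(list(dsc = dsc, sensitivity = sens, ppv = ppv, n_gs = n_gs,
                 n_pred = n_pred, n_gs_detected = n_gs_detected,
                 n_pred_correct = n_pred_correct, match_pairs = pairs),
            class = "detection_metrics")
}

#' Truncate a metric to 3 decimals for printing
#'
#' Detection metrics are printed truncated toward zero at the third decimal
#' (4/6 prints as 0.666); full precision is kept internally.
#' @param x numeric value.
#' @export
format_metric <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.3f", trunc(x * 1000) / 1000))
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    "<detection_metrics> DSC %s | sensitivity %s (%d/%d) | PPV %s (%d/%d)\n",
    format_metric(x$dsc), format_metric(x$sensitivity), x$n_gs_detected,
    x$n_gs, format_metric(x$ppv), x$n_pred_correct, x$n_pred))
  invisible(x)
}

#' Intraclass correlation coefficient, two-way absolute agreement
#'
#' ICC(2,1): two-way random-effects, absolute-agreement, single-measures,
#' computed from the ANOVA mean squares of the subjects-by-raters table
#' (here two raters: e.g. gold standard vs algorithm). The p-value is from
#' the F test of the subject effect, `F = MSR / MSE` with `n - 1` and
#' `(n - 1)(k - 1)` degrees of freedom. With zero total variance the
#' coefficient is undefined (NA).
#'
#' @param x,y paired measurements of the same quantity by two sources, at
#'   least 3 pairs.
#' @return List with `icc`, `p_value`, and the mean squares (`msr`, `msc`,
#'   `mse`).
#' @export
icc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  m <- cbind(x, y)
  k <- 2
  grand <- mean(m)
  if (var(as.numeric(m)) == 0)
    return(list(icc = NA_real_, p_value = NA_real_, msr = 0, msc = 0, mse = 0))
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc_val <- (msr - mse) /
    (msr + (k - 1) * mse + k * (msc - mse) / n)
  f <- msr / mse
  p <- pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc_val, p_value = p, msr = msr, msc = msc, mse = mse)
}

#' Pairwise Dice matrix over reader masks
#'
#' Inter-reader agreement summary: symmetric matrix of Dice coefficients
#' between every pair of masks. (Distribution comparisons, e.g. a Wilcoxon
#' signed-rank test between agreement samples, are delegated to
#' [stats::wilcox.test()].)
#'
#' @param masks list of grid-compatible `binary_mask`s.
#' @export
pairwise_dice <- function(masks) {
  n <- length(masks)
  out <- matrix(NA_real_, n, n)
  diag(out) <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    out[i, j] <- out[j, i] <- dice(masks[[i]], masks[[j]])
  dimnames(out) <- list(names(masks), names(masks))
  out
}
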