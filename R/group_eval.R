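#' Voxelwise median of a stack of co-registered volumes
#'
#' The group template used to visualize method-wise alignment sharpness:
#' the median intensity at each voxel across the stack. Even stack sizes use
#' the mean of the two central order statistics. Permutation-invariant in
#' the stack order.
#'
#' @param stack A list of [lab_volume()] objects on one identical grid.
#' @return A [lab_volume()] on the shared grid.
#' @export
median_volume <- function(stack) {
  if (!length(stack)) stopf("`stack` must contain at least one volume")
  ref <- stack[[1]]
  stopifnot(is_lab_volume(ref))
  for (v in stack[-1]) {
    if (!same_grid(ref, v)) stopf("all volumes in the stack must share one grid")
  }
  n <- length(stack)
  if (n == 1L) return(ref)
  M <- vapply(stack, function(v) as.numeric(v$voxels),
              numeric(prod(dim(ref$voxels))))
  # row-wise median via column sort: for each voxel take the central order
  # statistic(s) of its n values
  Ms <- apply(M, 1, sort)            # n x n_voxels
  med <- if (n %% 2L == 1L) {
    Ms[(n + 1L) %/% 2L, ]
  } else {
    (Ms[n %/% 2L, ] + Ms[n %/% 2L + 1L, ]) / 2
  }
  lab_volume(array(med, dim(ref$voxels)), ref$spacing, ref$origin,
             ref$direction)
}

roi_values <- function(volume, roi) {
  stopifnot(is_lab_volume(volume), inherits(roi, "lab_mask"))
  if (!same_grid(volume, roi)) stopf("volume and ROI must share one grid")
  as.numeric(volume$voxels)[as.logical(roi$voxels)]
}

# Orthogonal (total-least-squares) regression ch2 ~ a*ch1 + b via the
# principal axis of the centered 2D cloud; the slope sign follows the
# covariance.
tls_regression <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2); syy <- mean((y - my)^2); sxy <- mean((x - mx) * (y - my))
  if (sxx == 0) stopf("degenerate (constant) channel 1")
  # largest-eigenvalue direction of the 2x2 covariance
  lam <- (sxx + syy) / 2 + sqrt(((sxx - syy) / 2)^2 + sxy^2)
  a <- if (sxy == 0) 0 else (lam - sxx) / sxy
  b <- my - a * mx
  c(slope = a, intercept = b)
}

#' Costes automatic threshold
#'
#' Determines the channel thresholds above which intensities are considered
#' colocalized, following the Costes procedure: an orthogonal regression
#' `ch2 ~ a*ch1 + b` over the ROI fixes the line along which the candidate
#' threshold pair `(T, a*T + b)` moves; the candidate `T` is swept downward
#' through the distinct observed `ch1` intensities, and the procedure stops
#' at the largest `T` for which the Pearson correlation of the voxels
#' *below* both thresholds is <= 0. If even the full ROI correlates
#' non-positively, the thresholds are set to the channel maxima and flagged.
#'
#' @param ch1,ch2 [lab_volume()] objects on one grid (e.g. atlas and
#'   registered volume).
#' @param roi A non-empty [lab_mask()] on the same grid; mandatory so that
#'   background voxels cannot inflate the colocalization.
#' @return A list: `threshold_ch1`, `threshold_ch2`, `slope`, `intercept`
#'   (orthogonal regression), `no_positive_colocalization` flag.
#' @export
costes_threshold <- function(ch1, ch2, roi) {
  x <- roi_values(ch1, roi)
  y <- roi_values(ch2, roi)
  if (length(x) < 3) stopf("ROI must contain at least 3 voxels")
  if (var(x) == 0 || var(y) == 0) stopf("degenerate (constant) channel within ROI")
  fit <- tls_regression(x, y)
  a <- fit[["slope"]]; b <- fit[["intercept"]]
  if (cor(x, y) <= 0) {
    return(list(threshold_ch1 = max(x), threshold_ch2 = max(y),
                slope = a, intercept = b,
                no_positive_colocalization = TRUE))
  }
  cand <- sort(unique(x), decreasing = TRUE)
  # incremental downward sweep; the below-threshold subset only shrinks when
  # a >= 0, but correctness does not rely on that: sums are recomputed
  # incrementally only when monotone, otherwise directly.
  n <- length(x)
  thr_found <- NA_real_
  if (a >= 0) {
    # voxel leaves the subset when T drops to its ch1 value or when a*T+b
    # drops to its ch2 value; i.e. it is in the subset iff T > max(x_i,
    # (y_i - b)/a). Sweep candidates descending, removing voxels whose
    # exit level >= current T.
    exit_level <- pmax(x, if (a > 0) (y - b) / a else -Inf)
    ord <- order(exit_level, decreasing = TRUE)
    S <- c(n = n, sx = sum(x), sy = sum(y), sxx = sum(x^2), syy = sum(y^2),
           sxy = sum(x * y))
    ptr <- 1L
    for (T in cand) {
      # remove voxels with exit_level >= T
      while (ptr <= n && exit_level[ord[ptr]] >= T) {
        i <- ord[ptr]
        S <- S - c(1, x[i], y[i], x[i]^2, y[i]^2, x[i] * y[i])
        ptr <- ptr + 1L
      }
      if (S[["n"]] >= 3) {
        nn <- S[["n"]]
        cxx <- S[["sxx"]] - S[["sx"]]^2 / nn
        cyy <- S[["syy"]] - S[["sy"]]^2 / nn
        cxy <- S[["sxy"]] - S[["sx"]] * S[["sy"]] / nn
        if (cxx > 1e-12 && cyy > 1e-12) {
          r <- cxy / sqrt(cxx * cyy)
          if (r <= 0) { thr_found <- T; break }
        }
      }
    }
  } else {
    for (T in cand) {
      sub <- x < T & y < a * T + b
      if (sum(sub) >= 3 && var(x[sub]) > 0 && var(y[sub]) > 0) {
        if (cor(x[sub], y[sub]) <= 0) { thr_found <- T; break }
      }
    }
  }
  if (is.na(thr_found)) thr_found <- min(x)
  list(threshold_ch1 = thr_found,
       threshold_ch2 = a * thr_found + b,
       slope = a, intercept = b,
       no_positive_colocalization = FALSE)
}

#' Thresholded Manders split coefficients
#'
#' `tM1` is the fraction of channel-1 intensity (summed over the ROI) that
#' lies where channel 2 exceeds its threshold; `tM2` symmetrically with the
#' channels swapped. Negative intensities are clipped to zero for the sums
#' (with a message when any are present).
#'
#' @inheritParams costes_threshold
#' @param threshold_ch1,threshold_ch2 Channel thresholds (e.g. from
#'   [costes_threshold()]).
#' @return A list with `tM1` and `tM2`, both in `[0, 1]`.
#' @export
manders_split <- function(ch1, ch2, threshold_ch1, threshold_ch2, roi) {
  x <- roi_values(ch1, roi)
  y <- roi_values(ch2, roi)
  n_neg <- sum(x < 0) + sum(y < 0)
  if (n_neg > 0) {
    message(sprintf("clipping %d negative intensities to 0 for Manders sums", n_neg))
  }
  xp <- pmax(x, 0)
  yp <- pmax(y, 0)
  if (sum(xp) == 0 || sum(yp) == 0) {
    stopf("a channel is all-zero within the ROI; Manders coefficients undefined")
  }
  list(tM1 = sum(xp[y > threshold_ch2]) / sum(xp),
       tM2 = sum(yp[x > threshold_ch1]) / sum(yp))
}

#' Voxelwise correlation within an ROI
#'
#' Pearson correlation on raw intensities and Spearman correlation (Pearson
#' on average ranks, ties averaged) over the ROI voxels.
#'
#' @inheritParams costes_threshold
#' @return A list with `pearson_r` and `spearman_rho`.
#' @export
voxel_correlation <- function(ch1, ch2, roi) {
  x <- roi_values(ch1, roi)
  y <- roi_values(ch2, roi)
  if (length(x) < 3) stopf("ROI must contain at least 3 voxels")
  if (var(x) == 0 || var(y) == 0) {
    stopf("correlation undefined for a constant channel")
  }
  list(pearson_r = cor(x, y),
       spearman_rho = cor(rank(x), rank(y)))
}

#' Ordinary least-squares fit of one channel on the other within an ROI
#'
#' The scatterplot fit reported alongside the colocalization metrics:
#' `ch2 = slope * ch1 + intercept` by OLS over ROI voxels (an ideally
#' registered volume has slope near 1).
#'
#' @inheritParams costes_threshold
#' @return A list with `slope` and `intercept`.
#' @export
coloc_regression <- function(ch1, ch2, roi) {
  x <- roi_values(ch1, roi)
  y <- roi_values(ch2, roi)
  if (var(x) == 0) stopf("constant predictor channel within ROI")
  slope <- cov(x, y) / var(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Full colocalization analysis of a registered volume against the atlas
#'
#' Convenience wrapper running [costes_threshold()], [manders_split()],
#' [voxel_correlation()] and [coloc_regression()] over one ROI.
#'
#' @param image The registered [lab_volume()] (channel 2).
#' @param atlas The atlas [lab_volume()] (channel 1).
#' @param roi A non-empty [lab_mask()] on the shared grid.
#' @return A list of class `coloc_result` with fields
#'   `costes_threshold_ch1/2`, `manders_tM1/2`, `pearson_r`,
#'   `spearman_rho`, `regression_slope/intercept`, `n_voxels`,
#'   `no_positive_colocalization`.
#' @export
coloc_analysis <- function(image, atlas, roi) {
  ct <- costes_threshold(atlas, image, roi)
  ms <- manders_split(atlas, image, ct$threshold_ch1, ct$threshold_ch2, roi)
  cc <- voxel_correlation(atlas, image, roi)
  rg <- coloc_regression(atlas, image, roi)
  structure(list(costes_threshold_ch1 = ct$threshold_ch1,
                 costes_threshold_ch2 = ct$threshold_ch2,
                 manders_tM1 = ms$tM1, manders_tM2 = ms$tM2,
                 pearson_r = cc$pearson_r, spearman_rho = cc$spearman_rho,
                 regression_slope = rg$slope,
                 regression_intercept = rg$intercept,
                 n_voxels = sum(roi$voxels),
                 no_positive_colocalization = ct$no_positive_colocalization),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> n = %d ROI voxels\n", x$n_voxels))
  cat(sprintf("  Costes thresholds: ch1 %.4g, ch2 %.4g%s\n",
              x$costes_threshold_ch1, x$costes_threshold_ch2,
              if (x$no_positive_colocalization) " [no positive colocalization]" else ""))
  cat(sprintf("  Manders tM1 %.4f, tM2 %.4f\n", x$manders_tM1, x$manders_tM2))
  cat(sprintf("  Pearson r %.4f, Spearman rho %.4f\n", x$pearson_r, x$spearman_rho))
  cat(sprintf("  OLS fit: y = %.4g x + %.4g\n", x$regression_slope,
              x$regression_intercept))
  invisible(x)
}
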