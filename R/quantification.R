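#' Compute an ADC map from two b-value DWI volumes
#'
#' Two-point apparent diffusion coefficient from the mono-exponential decay
#' model `S_i = S_0 exp(-b ADC)`:
#' `ADC = -ln(S_i / S_0) / (b_i - b_0)`, in mm^2/s with b-values in s/mm^2.
#' ADC is defined only where both signals are strictly positive; other
#' voxels are marked invalid (NA in the map, excluded from `valid_mask`)
#' rather than becoming +/-Inf. Negative ADC values (noise pushing
#' S_i > S_0) are retained by default to preserve histogram shape;
#' `clip_negative = TRUE` clamps them to 0.
#'
#' @param s_high DWI volume at the higher b-value (800 or 1000 s/mm^2
#'   typically).
#' @param s_low DWI volume at the lower b-value (usually b = 0).
#' @param b_high,b_low the two b-values in s/mm^2, `b_high > b_low >= 0`.
#' @param clip_negative clamp negative ADC values to zero (default FALSE).
#' @return An `adc_map`: a `volumetric_image`-like object with `data` in
#'   mm^2/s (NA where invalid), the b-values, and a `valid_mask`.
#' @export
compute_adc <- function(s_high, s_low, b_high, b_low = 0,
                        clip_negative = FALSE) {
  stop_if_incompatible(s_high, s_low)
  if (!(b_high > b_low) || b_low < 0)
    stop("require b_high > b_low >= 0")
  valid <- s_high$data > 0 & s_low$data > 0
  adc <- array(NA_real_, dim(s_high$data))
  adc[valid] <- -log(s_high$data[valid] / s_low$data[valid]) / (b_high - b_low)
  if (clip_negative) adc[valid] <- pmax(adc[valid], 0)
  structure(list(data = adc, spacing = s_high$spacing, origin = s_high$origin,
                 direction = s_high$direction, b_high = b_high, b_low = b_low,
                 valid_mask = binary_mask(valid, s_high$spacing,
                                          s_high$origin, s_high$direction,
                                          role = "lesion")),
            class = c("adc_map"))
}

#' @export
print.adc_map <- function(x, ...) {
  v <- x$data[x$valid_mask$data]
  cat(sprintf("<adc_map> b %g/%g s/mm^2, %d valid voxel(s), median %.3g mm^2/s\n",
              x$b_high, x$b_low, length(v), median(v)))
  invisible(x)
}

#' ADC histogram metrics of a value vector
#'
#' Median, mean, 5th/25th/75th/95th percentiles (linear interpolation of
#' order statistics, matching the quartile convention of
#' [compute_iqr_threshold()]), Fisher skewness g1 and Fisher excess
#' kurtosis g2 (so a normal distribution has kurtosis 0). Skewness and
#' kurtosis require at least 3 values and nonzero variance and are reported
#' as NA (undefined) otherwise, never silently as 0.
#'
#' @param values numeric vector, at least one value.
#' @return Named list: `n`, `mean`, `median`, `p5`, `p25`, `p75`, `p95`,
#'   `skewness`, `kurtosis`.
#' @export
histogram_metrics <- function(values) {
  if (length(values) == 0) stop("no values")
  values <- as.numeric(values)
  p <- quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE,
                type = 7)
  sk <- ku <- NA_real_
  if (length(values) >= 3 && var(values) > 0) {
    sk <- e1071::skewness(values, type = 1)
    ku <- e1071::kurtosis(values, type = 1)
  }
  list(n = length(values), mean = mean(values), median = p[3],
       p5 = p[1], p25 = p[2], p75 = p[4], p95 = p[5],
       skewness = sk, kurtosis = ku)
}

#' Per-lesion and aggregate ADC report
#'
#' For each labelled component, computes [histogram_metrics()] over the ADC
#' values at the component's valid voxels, plus the component volume in ml.
#' A final aggregate row pools the ADC values of all (selected) lesions;
#' its volume is the exact sum of the per-lesion volumes. Components with no
#' valid ADC voxel get NA metrics and are flagged. `ids` restricts the
#' report to a subset of component ids - e.g. only the predicted lesions
#' matched to the gold standard, as provided by [match_lesions()].
#'
#' @param components `labeled_components` on the ADC grid.
#' @param adc an `adc_map` from [compute_adc()].
#' @param ids optional integer vector of component ids to report.
#' @return A data frame, one row per lesion plus one `"aggregate"` row:
#'   columns `id`, `voxel_count`, `n_valid`, `volume_ml`, the histogram
#'   metrics, and `flag_no_valid_adc`.
#' @export
lesion_report <- function(components, adc, ids = NULL) {
  stop_if_incompatible(components, adc)
  all_ids <- components$components$id
  if (is.null(ids)) ids <- all_ids
  if (!all(ids %in% all_ids)) stop("unknown component id(s)")
  vox_ml <- prod(components$spacing) / 1000
  rows <- lapply(ids, function(i) {
    sel <- components$labels == i
    vals <- adc$data[sel & adc$valid_mask$data]
    m <- if (length(vals) > 0) histogram_metrics(vals) else
      list(n = 0L, mean = NA_real_, median = NA_real_, p5 = NA_real_,
           p25 = NA_real_, p75 = NA_real_, p95 = NA_real_,
           skewness = NA_real_, kurtosis = NA_real_)
    data.frame(id = as.character(i), voxel_count = sum(sel),
               n_valid = m$n, volume_ml = sum(sel) * vox_ml,
               mean = m$mean, median = m$median, p5 = m$p5, p25 = m$p25,
               p75 = m$p75, p95 = m$p95, skewness = m$skewness,
               kurtosis = m$kurtosis,
               flag_no_valid_adc = m$n == 0L)
  })
  per <- do.call(rbind, rows)
  sel <- components$labels %in% ids
  vals <- adc$data[sel & adc$valid_mask$data]
  m <- if (length(vals) > 0) histogram_metrics(vals) else
    list(n = 0L, mean = NA_real_, median = NA_real_, p5 = NA_real_,
         p25 = NA_real_, p75 = NA_real_, p95 = NA_real_,
         skewness = NA_real_, kurtosis = NA_real_)
  agg <- data.frame(id = "aggregate", voxel_count = sum(per$voxel_count),
                    n_valid = m$n, volume_ml = sum(per$volume_ml),
                    mean = m$mean, median = m$median, p5 = m$p5, p25 = m$p25,
                    p75 = m$p75, p95 = m$p95, skewness = m$skewness,
                    kurtosis = m$kurtosis, flag_no_valid_adc = m$n == 0L)
  rbind(per, agg)
}
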