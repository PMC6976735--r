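#' Region-wise MAE between synthetic and real CT
#'
#' Mean absolute CT-number error over three regions defined on the real CT
#' inside the body mask: the whole body, the soft-tissue region
#' (-100 HU < rCT < 150 HU, strict on both ends) and the bone region
#' (rCT >= 250 HU).
#'
#' @param sct,rct `image_volume`s sharing a geometry.
#' @param mask A [body_mask()].
#' @return Object of class `region_mae_report`: list with `mae_body`,
#'   `mae_soft`, `mae_bone` (HU; `NA` for an empty region) and `n_body`,
#'   `n_soft`, `n_bone` voxel counts.
#' @export
region_mae <- function(sct, rct, mask) {
  check_same_geometry(sct, rct)
  m <- mask_array(mask, rct)
  if (!any(m)) stop("invalid input: empty mask", call. = FALSE)
  r <- rct$data[m]
  s <- sct$data[m]
  ad <- abs(s - r)
  soft <- r > -100 & r < 150
  bone <- r >= 250
  mae_of <- function(sel) if (any(sel)) mean(ad[sel]) else NA_real_
  structure(list(mae_body = mean(ad), mae_soft = mae_of(soft),
                 mae_bone = mae_of(bone),
                 n_body = length(ad), n_soft = sum(soft), n_bone = sum(bone)),
            class = "region_mae_report")
}

#' @export
print.region_mae_report <- function(x, ...) {
  cat(sprintf("MAE body %.1f HU (n=%d) | soft tissue %.1f HU (n=%d) | bone %.1f HU (n=%d)\n",
              x$mae_body, x$n_body, x$mae_soft, x$n_soft, x$mae_bone, x$n_bone))
  invisible(x)
}

#' Binned HU-difference profile
#'
#' Groups masked voxels by their real-CT number into contiguous bins
#' (default width 20 HU, edges anchored at -1000 HU) and reports the 25th,
#' 50th and 75th percentile of the signed difference (sCT - rCT) and of the
#' absolute difference per bin, plus voxel counts.  Percentiles use linear
#' interpolation between order statistics.
#'
#' @param sct,rct `image_volume`s sharing a geometry.
#' @param mask A [body_mask()].
#' @param bin_width Bin width in HU (> 0, default 20).
#' @return Object of class `binned_diff`: data.frame with columns `bin_lo`,
#'   `bin_hi`, `n`, `p25`, `median`, `p75`, `abs_p25`, `abs_median`,
#'   `abs_p75`; empty bins in the covered range carry `n = 0` and `NA`
#'   statistics.
#' @export
binned_difference <- function(sct, rct, mask, bin_width = 20) {
  check_same_geometry(sct, rct)
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  m <- mask_array(mask, rct)
  r <- rct$data[m]
  d <- sct$data[m] - r
  bin <- floor((r - (-1000)) / bin_width)   # edges -1000, -980, ...
  bins <- seq(min(bin), max(bin))
  q <- function(v, p) if (length(v)) unname(stats::quantile(v, p, type = 7)) else NA_real_
  rows <- lapply(bins, function(b) {
    sel <- bin == b
    dv <- d[sel]
    data.frame(bin_lo = -1000 + b * bin_width,
               bin_hi = -1000 + (b + 1) * bin_width,
               n = sum(sel),
               p25 = q(dv, 0.25), median = q(dv, 0.5), p75 = q(dv, 0.75),
               abs_p25 = q(abs(dv), 0.25), abs_median = q(abs(dv), 0.5),
               abs_p75 = q(abs(dv), 0.75))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("binned_diff", "data.frame"))
}
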