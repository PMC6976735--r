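#' Build the rCT -> median-sCT HU lookup
#'
#' Over the region where both the real and the predicted CT exist, groups
#' masked voxels by their integer rCT CT number and records, for each CT
#' number present, the median of the predicted sCT values at those voxels.
#' The lookup drives the missing-slice compensation: real slices outside
#' the predicted range are re-valued through it.
#'
#' @param rct_overlap,sct_overlap `image_volume`s sharing a geometry
#'   (the predicted overlap region).
#' @param mask A [body_mask()] restricting which voxels contribute.
#' @return Object of class `hu_lookup`: data.frame with columns `hu`
#'   (sorted integers) and `median_hu`.
#' @export
build_hu_lookup <- function(rct_overlap, sct_overlap, mask) {
  check_same_geometry(rct_overlap, sct_overlap)
  m <- mask_array(mask, rct_overlap)
  if (!any(m)) stop("invalid input: empty overlap/mask", call. = FALSE)
  r <- as.integer(round(rct_overlap$data[m]))
  s <- sct_overlap$data[m]
  med <- tapply(s, r, stats::median)
  tab <- data.frame(hu = as.integer(names(med)), median_hu = as.numeric(med))
  tab <- tab[order(tab$hu), ]
  rownames(tab) <- NULL
  structure(tab, class = c("hu_lookup", "data.frame"))
}

# evaluate the lookup with linear interpolation between covered HU values
# and constant extrapolation beyond the covered range
lookup_hu <- function(lookup, v) {
  if (nrow(lookup) == 1L) return(rep(lookup$median_hu, length(v)))
  stats::approx(lookup$hu, lookup$median_hu, xout = v, rule = 2)$y
}

#' Compensate missing sCT slices from the real CT
#'
#' The generator may not cover the top/bottom slices of the volume.  Slices
#' inside `predicted_slice_range` are taken from the prediction; slices
#' outside are filled with the corresponding real-CT slices whose CT numbers
#' are replaced through the [build_hu_lookup()] table (linear interpolation
#' between covered CT numbers, constant beyond the covered range).
#' Background voxels (-1000 HU) pass through unchanged.
#'
#' @param sct_partial Predicted `image_volume` (valid on the predicted range).
#' @param rct_full Real CT `image_volume`, full extent.
#' @param predicted_slice_range Integer vector (or `c(first, last)`) of slice
#'   indices carrying predictions; must be non-empty and within the volume.
#' @param lookup An `hu_lookup`.
#' @return Completed `image_volume` on the rCT geometry.
#' @export
compensate_missing_slices <- function(sct_partial, rct_full,
                                      predicted_slice_range, lookup) {
  check_same_geometry(sct_partial, rct_full)
  nsl <- dim(rct_full$data)[3]
  rng <- as.integer(predicted_slice_range)
  if (length(rng) == 2L && rng[2] >= rng[1]) rng <- rng[1]:rng[2]
  if (length(rng) == 0L) stop("invalid input: empty predicted slice range", call. = FALSE)
  if (any(rng < 1L | rng > nsl))
    stop("invalid input: predicted slice range outside the volume", call. = FALSE)
  out <- rct_full$data
  for (k in seq_len(nsl)) {
    if (k %in% rng) {
      out[, , k] <- sct_partial$data[, , k]
    } else {
      sl <- rct_full$data[, , k]
      bg <- sl == -1000
      repl <- lookup_hu(lookup, sl)
      repl[bg] <- -1000
      out[, , k] <- repl
    }
  }
  image_volume(out, rct_full$spacing, rct_full$origin)
}
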