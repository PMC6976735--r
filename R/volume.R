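#' 3D image volume container
#'
#' A minimal container for a 3D scalar grid (CT in Hounsfield units, a single
#' MR sequence, a dose distribution, ...) together with its geometry.  Arrays
#' are stored in R's column-major order as `(row, column, slice)`; the centre
#' of voxel `(i, j, k)` (1-based) sits at `origin + (c(i, j, k) - 1) * spacing`
#' in millimetres.  Slices are axial.
#'
#' @param data Numeric 3D array.
#' @param spacing Voxel spacing in mm, length 3 (`row`, `column`, `slice`).
#' @param origin Physical position (mm) of voxel `(1, 1, 1)`.
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `spacing` and `origin`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 4)), spacing = c(1, 1, 2.5))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
as.array.image_volume <- function(x, ...) x$data

is_image_volume <- function(x) inherits(x, "image_volume")

#' Multi-sequence MR volume (T1w, T2w, FLAIR)
#'
#' Combines three co-registered single-sequence volumes into one
#' three-channel object, channel order fixed as `(t1, t2, flair)`.  This is
#' the three-channel "colour image" representation fed to the generator.
#'
#' @param t1,t2,flair `image_volume` objects sharing one geometry.
#' @return An object of class `multi_sequence_volume`: list with `data` (4D
#'   array `(row, col, slice, channel)`), `spacing`, `origin`,
#'   `channels = c("t1", "t2", "flair")`.
#' @seealso [unstack_sequences()]
#' @export
stack_sequences <- function(t1, t2, flair) {
  vols <- list(t1 = t1, t2 = t2, flair = flair)
  for (v in vols)
    if (!is_image_volume(v)) stop("inputs must be image_volume objects", call. = FALSE)
  check_same_geometry(t1, t2)
  check_same_geometry(t1, flair)
  d <- dim(t1$data)
  arr <- array(0, c(d, 3L))
  arr[, , , 1L] <- t1$data
  arr[, , , 2L] <- t2$data
  arr[, , , 3L] <- flair$data
  structure(list(data = arr, spacing = t1$spacing, origin = t1$origin,
                 channels = c("t1", "t2", "flair")),
            class = "multi_sequence_volume")
}

#' Split a multi-sequence volume back into single-sequence volumes
#'
#' @param x A `multi_sequence_volume`.
#' @return Named list of three `image_volume` objects (`t1`, `t2`, `flair`).
#' @export
unstack_sequences <- function(x) {
  stopifnot(inherits(x, "multi_sequence_volume"))
  out <- lapply(1:3, function(ch)
    image_volume(array(x$data[, , , ch], dim(x$data)[1:3]), x$spacing, x$origin))
  names(out) <- x$channels
  out
}

#' @export
print.multi_sequence_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multi_sequence_volume> %d x %d x %d voxels x %d channels (%s)\n",
              d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Body mask on an image-volume geometry
#'
#' @param data Logical 3D array (TRUE = body).
#' @param spacing,origin Geometry, as in [image_volume()].
#' @return Object of class `body_mask`.
#' @export
body_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("`data` must be a logical 3D array", call. = FALSE)
  v <- image_volume(data + 0, spacing, origin)  # reuse geometry validation
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("<body_mask> %s voxels, %d foreground (%.1f%%)\n",
              paste(dim(x$data), collapse = " x "), sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

mask_array <- function(mask, ref = NULL) {
  a <- if (inherits(mask, "body_mask")) mask$data else mask
  if (!is.null(ref)) {
    refd <- if (is_image_volume(ref) || inherits(ref, "dose_grid")) dim(ref$data) else dim(ref)
    if (!identical(dim(a), refd))
      stop("mask geometry does not match the volume", call. = FALSE)
  }
  if (!is.logical(a)) stop("mask must be logical", call. = FALSE)
  a
}

check_same_geometry <- function(a, b) {
  da <- if (is.list(a)) dim(a$data) else dim(a)
  db <- if (is.list(b)) dim(b$data) else dim(b)
  if (!identical(da[1:3], db[1:3]))
    stop("volumes do not share a geometry (shape mismatch)", call. = FALSE)
  if (is.list(a) && is.list(b) && !is.null(a$spacing) && !is.null(b$spacing)) {
    if (max(abs(a$spacing - b$spacing)) > 1e-9)
      stop("volumes do not share a geometry (spacing mismatch)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`) into an [image_volume()],
#' preserving voxel spacing and origin.  Only 3D images are accepted.
#'
#' @param path Path to the file.
#' @return An `image_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), "D", call. = FALSE)
  pix <- RNifti::pixdim(img)
  orig <- attr(img, "origin")
  origin <- rep(0, 3)
  image_volume(array(as.numeric(arr), dim(arr)), spacing = pix[1:3], origin = origin)
}

#' Write a volume as NIfTI
#'
#' Integer-valued data are written as int16 (HU and label maps round-trip
#' bit-exactly); everything else as float32/float64 depending on range needs.
#'
#' @param vol An `image_volume` (or `body_mask`, written as uint8).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype; `"auto"` picks int16 for integer-valued
#'   data in range, else `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "auto") {
  if (inherits(vol, "body_mask"))
    vol <- image_volume(vol$data + 0L, vol$spacing, vol$origin)
  stopifnot(is_image_volume(vol))
  dat <- vol$data
  if (datatype == "auto") {
    intlike <- all(dat == round(dat)) && min(dat) >= -32768 && max(dat) <= 32767
    datatype <- if (intlike) "int16" else "double"
  }
  attr(dat, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(dat, datatype = datatype)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
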