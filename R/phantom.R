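#' Tissue contrast model for the digital head phantom
#'
#' Defines, per tissue class, the mean CT number and the mean signal of each
#' MR sequence, plus the Rician noise scale per sequence and the parameters
#' of the smooth multiplicative bias field.  Tissue classes (label codes):
#' 0 air/background, 1 scalp/soft tissue, 2 skull bone, 3 brain parenchyma,
#' 4 CSF/ventricle, 5 lesion, 6 metal clip.
#'
#' Default HU means: air -1000, scalp 40, bone 900, brain 30, CSF 10,
#' lesion 35, metal 3000.  Default MR means encode the usual sequence
#' contrasts (CSF bright on T2w, suppressed on FLAIR; cortical bone dark on
#' all sequences; lesion bright on FLAIR).
#'
#' @param hu Named numeric vector of per-tissue mean HU.
#' @param mr Numeric matrix, rows = tissues (same names as `hu`), columns =
#'   `t1`, `t2`, `flair`: per-sequence mean intensity (arbitrary scanner
#'   units, strictly positive for body tissues).
#' @param noise_sd Rician noise scale per sequence (same units as `mr`).
#' @param bias_amplitude Log-amplitude of the multiplicative bias field
#'   (0 disables it); the field is `exp(p(x))` with `p` a random polynomial.
#' @param bias_order Polynomial order of the bias field (default 2).
#' @return Object of class `contrast_model`.
#' @export
contrast_model <- function(hu = c(air = -1000, scalp = 40, bone = 900,
                                  brain = 30, csf = 10, lesion = 35,
                                  metal = 3000),
                           mr = NULL,
                           noise_sd = c(t1 = 0, t2 = 0, flair = 0),
                           bias_amplitude = 0,
                           bias_order = 2L) {
  tissues <- c("air", "scalp", "bone", "brain", "csf", "lesion", "metal")
  if (is.null(mr)) {
    mr <- rbind(air    = c(0,   0,   0),
                scalp  = c(700, 400, 420),
                bone   = c(150, 100, 110),
                brain  = c(500, 450, 500),
                csf    = c(180, 900, 100),
                lesion = c(350, 700, 800),
                metal  = c(60,  60,  60))
    colnames(mr) <- c("t1", "t2", "flair")
  }
  if (!all(tissues %in% names(hu)))
    stop("`hu` must name all tissues: ", paste(tissues, collapse = ", "), call. = FALSE)
  if (any(hu < -1000 | hu > 3100))
    stop("HU means must lie in [-1000, 3100]", call. = FALSE)
  if (!all(tissues %in% rownames(mr)) || ncol(mr) != 3L)
    stop("`mr` must have one row per tissue and columns t1, t2, flair", call. = FALSE)
  body <- setdiff(tissues, "air")
  if (any(mr[body, ] <= 0))
    stop("MR intensity means must be strictly positive for body tissues", call. = FALSE)
  if (any(noise_sd < 0)) stop("noise scale must be >= 0", call. = FALSE)
  structure(list(hu = hu[tissues], mr = mr[tissues, , drop = FALSE],
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 bias_order = as.integer(bias_order)),
            class = "contrast_model")
}

# label code -> tissue name
.tissue_names <- c("air", "scalp", "bone", "brain", "csf", "lesion", "metal")
label_tissue <- function(lab) .tissue_names[lab + 1L]

#' Generate a digital head phantom
#'
#' Builds a seeded label-map phantom from nested ellipsoids (scalp, skull,
#' brain) with a CSF ventricle, an off-centre spherical lesion and an
#' optional metal clip, and derives the HU volume by assigning each label
#' its [contrast_model()] HU mean, optionally plus small Gaussian texture.
#' Analytic shapes keep voxel counts exactly census-able.
#'
#' @param shape Voxels per axis (row, col, slice); each >= 32.
#' @param spacing mm per axis.
#' @param anatomy Optional overrides: list with elements `head_frac`
#'   (semi-axis fractions of the half-extent), `scalp_mm`, `skull_mm`
#'   (layer thicknesses), `vent_frac`, `lesion_frac`, `lesion_offset_frac`,
#'   `include_metal`.
#' @param model A [contrast_model()] providing the HU means.
#' @param texture_sd Gaussian texture added to the HU volume (HU; default 0,
#'   i.e. piecewise-constant CT).
#' @param seed Integer seed; fixed seed gives voxel-identical output.
#' @return List with `labels` (an `image_volume` of integer codes 0-6) and
#'   `ct` (an `image_volume` in HU).
#' @examples
#' ph <- generate_head_phantom(shape = c(48, 48, 16), spacing = c(3, 3, 3), seed = 1)
#' table(ph$labels$data)
#' @export
generate_head_phantom <- function(shape = c(96, 96, 40),
                                  spacing = c(2.5, 2.5, 2.5),
                                  anatomy = list(),
                                  model = contrast_model(),
                                  texture_sd = 0,
                                  seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("`shape` must give >= 32 voxels per axis", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("`spacing` must be positive", call. = FALSE)
  an <- utils::modifyList(list(head_frac = c(0.80, 0.88, 0.92),
                               scalp_mm = 5, skull_mm = 7,
                               vent_frac = c(0.22, 0.30, 0.30),
                               lesion_frac = 0.16,
                               lesion_offset_frac = c(0.35, 0.25, 0.05),
                               include_metal = FALSE), anatomy)

  ext <- shape * spacing / 2                      # half-extents, mm
  ctr <- (shape - 1) * spacing / 2                # physical centre
  x <- ((seq_len(shape[1]) - 1) * spacing[1] - ctr[1])
  y <- ((seq_len(shape[2]) - 1) * spacing[2] - ctr[2])
  z <- ((seq_len(shape[3]) - 1) * spacing[3] - ctr[3])

  inside_ellipsoid <- function(semi, off = c(0, 0, 0)) {
    u2 <- ((x - off[1]) / semi[1])^2
    v2 <- ((y - off[2]) / semi[2])^2
    w2 <- ((z - off[3]) / semi[3])^2
    outer(outer(u2, v2, "+"), w2, "+") <= 1
  }

  head_semi <- an$head_frac * ext
  skull_semi <- pmax(head_semi - an$scalp_mm, 1)
  brain_semi <- pmax(skull_semi - an$skull_mm, 1)

  lab <- array(0L, shape)
  lab[inside_ellipsoid(head_semi)] <- 1L          # scalp / soft tissue
  lab[inside_ellipsoid(skull_semi)] <- 2L         # skull
  lab[inside_ellipsoid(brain_semi)] <- 3L         # brain parenchyma
  vent <- inside_ellipsoid(an$vent_frac * brain_semi) & lab == 3L
  lab[vent] <- 4L                                 # CSF ventricle
  les_r <- an$lesion_frac * min(brain_semi)
  les_off <- an$lesion_offset_frac * brain_semi
  les <- inside_ellipsoid(rep(les_r, 3), les_off) & lab == 3L
  lab[les] <- 5L                                  # lesion
  if (isTRUE(an$include_metal)) {
    clip <- inside_ellipsoid(rep(max(2 * max(spacing), 4), 3),
                             c(0, -0.95 * skull_semi[2], 0)) & lab %in% c(1L, 2L)
    lab[clip] <- 6L                               # surgical clip
  }

  hu <- array(model$hu[label_tissue(lab)], shape)
  if (texture_sd > 0) {
    set.seed(as.integer(seed))
    hu <- hu + array(stats::rnorm(length(hu), 0, texture_sd), shape)
    hu[lab == 0L] <- model$hu["air"]              # keep background clean
  }
  list(labels = image_volume(lab, spacing), ct = image_volume(hu, spacing))
}

# smooth strictly-positive multiplicative field: exp(low-order polynomial in
# coordinates normalised to [-1, 1]
random_bias_field <- function(shape, amplitude, order) {
  if (amplitude <= 0) return(array(1, shape))
  u <- seq(-1, 1, length.out = shape[1])
  v <- seq(-1, 1, length.out = shape[2])
  w <- seq(-1, 1, length.out = shape[3])
  logf <- array(0, shape)
  terms <- 0L
  for (i in 0:order) for (j in 0:order) for (k in 0:order) {
    if (i + j + k == 0 || i + j + k > order) next
    coef <- stats::rnorm(1)
    logf <- logf + coef * outer(outer(u^i, v^j, "*"), w^k, "*")
    terms <- terms + 1L
  }
  s <- stats::sd(logf)
  if (s > 0) logf <- logf * (amplitude / s)
  exp(logf - mean(logf))
}

#' Simulate multi-sequence MR from a label phantom
#'
#' Per sequence, the image is `bias_field x tissue_mean` corrupted by Rician
#' noise (magnitude of a complex Gaussian, matching MR magnitude-image
#' physics).  Background tissue mean is ~0, so background ends up at the
#' noise floor.
#'
#' @param labels `image_volume` of integer tissue codes (0-6).
#' @param model A [contrast_model()]; must define all three sequences for
#'   every label present.
#' @param seed Integer seed.
#' @param return_bias If TRUE, attach the per-sequence bias fields as
#'   attribute `"bias_fields"`.
#' @return A `multi_sequence_volume`.
#' @export
simulate_mr <- function(labels, model = contrast_model(), seed = 1L,
                        return_bias = FALSE) {
  stopifnot(is_image_volume(labels))
  lab <- labels$data
  present <- sort(unique(as.vector(lab)))
  if (any(present < 0 | present > 6))
    stop("missing contrast entry: unknown label code(s) ",
         paste(setdiff(present, 0:6), collapse = ", "), call. = FALSE)
  shape <- dim(lab)
  set.seed(as.integer(seed))
  seqs <- colnames(model$mr)
  vols <- list()
  biases <- list()
  for (s in seqs) {
    means <- array(model$mr[label_tissue(lab), s], shape)
    bias <- random_bias_field(shape, model$bias_amplitude, model$bias_order)
    img <- means * bias
    ns <- model$noise_sd[[s]]
    if (ns > 0) {
      re <- img + stats::rnorm(length(img), 0, ns)
      im <- stats::rnorm(length(img), 0, ns)
      img <- array(sqrt(re^2 + im^2), shape)
    }
    vols[[s]] <- image_volume(img, labels$spacing, labels$origin)
    biases[[s]] <- bias
  }
  out <- stack_sequences(vols$t1, vols$t2, vols$flair)
  if (return_bias) attr(out, "bias_fields") <- biases
  out
}

#' Dose grid container
#'
#' @param data 3D dose array (Gy).
#' @param spacing,origin Geometry, as in [image_volume()].
#' @param prescription Prescription dose (Gy) used for normalisation.
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      prescription = 1) {
  v <- image_volume(data, spacing, origin)
  if (!is.finite(prescription) || prescription <= 0)
    stop("`prescription` must be > 0", call. = FALSE)
  structure(c(v, list(prescription = prescription)), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, prescription %g Gy, max %g Gy\n",
              paste(dim(x$data), collapse = " x "), x$prescription,
              max(x$data)))
  invisible(x)
}

#' Analytic dose grid from superposed beams
#'
#' A smooth stand-in for a treatment-planning dose: each beam deposits
#' `exp(-mu * depth)` along its axis with a Gaussian lateral profile, where
#' depth is measured from the body surface along the beam direction.  With
#' `ct` and `cal` supplied, depth becomes radiological (water-equivalent)
#' depth, so the dose responds to HU differences between two CT volumes.
#' The summed field is scaled so the isocenter receives the prescription.
#'
#' Beam angles follow the IEC 61217 gantry convention used throughout the
#' package: 0 deg enters from anterior, increasing clockwise viewed from the
#' couch foot.
#'
#' @param mask A `body_mask` defining the body (and the geometry).
#' @param beams List of beams, each a list with `angle` (deg), optional `mu`
#'   (1/mm attenuation, default 0.005), optional `width` (lateral FWHM in mm,
#'   `Inf` = flat beam).
#' @param prescription Prescription dose in Gy (> 0); the isocenter voxel is
#'   normalised to this value.
#' @param iso Isocenter voxel index `c(row, col, slice)`; default volume
#'   centre.
#' @param ct,cal Optional `image_volume` (HU) and [density_calibration()];
#'   when given, attenuation uses radiological depth.
#' @return A [dose_grid()]; the maximum dose is available as `max(x$data)`.
#' @export
analytic_dose_grid <- function(mask, beams, prescription, iso = NULL,
                               ct = NULL, cal = NULL) {
  if (length(beams) == 0) stop("empty beam specification", call. = FALSE)
  if (!is.finite(prescription) || prescription <= 0)
    stop("`prescription` must be > 0", call. = FALSE)
  m <- mask_array(mask)
  shape <- dim(m)
  sp <- if (inherits(mask, "body_mask")) mask$spacing else c(1, 1, 1)
  if (is.null(iso)) iso <- round(shape / 2)
  red <- NULL
  if (!is.null(ct)) {
    if (is.null(cal)) cal <- density_calibration()
    red <- array(hu_to_red(ct$data, cal), shape)
  }
  xs <- (seq_len(shape[1]) - 1) * sp[1]
  ys <- (seq_len(shape[2]) - 1) * sp[2]
  X <- matrix(xs, shape[1], shape[2])
  Y <- matrix(ys, shape[1], shape[2], byrow = TRUE)
  iso_xy <- c(xs[iso[1]], ys[iso[2]])
  total <- array(0, shape)
  for (bm in beams) {
    ang <- bm$angle * pi / 180
    mu <- if (is.null(bm$mu)) 0.005 else bm$mu
    width <- if (is.null(bm$width)) Inf else bm$width
    # direction of travel (toward the patient) in (x=row-ish?, here x is the
    # "column" physical axis and y the "row" axis): see compute_epl for the
    # shared convention.  Work in (row, col) physical coords: rows = y
    # (anterior->posterior), cols = x (toward patient left).
    d <- c(cos(ang), -sin(ang))       # (row, col) components
    perp <- c(-d[2], d[1])
    S <- (X - iso_xy[1]) * d[1] + (Y - iso_xy[2]) * d[2]     # along-beam
    L <- (X - iso_xy[1]) * perp[1] + (Y - iso_xy[2]) * perp[2]  # lateral
    lat_bin <- round(L / min(sp[1:2]))
    prof <- if (is.finite(width)) {
      sig <- width / (2 * sqrt(2 * log(2)))
      exp(-L^2 / (2 * sig^2))
    } else matrix(1, shape[1], shape[2])
    slice_dose <- matrix(0, shape[1], shape[2])
    anybody <- apply(m, c(1, 2), any)   # in-plane body footprint
    bins <- split(seq_along(S), lat_bin)
    for (bi in bins) {
      body_i <- bi[anybody[bi]]
      if (length(body_i) == 0) next
      ord <- bi[order(S[bi])]
      s0 <- min(S[body_i])
      inb <- S[ord] >= s0 - 1e-9
      slice_dose[ord[inb]] <- exp(-mu * (S[ord[inb]] - s0))
    }
    for (k in seq_len(shape[3])) {
      sd_k <- slice_dose
      if (!is.null(red)) {
        # radiological depth: rescale the exponent per voxel using the mean
        # RED between surface and voxel, approximated along sorted bins
        sd_k <- matrix(0, shape[1], shape[2])
        bodyk <- m[, , k]
        for (bi in bins) {
          body_i <- bi[bodyk[bi]]
          if (length(body_i) == 0) next
          ord <- bi[order(S[bi])]
          s0 <- min(S[body_i])
          sel <- ord[S[ord] >= s0 - 1e-9]
          svals <- S[sel]
          rvals <- red[, , k][sel]
          dstep <- diff(c(s0, svals))
          rad <- cumsum(rvals * pmax(dstep, 0))
          sd_k[sel] <- exp(-mu * rad)
        }
      }
      total[, , k] <- total[, , k] + sd_k * prof
    }
  }
  iso_dose <- total[iso[1], iso[2], iso[3]]
  if (iso_dose <= 0) stop("no beam reaches the isocenter", call. = FALSE)
  total <- total * (prescription / iso_dose)
  dose_grid(total, sp, if (inherits(mask, "body_mask")) mask$origin else c(0, 0, 0),
            prescription = prescription)
}
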