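#' HU to relative electron density calibration
#'
#' Piecewise-linear calibration curve mapping CT number to electron density
#' relative to water.  The curve must be strictly increasing in HU,
#' nonnegative and nondecreasing in RED, and must contain the anchors
#' (-1000, 0.0) (air) and (0, 1.0) (water).  The default table adds
#' (1000, 1.52) and (3000, 2.5) to span bone and metal.
#'
#' @param hu,red Anchor vectors of equal length.
#' @return Object of class `density_calibration`.
#' @export
density_calibration <- function(hu = c(-1000, 0, 1000, 3000),
                                red = c(0, 1, 1.52, 2.5)) {
  if (length(hu) != length(red) || length(hu) < 2)
    stop("invalid argument: need matching hu/red anchors", call. = FALSE)
  if (any(diff(hu) <= 0))
    stop("invalid argument: HU anchors must be strictly increasing", call. = FALSE)
  if (any(red < 0) || any(diff(red) < 0))
    stop("invalid argument: RED must be nonnegative and nondecreasing", call. = FALSE)
  if (!any(hu == -1000 & red == 0) || !any(hu == 0 & red == 1))
    stop("invalid argument: calibration must contain anchors (-1000, 0) and (0, 1)",
         call. = FALSE)
  structure(list(hu = as.numeric(hu), red = as.numeric(red)),
            class = "density_calibration")
}

#' Convert HU to relative electron density
#'
#' Linear interpolation between calibration anchors; values below the first
#' anchor clip to its RED (0 for a valid calibration), values above the last
#' anchor clip to the last RED.
#'
#' @param hu Numeric vector/array of CT numbers.
#' @param cal A [density_calibration()].
#' @return Relative electron densities, same shape as `hu`.
#' @export
hu_to_red <- function(hu, cal = density_calibration()) {
  stopifnot(inherits(cal, "density_calibration"))
  stats::approx(cal$hu, cal$red, xout = as.vector(hu), rule = 2)$y
}

#' Enumerate gantry angles of a beam sweep
#'
#' Angles run from `start_deg` to `end_deg` inclusive in `step_deg`
#' increments modulo 360 (IEC 61217 gantry scale).  The sweep
#' (181, 179, 2) yields the 180 unique angles 181, 183, ..., 359, 1, ...,
#' 179 used for the equivalent-path-length comparison.
#'
#' @param start_deg,end_deg First and last angle (degrees).
#' @param step_deg Positive step; must divide the swept arc.
#' @return Numeric vector of angles in \[0, 360), no duplicates.
#' @export
enumerate_beam_angles <- function(start_deg, end_deg, step_deg) {
  if (step_deg <= 0) stop("invalid argument: step must be > 0", call. = FALSE)
  arc <- (end_deg - start_deg) %% 360
  if (abs(arc / step_deg - round(arc / step_deg)) > 1e-9)
    stop("invalid argument: step does not divide the swept arc", call. = FALSE)
  n <- round(arc / step_deg)
  ang <- (start_deg + step_deg * (0:n)) %% 360
  if (anyDuplicated(ang))
    stop("invalid argument: sweep wraps past the start angle", call. = FALSE)
  ang
}

# exact voxel-boundary (Siddon-type) 2D traversal in the axial plane.
# Gantry convention (IEC 61217): 0 deg enters from anterior (increasing row
# index), angles increase clockwise viewed from the couch foot; columns
# increase toward the patient's left.  Direction of travel:
# (d_row, d_col) = (cos g, -sin g).
ray_segments <- function(n1, n2, sp, iso_xy, angle_deg) {
  g <- angle_deg * pi / 180
  d <- c(cos(g), -sin(g))
  L <- sqrt((n1 * sp[1])^2 + (n2 * sp[2])^2) + 2 * max(sp)
  p0 <- iso_xy - d * L
  ts <- c(0, L)
  for (ax in 1:2) {
    if (abs(d[ax]) < 1e-12) next
    bounds <- (seq(0, c(n1, n2)[ax]) - 0.5) * sp[ax]
    tt <- (bounds - p0[ax]) / d[ax]
    ts <- c(ts, tt[tt > 1e-12 & tt < L - 1e-12])
  }
  ts <- sort(unique(ts))
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  py <- p0[1] + d[1] * mid
  px <- p0[2] + d[2] * mid
  i <- round(py / sp[1]) + 1
  j <- round(px / sp[2]) + 1
  inside <- i >= 1 & i <= n1 & j >= 1 & j <= n2
  list(len = diff(ts), i = i, j = j, inside = inside, t0 = ts[-length(ts)],
       t1 = ts[-1], L = L)
}

#' Equivalent path length along a beam central axis
#'
#' Casts the central-axis ray of a beam through the CT volume in the axial
#' plane of the isocenter, finds the body-surface entry point, and reports
#' the physical depth (entry to isocenter, mm) and the equivalent path
#' length: the line integral of relative electron density along the same
#' segment, accumulated with exact voxel-boundary (Siddon-type) traversal.
#' EPL equals physical depth in water and 0 in air.
#'
#' @param ct `image_volume` in HU.
#' @param mask [body_mask()]; the isocenter must lie inside it.
#' @param beam List with `angle` (deg, IEC 61217) and `iso` voxel index
#'   `c(row, col, slice)`.
#' @param cal A [density_calibration()].
#' @param to `"iso"` (default): integrate entry -> isocenter;
#'   `"exit"`: entry -> body exit.
#' @return List with `depth` and `epl` (mm).
#' @export
compute_epl <- function(ct, mask, beam, cal = density_calibration(),
                        to = c("iso", "exit")) {
  to <- match.arg(to)
  stopifnot(is_image_volume(ct))
  m <- mask_array(mask, ct)
  iso <- as.integer(beam$iso)
  if (length(iso) != 3L) stop("beam$iso must be c(row, col, slice)", call. = FALSE)
  if (!m[iso[1], iso[2], iso[3]])
    stop("invalid argument: isocenter outside the body mask", call. = FALSE)
  d <- dim(ct$data)
  sp <- ct$spacing
  iso_xy <- c((iso[1] - 1) * sp[1], (iso[2] - 1) * sp[2])
  seg <- ray_segments(d[1], d[2], sp[1:2], iso_xy, beam$angle)
  k <- iso[3]
  msl <- m[, , k]
  ctsl <- ct$data[, , k]
  inmask <- rep(FALSE, length(seg$len))
  red <- rep(0, length(seg$len))
  ii <- seg$i[seg$inside]; jj <- seg$j[seg$inside]
  inmask[seg$inside] <- msl[cbind(ii, jj)]
  red[seg$inside] <- hu_to_red(ctsl[cbind(ii, jj)], cal)
  if (!any(inmask)) stop("no-entry error: ray misses the body", call. = FALSE)
  first <- which(inmask)[1]
  t_entry <- seg$t0[first]
  if (to == "iso") {
    t_end <- seg$L
  } else {
    last <- max(which(inmask))
    t_end <- seg$t1[last]
  }
  use <- seg$t0 >= t_entry - 1e-12 & seg$t1 <= t_end + 1e-12
  epl <- sum(red[use] * seg$len[use])
  list(depth = t_end - t_entry, epl = epl, t_entry = t_entry, angle = beam$angle)
}

#' Per-angle EPL difference sweep between two CT volumes
#'
#' Runs [compute_epl()] for both volumes (same mask and isocenter) over a
#' set of gantry angles and tabulates the EPL difference (b - a) per angle,
#' with summary mean, SD, range, and the fraction of beams whose absolute
#' difference stays within 5 mm (the +/-0.5 cm band highlighted in the
#' per-angle comparison).
#'
#' @param ct_a,ct_b `image_volume`s on one geometry (e.g. real and
#'   synthetic CT).
#' @param mask [body_mask()].
#' @param iso Isocenter voxel index `c(row, col, slice)`.
#' @param angles Numeric vector of gantry angles (see
#'   [enumerate_beam_angles()]).
#' @param cal A [density_calibration()].
#' @param to Passed to [compute_epl()].
#' @return Object of class `epl_sweep`: data.frame with columns `angle`,
#'   `depth`, `epl_a`, `epl_b`, `diff` (mm) and attribute `summary`
#'   (list: mean, sd, range, frac_within_5mm).
#' @export
epl_sweep <- function(ct_a, ct_b, mask, iso, angles,
                      cal = density_calibration(), to = "iso") {
  check_same_geometry(ct_a, ct_b)
  rows <- lapply(angles, function(a) {
    ea <- compute_epl(ct_a, mask, list(angle = a, iso = iso), cal, to)
    eb <- compute_epl(ct_b, mask, list(angle = a, iso = iso), cal, to)
    data.frame(angle = a, depth = ea$depth, epl_a = ea$epl, epl_b = eb$epl,
               diff = eb$epl - ea$epl)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(mean = mean(out$diff), sd = stats::sd(out$diff),
                               range = range(out$diff),
                               frac_within_5mm = mean(abs(out$diff) <= 5))
  class(out) <- c("epl_sweep", "data.frame")
  out
}

#' @export
print.epl_sweep <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<epl_sweep> %d beams: diff %.2f +/- %.2f mm (range %.2f to %.2f), %.1f%% within 5 mm\n",
              nrow(x), s$mean, s$sd, s$range[1], s$range[2],
              100 * s$frac_within_5mm))
  invisible(x)
}

# separable bilinear upsampling of a matrix by an integer factor; the new
# pixel centres subdivide the old spacing so grid extents coincide
upsample_bilinear <- function(m, factor) {
  if (factor <= 1) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  x1 <- seq_len(n1)
  xo1 <- seq(1, n1, by = 1 / factor)
  tmp <- apply(m, 2, function(col) stats::approx(x1, col, xout = xo1)$y)
  x2 <- seq_len(n2)
  xo2 <- seq(1, n2, by = 1 / factor)
  t(apply(tmp, 1, function(row) stats::approx(x2, row, xout = xo2)$y))
}

#' 2D gamma analysis of two dose distributions
#'
#' Global gamma: for each evaluated-grid point `p`,
#' `gamma(p) = min over reference points q within the search radius of
#' sqrt(((D_eval(p) - D_ref(q)) / (dd/100 * D_norm))^2 + (|p-q| / dta)^2)`;
#' a point passes when `gamma <= 1`.  The reference grid is optionally
#' upsampled (bilinear, default x3) before the search, and the search disc
#' radius defaults to 3x the distance-to-agreement.  Points below
#' `low_dose_cutoff_frac * D_norm` are excluded when the cutoff is positive.
#'
#' @param ref,eval_ Reference and evaluated dose slices: matrices, or
#'   `dose_grid` objects (a slice is taken via `slice`, default the middle).
#' @param dd Dose-difference criterion in percent of `norm_dose`.
#' @param dta Distance-to-agreement criterion in mm.
#' @param norm_dose Normalisation dose in Gy (> 0); defaults to the
#'   reference prescription (global gamma).
#' @param mask Optional logical matrix of points to evaluate.
#' @param low_dose_cutoff_frac Exclude evaluated points below this fraction
#'   of `norm_dose` (default 0 = keep all; 0.1 is the common clinical
#'   convention).
#' @param spacing In-plane pixel spacing in mm (length 1 or 2); taken from
#'   `dose_grid` inputs automatically.
#' @param slice Slice index for `dose_grid` inputs.
#' @param resample_factor Integer upsampling factor for the searched
#'   (reference) grid.
#' @param search_radius_factor Search radius as a multiple of `dta`.
#' @return Object of class `gamma_result`: list with `gamma` (matrix, `NA`
#'   at excluded points), `pass_rate` (%), `dd`, `dta`, `norm_dose`,
#'   `n_evaluated`.
#' @export
gamma_2d <- function(ref, eval_, dd = 3, dta = 3, norm_dose = NULL,
                     mask = NULL, low_dose_cutoff_frac = 0, spacing = c(1, 1),
                     slice = NULL, resample_factor = 3L,
                     search_radius_factor = 3) {
  grab <- function(x) {
    if (inherits(x, "dose_grid")) {
      k <- if (is.null(slice)) ceiling(dim(x$data)[3] / 2) else slice
      list(m = x$data[, , k], sp = x$spacing[1:2], presc = x$prescription)
    } else list(m = as.matrix(x), sp = rep(spacing, length.out = 2), presc = NULL)
  }
  R <- grab(ref); E <- grab(eval_)
  if (!identical(dim(R$m), dim(E$m)) || max(abs(R$sp - E$sp)) > 1e-9)
    stop("invalid input: dose slices do not share a geometry", call. = FALSE)
  if (is.null(norm_dose)) norm_dose <- R$presc
  if (is.null(norm_dose) || !is.finite(norm_dose) || norm_dose <= 0)
    stop("invalid argument: normalisation dose must be > 0", call. = FALSE)
  include <- if (is.null(mask)) matrix(TRUE, nrow(E$m), ncol(E$m)) else mask
  if (low_dose_cutoff_frac > 0)
    include <- include & (E$m >= low_dose_cutoff_frac * norm_dose)
  f <- max(1L, as.integer(resample_factor))
  refup <- upsample_bilinear(R$m, f)
  g <- gamma_kernel_cpp(E$m, refup, as.numeric(E$sp), as.numeric(R$sp / f),
                        dd / 100 * norm_dose, dta, search_radius_factor * dta,
                        include)
  n_eval <- sum(include)
  pass <- if (n_eval > 0) 100 * mean(g[include] <= 1 + 1e-9) else NA_real_
  structure(list(gamma = g, pass_rate = pass, dd = dd, dta = dta,
                 norm_dose = norm_dose, n_evaluated = n_eval),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: pass rate %.1f%% (%d points)\n",
              x$dd, x$dta, x$pass_rate, x$n_evaluated))
  invisible(x)
}

#' Dose-volume histogram metrics
#'
#' `D_x%` is the dose exceeded by exactly x% of the structure volume
#' (linear interpolation on the sorted voxel doses); `V_95%` is the percent
#' of structure voxels receiving at least 95% of the prescription;
#' `Dmax`/`Dmean` are the maximum and arithmetic mean voxel dose.
#'
#' @param dose A [dose_grid()] (or `image_volume` in Gy).
#' @param structure A [body_mask()] / logical array selecting the structure
#'   (nonempty).
#' @param prescription Prescription dose in Gy; defaults to the dose grid's.
#' @return Object of class `dvh_metrics`: list with `D2`, `D50`, `D98`,
#'   `V95`, `Dmax`, `Dmean`.
#' @export
dvh_metrics <- function(dose, structure, prescription = NULL) {
  m <- mask_array(structure, dose)
  if (!any(m)) stop("invalid input: empty structure", call. = FALSE)
  if (is.null(prescription)) prescription <- dose$prescription
  v <- dose$data[m]
  dx <- function(x) unname(stats::quantile(v, probs = 1 - x / 100, type = 7))
  structure(list(D2 = dx(2), D50 = dx(50), D98 = dx(98),
                 V95 = 100 * mean(v >= 0.95 * prescription),
                 Dmax = max(v), Dmean = mean(v),
                 prescription = prescription, n = length(v)),
            class = "dvh_metrics")
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("D2%% %.2f | D50%% %.2f | D98%% %.2f Gy | V95%% %.1f%% | Dmax %.2f | Dmean %.2f Gy\n",
              x$D2, x$D50, x$D98, x$V95, x$Dmax, x$Dmean))
  invisible(x)
}

#' Paired comparison with normality-driven test choice
#'
#' Computes per-pair differences `a - b`, checks their normality
#' (Shapiro-Wilk at `alpha`), and applies the paired t-test when normality
#' is not rejected or the Wilcoxon signed-rank test otherwise (exact null
#' distribution when n <= 25 with no zero or tied differences, else normal
#' approximation with continuity correction).  If every difference is zero
#' the comparison is flagged degenerate with statistic 0 and p = 1.
#'
#' @param a,b Equal-length numeric vectors (n >= 3) of paired measurements.
#' @param alpha Significance level of the normality check.
#' @param test `"auto"` (default), or force `"t"` / `"wilcoxon"`.
#' @return Object of class `paired_comparison`: list with `differences`,
#'   `normality_p`, `test`, `statistic`, `p_value`, `degenerate`.
#' @export
paired_compare <- function(a, b, alpha = 0.05, test = c("auto", "t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(a) != length(b)) stop("invalid input: unequal lengths", call. = FALSE)
  n <- length(a)
  if (n < 3) stop("invalid input: need at least 3 pairs", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(structure(list(differences = d, normality_p = NA_real_,
                          test = "degenerate", statistic = 0, p_value = 1,
                          degenerate = TRUE),
                     class = "paired_comparison"))
  norm_p <- if (stats::sd(d) > 0 && n >= 3 && n <= 5000)
    tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  else NA_real_
  if (test == "auto")
    test <- if (!is.na(norm_p) && norm_p > alpha) "t" else "wilcoxon"
  if (test == "t") {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                test = "paired t")
  } else {
    dd <- d[d != 0]
    exact <- length(dd) <= 25 && !any(duplicated(abs(dd))) && length(dd) == n
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = exact, correct = TRUE))
    res <- list(statistic = unname(wt$statistic), p_value = wt$p.value,
                test = if (exact) "wilcoxon signed-rank (exact)"
                       else "wilcoxon signed-rank (normal approx.)")
  }
  structure(list(differences = d, normality_p = norm_p, test = res$test,
                 statistic = res$statistic, p_value = res$p_value,
                 degenerate = FALSE),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: statistic %.4g, p = %.4g (normality p = %.3g)\n",
              x$test, x$statistic, x$p_value,
              if (is.na(x$normality_p)) NA else x$normality_p))
  invisible(x)
}
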