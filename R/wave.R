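# Calcium-imaging statistics for quantifying ionic-current modulation of
# neuronal networks: relative concentration normalization, weighted-mean
# centre of fluorescence along a measurement line, relative displacement,
# wave-speed estimation, activation-pattern classification and group
# comparison.

#' Construct a time-lapse fluorescence stack
#'
#' @param intensities numeric array `frames x height x width`,
#'   non-negative arbitrary units.
#' @param frame_interval_s seconds per frame (1.28 s in the acquisitions
#'   this package emulates).
#' @param pixel_size_um physical pixel size.
#' @param metadata free-form list (labels, seed, ground-truth pointers).
#' @return An object of class `time_lapse_stack`.
#' @export
time_lapse_stack <- function(intensities, frame_interval_s = 1.28,
                             pixel_size_um = 2, metadata = list()) {
  if (length(dim(intensities)) != 3)
    stop_invalid("intensities must be a frames x height x width array")
  if (any(intensities < 0)) stop_invalid("intensities must be non-negative")
  if (frame_interval_s <= 0 || pixel_size_um <= 0)
    stop_invalid("frame interval and pixel size must be positive")
  structure(list(intensities = intensities,
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um, metadata = metadata),
            class = "time_lapse_stack")
}

#' @export
print.time_lapse_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "time_lapse_stack: %d frames of %d x %d px (%.3g s/frame, %.3g um/px)\n",
    d[1], d[2], d[3], x$frame_interval_s, x$pixel_size_um))
  invisible(x)
}

#' Maximum intensity projection over z
#'
#' Collapses a `slices x height x width` z-stack to a single image by the
#' per-pixel maximum, the standard reduction applied to confocal z-stacks
#' before time-lapse analysis.
#'
#' @param z_stack numeric array `slices x height x width`.
#' @return a `height x width` matrix.
#' @export
max_z_projection <- function(z_stack) {
  d <- dim(z_stack)
  if (length(d) != 3 || d[1] < 1) stop_invalid("need >= 1 slice")
  out <- z_stack[1, , ]
  for (i in seq_len(d[1])[-1]) out <- pmax(out, z_stack[i, , ])
  out
}

# bilinear interpolation of an image at fractional pixel coordinates
# (x = column, y = row, 1-based pixel centres); vectorized over points
.bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- pmin(pmax(floor(x), 1), w - 1); y0 <- pmin(pmax(floor(y), 1), h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)];     i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]; i11 <- img[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Extract a line profile from every frame of a stack
#'
#' Samples the intensity along a straight line at roughly one-pixel
#' spacing, bilinearly interpolated and averaged transversely over `width`
#' parallel offsets. Distances are in micrometres from the first endpoint
#' (placed at the tissue boundary facing the incoming current).
#'
#' @param stack a [time_lapse_stack()].
#' @param endpoints 2 x 2 matrix of pixel coordinates, rows = start/end
#'   points, columns = (x, y).
#' @param width transverse averaging width in pixels (odd, >= 1).
#' @return An object of class `line_profile` with fields `distance_um`
#'   (strictly increasing from 0), `intensity` (frames x samples),
#'   `times_s`, `total_length_um`, `endpoints`, `width`.
#' @export
extract_line_profile <- function(stack, endpoints, width = 1) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  endpoints <- as.matrix(endpoints)
  if (!all(dim(endpoints) == c(2, 2))) stop_invalid("endpoints must be 2 x 2")
  if (width < 1) stop_invalid("width must be >= 1")
  d <- dim(stack$intensities)
  len_px <- sqrt(sum((endpoints[2, ] - endpoints[1, ])^2))
  if (len_px <= 0) stop_invalid("degenerate line")
  n_s <- max(2L, ceiling(len_px) + 1L)
  tt <- seq(0, 1, length.out = n_s)
  ux <- (endpoints[2, 1] - endpoints[1, 1]) / len_px
  uy <- (endpoints[2, 2] - endpoints[1, 2]) / len_px
  offs <- seq_len(width) - (width + 1) / 2      # transverse offsets, px
  xs <- outer(endpoints[1, 1] + tt * len_px * ux, -uy * offs, `+`)
  ys <- outer(endpoints[1, 2] + tt * len_px * uy,  ux * offs, `+`)
  if (any(xs < 1) || any(xs > d[3]) || any(ys < 1) || any(ys > d[2]))
    stop_invalid("line (with transverse width) leaves the image")
  prof <- matrix(0, d[1], n_s)
  for (f in seq_len(d[1])) {
    v <- .bilinear(stack$intensities[f, , ], as.vector(xs), as.vector(ys))
    prof[f, ] <- rowMeans(matrix(v, n_s, width))
  }
  structure(list(
    distance_um = tt * len_px * stack$pixel_size_um,
    intensity = prof,
    times_s = (seq_len(d[1]) - 1) * stack$frame_interval_s,
    total_length_um = len_px * stack$pixel_size_um,
    endpoints = endpoints, width = width,
    pixel_size_um = stack$pixel_size_um
  ), class = "line_profile")
}

#' Fluorescence trace with normalization anchors
#'
#' @param values intensity time series at one location.
#' @param mode `"fluorogenic"` (indicator brightens with analyte, F_final
#'   is the maximum, as for a calcium indicator) or `"quenching"` (F_final
#'   is the minimum, as for a chloride indicator).
#' @param baseline_frames frames averaged for the initial intensity F0
#'   (recorded before the conductive hydrogel network forms).
#' @return An object of class `fluorescence_trace` with `f0` and
#'   `f_final`.
#' @export
fluorescence_trace <- function(values, mode = c("fluorogenic", "quenching"),
                               baseline_frames = 3) {
  mode <- match.arg(mode)
  if (length(values) < baseline_frames + 1)
    stop_invalid("trace shorter than the baseline window")
  f0 <- mean(values[seq_len(baseline_frames)])
  f_final <- if (mode == "fluorogenic") max(values) else min(values)
  if (f_final == f0)
    stop("degenerate normalization: F_final equals F0", call. = FALSE)
  structure(list(values = values, mode = mode, f0 = f0, f_final = f_final),
            class = "fluorescence_trace")
}

#' Relative concentration from a fluorescence trace
#'
#' Normalizes fluorescence to the relative analyte concentration
#' `C = (Fluo(t) - F0) / (F_final - F0)`, which is 0 at baseline and 1 at
#' the extremal frame, and is invariant to affine rescaling (gain/offset)
#' of the raw intensities.
#'
#' @param trace a [fluorescence_trace()].
#' @param t optional frame indices; default the whole series.
#' @return relative concentration values.
#' @export
relative_concentration <- function(trace, t = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  v <- if (is.null(t)) trace$values else trace$values[t]
  (v - trace$f0) / (trace$f_final - trace$f0)
}

#' Weighted-mean distance (centre of fluorescence)
#'
#' Intensity-weighted mean position along a measurement line,
#' `sum(Intensity * Distance) / sum(Intensity)`. The statistic is
#' translation-equivariant and invariant to intensity scaling, but it is
#' sensitive to constant offsets (a uniform background pulls it toward the
#' line midpoint); `background` optionally subtracts such a constant
#' (values clipped at zero) before weighting.
#'
#' @param intensity non-negative weights along the line.
#' @param distance_um positions, micrometres.
#' @param background constant background to subtract (default 0, i.e.
#'   off).
#' @return the centre of fluorescence in micrometres.
#' @export
weighted_mean_distance <- function(intensity, distance_um, background = 0) {
  if (length(intensity) != length(distance_um))
    stop_invalid("intensity and distance lengths differ")
  w <- pmax(intensity - background, 0)
  s <- sum(w)
  if (s <= 0)
    stop("undefined centre: all intensities zero after background removal",
         call. = FALSE)
  sum(w * distance_um) / s
}

#' Relative displacement of the centre of fluorescence
#'
#' `(wmd_end - wmd_start) / total_length`: the shift of the centre of
#' fluorescence between before and after attachment of the droplet device,
#' as a fraction of the measurement-line length.
#'
#' @param wmd_start_um,wmd_end_um centres of fluorescence, micrometres.
#' @param total_length_um line length, micrometres (> 0).
#' @return dimensionless displacement in [-1, 1].
#' @export
relative_displacement <- function(wmd_start_um, wmd_end_um, total_length_um) {
  if (total_length_um <= 0) stop_invalid("total length must be positive")
  (wmd_end_um - wmd_start_um) / total_length_um
}

#' Displacement trajectory of a line profile
#'
#' Computes the weighted-mean-distance trajectory of a [line_profile] and
#' summarizes it: the relative displacement between the pre-attachment
#' baseline and the end of the observation window, and the wave speed over
#' the window.
#'
#' The first `baseline_frames` frames are treated as recorded before
#' device attachment; the observation window covers `window_s` seconds
#' from attachment. Endpoints are short averages (the baseline frames at
#' the start, the final `end_frames` frames of the window) rather than
#' single frames.
#'
#' @param profile a [extract_line_profile()] result.
#' @param window_s observation window after attachment, seconds.
#' @param baseline_frames pre-attachment frames.
#' @param end_frames frames averaged for the window endpoint.
#' @param background constant background subtracted before weighting;
#'   `"auto"` estimates it robustly from the pre-attachment frames as
#'   median + 2 MAD, the guard band suppressing the spurious uniform
#'   weight that clipped noise would otherwise contribute in empty
#'   regions.
#' @return An object of class `displacement_result` with the trajectory
#'   (`wmd_um`, `times_s`), `relative_displacement`, `total_length_um`,
#'   `wave_speed_um_s` and the window definition.
#' @export
displacement_result <- function(profile, window_s = 90, baseline_frames = 3,
                                end_frames = 3, background = 0) {
  stopifnot(inherits(profile, "line_profile"))
  nf <- nrow(profile$intensity)
  if (nf < baseline_frames + 2)
    stop_invalid("profile has too few frames for the baseline window")
  if (identical(background, "auto")) {
    bl <- profile$intensity[seq_len(baseline_frames), ]
    background <- stats::median(bl) + 2 * stats::mad(bl)
  }
  # frames with no weight (e.g. noise-free pre-onset frames) get NA
  wmd <- vapply(seq_len(nf), function(f) {
    w <- pmax(profile$intensity[f, ] - background, 0)
    if (sum(w) <= 0) NA_real_
    else sum(w * profile$distance_um) / sum(w)
  }, numeric(1))
  t_attach <- profile$times_s[baseline_frames]   # attachment reference
  in_window <- profile$times_s > t_attach &
    profile$times_s <= t_attach + window_s
  iw <- which(in_window)
  if (length(iw) < 2) stop_invalid("observation window contains < 2 frames")
  # an empty line (all frames undefined before onset) has its centre at
  # the midpoint by symmetry convention
  wb <- wmd[seq_len(baseline_frames)]
  wmd_start <- if (any(is.finite(wb))) mean(wb[is.finite(wb)])
  else profile$total_length_um / 2
  we <- wmd[utils::tail(iw, end_frames)]
  if (!any(is.finite(we)))
    stop("insufficient data: no defined centre at the window end",
         call. = FALSE)
  wmd_end <- mean(we[is.finite(we)])
  res <- structure(list(
    wmd_um = wmd, times_s = profile$times_s,
    window_frames = iw, window_s = window_s,
    baseline_frames = baseline_frames,
    wmd_start_um = wmd_start, wmd_end_um = wmd_end,
    total_length_um = profile$total_length_um,
    relative_displacement = relative_displacement(wmd_start, wmd_end,
                                                  profile$total_length_um),
    background = background
  ), class = "displacement_result")
  res$wave_speed_um_s <- wave_speed(res)
  res
}

#' @export
print.displacement_result <- function(x, ...) {
  cat(sprintf(paste0(
    "displacement_result: relative displacement %.3f over %.4g um ",
    "(%.4g s window),\n  wave speed %.3g um/s\n"),
    x$relative_displacement, x$total_length_um, x$window_s,
    x$wave_speed_um_s))
  invisible(x)
}

#' Wave propagation speed from a displacement trajectory
#'
#' Least-squares slope of the weighted-mean distance against time over the
#' observation window.
#'
#' @param result a [displacement_result()].
#' @return speed in um/s.
#' @export
wave_speed <- function(result) {
  stopifnot(inherits(result, "displacement_result"))
  iw <- result$window_frames
  ok <- iw[is.finite(result$wmd_um[iw])]
  if (length(ok) < 2)
    stop("insufficient data: fewer than 2 frames with a defined centre",
         call. = FALSE)
  unname(stats::coef(stats::lm(result$wmd_um[ok] ~ result$times_s[ok]))[2])
}

#' Classify an activation pattern as wave-like or simultaneous
#'
#' A recording whose centre of fluorescence shifts by more than
#' `threshold` (as a fraction of the line) is called wave-like; otherwise
#' the network responded simultaneously. The default threshold comes from
#' the midpoint calibration on synthetic cohorts
#' ([calibrate_activation_threshold()]).
#'
#' @param result a [displacement_result()].
#' @param threshold decision threshold on `|relative_displacement|`.
#' @return `"wave_like"` or `"simultaneous"`.
#' @export
classify_activation <- function(result, threshold = 0.1) {
  stopifnot(inherits(result, "displacement_result"))
  if (abs(result$relative_displacement) > threshold) "wave_like"
  else "simultaneous"
}

#' Midpoint calibration of the activation-pattern threshold
#'
#' @param wave_displacements,synchronous_displacements relative
#'   displacements measured on labelled (e.g. synthetic) recordings of the
#'   two regimes.
#' @return the midpoint of the two mean absolute displacements.
#' @export
calibrate_activation_threshold <- function(wave_displacements,
                                           synchronous_displacements) {
  (mean(abs(wave_displacements)) + mean(abs(synchronous_displacements))) / 2
}

#' Compare relative displacements between experimental groups
#'
#' Pairwise unpaired one-tailed two-sample t-tests (pooled-variance by
#' default, Welch selectable), testing whether the first group of each
#' pair shifted farther than the second; optionally a one-way ANOVA across
#' all groups.
#'
#' @param groups named list of numeric vectors (n >= 2 each).
#' @param alternative passed to [stats::t.test()]; `"greater"` tests
#'   group1 > group2.
#' @param welch use the Welch (unequal-variance) t-test.
#' @param method `"t"` for pairwise t-tests, `"anova"` for a single
#'   one-way analysis of variance.
#' @return For `method = "t"`, a data.frame with one row per ordered pair:
#'   `group1`, `group2`, `statistic`, `df`, `p_value`, `note` (flags
#'   degenerate zero-variance comparisons instead of returning silent
#'   NaN). For `method = "anova"`, a one-row data.frame with the F
#'   statistic and p-value.
#' @export
group_compare <- function(groups, alternative = "greater", welch = FALSE,
                          method = c("t", "anova")) {
  method <- match.arg(method)
  if (length(groups) < 2) stop_invalid("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop_invalid("each group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  if (method == "anova") {
    dat <- data.frame(
      y = unlist(groups, use.names = FALSE),
      g = factor(rep(names(groups), lengths(groups))))
    fit <- stats::aov(y ~ g, data = dat)
    s <- summary(fit)[[1]]
    return(data.frame(statistic = s[["F value"]][1],
                      df1 = s[["Df"]][1], df2 = s[["Df"]][2],
                      p_value = s[["Pr(>F)"]][1]))
  }
  pairs <- utils::combn(names(groups), 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- groups[[pairs[1, k]]]; g2 <- groups[[pairs[2, k]]]
    if (stats::var(g1) == 0 && stats::var(g2) == 0) {
      return(data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                        statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, note = "degenerate variance"))
    }
    tt <- stats::t.test(g1, g2, alternative = alternative,
                        var.equal = !welch)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               statistic = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               note = "")
  })
  do.call(rbind, out)
}
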