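# Seeded generators for every input the analysis needs: time-lapse
# fluorescence stacks with planted activation patterns (travelling wave,
# synchronous, pharmacologically suppressed) and noisy discharge traces.
# All randomness is confined to these generators and controlled by a seed;
# the caller's RNG state is preserved.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' Specification of a synthetic calcium-imaging recording
#'
#' Describes a spherical neural microtissue (seen as a disc in maximum
#' projection) whose somata light up according to one of three planted
#' activation regimes:
#' \describe{
#'   \item{wave_like}{onset at `distance-from-left-boundary / speed`,
#'     emulating a directional calcium wave driven by an ionic current
#'     entering from the left;}
#'   \item{synchronous}{a common onset latency with small per-soma jitter,
#'     as in a strongly coupled mature network;}
#'   \item{suppressed}{wave-like onsets with the response amplitude scaled
#'     down, emulating partial restoration of the wave pattern under an
#'     inhibitory neurotransmitter.}
#' }
#' Each soma follows double-exponential indicator kinetics
#' `A (exp(-(t - t0)/tau_decay) - exp(-(t - t0)/tau_rise))`, rendered as a
#' Gaussian blob. Noise is Gaussian with intensity-proportional variance
#' (photon-like, `sd = noise_scale * sqrt(I)`) on top of a constant tissue
#' baseline; `noise_scale = 0` disables both noise and baseline.
#'
#' @param regime activation regime.
#' @param diameter_um tissue diameter (570 um, the tube-defined microtissue
#'   size).
#' @param n_somata somata placed uniformly at random in the disc.
#' @param speed_um_s planted wave speed (wave_like/suppressed); the
#'   default lets a wave traverse the tissue within the 90-s observation
#'   window.
#' @param sync_latency_s,sync_jitter_s common onset and per-soma jitter sd
#'   of the synchronous regime.
#' @param rise_tau_s,decay_tau_s indicator kinetics (fast calcium-dye
#'   scales).
#' @param amplitude peak soma intensity, arbitrary units.
#' @param suppressed_factor amplitude multiplier of the suppressed regime
#'   (a free parameter of the emulation, not an estimate).
#' @param baseline resting tissue fluorescence added inside the tissue
#'   mask when noise is enabled.
#' @param noise_scale photon-noise scale; 0 = noise-free.
#' @param soma_sigma_um Gaussian radius of a rendered soma.
#' @param analysis_width_px transverse width of the standard measurement
#'   line assumed when computing the analytic ground-truth displacement.
#' @param baseline_frames pre-attachment frames before the onset clock
#'   starts.
#' @param duration_s recorded time after attachment.
#' @param frame_interval_s,pixel_size_um acquisition settings.
#' @param margin_px blank margin around the tissue.
#' @param soma_xy_um optional fixed soma positions (n x 2 matrix, um from
#'   the image origin) overriding random placement.
#' @param seed integer seed fixing all randomness.
#' @return An object of class `wave_spec`.
#' @export
wave_spec <- function(regime = c("wave_like", "synchronous", "suppressed"),
                      diameter_um = 570, n_somata = 800,
                      speed_um_s = 6,
                      sync_latency_s = 5, sync_jitter_s = 1,
                      rise_tau_s = 0.5, decay_tau_s = 3,
                      amplitude = 300, suppressed_factor = 0.25,
                      baseline = 10, noise_scale = 1,
                      soma_sigma_um = 6, analysis_width_px = 5,
                      baseline_frames = 8, duration_s = 100,
                      frame_interval_s = 1.28, pixel_size_um = 2,
                      margin_px = 8, soma_xy_um = NULL, seed = 1) {
  regime <- match.arg(regime)
  if (diameter_um <= 0) stop_invalid("tissue diameter must be positive")
  if (regime %in% c("wave_like", "suppressed") && speed_um_s <= 0)
    stop_invalid("wave-like regimes need a positive speed")
  if (noise_scale < 0 || baseline < 0)
    stop_invalid("noise scale and baseline must be non-negative")
  structure(as.list(environment()), class = "wave_spec")
}

# closed-form soma kinetics, peak-normalized to `amplitude`
.soma_kinetics <- function(t, t0, rise, decay, amplitude) {
  dt <- t - t0
  raw <- ifelse(dt > 0, exp(-dt / decay) - exp(-dt / rise), 0)
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-tpk / decay) - exp(-tpk / rise)
  amplitude * raw / peak
}

#' Generate a synthetic time-lapse stack with planted ground truth
#'
#' Renders the recording described by a [wave_spec()] and returns the
#' stack together with the generative ground truth: per-soma onset times,
#' the planted wave speed, and the analytic relative displacement of the
#' centre of fluorescence along the standard measurement line (the
#' horizontal tissue diameter), computed from the continuous generative
#' model without rasterization or noise.
#'
#' @param spec a [wave_spec()].
#' @return list with elements `stack` (a [time_lapse_stack()]) and `truth`
#'   (list: `soma_xy_um`, `onset_s`, `speed_um_s`, `amplitude`,
#'   `line_endpoints_px`, `wmd_start_um`, `wmd_end_um`,
#'   `relative_displacement`, `regime`, `seed`).
#' @export
gen_wave_stack <- function(spec) {
  stopifnot(inherits(spec, "wave_spec"))
  with_seed(spec$seed, .gen_wave_stack_impl(spec))
}

.gen_wave_stack_impl <- function(spec) {
  R_um <- spec$diameter_um / 2
  px <- spec$pixel_size_um
  side <- ceiling(spec$diameter_um / px) + 2L * spec$margin_px
  centre_um <- side / 2 * px
  n_post <- ceiling(spec$duration_s / spec$frame_interval_s)
  nf <- spec$baseline_frames + n_post
  # onset clock: t = 0 at device attachment (after the baseline frames)
  t_frame <- (seq_len(nf) - 1) * spec$frame_interval_s -
    spec$baseline_frames * spec$frame_interval_s

  if (is.null(spec$soma_xy_um)) {
    r <- R_um * sqrt(stats::runif(spec$n_somata))
    th <- stats::runif(spec$n_somata, 0, 2 * pi)
    xy <- cbind(centre_um + r * cos(th), centre_um + r * sin(th))
  } else xy <- as.matrix(spec$soma_xy_um)
  n_somata <- nrow(xy)

  dist_left <- xy[, 1] - (centre_um - R_um)   # um from left tissue boundary
  onset <- switch(spec$regime,
    wave_like = dist_left / spec$speed_um_s,
    suppressed = dist_left / spec$speed_um_s,
    synchronous = spec$sync_latency_s +
      stats::rnorm(n_somata, 0, spec$sync_jitter_s))
  amp <- spec$amplitude *
    if (spec$regime == "suppressed") spec$suppressed_factor else 1

  # tissue mask and baseline
  xs_um <- (seq_len(side) - 0.5) * px
  inside <- outer((xs_um - centre_um)^2, (xs_um - centre_um)^2, `+`) <=
    R_um^2   # rows = y, cols = x
  base_img <- if (spec$noise_scale > 0) spec$baseline * inside else
    matrix(0, side, side)

  arr <- array(rep(base_img, each = nf), dim = c(nf, side, side))
  sig_px <- spec$soma_sigma_um / px
  reach <- ceiling(3 * sig_px)
  for (i in seq_len(n_somata)) {
    trace_i <- .soma_kinetics(t_frame, onset[i], spec$rise_tau_s,
                              spec$decay_tau_s, amp)
    if (all(trace_i == 0)) next
    cx <- xy[i, 1] / px + 0.5; cy <- xy[i, 2] / px + 0.5
    ix <- max(1, floor(cx) - reach):min(side, ceiling(cx) + reach)
    iy <- max(1, floor(cy) - reach):min(side, ceiling(cy) + reach)
    blob <- exp(-(outer((iy - cy)^2, (ix - cx)^2, `+`)) / (2 * sig_px^2))
    arr[, iy, ix] <- arr[, iy, ix] +
      array(outer(trace_i, blob), dim = c(nf, length(iy), length(ix)))
  }
  if (spec$noise_scale > 0) {
    arr <- arr + stats::rnorm(length(arr), 0,
                              spec$noise_scale * sqrt(pmax(arr, 0)))
    arr[arr < 0] <- 0
  }
  stack <- time_lapse_stack(arr, spec$frame_interval_s, px,
                            metadata = list(regime = spec$regime,
                                            seed = spec$seed))

  # analytic ground truth along the horizontal diameter line
  line_y_um <- centre_um
  x0_px <- (centre_um - R_um) / px + 0.5
  x1_px <- (centre_um + R_um) / px + 0.5
  endpoints <- rbind(c(x0_px, line_y_um / px + 0.5),
                     c(x1_px, line_y_um / px + 0.5))
  xg <- seq(centre_um - R_um, centre_um + R_um, length.out = 573)
  base_line <- if (spec$noise_scale > 0) spec$baseline else 0
  # transverse offsets of the standard analysis line (um)
  toff <- (seq_len(spec$analysis_width_px) -
             (spec$analysis_width_px + 1) / 2) * px
  analytic_wmd <- function(t) {
    w <- rep(base_line, length(xg))
    for (i in seq_len(n_somata)) {
      trc <- .soma_kinetics(t, onset[i], spec$rise_tau_s,
                            spec$decay_tau_s, amp)
      if (trc == 0) next
      tw <- mean(exp(-(line_y_um + toff - xy[i, 2])^2 /
                       (2 * spec$soma_sigma_um^2)))
      w <- w + trc * tw * exp(-(xg - xy[i, 1])^2 /
                                (2 * spec$soma_sigma_um^2))
    }
    if (sum(w) <= 0) return(NA_real_)
    sum(w * (xg - xg[1])) / sum(w)
  }
  # evaluate the endpoint at the frame times the analysis averages
  # (the last 3 in-window frames of the default 90-s window)
  tw <- t_frame[t_frame > 0 & t_frame <= 90]
  t_eval <- utils::tail(tw, 3)
  truth <- list(
    soma_xy_um = xy, onset_s = onset,
    speed_um_s = if (spec$regime == "synchronous") 0 else spec$speed_um_s,
    amplitude = amp, line_endpoints_px = endpoints,
    wmd_start_um = spec$diameter_um / 2,   # uniform-baseline centre
    wmd_end_um = mean(vapply(t_eval, analytic_wmd, numeric(1))),
    regime = spec$regime, seed = spec$seed)
  truth$relative_displacement <-
    (truth$wmd_end_um - truth$wmd_start_um) / spec$diameter_um
  list(stack = stack, truth = truth)
}

#' Run the displacement analysis on a stack with its standard line
#'
#' Convenience pipeline: extracts the horizontal-diameter line profile and
#' computes the [displacement_result()].
#'
#' @param stack a [time_lapse_stack()].
#' @param endpoints line endpoints in pixel coordinates (defaults to the
#'   generator's standard line if recorded in `truth`, otherwise must be
#'   given).
#' @param width transverse averaging width, pixels.
#' @param window_s,baseline_frames,background passed to
#'   [displacement_result()].
#' @return a [displacement_result()].
#' @export
analyze_stack <- function(stack, endpoints, width = 5, window_s = 90,
                          baseline_frames = 8, background = 0) {
  prof <- extract_line_profile(stack, endpoints, width)
  displacement_result(prof, window_s = window_s,
                      baseline_frames = baseline_frames,
                      background = background)
}

#' Generate a labelled cohort of synthetic recordings
#'
#' Produces `n_per_regime` seeded recordings for each requested regime.
#' By default the stacks themselves are returned; supplying `analyze`
#' (a function of `stack` and `truth`) maps each recording to its analysis
#' result as soon as it is generated, so large cohorts never hold more
#' than one stack in memory.
#'
#' @param n_per_regime recordings per regime.
#' @param regimes regimes to include.
#' @param seed base seed; item i of regime j uses `seed + 1000 j + i`.
#' @param spec_template a [wave_spec()] providing all other parameters.
#' @param analyze optional `function(stack, truth)`.
#' @return a list with one element per recording: `regime`, `seed`,
#'   `truth`, and either `stack` or `result`.
#' @export
gen_cohort <- function(n_per_regime = 3,
                       regimes = c("wave_like", "synchronous", "suppressed"),
                       seed = 1, spec_template = wave_spec(),
                       analyze = NULL) {
  if (n_per_regime < 1) stop_invalid("n_per_regime must be >= 1")
  out <- list()
  for (j in seq_along(regimes)) {
    for (i in seq_len(n_per_regime)) {
      sp <- spec_template
      sp$regime <- regimes[j]
      sp$seed <- seed + 1000L * j + i
      g <- gen_wave_stack(sp)
      item <- list(regime = regimes[j], seed = sp$seed, truth = g$truth)
      if (is.null(analyze)) item$stack <- g$stack
      else item$result <- analyze(g$stack, g$truth)
      out[[length(out) + 1L]] <- item
    }
  }
  out
}

#' Specification of a synthetic (noisy) discharge trace
#'
#' @param unit the [power_unit()] to simulate (ignored when `base_trace`
#'   is supplied).
#' @param config an [npp_config()] for the underlying simulation.
#' @param base_trace optional precomputed noise-free `trace_result` to
#'   re-use instead of running the solver.
#' @param noise_sd_V_mV,noise_sd_I_uA Gaussian measurement-noise standard
#'   deviations.
#' @param seed integer seed.
#' @return object of class `trace_spec`.
#' @export
trace_spec <- function(unit = power_unit("KCl"),
                       config = npp_config(mode = "short_circuit",
                                           t_end_s = 60),
                       base_trace = NULL,
                       noise_sd_V_mV = 0, noise_sd_I_uA = 0, seed = 1) {
  if (noise_sd_V_mV < 0 || noise_sd_I_uA < 0)
    stop_invalid("noise sd must be non-negative")
  structure(list(unit = unit, config = config, base_trace = base_trace,
                 noise_sd_V_mV = noise_sd_V_mV,
                 noise_sd_I_uA = noise_sd_I_uA, seed = seed),
            class = "trace_spec")
}

#' Generate a noisy discharge trace
#'
#' Runs (or re-uses) a simulated discharge and superimposes Gaussian
#' measurement noise on the voltage and current channels; the cumulative
#' charge is recomputed from the noisy current. With zero noise the result
#' equals the simulator output.
#'
#' @param spec a [trace_spec()].
#' @return a `trace_result`.
#' @export
gen_discharge_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  base <- spec$base_trace %||% run_transient(spec$unit, spec$config)
  with_seed(spec$seed, {
    n <- nrow(base)
    trace_result(base$t_s,
                 base$V_mV + stats::rnorm(n, 0, spec$noise_sd_V_mV),
                 base$I_uA + stats::rnorm(n, 0, spec$noise_sd_I_uA))
  })
}
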