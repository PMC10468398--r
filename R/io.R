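# Readers and writers shared by all modules: multi-page TIFF stacks with a
# JSON metadata sidecar, discharge-trace CSV files, equivalent-circuit
# summaries and YAML/JSON run configuration. Units are embedded in column
# and key names (t_s, V_mV, volume_nl, ...) to prevent unit mistakes.

#' Write a time-lapse stack as a multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per frame, 32-bit samples. The TIFF writer stores values
#' in [0, 1] quantized to 32 bits, so intensities are divided by a
#' power-of-two scale recorded in the sidecar; the quantization error is
#' below 2^-32 of the scale (about 10 significant digits). When all
#' intensities are integer counts (the usual camera output) the sidecar
#' flags it and [read_stack()] restores them exactly.
#'
#' The sidecar records the frame interval, pixel size, scale and any stack
#' metadata (including the generator seed for synthetic stacks).
#'
#' @param stack a [time_lapse_stack()].
#' @param path output TIFF path.
#' @param sidecar sidecar JSON path (default `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  mx <- max(stack$intensities, 1)
  scale <- 2^ceiling(log2(mx))
  frames <- lapply(seq_len(dim(stack$intensities)[1]),
                   function(f) stack$intensities[f, , ] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32)
  meta <- list(frame_interval_s = stack$frame_interval_s,
               pixel_size_um = stack$pixel_size_um,
               intensity_scale = scale,
               integer_counts = all(stack$intensities ==
                                      round(stack$intensities)),
               metadata = stack$metadata)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF time-lapse stack
#'
#' Frames are ordered by page index. Acquisition metadata comes from the
#' JSON sidecar written by [write_stack()] or, failing that, from the
#' explicit arguments; if neither provides the frame interval and pixel
#' size, reading fails rather than assuming silent defaults.
#'
#' @param path TIFF path.
#' @param sidecar sidecar JSON path.
#' @param frame_interval_s,pixel_size_um explicit metadata overrides.
#' @return a [time_lapse_stack()].
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json"),
                       frame_interval_s = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("cannot read stack: no file at ", path,
                               call. = FALSE)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(frame_interval_s) || is.null(pixel_size_um))
    stop("stack metadata (frame interval, pixel size) missing: provide a ",
         "sidecar JSON or explicit arguments", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- meta$intensity_scale %||% 1
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]] * scale
  if (isTRUE(meta$integer_counts)) arr <- round(arr)
  time_lapse_stack(arr, as.numeric(frame_interval_s),
                   as.numeric(pixel_size_um),
                   metadata = meta$metadata %||% list())
}

.trace_columns <- c("t_s", "V_mV", "I_uA", "Q_mC")

#' Write a discharge trace as CSV
#'
#' Columns `t_s,V_mV,I_uA,Q_mC`, full double precision (period decimal
#' separator regardless of locale), so a write/read round trip preserves
#' values beyond 12 significant digits.
#'
#' @param trace a `trace_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_result"))
  df <- as.data.frame(trace)[, .trace_columns]
  fmt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  lines <- c(paste(.trace_columns, collapse = ","),
             if (nrow(df) > 0) apply(matrix(fmt, nrow = nrow(df)), 1,
                                     paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a discharge-trace CSV
#'
#' @param path CSV written by [write_trace()] (header
#'   `t_s,V_mV,I_uA,Q_mC`).
#' @return a `trace_result` with the stored columns.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("cannot read trace: no file at ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), .trace_columns))
    stop("trace schema error: expected header ",
         paste(.trace_columns, collapse = ","), call. = FALSE)
  if (nrow(df) > 0 && is.unsorted(df$t_s))
    stop("trace schema error: times not monotone", call. = FALSE)
  class(df) <- c("trace_result", "data.frame")
  df
}

#' Write an equivalent-circuit summary as JSON
#'
#' @param state a [circuit_state()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_circuit_state <- function(state, path) {
  stopifnot(inherits(state, "circuit_state"))
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Expects a `unit:` block (keys `salt`, `c_high_M`, `c_low_M`,
#' `volume_nl`, `temperature_K`, `permselectivity`,
#' `fixed_charge_mol_m3`, `area_factor`; all optional, with [power_unit()]
#' defaults) and an optional `network:` block (`n_series`, `n_parallel`).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list with elements `unit` (a [power_unit()]), `n_series`,
#'   `n_parallel`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: no file at ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  u <- cfg$unit %||% list()
  unit <- power_unit(
    salt = u$salt %||% "CaCl2",
    c_high = u$c_high_M %||% 2, c_low = u$c_low_M %||% 0.01,
    volume_nl = unlist(u$volume_nl) %||% 50,
    temperature_K = u$temperature_K %||% 298.15,
    permselectivity = unlist(u$permselectivity) %||% 1,
    fixed_charge_mol_m3 = u$fixed_charge_mol_m3 %||% 1000,
    area_factor = u$area_factor %||% 0.7)
  nw <- cfg$network %||% list()
  list(unit = unit, n_series = nw$n_series %||% 1L,
       n_parallel = nw$n_parallel %||% 1L)
}
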