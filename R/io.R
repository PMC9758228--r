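# On-disk formats: flat little-endian int16 + JSON sidecar for signals
# (diff-able, loss bounded by the declared gain), CSV for everything
# tabular. Readers validate the invariants of their target types.

#' Write / read a continuous signal (int16 binary + JSON sidecar)
#'
#' Samples are quantized to little-endian 16-bit integers at
#' `gain` units/bit; the sidecar (`<path>.json`) records
#' `sampling_rate_hz`, `start_time_s`, `gain_uV_per_bit`, and `n_samples`.
#' Reading validates the sidecar against the binary length and errors
#' naming the offending field.
#'
#' @param signal A [continuous_signal()].
#' @param path Path of the binary file (sidecar written alongside).
#' @param gain Units per bit; default scales the signal's maximum absolute
#'   value to 32000 counts (or 1 for an all-zero signal).
#' @return `write_signal()` returns `path` invisibly; `read_signal()` a
#'   [continuous_signal()].
#' @export
write_signal <- function(signal, path, gain = NULL) {
  stopifnot(inherits(signal, "continuous_signal"))
  if (is.null(gain)) {
    mx <- max(abs(signal$samples))
    gain <- if (mx == 0) 1 else mx / 32000
  }
  counts <- as.integer(round(signal$samples / gain))
  if (any(abs(counts) > 32767))
    abort("gain too small: samples overflow int16", class = "phasestim_config_error")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(counts, con, size = 2L, endian = "little")
  jsonlite::write_json(
    list(sampling_rate_hz = signal$sampling_rate,
         start_time_s = signal$start_time,
         gain_uV_per_bit = gain,
         n_samples = length(signal$samples)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    abort(paste0("missing sidecar: ", sidecar), class = "phasestim_data_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("sampling_rate_hz", "start_time_s", "gain_uV_per_bit", "n_samples"))
    if (is.null(meta[[field]]))
      abort(paste0("sidecar missing field `", field, "`"), class = "phasestim_data_error")
  expect_bytes <- 2 * meta$n_samples
  actual <- file.info(path)$size
  if (is.na(actual) || actual != expect_bytes)
    abort(sprintf("binary length %s does not match sidecar n_samples = %d (%d bytes)",
                  actual, meta$n_samples, expect_bytes),
          class = "phasestim_data_error")
  con <- file(path, "rb")
  on.exit(close(con))
  counts <- readBin(con, "integer", n = meta$n_samples, size = 2L,
                    signed = TRUE, endian = "little")
  continuous_signal(counts * meta$gain_uV_per_bit,
                    meta$sampling_rate_hz, meta$start_time_s)
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort(paste0(what, " missing required column(s): ",
                 paste(missing, collapse = ", ")), class = "phasestim_data_error")
  extra <- setdiff(names(df), required)
  if (length(extra))
    warn(paste0(what, " has unknown column(s), ignored: ",
                paste(extra, collapse = ", ")))
  df
}

.read_csv_quiet <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path),
                                class = "phasestim_data_error")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read spike trains, stimulation events, trajectories, epochs
#'
#' Plain CSV with fixed headers, times in seconds written at microsecond
#' precision. Readers enforce the type invariants (sorted spike times,
#' non-overlapping epochs, wrapped phases) and fail with informative
#' errors; unknown columns warn and are dropped.
#'
#' Headers: spikes `spike_time_s,unit_id`; events
#' `command_time_s,delivery_time_s,pulse_width_ms,target_phase_rad,predicted_phase_rad[,true_phase_rad]`;
#' trajectory `time_s,x_mm,y_mm,z_mm`; epochs `start_s,end_s,condition[,block]`.
#'
#' @param spikes,events,traj,epochs Objects as produced by the package.
#' @param path CSV path.
#' @return Writers return `path` invisibly; readers return the package's
#'   corresponding object.
#' @name io_csv
NULL

#' @rdname io_csv
#' @export
write_spikes <- function(spikes, path) {
  readr::write_csv(tibble(spike_time_s = sprintf("%.6f", spikes$spike_time),
                          unit_id = spikes$unit_id), path)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_spikes <- function(path) {
  df <- .check_columns(.read_csv_quiet(path), c("spike_time_s", "unit_id"), "spike CSV")
  if (nrow(df) == 0) return(spike_train(numeric(0)))
  if (is.unsorted(df$spike_time_s, strictly = TRUE))
    abort("spike times must be strictly increasing", class = "phasestim_data_error")
  spike_train(as.numeric(df$spike_time_s), df$unit_id[1])
}

#' @rdname io_csv
#' @export
write_events <- function(events, path) {
  out <- tibble(command_time_s = sprintf("%.6f", events$command_time),
                delivery_time_s = sprintf("%.6f", events$delivery_time),
                pulse_width_ms = events$pulse_width_ms,
                target_phase_rad = events$target_phase,
                predicted_phase_rad = events$predicted_phase,
                true_phase_rad = events$true_phase)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_events <- function(path) {
  req <- c("command_time_s", "delivery_time_s", "pulse_width_ms",
           "target_phase_rad", "predicted_phase_rad")
  df <- .read_csv_quiet(path)
  if (!"true_phase_rad" %in% names(df)) df$true_phase_rad <- NA_real_
  df <- .check_columns(df, c(req, "true_phase_rad"), "events CSV")
  if (nrow(df) && any(df$delivery_time_s < df$command_time_s - 1e-9))
    abort("delivery_time_s must be >= command_time_s", class = "phasestim_data_error")
  out <- tibble(command_time = as.numeric(df$command_time_s),
                delivery_time = as.numeric(df$delivery_time_s),
                pulse_width_ms = df$pulse_width_ms,
                target_phase = .wrap_or_na(df$target_phase_rad),
                predicted_phase = .wrap_or_na(df$predicted_phase_rad),
                true_phase = .wrap_or_na(df$true_phase_rad))
  class(out) <- c("stim_events", class(out))
  out
}

.wrap_or_na <- function(x) ifelse(is.na(x), NA_real_, wrap_phase(ifelse(is.na(x), 0, x)))

#' @rdname io_csv
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble(time_s = sprintf("%.6f", traj$time),
                          x_mm = traj$x, y_mm = traj$y, z_mm = traj$z), path)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_trajectory <- function(path) {
  df <- .check_columns(.read_csv_quiet(path),
                       c("time_s", "x_mm", "y_mm", "z_mm"), "trajectory CSV")
  out <- tibble(time = as.numeric(df$time_s), x = df$x_mm, y = df$y_mm, z = df$z_mm)
  if (nrow(out) > 1) {
    dt <- diff(out$time)
    # times are declared at microsecond precision
    if (any(abs(dt - mean(dt)) > 2e-6))
      abort("trajectory timestamps must be uniform", class = "phasestim_data_error")
    attr(out, "frame_rate") <- 1 / mean(dt)
  }
  class(out) <- c("head_trajectory", class(out))
  out
}

#' @rdname io_csv
#' @export
write_epochs <- function(epochs, path) {
  readr::write_csv(tibble(start_s = epochs$start, end_s = epochs$end,
                          condition = epochs$condition, block = epochs$block),
                   path)
  invisible(path)
}

#' @rdname io_csv
#' @export
read_epochs <- function(path) {
  df <- .read_csv_quiet(path)
  if (!"block" %in% names(df)) df$block <- NA_integer_
  df <- .check_columns(df, c("start_s", "end_s", "condition", "block"), "epoch CSV")
  epoch_set(df$start_s, df$end_s, df$condition,
            block = if (all(is.na(df$block))) NULL else df$block)
}
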