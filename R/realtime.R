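# Streaming simulation: a fixed-rate sample source feeding a ring buffer,
# and a detector that repeatedly copies the buffer, optionally checks that a
# beat sits near the center, converts the copy to an image and classifies it.
# While the detector is busy the source keeps pushing, so samples are
# missed; the workflow accounts for them exactly.
#
# In virtual-time mode time is counted in adjusted sample periods
# (period_factor / fs seconds each) on a logical clock, which makes the whole
# workflow deterministic. In wall-clock mode stage durations are measured
# with the system clock and converted to arrived samples at the same rate.

#' Fixed-capacity FIFO ring buffer
#'
#' Holds the most recent `capacity` pushed samples; once full, each push
#' evicts the oldest sample. `total_pushed` counts every push ever made.
#'
#' @param capacity Buffer size (the model input width `n`).
#' @return A `sample_buffer` object (environment with reference semantics).
#' @export
sample_buffer <- function(capacity) {
  stopifnot(capacity >= 1)
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$data <- numeric(capacity)
  buf$total_pushed <- 0L
  class(buf) <- "sample_buffer"
  buf
}

#' Push samples into a ring buffer
#'
#' @param buf A [sample_buffer()].
#' @param x Numeric vector of samples (pushed in order).
#' @return The buffer, invisibly.
#' @export
buffer_push <- function(buf, x) {
  n <- buf$capacity
  k <- length(x)
  pos <- (buf$total_pushed + seq_len(k) - 1L) %% n + 1L
  buf$data[pos] <- x
  buf$total_pushed <- buf$total_pushed + k
  invisible(buf)
}

#' Buffer contents in arrival order
#'
#' @param buf A [sample_buffer()].
#' @return Numeric vector of the most recent `min(total_pushed, capacity)`
#'   samples, oldest first (a copy: later pushes do not affect it).
#' @export
buffer_contents <- function(buf) {
  n <- buf$capacity
  t <- buf$total_pushed
  if (t <= n) return(buf$data[seq_len(t)])
  pos <- (t - n + seq_len(n) - 1L) %% n + 1L
  buf$data[pos]
}

#' @export
print.sample_buffer <- function(x, ...) {
  cat(sprintf("<sample_buffer> capacity %d, total pushed %d\n",
              x$capacity, x$total_pushed))
  invisible(x)
}

#' Stream a record through a ring buffer
#'
#' Emulates the sample source: pushes one sample of the chosen channel every
#' `period_factor / fs` seconds until the record is exhausted. In
#' virtual-time mode no wall time passes; the push schedule is purely
#' logical, so the final buffer state and push count are deterministic.
#'
#' @param record An [ecg_record()].
#' @param channel 1-based channel index.
#' @param capacity Buffer capacity (model input width).
#' @param period_factor Multiplier on the nominal period `1/fs`; the default
#'   0.9 pushes 10% faster than nominal to offset downstream overhead.
#' @param virtual_time If `TRUE` (default) do not sleep.
#' @return List with the final `buffer`, `total_pushed`, and the inter-push
#'   `period` in seconds.
#' @export
simulate_stream <- function(record, channel = 1L, capacity,
                            period_factor = 0.9, virtual_time = TRUE) {
  stopifnot(inherits(record, "ecg_record"), record$fs > 0)
  period <- period_factor / record$fs
  sig <- record$signal[channel, ]
  buf <- sample_buffer(capacity)
  if (virtual_time) {
    buffer_push(buf, sig)
  } else {
    for (v in sig) {
      t0 <- Sys.time()
      buffer_push(buf, v)
      dt <- period - as.numeric(Sys.time() - t0, units = "secs")
      if (dt > 0) Sys.sleep(dt)
    }
  }
  list(buffer = buf, total_pushed = buf$total_pushed, period = period)
}

#' Check that a window holds a beat near its center
#'
#' Locates the sample with the maximum absolute deviation from the window
#' median (ties broken toward the lowest index) and accepts the window iff
#' that position lies within `tolerance` samples of the center `n/2`
#' (0-based). Rejected windows make the detector start over on the next
#' buffer state.
#'
#' @param samples Numeric window of length `n`.
#' @param tolerance Acceptance half-width in samples (default `n %/% 8`).
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
check_center <- function(samples, tolerance = length(samples) %/% 8L) {
  n <- length(samples)
  dev <- abs(samples - median(samples))
  peak <- which.max(dev) - 1L  # 0-based; which.max takes the lowest tie
  abs(peak - n %/% 2L) <= tolerance
}

#' Run the streaming detection workflow over a record
#'
#' Repeats the detector loop until the stream ends: wait for the buffer to be
#' full, copy it, optionally run [check_center()] (a rejection restarts the
#' loop), convert the copy to a binary image, classify it, and record the
#' result together with the number of samples the source pushed while the
#' detector was busy. The detector only ever reads its private copy, never
#' the live buffer.
#'
#' In virtual-time mode, stage costs are taken from `virtual_costs` (in
#' sample periods) and the accounting is exact; in wall-clock mode stages are
#' timed with the system clock and arrived samples are derived from elapsed
#' time at the adjusted rate.
#'
#' @param record An [ecg_record()].
#' @param model An `ecg_cnn`, or any function `samples -> beat_prediction`
#'   (e.g. a stub classifier for latency experiments); for an `ecg_cnn` the
#'   buffer capacity is the model input width and `h` its input height.
#' @param channel 1-based channel to stream.
#' @param use_check_center Run the center check before classifying.
#' @param limits Length-2 quantization limits; `NULL` uses the channel's
#'   global min/max.
#' @param h Image height (ignored when `model` is a function).
#' @param n Buffer capacity; defaults to the model input width.
#' @param period_factor Multiplier on the nominal sample period (default 0.9).
#' @param virtual_time Deterministic logical clock (default `TRUE`).
#' @param virtual_costs Named list of stage costs in sample periods used in
#'   virtual-time mode: `check`, `convert`, `classify` (defaults all 0).
#' @param tolerance Center-check tolerance, passed to [check_center()].
#' @return A `stream_report`: list with `records` (data frame: id, start,
#'   end, label, confidence, samples_missed, and per-stage seconds) and
#'   `totals` (counts, mean missed samples, mean stage times, mean and
#'   beat-weighted mean confidence).
#' @export
run_workflow <- function(record, model, channel = 1L, use_check_center = TRUE,
                         limits = NULL, h = NULL, n = NULL,
                         period_factor = 0.9, virtual_time = TRUE,
                         virtual_costs = list(check = 0, convert = 0, classify = 0),
                         tolerance = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  is_net <- inherits(model, "ecg_cnn")
  if (is_net) {
    if (is.null(n)) n <- model$input_shape[1]
    if (is.null(h)) h <- model$input_shape[2]
    if (n != model$input_shape[1] || h != model$input_shape[2])
      stop(sprintf("buffer/image geometry (%d, %d) does not match model input (%d, %d)",
                   n, h, model$input_shape[1], model$input_shape[2]))
  } else if (is.null(n)) {
    stop("n (buffer capacity) is required for a stub classifier")
  }
  sig <- record$signal[channel, ]
  total <- length(sig)
  if (total < n) stop("record shorter than one buffer")
  if (is.null(limits)) limits <- range(sig)
  period <- period_factor / record$fs
  cost <- function(nm) {
    v <- virtual_costs[[nm]]
    if (is.null(v)) 0 else v
  }
  buf <- sample_buffer(n)
  buffer_push(buf, sig[seq_len(n)])
  t <- n  # samples pushed so far
  rows <- list()
  id <- 0L
  while (t < total) {  # the detector stops once the source is exhausted
    bc <- buffer_contents(buf)  # detector's private copy
    start <- t - n
    busy <- 0; wall <- c(check = 0, convert = 0, classify = 0)
    accepted <- TRUE
    if (use_check_center) {
      t0 <- Sys.time()
      accepted <- if (is.null(tolerance)) check_center(bc)
                  else check_center(bc, tolerance)
      wall["check"] <- as.numeric(Sys.time() - t0, units = "secs")
      busy <- busy + if (virtual_time) cost("check")
                     else wall["check"] / period
    }
    if (accepted) {
      t0 <- Sys.time()
      img <- signal_to_image(bc, limits[1], limits[2], h)
      wall["convert"] <- as.numeric(Sys.time() - t0, units = "secs")
      busy <- busy + if (virtual_time) cost("convert")
                     else wall["convert"] / period
      t0 <- Sys.time()
      pred <- if (is_net) predict(model, img) else model(bc)
      wall["classify"] <- as.numeric(Sys.time() - t0, units = "secs")
      busy <- busy + if (virtual_time) cost("classify")
                     else wall["classify"] / period
    }
    pushed <- min(floor(busy), total - t)  # arrivals while busy
    if (pushed > 0) buffer_push(buf, sig[(t + 1L):(t + pushed)])
    t <- t + pushed
    if (accepted) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, start = as.integer(start), end = as.integer(start + n),
        label = pred$label, confidence = pred$confidence,
        samples_missed = pushed,
        t_check = wall[["check"]], t_convert = wall[["convert"]],
        t_classify = wall[["classify"]])
      id <- id + 1L
    }
    # wait for the next buffer update before the next copy
    if (t >= total) break
    buffer_push(buf, sig[t + 1L])
    t <- t + 1L
  }
  records <- if (length(rows)) do.call(rbind, rows)
             else data.frame(id = integer(), start = integer(), end = integer(),
                             label = character(), confidence = numeric(),
                             samples_missed = numeric(), t_check = numeric(),
                             t_convert = numeric(), t_classify = numeric())
  totals <- list(
    n_classified = nrow(records),
    total_pushed = buf$total_pushed,
    total_missed = sum(records$samples_missed),
    mean_missed = if (nrow(records)) mean(records$samples_missed) else NA_real_,
    mean_t_check = if (nrow(records)) mean(records$t_check) else NA_real_,
    mean_t_convert = if (nrow(records)) mean(records$t_convert) else NA_real_,
    mean_t_classify = if (nrow(records)) mean(records$t_classify) else NA_real_,
    mean_confidence = if (nrow(records)) mean(records$confidence) else NA_real_,
    weighted_confidence = if (nrow(records)) {
      w <- table(records$label)[records$label]
      sum(records$confidence * as.numeric(w)) / sum(as.numeric(w))
    } else NA_real_)
  structure(list(records = records, totals = totals,
                 period = period, fs = record$fs,
                 use_check_center = use_check_center),
            class = "stream_report")
}

#' @export
print.stream_report <- function(x, ...) {
  tt <- x$totals
  cat(sprintf("<stream_report> %d classification(s) over %d pushed samples\n",
              tt$n_classified, tt$total_pushed))
  cat(sprintf("  mean samples missed per classification: %s\n",
              format(tt$mean_missed)))
  if (!is.na(tt$mean_confidence))
    cat(sprintf("  mean confidence: %.2f%% (beat-weighted %.2f%%)\n",
                100 * tt$mean_confidence, 100 * tt$weighted_confidence))
  invisible(x)
}

#' Write a stream report as CSV plus a JSON summary
#'
#' The CSV has one row per classification with columns `id`,
#' `location` (`"start-end"` in stream sample coordinates, `n` samples wide),
#' `classification` and `confidence` (as a percentage). The JSON summary
#' carries the mean stage timings and missed-sample counts.
#'
#' @param report A `stream_report` from [run_workflow()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `csv_path`, invisibly.
#' @export
write_stream_report <- function(report, csv_path = NULL, json_path = NULL) {
  r <- report$records
  if (!is.null(csv_path)) {
    out <- data.frame(id = r$id,
                      location = sprintf("%d-%d", r$start, r$end),
                      classification = r$label,
                      confidence = sprintf("%.2f%%", 100 * r$confidence))
    write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(report$totals, json_path, digits = NA,
                         auto_unbox = TRUE)
  invisible(csv_path)
}
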