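#' Command specification for the processing pipeline
#'
#' The pipeline mirrors a command-driven control unit with nine commands:
#' \describe{
#'   \item{C1}{record to memory: capture a recording and store it to a file}
#'   \item{C2}{stream raw samples}
#'   \item{C3}{intra-channel (action-potential) compression, lossless or
#'     near-lossless, Golomb or arithmetic backend}
#'   \item{C4}{cross-channel (LFP) compression of a group of up to 8 channels}
#'   \item{C5}{FIR filtering, streamed back to the caller}
#'   \item{C6}{FIR filtering, stored to a file}
#'   \item{C7}{spike-raster packetization}
#'   \item{C8}{adaptive-threshold-estimator report (per-window thresholds)}
#'   \item{C9}{adaptive-threshold-estimator update (stage-1 detector
#'     parameters to be written back to the frontend registers)}
#' }
#' C1/C2 and C5/C6 share handlers and differ only in the output sink; C8/C9
#' share the estimator run.  The `debug` flag sources the input from a stored
#' file instead of a live recording object.
#'
#' @param command one of `"C1"`..`"C9"`.
#' @param channels channel selection (default: all available).
#' @param mode `"lossless"` or `"near_lossless"` (C3).
#' @param backend `"gc"` or `"ac"` (C3).
#' @param coeffs FIR coefficients (C5/C6).
#' @param out output file path (C1/C6).
#' @param debug read the input recording from a file path.
#' @param config an [ate_config()].
#' @return a `command_spec` list.
#' @export
command_spec <- function(command, channels = NULL, mode = "lossless",
                         backend = "gc", coeffs = NULL, out = NULL,
                         debug = FALSE, config = ate_config()) {
  if (!command %in% paste0("C", 1:9))
    stopf("unknown command: %s", command)
  structure(list(command = command, channels = channels, mode = mode,
                 backend = backend, coeffs = coeffs, out = out,
                 debug = debug, config = config),
            class = "command_spec")
}

resolve_input <- function(spec, input) {
  if (isTRUE(spec$debug)) {
    if (!is.character(input)) stopf("debug mode expects a stored file path")
    read_recording(input)
  } else if (inherits(input, "neuro_recording")) input
  else if (is.character(input)) read_recording(input)
  else stopf("input must be a recording or a file path")
}

#' Run a pipeline command
#'
#' Dispatches a [command_spec()] to the matching engine, logging per-stage
#' wall time and output byte counts.
#'
#' @param spec a [command_spec()].
#' @param input a [new_recording()] or a stored recording path.
#' @return list with `command`, `output` (command-specific), and `log`
#'   (data.frame of stages with seconds and bytes).
#' @export
run_command <- function(spec, input) {
  stopifnot(inherits(spec, "command_spec"))
  rec <- resolve_input(spec, input)
  channels <- if (is.null(spec$channels)) rec$channel_ids else spec$channels
  if (!all(channels %in% rec$channel_ids))
    stopf("channel selection outside available channels")
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  note <- function(stage, t0, bytes = NA_real_) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage,
                                           seconds = tic() - t0,
                                           bytes = bytes)
  }
  out <- switch(spec$command,
    C1 = {
      t0 <- tic()
      if (is.null(spec$out)) stopf("C1 requires an output path")
      write_recording(rec, spec$out)
      note("store", t0, file.size(spec$out))
      spec$out
    },
    C2 = {
      t0 <- tic()
      sub <- new_recording(rec$samples[match(channels, rec$channel_ids), ,
                                       drop = FALSE],
                           fs = rec$fs, bit_depth = rec$bit_depth,
                           channel_ids = channels)
      note("stream", t0, length(sub$samples) * 2)
      sub
    },
    C3 = {
      streams <- lapply(channels, function(ch) {
        t0 <- tic()
        ev <- if (spec$mode == "near_lossless")
          detect_spikes(rec, ch, spec$config) else NULL
        bs <- compress_channel(rec, ch, mode = spec$mode,
                               backend = spec$backend, events = ev)
        note(sprintf("ice_ch%d", ch), t0, ceiling(bs$payload_nbits / 8))
        bs
      })
      names(streams) <- as.character(channels)
      streams
    },
    C4 = {
      t0 <- tic()
      tree <- train_channel_tree(rec, channels)
      note("cce_train", t0)
      t0 <- tic()
      bs <- cce_compress(rec, tree)
      note("cce_compress", t0, ceiling(bs$payload_nbits / 8))
      bs
    },
    C5 = ,
    C6 = {
      t0 <- tic()
      if (is.null(spec$coeffs)) stopf("FIR commands require coefficients")
      fb <- filterbank(rec, spec$coeffs, channels)
      note("fir", t0, length(fb$y) * 4)
      if (spec$command == "C6") {
        if (is.null(spec$out)) stopf("C6 requires an output path")
        t0 <- tic()
        saveRDS(fb, spec$out)
        note("store", t0, file.size(spec$out))
        spec$out
      } else fb
    },
    C7 = {
      t0 <- tic()
      sub <- new_recording(rec$samples[match(channels, rec$channel_ids), ,
                                       drop = FALSE],
                           fs = rec$fs, bit_depth = rec$bit_depth,
                           channel_ids = channels)
      frames <- make_raster(detection_bits(sub, spec$config))
      note("raster", t0, length(encode_raster_packets(frames)))
      frames
    },
    C8 = ,
    C9 = {
      t0 <- tic()
      reports <- lapply(channels, function(ch) {
        run <- ate_run(rec_channel(rec, ch), spec$config)
        data.frame(channel = ch, window = seq_along(run$thr_neo),
                   thr_neo = run$thr_neo, thr_amp = run$thr_amp,
                   noise_neo = run$noise_neo, zc_count = run$zc_count)
      })
      rep <- do.call(rbind, reports)
      note("ate", t0)
      if (spec$command == "C8") rep
      else {
        # C9: latest per-channel register values for the stage-1 detector
        last <- do.call(rbind, lapply(split(rep, rep$channel), tail, 1))
        rownames(last) <- NULL
        last[, c("channel", "thr_amp", "thr_neo")]
      }
    })
  list(command = spec$command, output = out, log = do.call(rbind, log))
}

#' Summary metrics of a processing run
#'
#' Collects compression and detection figures into a JSON-serializable list:
#' per-channel SSR for compression outputs, spike counts, and sorting
#' accuracy when ground truth is supplied.
#'
#' @param run a [run_command()] result (or a list of `neuro_bitstream`s).
#' @param truth optional ground-truth data.frame (with `onset`,
#'   `template_id`) for detection/sorting scoring.
#' @param sorted optional [sort_spikes()] result to score against `truth`.
#' @return a named list; serialize with `jsonlite::toJSON`.
#' @export
report_metrics <- function(run, truth = NULL, sorted = NULL) {
  out <- list()
  output <- if (!is.null(run$output)) run$output else run
  if (inherits(output, "cce_bitstream")) {
    out$ssr_total <- ssr(output$n_samples * output$bit_depth *
                           length(output$tree$channels),
                         output$payload_nbits)
  } else if (is.list(output) && length(output) &&
             all(vapply(output, inherits, logical(1), "neuro_bitstream"))) {
    out$ssr_per_channel <- vapply(output, ssr_of, numeric(1))
    out$spike_counts <- vapply(output, function(b) b$header$n_events,
                               integer(1))
  }
  if (!is.null(truth) && !is.null(sorted)) {
    m <- match_events_to_truth(sorted$events, truth)
    ok <- !is.na(m)
    out$detection_rate <- mean(ok)
    out$sorting_accuracy <- sorting_accuracy(sorted$labels[ok],
                                             truth$template_id[m[ok]])
  }
  out
}

# nearest-onset matching of detected events to ground-truth rows
match_events_to_truth <- function(events, truth, tol = 32) {
  vapply(events$events$onset, function(o) {
    d <- abs(truth$onset - o)
    j <- which.min(d)
    if (length(j) && d[j] <= tol) j else NA_integer_
  }, integer(1))
}
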