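#' Acquisition workflow timing parameters
#'
#' Stage durations of the acquisition -> transfer -> processing -> saving
#' workflow. Defaults are the measured operating point of the fast architecture:
#' 512 frames at 100 Hz (5.12 s acquisition per batch), 0.79 s RAM transfer,
#' 1.34 s GPU processing, 0.53 s saving. An optional per-batch stall models the
#' stage-translation overhead of mosaicking on free-floating samples (the data
#' flow must stop during slow stage drift), added to the acquisition stage.
#'
#' @param n_frames Frames per batch (N).
#' @param frame_period_s Frame period T_s in seconds (1 / frame rate).
#' @param t_transfer_s RAM transfer time t_p per batch, seconds.
#' @param t_process_s GPU processing time t_gpu per batch, seconds.
#' @param t_save_s Saving time t_save per batch, seconds.
#' @param n_batches Number of batches (D-FFOCT images) to produce.
#' @param t_stall_s Additive per-batch acquisition stall, seconds (default 0).
#' @return An object of class `acquisition_timing`.
#' @examples
#' acquisition_timing()          # the measured operating point
#' @export
acquisition_timing <- function(n_frames = 512, frame_period_s = 1 / 100,
                               t_transfer_s = 0.79, t_process_s = 1.34,
                               t_save_s = 0.53, n_batches = 10,
                               t_stall_s = 0) {
  stopifnot(n_frames >= 1, frame_period_s >= 0, t_transfer_s >= 0,
            t_process_s >= 0, t_save_s >= 0, n_batches >= 0, t_stall_s >= 0)
  structure(list(n_frames = n_frames, frame_period_s = frame_period_s,
                 t_transfer_s = t_transfer_s, t_process_s = t_process_s,
                 t_save_s = t_save_s, n_batches = n_batches,
                 t_stall_s = t_stall_s),
            class = "acquisition_timing")
}

stage_durations <- function(t) {
  c(acquire = t$n_frames * t$frame_period_s + t$t_stall_s,
    transfer = t$t_transfer_s, process = t$t_process_s, save = t$t_save_s)
}

#' Sequential (unpipelined) total time
#'
#' Total time when each batch runs acquisition, transfer, processing and saving
#' back to back: `n_batches * (N * T_s + t_p + t_gpu + t_save)`.
#'
#' @param t An [acquisition_timing()].
#' @return Seconds.
#' @examples
#' sequential_time(acquisition_timing(n_batches = 10))   # 77.8 s
#' @export
sequential_time <- function(t) {
  stopifnot(inherits(t, "acquisition_timing"))
  t$n_batches * sum(stage_durations(t))
}

#' Discrete-event simulation of the pipelined workflow
#'
#' Executes the four-stage pipeline with one worker per stage, FIFO batches and
#' unbounded inter-stage buffers (batches are logged to RAM): a batch's stage
#' starts as soon as both the previous batch has released the stage's worker
#' and the batch itself has finished the previous stage.
#'
#' @param t An [acquisition_timing()].
#' @return An object of class `schedule_trace`: `trace` (data frame with batch,
#'   stage, start_s, end_s), `completion_s`, `stage_busy_s` (per-stage total
#'   busy time), `bottleneck` (name of the longest stage).
#' @export
simulate_schedule <- function(t) {
  stopifnot(inherits(t, "acquisition_timing"))
  dur <- stage_durations(t)
  B <- t$n_batches
  if (B == 0) {
    return(structure(list(
      trace = data.frame(batch = integer(0), stage = character(0),
                         start_s = numeric(0), end_s = numeric(0)),
      completion_s = 0, stage_busy_s = dur * 0,
      bottleneck = names(dur)[which.max(dur)]), class = "schedule_trace"))
  }
  ns <- length(dur)
  end <- matrix(0, B, ns)
  start <- matrix(0, B, ns)
  for (b in seq_len(B)) {
    for (s in seq_len(ns)) {
      worker_free <- if (b > 1) end[b - 1, s] else 0
      upstream <- if (s > 1) end[b, s - 1] else 0
      start[b, s] <- max(worker_free, upstream)
      end[b, s] <- start[b, s] + dur[s]
    }
  }
  trace <- data.frame(batch = rep(seq_len(B), each = ns),
                      stage = rep(names(dur), B),
                      start_s = as.vector(t(start)),
                      end_s = as.vector(t(end)))
  structure(list(trace = trace, completion_s = end[B, ns],
                 stage_busy_s = dur * B,
                 bottleneck = names(dur)[which.max(dur)]),
            class = "schedule_trace")
}

#' @export
print.schedule_trace <- function(x, ...) {
  cat("Schedule: ", max(x$trace$batch, 0), " batches, completion ",
      signif(x$completion_s, 6), " s, bottleneck stage: ", x$bottleneck,
      "\n", sep = "")
  invisible(x)
}

#' Pipelined total time
#'
#' Closed form for the multithreaded workflow,
#' `n_batches * (N * T_s) + t_p + t_gpu + t_save`: all batches' acquisitions run
#' back to back while the trailing transfer, processing and saving of the last
#' batch drain the pipeline. The closed form holds when acquisition is the
#' bottleneck stage; otherwise the discrete-event simulation result is returned
#' (with the closed form attached as an attribute).
#'
#' @param t An [acquisition_timing()].
#' @return Seconds. When the closed form does not apply, the simulated
#'   completion time, with attribute `closed_form`.
#' @examples
#' pipelined_time(acquisition_timing(n_batches = 10))   # 53.86 s
#' @export
pipelined_time <- function(t) {
  stopifnot(inherits(t, "acquisition_timing"))
  dur <- stage_durations(t)
  closed <- t$n_batches * dur[["acquire"]] + sum(dur[-1])
  if (t$n_batches <= 1) return(t$n_batches * sum(dur))
  if (dur[["acquire"]] >= max(dur[-1])) return(closed)
  sim <- simulate_schedule(t)$completion_s
  structure(sim, closed_form = closed)
}

#' Steady-state per-image period
#'
#' The limiting time per D-FFOCT image as the number of batches grows: the
#' duration of the slowest pipeline stage. At the measured operating point this
#' is the acquisition itself, 512 frames at 100 Hz = 5.12 s per image.
#'
#' @param t An [acquisition_timing()].
#' @return Seconds per batch.
#' @examples
#' steady_state_period(acquisition_timing())   # 5.12
#' @export
steady_state_period <- function(t) {
  stopifnot(inherits(t, "acquisition_timing"))
  max(stage_durations(t))
}

#' Pipelining feasibility conditions
#'
#' Evaluates the three stage-nesting inequalities of the pipelined workflow —
#' `N*T_s >= t_p`, `N*T_s + t_p >= t_gpu`, and `N*T_s + t_p + t_gpu >= t_save` —
#' together with the stricter condition under which the closed-form
#' [pipelined_time()] provably equals the discrete-event completion time,
#' namely that acquisition is at least as long as every other stage. The
#' cumulative inequalities are necessary-style workload conditions; the
#' simulation remains authoritative when they hold but acquisition is not the
#' bottleneck.
#'
#' @param t An [acquisition_timing()].
#' @return Named logical vector: `acq_covers_transfer`, `chain_covers_process`,
#'   `chain_covers_save`, `all_conditions`, `closed_form_exact`.
#' @export
pipelining_feasible <- function(t) {
  stopifnot(inherits(t, "acquisition_timing"))
  d <- stage_durations(t)
  a <- d[["acquire"]]
  c1 <- a >= d[["transfer"]]
  c2 <- a + d[["transfer"]] >= d[["process"]]
  c3 <- a + d[["transfer"]] + d[["process"]] >= d[["save"]]
  c(acq_covers_transfer = c1, chain_covers_process = c2,
    chain_covers_save = c3, all_conditions = c1 && c2 && c3,
    closed_form_exact = a >= max(d[-1]))
}

#' Throughput speed-up versus a sequential reference
#'
#' Ratio of a reference per-image time to the pipelined steady-state period.
#' Against the 50.5 s per image of the prior sequential architecture, the
#' 5.12 s steady-state period gives a factor of about 10.
#'
#' @param t An [acquisition_timing()].
#' @param reference_per_image_s Reference per-image time, seconds (> 0).
#' @return The speed-up factor, with attribute `rounded` (nearest integer).
#' @examples
#' speedup(acquisition_timing(), 50.5)
#' @export
speedup <- function(t, reference_per_image_s) {
  if (reference_per_image_s <= 0) {
    stop("`reference_per_image_s` must be positive", call. = FALSE)
  }
  f <- reference_per_image_s / steady_state_period(t)
  structure(f, rounded = as.integer(round_half_away(f)))
}

#' @export
print.acquisition_timing <- function(x, ...) {
  d <- stage_durations(x)
  cat("Acquisition timing: ", x$n_frames, " frames x ",
      signif(x$frame_period_s * 1000, 4), " ms -> ", signif(d[["acquire"]], 4),
      " s/batch; transfer ", x$t_transfer_s, " s, process ", x$t_process_s,
      " s, save ", x$t_save_s, " s; ", x$n_batches, " batches\n", sep = "")
  cat("  steady-state period ", signif(steady_state_period(x), 4),
      " s/image\n", sep = "")
  invisible(x)
}
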