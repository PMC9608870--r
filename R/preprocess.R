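#' Reject trials by electrooculogram amplitude
#'
#' A trial is rejected when the absolute EOG value exceeds the threshold at
#' any sample of the epoch (strictly greater than; a peak exactly at the
#' threshold is retained). If the trial set carries no EOG channel all trials
#' are retained with a warning.
#'
#' @param trials a `trial_set`.
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @return logical vector, `TRUE` for retained trials.
#' @export
reject_by_eog <- function(trials, threshold_uv = 100) {
  stopifnot(inherits(trials, "trial_set"))
  if (threshold_uv <= 0) stop_("threshold_uv must be positive")
  if (is.null(trials$eog)) {
    warn_("trial set has no EOG channel; retaining all trials")
    return(rep(TRUE, dim(trials$data)[1]))
  }
  peak <- apply(abs(trials$eog), 1, max)
  peak <= threshold_uv
}

#' Apply a retention mask to a trial set
#'
#' @param trials a `trial_set`.
#' @param retained logical vector as returned by [reject_by_eog()].
#' @return the trial set with its `retained` flag updated (trials are kept in
#'   place; downstream operations honour the flag).
#' @export
apply_retention <- function(trials, retained) {
  stopifnot(inherits(trials, "trial_set"),
            length(retained) == dim(trials$data)[1])
  trials$retained <- trials$retained & retained
  trials
}

#' Average each retained trial over the critical temporal window
#'
#' Reduces the trials x vertices x time array to a trials x vertices matrix
#' by the arithmetic mean over all samples with
#' `t_start_ms <= t <= t_end_ms` (both endpoints inclusive). Only retained
#' trials are kept. The default window is the 150-250 ms period of
#' working-memory retrieval; at 400 samples/s it contains 41 samples.
#'
#' @param trials a `trial_set`.
#' @param t_start_ms,t_end_ms window endpoints in ms.
#' @return an object of class `windowed_trials`: list with `data`
#'   (retained trials x vertices matrix), `subject`, `group`, `window`,
#'   `n_samples` (samples averaged) and `rejected` (subject ids of dropped
#'   trials).
#' @export
window_average <- function(trials, t_start_ms = 150, t_end_ms = 250) {
  stopifnot(inherits(trials, "trial_set"))
  if (t_start_ms >= t_end_ms) stop_("t_start_ms must be < t_end_ms")
  tt <- trials$times
  if (t_start_ms < min(tt) || t_end_ms > max(tt)) {
    stop_("window [", t_start_ms, ", ", t_end_ms, "] ms lies outside the epoch [",
          min(tt), ", ", max(tt), "] ms")
  }
  sel <- which(tt >= t_start_ms & tt <= t_end_ms)
  keep <- which(trials$retained)
  x <- trials$data[keep, , sel, drop = FALSE]
  out <- x[, , 1]
  if (length(sel) > 1L) {
    for (j in 2:length(sel)) out <- out + x[, , j]
  }
  out <- out / length(sel)
  if (is.null(dim(out))) out <- matrix(out, nrow = length(keep))

  structure(
    list(data = out,
         subject = trials$subject[keep],
         group = trials$group[keep],
         window = c(t_start_ms, t_end_ms),
         n_samples = length(sel),
         rejected = trials$subject[!trials$retained]),
    class = "windowed_trials"
  )
}

#' @export
print.windowed_trials <- function(x, ...) {
  cat("Windowed trials:", nrow(x$data), "trials x", ncol(x$data),
      "vertices, window", x$window[1], "-", x$window[2], "ms (",
      x$n_samples, "samples )\n")
  if (length(x$rejected)) cat("Rejected trials:", length(x$rejected), "\n")
  invisible(x)
}
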