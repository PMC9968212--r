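#' Build a temperature ramp
#'
#' The default ramp samples 300 K to 450 K in 10 K increments, 10 ns per
#' window (16 windows). Window durations need not be equal: a scalar
#' duration is broadcast, a vector (one entry per window) is honoured
#' verbatim.
#'
#' @param t_start,t_end first and last window temperatures, K.
#' @param increment temperature step between windows, K.
#' @param durations window length(s), ns; scalar or one per window.
#' @return object of class `ttmd_ramp` with `window_temperatures` and
#'   `window_durations`.
#' @export
build_ramp <- function(t_start = 300, t_end = 450, increment = 10, durations = 10) {
  if (t_end < t_start) stop("t_end must be >= t_start")
  if (increment <= 0) stop("increment must be positive")
  temps <- seq(t_start, t_end, by = increment)
  if (any(durations <= 0)) stop("window durations must be positive")
  if (length(durations) == 1) durations <- rep(durations, length(temps))
  if (length(durations) != length(temps))
    stop("duration list length (", length(durations),
         ") does not match window count (", length(temps), ")")
  structure(list(t_start = t_start, t_end = t_end, increment = increment,
                 window_temperatures = temps, window_durations = durations),
            class = "ttmd_ramp")
}

#' Reference fingerprint of the native pose
#'
#' Fingerprints the reference frame (the equilibrated protein-ligand
#' complex the titration starts from). An all-zero result aborts: a pose
#' with no detectable native interactions cannot anchor a titration.
#'
#' @param model a perceived `ttmd_complex`.
#' @param reference_frame a `ttmd_frame` (defaults to the model coordinates).
#' @param cfg a [geometry_config()].
#' @return a non-zero `ttmd_fingerprint`.
#' @export
compute_reference_fp <- function(model, reference_frame = NULL, cfg = geometry_config()) {
  inter <- detect_interactions(model, reference_frame, cfg)
  fp <- build_fingerprint(inter, model$residue_order, model$r)
  if (all(fp == 0)) stop("pose has no detectable native interactions")
  fp
}

score_frame <- function(model, frame, reference_fp, cfg = geometry_config()) {
  inter <- detect_interactions(model, frame, cfg)
  fp <- build_fingerprint(inter, model$residue_order, model$r)
  list(ifp_cs = ifp_cs_score(reference_fp, fp), frame = frame$index,
       temperature = frame$temperature)
}

#' Early-termination test for a scored window
#'
#' TRUE iff the window's mean IFP_CS is exactly zero, i.e. no frame of
#' the window shared any fingerprint feature with the reference (the
#' native binding mode was never sampled). Exact equality is achievable
#' because fingerprints are integer vectors: every per-frame score is 0
#' or strictly negative.
#'
#' @param window a window-result record with a `mean_ifpcs` element.
#' @return logical flag.
#' @export
check_termination <- function(window) {
  if (is.null(window$mean_ifpcs) || is.na(window$mean_ifpcs)) stop("unscored window")
  window$mean_ifpcs == 0
}

#' Run a thermal titration
#'
#' Iterates the temperature windows of `ramp` in order, calling the
#' dynamics backend for each window and chaining its end state into the
#' next (a continuous titration, not independent restarts). Every frame
#' is scored against the reference fingerprint; after each window the
#' mean IFP_CS is checked and the titration terminates early at the first
#' window whose mean is zero. A backbone-RMSD fold monitor is logged per
#' window and warns above `rmsd_warn` but never terminates the run.
#'
#' @param model a perceived `ttmd_complex`.
#' @param pose_frame the starting pose (also the scoring reference),
#'   default the model coordinates.
#' @param ramp a [build_ramp()].
#' @param backend a function `(state, temperature, duration_ns, stride_ps,
#'   seed) -> list(frames, end_state)` satisfying the dynamics backend
#'   contract, e.g. [synth_backend()].
#' @param cfg a [geometry_config()].
#' @param stride_ps frame save interval, ps (default 100: 100 frames per
#'   10 ns window).
#' @param seed integer; all window seeds derive from it.
#' @param rmsd_warn backbone-RMSD warning threshold, Angstrom.
#' @param monitor_rmsd logical; compute the backbone fold monitor.
#' @return object of class `ttmd_run`.
#' @export
run_titration <- function(model, pose_frame = NULL, ramp = build_ramp(),
                          backend, cfg = geometry_config(), stride_ps = 100,
                          seed = 1, rmsd_warn = 5, monitor_rmsd = TRUE) {
  if (is.null(pose_frame)) pose_frame <- as_reference_frame(model)
  check_frame_congruent(model, pose_frame)
  reference_fp <- compute_reference_fp(model, pose_frame, cfg)
  bb_rows <- which(model$protein$name %in% c("N", "CA", "C", "O") &
                   !model$protein$is_h & !model$protein$is_metal)

  state <- list(frame = pose_frame)
  windows <- list()
  terminated <- FALSE
  for (w in seq_along(ramp$window_temperatures)) {
    temp <- ramp$window_temperatures[w]
    dur <- ramp$window_durations[w]
    res <- tryCatch(
      backend(state, temp, dur, stride_ps, derive_seed(seed, w)),
      error = function(e) stop("dynamics backend failed in window ", w,
                               " (", temp, " K): ", conditionMessage(e)))
    if (length(res$frames) == 0) stop("backend returned no frames for window ", w)
    scores <- lapply(res$frames, score_frame, model = model,
                     reference_fp = reference_fp, cfg = cfg)
    mean_ifpcs <- window_mean_ifpcs(scores)
    bb_rmsd <- NA_real_
    if (monitor_rmsd && length(bb_rows) >= 3) {
      bb_rmsd <- mean(vapply(res$frames, function(fr)
        superpose_kabsch(fr$protein_xyz, pose_frame$protein_xyz, bb_rows)$rmsd, 0))
      if (is.finite(bb_rmsd) && bb_rmsd > rmsd_warn)
        warning(sprintf("backbone RMSD %.2f A exceeds %.1f A in window %d (%g K): check ramp design",
                        bb_rmsd, rmsd_warn, w, temp), call. = FALSE)
    }
    win <- list(temperature = temp, duration = dur, frames = res$frames,
                frame_scores = scores, mean_ifpcs = mean_ifpcs,
                backbone_rmsd = bb_rmsd, terminated_here = FALSE)
    win$terminated_here <- check_termination(win)
    windows[[w]] <- win
    state <- res$end_state
    state$frame <- res$frames[[length(res$frames)]]
    if (win$terminated_here) { terminated <- TRUE; break }
  }

  structure(list(reference_fp = reference_fp, windows = windows,
                 last_temperature = windows[[length(windows)]]$temperature,
                 completed_full_ramp = !terminated,
                 ramp = ramp, seed = seed, stride_ps = stride_ps,
                 model = model, pose_frame = pose_frame),
            class = "ttmd_run")
}

#' @export
print.ttmd_run <- function(x, ...) {
  cat("ttmd titration run: ", length(x$windows), " window(s), ",
      x$ramp$t_start, "-", x$last_temperature, " K, ",
      if (x$completed_full_ramp) "completed full ramp"
      else "terminated early (native binding mode lost)", "\n", sep = "")
  for (w in x$windows)
    cat(sprintf("  %4g K  %5.1f ns  mean IFP_CS %+.4f%s\n", w$temperature,
                w$duration, w$mean_ifpcs, if (w$terminated_here) "  <- terminated" else ""))
  invisible(x)
}
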