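#' Quasistatic hysteresis scan
#'
#' Sweeps the input from 0 to 1 in steps of `delta_i`, relaxing fully at
#' each grid point and seeding each relaxation with the previous steady
#' state (the quasistatic limit); then sweeps back down from 1 to 0. The
#' first point of each sweep starts from the uniform 0.5 state. The
#' network is bistable when the two branches of the output gene's steady
#' value differ by more than `threshold` (default 0.01) at any grid point
#' — a heuristic lower-bound criterion: very weak bistability below the
#' threshold goes undetected.
#'
#' @param net a `grn` with assigned output (see [assign_output()]).
#' @param params a [dyn_params()].
#' @param delta_i input grid step.
#' @param threshold branch-discrepancy threshold for declaring bistability.
#' @return a list of class `hysteresis_scan` with `input` (grid),
#'   `up`/`down` branches, `bistable`, `bistable_interval` (`c(I_lo, I_hi)`
#'   or `NULL`) and `switch_class`.
#' @export
hysteresis_scan <- function(net, params = dyn_params(), delta_i = 0.001,
                            threshold = 0.01) {
  stopifnot(inherits(net, "grn"), !is.na(net$output),
            delta_i > 0, delta_i <= 0.5, threshold > 0)
  res <- cpp_hysteresis(net$J, net$input - 1L, net$output - 1L,
                        unclass(params), delta_i)
  gap <- abs(res$up - res$down)
  hit <- gap > threshold
  scan <- list(input = res$input, up = res$up, down = res$down,
               threshold = threshold, delta_i = delta_i,
               bistable = any(hit),
               bistable_interval = if (any(hit))
                 c(min(res$input[hit]), max(res$input[hit])) else NULL)
  scan$switch_class <- classify_interval(scan$bistable_interval, delta_i)
  structure(scan, class = "hysteresis_scan")
}

classify_interval <- function(interval, delta_i) {
  if (is.null(interval)) return("monostable")
  eps <- delta_i / 2
  at0 <- interval[1L] <= eps
  at1 <- interval[2L] >= 1 - eps
  if (at0 && at1) "unswitchable"
  else if (at0 || at1) "one_way"
  else "toggle"
}

#' Classify the switching behaviour of a hysteresis scan
#'
#' Bistable networks fall into three classes by where the bistable input
#' interval sits: strictly inside (0, 1) gives a *toggle* switch (both
#' input states are monostable, so the network can be flipped back and
#' forth); an interval touching exactly one of I = 0 or I = 1 gives a
#' *one-way* switch; an interval covering both endpoints is
#' *unswitchable*. Scans without a bistable interval are *monostable*.
#'
#' @param scan a [hysteresis_scan()].
#' @return one of `"toggle"`, `"one_way"`, `"unswitchable"`,
#'   `"monostable"`.
#' @export
classify_switch <- function(scan) {
  stopifnot(inherits(scan, "hysteresis_scan"))
  classify_interval(scan$bistable_interval, scan$delta_i)
}

#' @export
print.hysteresis_scan <- function(x, ...) {
  cat(sprintf("Hysteresis scan (grid step %g, threshold %g): %s\n",
              x$delta_i, x$threshold, x$switch_class))
  if (x$bistable)
    cat(sprintf("  bistable interval [%.3f, %.3f], max branch gap %.4f\n",
                x$bistable_interval[1L], x$bistable_interval[2L],
                max(abs(x$up - x$down))))
  invisible(x)
}

#' @export
plot.hysteresis_scan <- function(x, xlab = "input I",
                                 ylab = "output expression", ...) {
  graphics::plot(x$input, x$up, type = "l", col = "steelblue",
                 ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  graphics::lines(x$input, x$down, col = "darkorange")
  graphics::legend("topleft", legend = c("increasing I", "decreasing I"),
                   col = c("steelblue", "darkorange"), lty = 1, bty = "n")
  invisible(x)
}

#' Step-input protocol
#'
#' Runs the dynamics from the uniform 0.5 start through a piecewise
#' constant input schedule (default 0 for 1000 steps, 1 for 1000 steps, 0
#' for 1000 steps), optionally with input or internal noise. The network
#' "follows" the input when the output's tail-mean excursion in the middle
#' phase is at least `excursion` and it returns to within `return_tol` of
#' the first phase's tail mean in the last phase; the tail means use the
#' final `tail_window` steps of each phase. These thresholds reflect the
#' near-0/1 responses of highly fit networks and are tunable.
#'
#' @param net a `grn` with assigned output.
#' @param params a [dyn_params()].
#' @param schedule input level per phase.
#' @param phase_len steps per phase (recycled to `length(schedule)`).
#' @param noise optional [noise_spec()] applied at every step.
#' @param tail_window steps of each phase used for the tail mean.
#' @param excursion minimum |mean2 - mean1| to count as a response.
#' @param return_tol maximum |mean3 - mean1| to count as returned.
#' @return a list of class `step_protocol` with `trajectory` (output
#'   expression per step), `phase_means` and `follows`.
#' @export
step_protocol <- function(net, params = dyn_params(), schedule = c(0, 1, 0),
                          phase_len = 1000L, noise = NULL,
                          tail_window = 200L, excursion = 0.5,
                          return_tol = 0.1) {
  stopifnot(inherits(net, "grn"), !is.na(net$output))
  phase_len <- as.integer(rep_len(phase_len, length(schedule)))
  kind <- 0L
  amp <- 0
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    kind <- match(noise$kind, c("input", "internal"))
    amp <- noise$amplitude
  }
  traj <- cpp_step_protocol(net$J, net$input - 1L, net$output - 1L,
                            unclass(params), schedule, phase_len, kind, amp)
  ends <- cumsum(phase_len)
  means <- mapply(function(e, len) {
    w <- min(tail_window, len)
    if (len == 0L) return(NA_real_)
    mean(traj[(e - w + 1L):e])
  }, ends, phase_len)
  follows <- length(means) >= 3L && !anyNA(means[1:3]) &&
    abs(means[2L] - means[1L]) >= excursion &&
    abs(means[3L] - means[1L]) <= return_tol
  structure(list(trajectory = traj, phase_means = means,
                 schedule = schedule, phase_len = phase_len,
                 follows = follows, noise = noise),
            class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf("Step protocol (%s): phase tail means %s -> follows = %s\n",
              paste(x$schedule, collapse = " -> "),
              paste(format(round(x$phase_means, 3)), collapse = ", "),
              x$follows))
  invisible(x)
}

#' @export
plot.step_protocol <- function(x, xlab = "time step",
                               ylab = "output expression", ...) {
  graphics::plot(seq_along(x$trajectory), x$trajectory, type = "l",
                 ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = cumsum(x$phase_len)[-length(x$phase_len)],
                   lty = 3, col = "grey50")
  invisible(x)
}
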