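#' Stimulation protocols
#'
#' A stimulation protocol describes the current delivered during one session:
#' a linear ramp-up from 0 to the target intensity, a constant plateau, and a
#' linear ramp-down back to 0.  The conventional active protocol holds 1 mA
#' for 10 min; the matched sham holds 1 mA for only 20 s, so that the initial
#' scalp sensations are present in both conditions while the sham delivers no
#' sustained stimulation.  Time is measured in seconds since ramp-up onset.
#'
#' @param label Either `"active"` or `"sham"`.
#' @param ramp_up_s,plateau_s,ramp_down_s Phase durations in seconds; all
#'   must be non-negative.
#' @param intensity_mA Plateau current in milliamperes.
#'
#' @return A `stim_protocol` object (a named list with the four parameters
#'   and the label).
#' @examples
#' active_protocol()
#' total_on_s(active_protocol()) - total_on_s(sham_protocol())  # 580 s
#' @export
stim_protocol <- function(label = c("active", "sham"),
                          ramp_up_s = 30,
                          plateau_s = 600,
                          ramp_down_s = 30,
                          intensity_mA = 1) {
  label <- match.arg(label)
  for (d in c(ramp_up_s, plateau_s, ramp_down_s)) {
    if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0) {
      abort("protocol durations must be single non-negative numbers")
    }
  }
  if (!is.numeric(intensity_mA) || intensity_mA < 0) {
    abort("`intensity_mA` must be non-negative")
  }
  structure(
    list(label = label, ramp_up_s = ramp_up_s, plateau_s = plateau_s,
         ramp_down_s = ramp_down_s, intensity_mA = intensity_mA),
    class = "stim_protocol"
  )
}

#' @rdname stim_protocol
#' @export
active_protocol <- function(intensity_mA = 1) {
  stim_protocol("active", 30, 600, 30, intensity_mA)
}

#' @rdname stim_protocol
#' @export
sham_protocol <- function(intensity_mA = 1) {
  stim_protocol("sham", 30, 20, 30, intensity_mA)
}

#' @rdname stim_protocol
#' @param protocol A `stim_protocol`.
#' @export
total_on_s <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  protocol$ramp_up_s + protocol$plateau_s + protocol$ramp_down_s
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol: %s> %g s ramp-up + %g s at %g mA + %g s ramp-down (%g s total)\n",
              x$label, x$ramp_up_s, x$plateau_s, x$intensity_mA,
              x$ramp_down_s, total_on_s(x)))
  invisible(x)
}

#' Current intensity at a given time
#'
#' Piecewise-linear current profile: 0 to `intensity_mA` over the ramp-up,
#' constant during the plateau, back to 0 over the ramp-down, and 0
#' afterwards.
#'
#' @param protocol A [stim_protocol()].
#' @param t Time in seconds since ramp-up onset; vectorised.  Negative times
#'   are an error.
#' @return Current in mA, same length as `t`.
#' @examples
#' current_at(active_protocol(), c(0, 15, 30, 300, 660))
#' current_at(sham_protocol(), 81)  # 0: sham is fully off after 80 s
#' @export
current_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (!is.numeric(t) || anyNA(t)) abort("`t` must be numeric with no NA")
  if (any(t < 0)) abort("`t` must be non-negative (seconds since ramp-up onset)")
  up <- protocol$ramp_up_s
  pl <- protocol$plateau_s
  dn <- protocol$ramp_down_s
  i0 <- protocol$intensity_mA
  end <- up + pl + dn
  out <- numeric(length(t))
  in_up <- t < up
  out[in_up] <- i0 * t[in_up] / up
  in_pl <- t >= up & t < up + pl
  out[in_pl] <- i0
  in_dn <- t >= up + pl & t < end
  out[in_dn] <- i0 * (end - t[in_dn]) / dn
  # ramp edges of zero duration: treat boundary as plateau value
  out[t == end & dn == 0] <- 0
  out
}

#' Probe schedule
#'
#' Times at which the in-task detection probes ("Is the stimulation on?",
#' "How sure are you?") are presented: every `interval_s` seconds from the
#' first interval up to `total_task_s`.  The default 16-min task probed every
#' 30 s gives 32 probes, the first at 30 s (when both protocols have just
#' reached full intensity) and the last at 960 s.
#'
#' @param total_task_s Task duration in seconds (> 0).
#' @param interval_s Probe spacing in seconds (> 0).
#' @return Numeric vector of probe times in seconds.
#' @examples
#' length(probe_schedule())     # 32
#' probe_schedule(30, 30)       # 30
#' @export
probe_schedule <- function(total_task_s = 960, interval_s = 30) {
  if (!is.numeric(total_task_s) || total_task_s <= 0) {
    abort("`total_task_s` must be positive")
  }
  if (!is.numeric(interval_s) || interval_s <= 0) {
    abort("`interval_s` must be positive")
  }
  seq_len(floor(total_task_s / interval_s)) * interval_s
}
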