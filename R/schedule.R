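# Treatment schedules: four dose channels (chemo v_M, IL-2 v_I, CD8+ v_L,
# CD4+ v_Y), each OFF, CONSTANT or PULSED, piecewise constant in time.

#' Dose channel constructors
#'
#' A channel is the time course of one therapy input.  `channel_off()` is
#' identically zero, `channel_constant()` delivers `intensity` at all
#' times, and `channel_pulsed()` delivers `intensity` on `n_pulses`
#' half-open windows `[start + i * period, start + i * period + duration)`
#' for `i = 0, ..., n_pulses - 1`.  Doses are constant-rate infusions: the
#' reference regimens state intensity, start, period and count but no
#' pulse shape, so pulses default to one-day infusions (the convention of
#' the predecessor modelling literature) with the duration configurable.
#'
#' @param intensity dose rate (concentration units per day), >= 0.
#' @param start first pulse onset (days).
#' @param period pulse spacing (days), > 0.
#' @param n_pulses number of pulses, >= 1.
#' @param duration infusion length of each pulse (days), in `(0, period]`.
#' @return A `dose_channel` object.
#' @export
channel_off <- function() {
  structure(list(mode = "off"), class = "dose_channel")
}

#' @rdname channel_off
#' @export
channel_constant <- function(intensity) {
  stopifnot(is.finite(intensity), intensity >= 0)
  structure(list(mode = "constant", intensity = as.numeric(intensity)),
            class = "dose_channel")
}

#' @rdname channel_off
#' @export
channel_pulsed <- function(intensity, start, period, n_pulses,
                           duration = 1) {
  stopifnot(is.finite(intensity), intensity >= 0, is.finite(start),
            start >= 0, period > 0, n_pulses >= 1,
            duration > 0, duration <= period)
  structure(list(mode = "pulsed", intensity = as.numeric(intensity),
                 start = as.numeric(start), period = as.numeric(period),
                 n_pulses = as.integer(n_pulses),
                 duration = as.numeric(duration)),
            class = "dose_channel")
}

#' Treatment schedule
#'
#' Combines the four dose channels of the treated model: chemotherapy
#' `v_M`, IL-2 cytokine `v_I`, adoptive CD8+ T `v_L` and adoptive CD4+ T
#' `v_Y`.
#'
#' @param v_M,v_I,v_L,v_Y [channel_off()], [channel_constant()] or
#'   [channel_pulsed()] objects.
#' @return A `treatment_schedule` object.
#' @export
treatment_schedule <- function(v_M = channel_off(), v_I = channel_off(),
                               v_L = channel_off(), v_Y = channel_off()) {
  chans <- list(v_M = v_M, v_I = v_I, v_L = v_L, v_Y = v_Y)
  ok <- vapply(chans, inherits, logical(1L), what = "dose_channel")
  if (!all(ok)) stop("all channels must be dose_channel objects")
  structure(chans, class = "treatment_schedule")
}

.channel_dose <- function(ch, t) {
  switch(ch$mode,
    off = 0,
    constant = ch$intensity,
    pulsed = {
      rel <- t - ch$start
      i <- floor(rel / ch$period)
      if (is.finite(i) && i >= 0 && i < ch$n_pulses &&
          rel - i * ch$period < ch$duration) ch$intensity else 0
    })
}

#' Evaluate the dose rates of a schedule at one time
#'
#' @param schedule a [treatment_schedule()].
#' @param t time (days).
#' @return Named numeric vector `(v_M, v_I, v_L, v_Y)`.
#' @export
dose_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "treatment_schedule"), is.finite(t))
  vapply(schedule, .channel_dose, numeric(1L), t = t)
}

#' Dose discontinuity times of a schedule
#'
#' Pulse on/off instants within `t_span`, deduplicated and sorted.  The
#' multistep integrator restarts its history at these times because a dose
#' jump breaks the smoothness the Adams formulas rely on.  Constant and
#' off channels contribute no events.
#'
#' @param schedule a [treatment_schedule()].
#' @param t_span length-2 numeric `(t0, t1)`.
#' @return Sorted numeric vector of event times strictly inside `t_span`.
#' @export
event_times <- function(schedule, t_span) {
  stopifnot(inherits(schedule, "treatment_schedule"),
            length(t_span) == 2L, all(is.finite(t_span)))
  ev <- unlist(lapply(schedule, function(ch) {
    if (ch$mode != "pulsed") return(numeric(0L))
    on <- ch$start + (seq_len(ch$n_pulses) - 1L) * ch$period
    c(on, on + ch$duration)
  }), use.names = FALSE)
  ev <- sort(unique(ev[ev > t_span[1L] & ev < t_span[2L]]))
  ev
}

#' Read / write a treatment schedule as YAML
#'
#' Per-channel blocks `{mode: off|constant|pulsed, intensity, start,
#' period, n_pulses, duration}` under the keys `v_M`, `v_I`, `v_L`, `v_Y`.
#'
#' @param path file path.
#' @return `read_schedule` returns a [treatment_schedule()];
#'   `write_schedule` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  mk <- function(b) {
    if (is.null(b) || identical(b$mode, "off")) return(channel_off())
    switch(b$mode,
      constant = channel_constant(b$intensity),
      pulsed = channel_pulsed(b$intensity, b$start, b$period, b$n_pulses,
                              if (is.null(b$duration)) 1 else b$duration),
      stop("unknown channel mode: ", b$mode))
  }
  treatment_schedule(v_M = mk(raw$v_M), v_I = mk(raw$v_I),
                     v_L = mk(raw$v_L), v_Y = mk(raw$v_Y))
}

#' @rdname read_schedule
#' @param schedule a [treatment_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  yaml::write_yaml(lapply(schedule, unclass), path, precision = 15L)
  invisible(path)
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat("Treatment schedule:\n")
  for (nm in names(x)) {
    ch <- x[[nm]]
    desc <- switch(ch$mode,
      off = "off",
      constant = sprintf("constant, intensity %g", ch$intensity),
      pulsed = sprintf(
        "%d pulse(s) of intensity %g, start day %g, period %g d, duration %g d",
        ch$n_pulses, ch$intensity, ch$start, ch$period, ch$duration))
    cat(sprintf("  %s: %s\n", nm, desc))
  }
  invisible(x)
}
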