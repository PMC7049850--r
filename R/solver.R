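# Fixed-step Adams predictor-corrector (PECE) integrator with a
# self-starting refined ramp-up and restarts at dose discontinuities.

#' Solver configuration
#'
#' @param order formal order `k` of the predictor-corrector pair (1-12).
#'   Order `k` pairs the `k`-step Adams-Bashforth predictor with the
#'   Adams-Moulton corrector of the same formal order.
#' @param dt nominal step size (days).  Each integration segment uses the
#'   largest uniform step not exceeding `dt` that divides the segment.
#' @param max_state divergence guard: integration aborts if any state
#'   component exceeds this magnitude.
#' @param clip_negative if `TRUE` (default), any state component driven
#'   below zero by a step is set to zero at the end of that step (states
#'   are populations/concentrations; the lysis fraction is undefined for
#'   negative values).  Clips are counted in the result.
#' @param corrector_iterations number of corrector applications per step;
#'   1 (default) is the classical PECE scheme in which the corrector is
#'   evaluated once at the predicted state.
#' @param startup_substeps substep refinement factor for the self-starting
#'   ramp: the first `k - 1` intervals of every segment are integrated on
#'   a grid this many times finer (with the order ramping up), which keeps
#'   the startup error far below the main method's.
#' @param save_stride keep every `save_stride`-th step (plus the final
#'   one) in returned trajectories.
#' @return A `solver_config` object.
#' @export
solver_config <- function(order = 12L, dt = 2^-9, max_state = 1e15,
                          clip_negative = TRUE, corrector_iterations = 1L,
                          startup_substeps = 64L, save_stride = 1L) {
  order <- as.integer(order)
  stopifnot(order >= 1L, order <= 12L, dt > 0, max_state > 0,
            corrector_iterations >= 1L, startup_substeps >= 1L,
            save_stride >= 1L)
  structure(list(order = order, dt = dt, max_state = max_state,
                 clip_negative = isTRUE(clip_negative),
                 corrector_iterations = as.integer(corrector_iterations),
                 startup_substeps = as.integer(startup_substeps),
                 save_stride = as.integer(save_stride)),
            class = "solver_config")
}

.divergence_stop <- function(t, state) {
  cond <- structure(
    class = c("tumorimmune_divergence", "error", "condition"),
    list(message = sprintf(
           "solution diverged at t = %.6g (max |state| = %.3g)",
           t, max(abs(state))),
         call = NULL, time = t, state = state))
  stop(cond)
}

#' One predictor-corrector step
#'
#' Advances one step of size `dt` from `y_prev` using a history of `k`
#' equally spaced derivative evaluations: Adams-Bashforth prediction,
#' one (or more) Adams-Moulton corrections evaluated at the predicted
#' state (PECE).
#'
#' @param f derivative function `f(t, y)`.
#' @param history list with `t` (times, most recent first) and `f`
#'   (matrix, one column of derivatives per history time, same order).
#' @param y_prev state at `history$t[1]`.
#' @param dt step size.
#' @param corrector_iterations number of corrector applications.
#' @return List with the new time `t`, corrected state `y`, and the
#'   derivative `f` evaluated at the corrected state.
#' @export
pc_step <- function(f, history, y_prev, dt, corrector_iterations = 1L) {
  k <- length(history$t)
  stopifnot(k >= 1L, is.matrix(history$f), ncol(history$f) == k)
  if (k > 1L && any(abs(diff(history$t) + dt) > 1e-9 * dt))
    stop("history must be equally spaced at the step size")
  ab <- adams_bashforth(k)$value
  am <- adams_moulton(k - 1L)$value
  tn <- history$t[1L] + dt
  yp <- y_prev + dt * as.vector(history$f[, seq_len(k), drop = FALSE] %*% ab)
  hist_part <- if (k > 1L)
    as.vector(history$f[, seq_len(k - 1L), drop = FALSE] %*% am[-1L]) else 0
  yc <- yp
  for (it in seq_len(corrector_iterations)) {
    fp <- f(tn, yc)
    if (any(!is.finite(fp))) .divergence_stop(tn, yc)
    yc <- y_prev + dt * (am[1L] * fp + hist_part)
  }
  list(t = tn, y = yc, f = f(tn, yc))
}

# Integrate one smooth segment [t0, t1] with uniform steps.  Returns the
# states at the n + 1 uniform grid times.  `state0` holds y at t0.
.integrate_segment <- function(f, y0, t0, t1, config) {
  k <- config$order
  nsub <- config$startup_substeps
  iters <- config$corrector_iterations
  clip <- config$clip_negative
  maxs <- config$max_state
  n <- max(1L, as.integer(ceiling((t1 - t0) / config$dt - 1e-9)))
  h <- (t1 - t0) / n
  d <- length(y0)
  AB <- lapply(seq_len(k), function(m) adams_bashforth(m)$value)
  # While ramping up (m < k) the corrector uses the full available
  # history (Adams-Moulton with m nodes, formal order m + 1) so that the
  # low-order startup steps do not cap the global order; at m = k the
  # scheme settles into the standard order-k pairing AB(k) + AM(k - 1).
  AM <- lapply(seq_len(k), function(m)
    adams_moulton(if (m < k) m else k - 1L)$value)
  clips <- 0L
  advance <- function(tn, yprev, Fh, nav, hh) {
    mm <- if (nav < k) nav else k
    yp <- yprev + hh * as.vector(Fh[, seq_len(mm), drop = FALSE] %*% AB[[mm]])
    am <- AM[[mm]]
    nh <- length(am) - 1L
    hist_part <- if (nh > 0L)
      as.vector(Fh[, seq_len(nh), drop = FALSE] %*% am[-1L]) else 0
    yc <- yp
    for (it in seq_len(iters)) {
      fp <- f(tn, yc)
      if (any(!is.finite(fp))) .divergence_stop(tn, yc)
      yc <- yprev + hh * (am[1L] * fp + hist_part)
    }
    if (any(!is.finite(yc)) || max(abs(yc)) > maxs) .divergence_stop(tn, yc)
    if (clip && any(yc < 0)) {
      yc[yc < 0] <- 0
      clips <<- clips + 1L
    }
    fe <- f(tn, yc)
    if (any(!is.finite(fe))) .divergence_stop(tn, yc)
    list(y = yc, f = fe)
  }
  out <- matrix(NA_real_, n + 1L, d)
  out[1L, ] <- y0
  f0 <- f(t0, y0)
  if (any(!is.finite(f0))) .divergence_stop(t0, y0)
  Fg <- matrix(0, d, k)
  Fg[, 1L] <- f0
  navg <- 1L
  y <- y0
  nstart <- min(k - 1L, n)
  if (nstart > 0L && nsub > 1L) {
    hs <- h / nsub
    Fs <- matrix(0, d, k)
    Fs[, 1L] <- f0
    navs <- 1L
    for (jg in seq_len(nstart)) {
      base <- t0 + (jg - 1L) * h
      for (ss in seq_len(nsub)) {
        res <- advance(base + ss * hs, y, Fs, navs, hs)
        Fs <- cbind(res$f, Fs[, seq_len(k - 1L), drop = FALSE])
        navs <- min(navs + 1L, k)
        y <- res$y
      }
      out[jg + 1L, ] <- y
      Fg <- cbind(res$f, Fg[, seq_len(k - 1L), drop = FALSE])
      navg <- navg + 1L
    }
  } else if (nstart > 0L) {
    for (jg in seq_len(nstart)) {
      res <- advance(t0 + jg * h, y, Fg, navg, h)
      Fg <- cbind(res$f, Fg[, seq_len(k - 1L), drop = FALSE])
      navg <- navg + 1L
      y <- res$y
      out[jg + 1L, ] <- y
    }
  }
  if (n > nstart) {
    for (step in (nstart + 1L):n) {
      res <- advance(t0 + step * h, y, Fg, navg, h)
      Fg <- cbind(res$f, Fg[, seq_len(k - 1L), drop = FALSE])
      navg <- min(navg + 1L, k)
      y <- res$y
      out[step + 1L, ] <- y
    }
  }
  list(t = t0 + (0:n) * h, y = out, clips = clips)
}

#' Integrate an ODE with the Adams predictor-corrector
#'
#' Fixed-step PECE integration of `dy/dt = f(t, y)` over `t_span`.  The
#' span is split at `events` (dose discontinuities); each segment restarts
#' the multistep history with the self-starting refined ramp and is
#' integrated with a uniform step no larger than `config$dt`.
#'
#' @param f derivative function `f(t, y)`; ignored within a segment if
#'   `segment_fn` is given.
#' @param y0 initial state (numeric vector).
#' @param t_span length-2 numeric `(t0, t1)`.
#' @param events numeric vector of interior breakpoints (sorted times at
#'   which `f` is discontinuous in `t`).
#' @param config a [solver_config()].
#' @param segment_fn optional `function(t_lo, t_hi)` returning the
#'   derivative function to use on that segment; lets piecewise-constant
#'   forcing be resolved exactly (the returned function is evaluated with
#'   the segment's forcing even at its closed endpoints).
#' @return List with `t` (times), `y` (matrix, one row per time),
#'   `clips` (number of steps on which a negative component was clipped),
#'   and `events` (the breakpoints used).
#' @export
pc_integrate <- function(f, y0, t_span, events = numeric(0L),
                         config = solver_config(), segment_fn = NULL) {
  stopifnot(inherits(config, "solver_config"),
            length(t_span) == 2L, all(is.finite(t_span)),
            t_span[2L] > t_span[1L], all(is.finite(y0)))
  events <- sort(unique(events[events > t_span[1L] & events < t_span[2L]]))
  brk <- c(t_span[1L], events, t_span[2L])
  ts <- list()
  ys <- list()
  clips <- 0L
  y <- as.numeric(y0)
  for (i in seq_len(length(brk) - 1L)) {
    fi <- if (is.null(segment_fn)) f else segment_fn(brk[i], brk[i + 1L])
    seg <- .integrate_segment(fi, y, brk[i], brk[i + 1L], config)
    clips <- clips + seg$clips
    keep <- if (i == 1L) TRUE else -1L   # drop duplicated breakpoint row
    ts[[i]] <- seg$t[keep]
    ys[[i]] <- seg$y[keep, , drop = FALSE]
    y <- seg$y[nrow(seg$y), ]
  }
  list(t = do.call(c, ts), y = do.call(rbind, ys), clips = clips,
       events = events)
}

#' Simulate a patient trajectory
#'
#' Integrates the treated seven-state model for one parameter set, initial
#' state and treatment schedule.  Doses are piecewise constant; the
#' integrator restarts at every dose on/off instant.
#'
#' @param params a [parameter_set].
#' @param init named numeric initial state; any of `T`, `N`, `L`, `Y`,
#'   `C`, `I`, `M` (missing components default to 0).
#' @param t_span length-2 numeric `(t0, t1)` in days.
#' @param schedule a [treatment_schedule()].
#' @param config a [solver_config()].
#' @return A `trajectory`: data frame with columns `t`, `T`, `N`, `L`,
#'   `Y`, `C`, `I`, `M`, with solver metadata in attributes (`order`,
#'   `dt`, `events`, `clips`, `params_label`).
#' @export
simulate_patient <- function(params, init, t_span = c(0, 60),
                             schedule = treatment_schedule(),
                             config = solver_config()) {
  stopifnot(inherits(params, "parameter_set"),
            inherits(schedule, "treatment_schedule"))
  y0 <- stats::setNames(numeric(7L), .state_names7)
  if (is.null(names(init)) && length(init) == 7L) {
    y0[] <- init
  } else {
    bad <- setdiff(names(init), .state_names7)
    if (length(bad)) stop("unknown state components: ",
                          paste(bad, collapse = ", "))
    y0[names(init)] <- init
  }
  if (any(y0 < 0)) stop("initial state must be nonnegative")
  rhs <- .make_rhs_treated(params)
  ev <- event_times(schedule, t_span)
  seg_fn <- function(lo, hi) {
    dose <- dose_at(schedule, (lo + hi) / 2)
    function(t, y) rhs(y, dose)
  }
  sol <- pc_integrate(NULL, y0, t_span, events = ev, config = config,
                      segment_fn = seg_fn)
  idx <- unique(c(seq(1L, length(sol$t), by = config$save_stride),
                  length(sol$t)))
  tr <- data.frame(t = sol$t[idx], sol$y[idx, , drop = FALSE])
  names(tr) <- c("t", .state_names7)
  structure(tr, class = c("trajectory", "data.frame"),
            order = config$order, dt = config$dt, events = ev,
            clips = sol$clips, params_label = attr(params, "label"))
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' @param traj a trajectory from [simulate_patient()].
#' @param path output CSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(order = attr(traj, "order"), dt = attr(traj, "dt"),
               events = attr(traj, "events"), clips = attr(traj, "clips"),
               params_label = attr(traj, "params_label"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
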