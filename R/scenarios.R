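# Scenario workbench: the published no-treatment, continuous-therapy and
# pulsed-therapy experiments for the two reference patients, eradication
# outcomes, and restricted (T, Y) phase fields for streamline plots.

#' Define a simulation scenario
#'
#' @param name unique scenario name.
#' @param patient `"patient1"` or `"patient2"` (selects the bundled
#'   parameter fixture unless `params` is supplied to [run_scenario()]).
#' @param init named initial state (missing components default to 0).
#' @param schedule a [treatment_schedule()].
#' @param horizon simulation horizon (days).
#' @param description free text.
#' @return A `scenario` object.
#' @export
scenario <- function(name, patient, init,
                     schedule = treatment_schedule(), horizon = 60,
                     description = "") {
  stopifnot(is.character(name), nchar(name) > 0, horizon > 0,
            inherits(schedule, "treatment_schedule"))
  structure(list(name = name, patient = patient, init = init,
                 schedule = schedule, horizon = horizon,
                 description = description),
            class = "scenario")
}

#' Registry of the published treatment experiments
#'
#' The panel of no-treatment (tumor sizes 1e5 and 1e7, plus a
#' strengthened-immune variant), continuous-therapy and pulsed-therapy
#' runs for the two reference patients, with the printed initial states,
#' intensities, pulse counts, periods and start days.  Unstated initial
#' components are 0 (in particular IL-2 and drug); the CD8+/IL-2/chemo
#' comparison regimen of the predecessor model is run without CD4+ T
#' cells (`Y(0) = 0`) and its CD4+ alternative with `Y(0) = 1e6`.
#' Horizons: 60 days for no-treatment and continuous runs, 100 days for
#' pulsed runs (covering the 9-pulse regimen).
#'
#' The printed "6 pulses of IL-2 from day 8 to day 11" is internally
#' tense (6 pulses in 4 days); it is encoded as 6 equal sub-day infusions
#' evenly spaced over [8, 11.5), flagged in the scenario description.
#'
#' @return Named list of [scenario()] objects.
#' @export
scenario_registry <- function() {
  base1  <- c(N = 1e3, L = 10,  Y = 1e6, C = 6e8)
  base1b <- c(N = 1e3, L = 1e2, Y = 1e6, C = 6e8)
  sc <- list(
    scenario("p1_notreat_1e5", "patient1", c(T = 1e5, base1),
             description = "no treatment, small tumor"),
    scenario("p1_notreat_1e7", "patient1", c(T = 1e7, base1),
             description = "no treatment, large tumor"),
    scenario("p1_notreat_1e7_strong", "patient1",
             c(T = 1e7, N = 1e3, L = 1e2, Y = 1e6, C = 6e10),
             description = "no treatment, large tumor, strengthened immune"),
    scenario("p1_cd8_il2_continuous", "patient1", c(T = 1e6, base1),
             treatment_schedule(v_L = channel_constant(1e4),
                                v_I = channel_constant(1e4)),
             description = "continuous CD8+T (1e4) + IL-2 (1e4)"),
    scenario("p1_cd4_continuous", "patient1", c(T = 1e6, base1),
             treatment_schedule(v_Y = channel_constant(1e6)),
             description = "continuous CD4+T (1e6)"),
    scenario("p2_cd8_il2_continuous", "patient2", c(T = 1e6, base1b),
             treatment_schedule(v_L = channel_constant(1e6),
                                v_I = channel_constant(1e6)),
             description = "continuous CD8+T (1e6) + IL-2 (1e6)"),
    scenario("p2_cd4_continuous", "patient2", c(T = 1e6, base1b),
             treatment_schedule(v_Y = channel_constant(1e6)),
             description = "continuous CD4+T (1e6)"),
    scenario("p2_triple_continuous", "patient2", c(T = 1e6, base1b),
             treatment_schedule(v_L = channel_constant(1e6),
                                v_I = channel_constant(1e6),
                                v_Y = channel_constant(1e6)),
             description = "continuous CD8+T + IL-2 + CD4+T (all 1e6)"),
    scenario("p1_chemo5_T8e5", "patient1", c(T = 8e5, base1b),
             treatment_schedule(
               v_M = channel_pulsed(5, start = 6, period = 5, n_pulses = 5)),
             horizon = 100,
             description = "5 chemo pulses v_M=5, period 5 d, from day 6"),
    scenario("p1_cd8_il2_pulsed_T8e5", "patient1", c(T = 8e5, base1b),
             treatment_schedule(
               v_L = channel_pulsed(1e5, start = 6, period = 2, n_pulses = 7),
               v_I = channel_pulsed(1e5, start = 6, period = 2, n_pulses = 7)),
             horizon = 100,
             description = "7 CD8+T + IL-2 pulses (1e5), period 2 d, from day 6"),
    scenario("p1_cd8_il2_cd4_pulsed_T8e5", "patient1", c(T = 8e5, base1b),
             treatment_schedule(
               v_L = channel_pulsed(1e5, start = 6, period = 2, n_pulses = 7),
               v_I = channel_pulsed(1e5, start = 6, period = 2, n_pulses = 7),
               v_Y = channel_pulsed(1e7, start = 6, period = 2, n_pulses = 5)),
             horizon = 100,
             description = "pulsed CD8+T + IL-2 plus 5 CD4+T pulses (1e7)"),
    scenario("p1_chemo5_T3e6", "patient1", c(T = 3e6, base1),
             treatment_schedule(
               v_M = channel_pulsed(5, start = 6, period = 5, n_pulses = 5)),
             horizon = 100,
             description = "5 chemo pulses v_M=5 alone, larger tumor"),
    scenario("p1_chemo5_cd4_T3e6", "patient1", c(T = 3e6, base1),
             treatment_schedule(
               v_M = channel_pulsed(5, start = 6, period = 5, n_pulses = 5),
               v_Y = channel_pulsed(6e6, start = 6, period = 2, n_pulses = 5)),
             horizon = 100,
             description = "5 chemo pulses + 5 CD4+T pulses (6e6)"),
    scenario("p1_chemo_cd8_il2_T1e7", "patient1",
             c(T = 1e7, N = 1e3, L = 10, Y = 0, C = 6e8),
             treatment_schedule(
               v_M = channel_pulsed(5, start = 1, period = 10, n_pulses = 9),
               v_I = channel_pulsed(5e5, start = 8, period = 3.5 / 6,
                                    n_pulses = 6, duration = 3.5 / 12),
               v_L = channel_pulsed(1e9, start = 7, period = 2,
                                    n_pulses = 1, duration = 2)),
             horizon = 100,
             description = paste(
               "predecessor-model comparison: 9 chemo pulses (v_M=5,",
               "period 10 d from day 1), CD8+T 1e9 during days 7-8, 6",
               "sub-day IL-2 pulses (5e5) spread over days 8-11.5; no",
               "CD4+T compartment seeded")),
    scenario("p1_chemo_cd4_T1e7", "patient1", c(T = 1e7, base1),
             treatment_schedule(
               v_M = channel_pulsed(5, start = 1, period = 10, n_pulses = 3),
               v_Y = channel_pulsed(4e7, start = 6, period = 2, n_pulses = 5)),
             horizon = 100,
             description = "3 chemo pulses + 5 CD4+T pulses (4e7)"))
  stats::setNames(sc, vapply(sc, `[[`, character(1L), "name"))
}

#' Run a scenario and decide its outcome
#'
#' Integrates the scenario and applies the eradication rule: the tumor is
#' eradicated if its burden falls below `threshold` (default 1 cell) and
#' stays below it until the horizon; the eradication day is the first
#' crossing time of the sustained excursion.
#'
#' @param sc a [scenario()] or the name of a registry entry.
#' @param config a [solver_config()].
#' @param params optional [parameter_set] overriding the patient fixture.
#' @param threshold eradication threshold (cells).
#' @return List with `trajectory` and `outcome` (list: `name`,
#'   `eradicated`, `eradication_day`, `min_tumor`, `final_tumor`,
#'   `clips`).
#' @export
run_scenario <- function(sc, config = solver_config(), params = NULL,
                         threshold = 1) {
  if (is.character(sc)) {
    reg <- scenario_registry()
    if (!sc %in% names(reg)) stop("unknown scenario: ", sc)
    sc <- reg[[sc]]
  }
  stopifnot(inherits(sc, "scenario"))
  if (is.null(params)) params <- patient_params(sc$patient)
  traj <- tryCatch(
    simulate_patient(params, sc$init, c(0, sc$horizon), sc$schedule,
                     config),
    tumorimmune_divergence = function(e)
      stop(sprintf("scenario '%s': %s", sc$name, conditionMessage(e)),
           call. = FALSE))
  tum <- traj$T
  below <- tum < threshold
  erad <- below[length(below)] &&
    { last_above <- max(c(0L, which(!below))); last_above < length(below) }
  day <- if (erad) traj$t[max(c(0L, which(!below))) + 1L] else NA_real_
  out <- list(name = sc$name, eradicated = erad, eradication_day = day,
              min_tumor = min(tum), final_tumor = tum[length(tum)],
              clips = attr(traj, "clips"))
  list(trajectory = traj, outcome = out)
}

#' Outcome matrix over a set of scenarios
#'
#' Runs each scenario and tabulates its verdict.  Failures (e.g. solver
#' divergence) become rows with `eradicated = NA` and the error message,
#' not aborts.
#'
#' @param scenarios list of [scenario()] objects (default: the full
#'   registry).
#' @param config a [solver_config()].
#' @param threshold eradication threshold (cells).
#' @return Data frame: name, patient, eradicated, eradication_day,
#'   min_tumor, final_tumor, clips, error.
#' @export
outcome_matrix <- function(scenarios = scenario_registry(),
                           config = solver_config(), threshold = 1) {
  rows <- lapply(scenarios, function(sc) {
    res <- tryCatch(run_scenario(sc, config, threshold = threshold),
                    error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(name = sc$name, patient = sc$patient,
                        eradicated = NA, eradication_day = NA_real_,
                        min_tumor = NA_real_, final_tumor = NA_real_,
                        clips = NA_integer_,
                        error = conditionMessage(res)))
    o <- res$outcome
    data.frame(name = o$name, patient = sc$patient,
               eradicated = o$eradicated,
               eradication_day = o$eradication_day,
               min_tumor = o$min_tumor, final_tumor = o$final_tumor,
               clips = o$clips, error = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Restricted (T, Y) phase field around an equilibrium
#'
#' Evaluates the tumor and CD4+ T derivatives on a grid of `(T, Y)`
#' values with the other four states frozen (typically at an equilibrium
#' point's values), for streamline plotting of the local flow.
#'
#' @param params a [parameter_set].
#' @param fixed named numeric with components `N`, `L`, `C`, `I`.
#' @param T_range,Y_range length-2 ranges.
#' @param n grid size, length-2 `(nT, nY)` or scalar.
#' @return Data frame with `T`, `Y`, `dT`, `dY` (one row per grid node,
#'   `nT * nY` rows).
#' @export
phase_field <- function(params, fixed, T_range, Y_range, n = c(20L, 20L)) {
  stopifnot(inherits(params, "parameter_set"),
            all(c("N", "L", "C", "I") %in% names(fixed)),
            length(T_range) == 2L, length(Y_range) == 2L)
  n <- rep(as.integer(n), length.out = 2L)
  stopifnot(all(n >= 2L))
  Tg <- seq(T_range[1L], T_range[2L], length.out = n[1L])
  Yg <- seq(Y_range[1L], Y_range[2L], length.out = n[2L])
  gr <- expand.grid(T = Tg, Y = Yg)
  D <- lysis_fraction(gr$T, rep(fixed[["L"]], nrow(gr)), params)
  with(unclass(params), {
    dT <- a * gr$T * (1 - b * gr$T) - c * fixed[["N"]] * gr$T -
      D * gr$T - c1 * gr$T / (a1 + gr$T) * fixed[["I"]]
    dY <- beta1 * gr$T / (alpha1 + gr$T) * fixed[["I"]] - mu1 * gr$Y -
      delta2 * gr$T * gr$Y
    data.frame(T = gr$T, Y = gr$Y, dT = dT, dY = dY)
  })
}
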