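# Discrete-time session simulator. The machine is clocked: inputs are sampled
# once per tick and exactly one transition (possibly a self-loop) fires per
# tick. Analog sensor trajectories (temperature, tank level, flows, pressure,
# turbidity) are generated synthetically as simple phase-driven ramps with
# seeded sensor noise, then thresholded into the 16 boolean inputs. States
# annotated "with delay" hold the register through a timer that gates the
# clock enable; alarm transitions preempt the gate.

STATE_HN <- 3L; STATE_HF <- 4L; STATE_FS <- 5L; STATE_FE <- 6L
STATE_DWM <- 7L; STATE_DS <- 8L; STATE_V4F <- 9L; STATE_LS <- 11L
STATE_V31F <- 12L; STATE_FSH <- 13L; STATE_V456F <- 14L; STATE_V31N <- 15L
STATE_V1F <- 16L

# states whose exit transition is timed ("with delay" rows)
DELAY_STATES <- c(STATE_FE, STATE_DWM, STATE_V4F, STATE_V31F, STATE_V456F)

#' Simulation configuration
#'
#' Defaults encode the study conditions of the controller design: the flush
#' stage runs at 200 ml/min for a minimum of 2 minutes per cycle and the
#' heater targets body temperature (37 degrees C). The remaining values are
#' realistic desk-scale choices documented in the methods vignette.
#'
#' @param temperature_setpoint heater setpoint, degrees Celsius.
#' @param temperature_initial solution temperature at session start.
#' @param heater_rate heating rate, degrees Celsius per second.
#' @param fill_volume dialysate volume per exchange, millilitres.
#' @param fill_flow_rate,drain_flow_rate pump rates, millilitres per minute.
#' @param dwell_duration dwell time after filling ends, seconds.
#' @param delay_duration dwell of the other timed ("with delay") states,
#'   seconds.
#' @param flush_flow_rate flush-stage flow, millilitres per minute.
#' @param flush_min_duration minimum flush-stage duration, minutes.
#' @param turbidity_initial pre-dialysis effluent turbidity, arbitrary
#'   turbidity units.
#' @param turbidity_threshold session-termination threshold, same units.
#' @param turbidity_persistence_window consecutive ticks the threshold must
#'   persist before the turbidity input asserts.
#' @param turbidity_decay_ratio per-cycle multiplicative decay of drained
#'   turbidity, in (0, 1).
#' @param pressure_nominal,pressure_min,pressure_max line pressure and its
#'   safe band, arbitrary pressure units.
#' @param level_mark tank-level threshold for the level input, millilitres.
#' @param tick_length seconds of simulated time per clock tick.
#' @param max_ticks tick cap before a session times out.
#' @param max_cycles cap on fill-dwell-drain cycles.
#' @param noise_sd standard deviation of additive sensor-reading noise.
#' @param random_seed seed for the noise generator.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(temperature_setpoint = 37,
                       temperature_initial = 25,
                       heater_rate = 0.5,
                       fill_volume = 1000,
                       fill_flow_rate = 200,
                       drain_flow_rate = 200,
                       dwell_duration = 1800,
                       delay_duration = 5,
                       flush_flow_rate = 200,
                       flush_min_duration = 2,
                       turbidity_initial = 100,
                       turbidity_threshold = 10,
                       turbidity_persistence_window = 3,
                       turbidity_decay_ratio = 0.5,
                       pressure_nominal = 100,
                       pressure_min = 50,
                       pressure_max = 150,
                       level_mark = 10,
                       tick_length = 1,
                       max_ticks = 100000,
                       max_cycles = 25,
                       noise_sd = 0.05,
                       random_seed = 1L) {
  cfg <- list(temperature_setpoint = temperature_setpoint,
              temperature_initial = temperature_initial,
              heater_rate = heater_rate,
              fill_volume = fill_volume,
              fill_flow_rate = fill_flow_rate,
              drain_flow_rate = drain_flow_rate,
              dwell_duration = dwell_duration,
              delay_duration = delay_duration,
              flush_flow_rate = flush_flow_rate,
              flush_min_duration = flush_min_duration,
              turbidity_initial = turbidity_initial,
              turbidity_threshold = turbidity_threshold,
              turbidity_persistence_window = turbidity_persistence_window,
              turbidity_decay_ratio = turbidity_decay_ratio,
              pressure_nominal = pressure_nominal,
              pressure_min = pressure_min,
              pressure_max = pressure_max,
              level_mark = level_mark,
              tick_length = tick_length,
              max_ticks = max_ticks,
              max_cycles = max_cycles,
              noise_sd = noise_sd,
              random_seed = as.integer(random_seed))
  positive <- c("heater_rate", "fill_volume", "fill_flow_rate",
                "drain_flow_rate", "dwell_duration", "delay_duration",
                "flush_flow_rate", "flush_min_duration",
                "turbidity_threshold", "turbidity_persistence_window",
                "tick_length", "max_ticks", "max_cycles")
  for (nm in positive)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be positive")
  if (cfg$turbidity_decay_ratio <= 0 || cfg$turbidity_decay_ratio >= 1)
    stop("turbidity_decay_ratio must be in (0, 1)")
  if (cfg$pressure_min >= cfg$pressure_max)
    stop("pressure_min must be below pressure_max")
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a flat JSON file
#'
#' All fields optional; unspecified fields take the [sim_config()] defaults.
#'
#' @param path path to a JSON object file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Operator button settings
#'
#' @param start start button held.
#' @param dialysis_mode,flush_mode mode selection buttons.
#' @param audible request audible instructions (the interface's alternative
#'   to pressing Pass).
#' @param pass the Pass button.
#' @param start_dialysis the start-dialysis confirmation button.
#' @param audible_ticks ticks spent listening before Pass is pressed when
#'   `audible` is set.
#' @return an object of class `operator_intent`.
#' @export
operator_intent <- function(start = FALSE, dialysis_mode = FALSE,
                            flush_mode = FALSE, audible = FALSE,
                            pass = FALSE, start_dialysis = FALSE,
                            audible_ticks = 3L) {
  structure(list(start = start, dialysis_mode = dialysis_mode,
                 flush_mode = flush_mode, audible = audible, pass = pass,
                 start_dialysis = start_dialysis,
                 audible_ticks = as.integer(audible_ticks)),
            class = "operator_intent")
}

#' One joint analog sensor reading
#'
#' @param temperature degrees Celsius.
#' @param level tank level, millilitres (non-negative).
#' @param pressure line pressure, arbitrary units.
#' @param flow1,flow2,flow3,flow4 flow-meter readings, millilitres per
#'   minute.
#' @param turbidity effluent turbidity, arbitrary units (non-negative).
#' @return an object of class `analog_state`.
#' @export
analog_state <- function(temperature = 0, level = 0, pressure = 0,
                         flow1 = 0, flow2 = 0, flow3 = 0, flow4 = 0,
                         turbidity = 0) {
  if (level < 0) stop("level must be non-negative")
  if (turbidity < 0) stop("turbidity must be non-negative")
  structure(list(temperature = temperature, level = level,
                 pressure = pressure, flow1 = flow1, flow2 = flow2,
                 flow3 = flow3, flow4 = flow4, turbidity = turbidity),
            class = "analog_state")
}

#' A fault-injection event
#'
#' While a fault is active the simulator asserts both the danger-value and
#' the system-fault inputs (the per-state alarm rows pattern-match both), so
#' the machine reaches the alarm state on the next tick.
#'
#' @param tick tick at which the fault appears (>= 0).
#' @param kind `"sensor_fault"` or `"danger_value"`.
#' @param cleared_at optional tick at which the fault clears (must exceed
#'   `tick`); `NULL` means it persists.
#' @return an object of class `fault_spec`.
#' @export
fault_spec <- function(tick, kind = c("sensor_fault", "danger_value"),
                       cleared_at = NULL) {
  kind <- match.arg(kind)
  if (tick < 0) stop("fault tick must be non-negative")
  if (!is.null(cleared_at) && cleared_at <= tick)
    stop("cleared_at must be after tick")
  structure(list(tick = as.integer(tick), kind = kind,
                 cleared_at = if (is.null(cleared_at)) NULL
                              else as.integer(cleared_at)),
            class = "fault_spec")
}

#' Read fault specifications from a JSON file
#'
#' @param path path to a JSON array of objects with fields `tick`, `kind`
#'   and optional `cleared_at`.
#' @return list of [fault_spec()] objects.
#' @export
read_fault_specs <- function(path) {
  if (!file.exists(path)) stop("fault file not found: ", path)
  raw <- jsonlite::read_json(path)
  lapply(raw, function(x)
    fault_spec(x$tick, x$kind,
               cleared_at = if (is.null(x$cleared_at)) NULL else x$cleared_at))
}

fault_active_at <- function(faults, tick) {
  any(vapply(faults, function(f)
    tick >= f$tick && (is.null(f$cleared_at) || tick < f$cleared_at),
    logical(1)))
}

#' Threshold analog readings and buttons into an input vector
#'
#' Boolean thresholding of one analog reading: the temperature input asserts
#' at or above the setpoint, the level input at or above the level mark, a
#' flow input on any positive flow, the pressure input inside the safe band,
#' and the turbidity input only when the reading has been at or above the
#' threshold for at least the persistence window of consecutive ticks.
#' Button inputs come from the operator intent; the danger-value and fault
#' inputs from the fault flag.
#'
#' @param analog an [analog_state()].
#' @param config a [sim_config()].
#' @param state current state code (phase context; unused by the default
#'   thresholding but part of the sampling contract).
#' @param intent an [operator_intent()].
#' @param fault_active is a fault currently injected?
#' @param tu_streak consecutive ticks (including this one) the turbidity
#'   reading has been at or above threshold.
#' @return an [input_vector()].
#' @examples
#' generate_inputs(analog_state(turbidity = 50), sim_config(), 16L,
#'                 operator_intent(start = TRUE), tu_streak = 1)["TU"] # 0
#' @export
generate_inputs <- function(analog, config, state = 0L,
                            intent = operator_intent(),
                            fault_active = FALSE, tu_streak = Inf) {
  input_vector(
    S = as.integer(intent$start),
    DM = as.integer(intent$dialysis_mode),
    FM = as.integer(intent$flush_mode),
    AI = as.integer(intent$audible),
    P = as.integer(intent$pass),
    T = as.integer(analog$temperature >= config$temperature_setpoint),
    SD = as.integer(intent$start_dialysis),
    F1 = as.integer(analog$flow1 > 0),
    F2 = as.integer(analog$flow2 > 0),
    F3 = as.integer(analog$flow3 > 0),
    F4 = as.integer(analog$flow4 > 0),
    L = as.integer(analog$level >= config$level_mark),
    PR = as.integer(analog$pressure >= config$pressure_min &
                      analog$pressure <= config$pressure_max),
    TU = as.integer(analog$turbidity >= config$turbidity_threshold &
                      tu_streak >= config$turbidity_persistence_window),
    DV = as.integer(fault_active),
    F = as.integer(fault_active))
}

#' Number of fill-dwell-drain cycles a session performs
#'
#' Drained-effluent turbidity starts at `turbidity_initial` and is multiplied
#' by `turbidity_decay_ratio` on every cycle; the session stops at the first
#' cycle whose drained turbidity falls below `turbidity_threshold`, capped at
#' `max_cycles`.
#'
#' @param config a [sim_config()].
#' @return integer cycle count (>= 1).
#' @examples
#' turbidity_cycles(sim_config())  # 4 under the defaults
#' @export
turbidity_cycles <- function(config) {
  n <- 1L
  tu <- config$turbidity_initial * config$turbidity_decay_ratio
  while (tu >= config$turbidity_threshold && n < config$max_cycles) {
    n <- n + 1L
    tu <- tu * config$turbidity_decay_ratio
  }
  n
}

delay_for_state <- function(state, config) {
  if (state == STATE_FE) config$dwell_duration
  else config$delay_duration
}

#' Simulate a full dialysis or flush session
#'
#' Starts in standby (00000) and advances one transition per tick using
#' [next_state()] on synthetically generated sensor inputs. Timed states
#' (filling end, downward movement, valve-off stages) hold the register
#' until their timer elapses, except that alarm transitions preempt the
#' timer. The session ends when the machine returns to standby, or errors
#' with a partial log if the tick cap is exceeded.
#'
#' @param table a `transition_table` (normally [pd_transition_table()]).
#' @param config a [sim_config()].
#' @param faults list of [fault_spec()] objects.
#' @param mode `"dialysis"` or `"flush"` (device cleansing only).
#' @param intent operator buttons; `NULL` gives the nominal settings for the
#'   chosen mode (start held, mode selected, Pass pressed, start-dialysis
#'   confirmed).
#' @return an object of class `session_log`: list with `records` (one row
#'   per tick: tick, state code and name, the 16 input bits, the analog
#'   readings, and a `delay_hold` flag), `summary` (first-visit path, cycle
#'   count, flush volume, tick count, alarm ticks), `config` and `mode`.
#' @examples
#' \donttest{
#' log <- run_session(pd_transition_table(), sim_config())
#' log$summary$path
#' }
#' @export
run_session <- function(table, config = sim_config(), faults = list(),
                        mode = c("dialysis", "flush"), intent = NULL) {
  mode <- match.arg(mode)
  if (inherits(faults, "fault_spec")) faults <- list(faults)
  if (is.null(intent))
    intent <- operator_intent(start = TRUE,
                              dialysis_mode = mode == "dialysis",
                              flush_mode = mode == "flush",
                              audible = FALSE, pass = TRUE,
                              start_dialysis = TRUE)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$random_seed)

  tick_len <- config$tick_length
  cap <- as.integer(config$max_ticks)

  # simulator physical state
  temp <- config$temperature_initial
  level <- 0; flow1 <- 0; flow2 <- 0; flow3 <- 0; flow4 <- 0
  turbidity <- 0
  cycle <- 0L
  tu_streak <- 0
  heard <- FALSE          # audible instructions completed
  flush_ticks_total <- ceiling(config$flush_min_duration * 60 / tick_len)

  state <- 0L
  prev_state <- NA_integer_
  ticks_in_state <- 0L
  left_standby <- FALSE
  alarm_ticks <- 0L
  fills <- 0L

  n_alloc <- 4096L
  rec_tick <- integer(n_alloc); rec_state <- integer(n_alloc)
  rec_hold <- logical(n_alloc)
  rec_in <- matrix(NA_integer_, n_alloc, N_INPUTS,
                   dimnames = list(NULL, PD_INPUTS))
  rec_an <- matrix(NA_real_, n_alloc, 8,
                   dimnames = list(NULL, c("temperature", "level", "pressure",
                                           "flow1", "flow2", "flow3", "flow4",
                                           "turbidity")))
  n_rec <- 0L

  grow <- function() {
    n_alloc <<- n_alloc * 2L
    rec_tick <<- c(rec_tick, integer(n_alloc / 2L))
    rec_state <<- c(rec_state, integer(n_alloc / 2L))
    rec_hold <<- c(rec_hold, logical(n_alloc / 2L))
    rec_in <<- rbind(rec_in, matrix(NA_integer_, n_alloc / 2L, N_INPUTS))
    rec_an <<- rbind(rec_an, matrix(NA_real_, n_alloc / 2L, 8))
  }

  for (tick in 0:cap) {
    entering <- is.na(prev_state) || state != prev_state
    if (entering) ticks_in_state <- 0L

    # ---- phase-driven analog dynamics -----------------------------------
    if (entering) {
      if (state == STATE_FS) {          # filling: upper tank drains to patient
        level <- config$fill_volume; flow2 <- config$fill_flow_rate
        fills <- fills + 1L
      } else if (state == STATE_DS) {   # drain: effluent of this cycle
        cycle <- cycle + 1L
        turbidity <- config$turbidity_initial *
          config$turbidity_decay_ratio^cycle
        flow4 <- config$drain_flow_rate
        level <- 0
      } else if (state == STATE_FSH) {  # flush pump on
        flow4 <- config$flush_flow_rate
      } else if (state %in% c(STATE_LS, STATE_V31N)) {
        flow1 <- 0; flow2 <- 0; flow3 <- 0; flow4 <- 0
        level <- config$fill_volume     # receiving tank full / line primed
      } else if (state %in% c(STATE_FE, STATE_V31F, STATE_V456F, STATE_V1F)) {
        flow1 <- 0; flow2 <- 0; flow3 <- 0; flow4 <- 0
      }
    }
    if (state == STATE_HN)
      temp <- min(temp + config$heater_rate * tick_len,
                  config$temperature_setpoint + 1)
    if (state == STATE_FS)
      level <- max(level - config$fill_flow_rate * tick_len / 60, 0)
    if (state == STATE_FSH && ticks_in_state >= flush_ticks_total)
      flow4 <- 0                        # minimum flush delivered; pump stops

    fault_now <- fault_active_at(faults, tick)

    # sensor readings with seeded noise (margins dwarf the noise scale)
    analog <- analog_state(
      temperature = temp + stats::rnorm(1, 0, config$noise_sd),
      level = level,
      pressure = config$pressure_nominal + stats::rnorm(1, 0, config$noise_sd),
      flow1 = flow1, flow2 = flow2, flow3 = flow3, flow4 = flow4,
      turbidity = max(turbidity + stats::rnorm(1, 0, config$noise_sd), 0))

    tu_streak <- if (analog$turbidity >= config$turbidity_threshold)
      tu_streak + 1 else 0

    # controller-driven mode bits: the post-dialysis flush rows pattern-match
    # flush mode, and standby re-entry pattern-matches dialysis mode
    eff <- intent
    if (state %in% c(STATE_V31F, STATE_FSH)) {
      eff$dialysis_mode <- FALSE; eff$flush_mode <- TRUE
    } else if (state == STATE_V1F) {
      eff$dialysis_mode <- TRUE; eff$flush_mode <- FALSE
    }
    if (intent$audible) {
      if (state == 2L && ticks_in_state >= intent$audible_ticks) heard <- TRUE
      eff$pass <- heard
      eff$audible <- !heard
    }

    inputs <- generate_inputs(analog, config, state, eff,
                              fault_active = fault_now,
                              tu_streak = tu_streak)

    ns <- next_state(table, state, inputs)
    gated <- state %in% DELAY_STATES &&
      ticks_in_state * tick_len < delay_for_state(state, config)
    held <- gated && ns != ALARM_CODE
    if (held) ns <- state

    n_rec <- n_rec + 1L
    if (n_rec > n_alloc) grow()
    rec_tick[n_rec] <- tick
    rec_state[n_rec] <- state
    rec_hold[n_rec] <- held
    rec_in[n_rec, ] <- inputs
    rec_an[n_rec, ] <- unlist(analog)

    if (state == ALARM_CODE) alarm_ticks <- alarm_ticks + 1L
    if (state != 0L) left_standby <- TRUE
    if (state == 0L && left_standby) break

    if (tick == cap) {
      log <- finish_log(rec_tick, rec_state, rec_hold, rec_in, rec_an, n_rec,
                        table, config, mode, fills, alarm_ticks,
                        terminated = FALSE)
      cond <- structure(
        class = c("pdfsm_timeout", "error", "condition"),
        list(message = sprintf(
          "session did not terminate within %d ticks (state %s)",
          cap, code_to_bits(state)),
          call = NULL, log = log))
      stop(cond)
    }

    prev_state <- state
    ticks_in_state <- ticks_in_state + 1L
    state <- ns
  }

  finish_log(rec_tick, rec_state, rec_hold, rec_in, rec_an, n_rec,
             table, config, mode, fills, alarm_ticks, terminated = TRUE)
}

finish_log <- function(rec_tick, rec_state, rec_hold, rec_in, rec_an, n,
                       table, config, mode, fills, alarm_ticks, terminated) {
  idx <- seq_len(n)
  records <- data.frame(tick = rec_tick[idx],
                        state = rec_state[idx],
                        state_code = code_to_bits(rec_state[idx]),
                        state_name = state_name(rec_state[idx],
                                                table$catalog),
                        delay_hold = rec_hold[idx])
  records <- cbind(records, as.data.frame(rec_in[idx, , drop = FALSE]),
                   as.data.frame(rec_an[idx, , drop = FALSE]))
  first <- records$state[!duplicated(records$state)]
  path <- code_to_bits(first)
  if (terminated && length(first) > 1L) path <- c(path, code_to_bits(0L))
  log <- structure(list(records = records,
                        summary = list(path = path,
                                       path_names = state_name(
                                         c(first,
                                           if (terminated && length(first) > 1L)
                                             0L),
                                         table$catalog),
                                       cycles = fills,
                                       n_ticks = n,
                                       alarm_ticks = alarm_ticks,
                                       terminated = terminated),
                        config = config, mode = mode),
                   class = "session_log")
  fm <- flush_metrics(log, config)
  log$summary$flush_intervals <- nrow(fm)
  log$summary$flush_volume_ml <- sum(fm$volume_ml)
  log
}

#' @export
print.session_log <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Session (%s mode): %d ticks, %s\n", x$mode, s$n_ticks,
              if (s$terminated) "returned to standby" else "did not terminate"))
  cat("  path:", paste(s$path, collapse = " -> "), "\n")
  cat(sprintf("  cycles: %d, flush intervals: %d (%.0f ml), alarm ticks: %d\n",
              s$cycles, s$flush_intervals, s$flush_volume_ml, s$alarm_ticks))
  invisible(x)
}

#' Flush-stage intervals of a session log
#'
#' Each maximal run of ticks spent in the flush stage (state 01101), with
#' its duration in minutes and delivered volume (the time integral of the
#' flush-line flow reading).
#'
#' @param log a [run_session()] log.
#' @param config the `sim_config` used (defaults to the one stored in the
#'   log).
#' @return data frame with columns `interval`, `start_tick`, `end_tick`,
#'   `duration_min`, `volume_ml`; zero rows if the session never entered the
#'   flush stage.
#' @export
flush_metrics <- function(log, config = log$config) {
  rec <- log$records
  r <- rle(rec$state == STATE_FSH)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(interval = seq_along(keep),
                    start_tick = rec$tick[starts[keep]],
                    end_tick = rec$tick[ends[keep]],
                    duration_min = r$lengths[keep] * config$tick_length / 60,
                    volume_ml = vapply(keep, function(k)
                      sum(rec$flow4[starts[k]:ends[k]]) *
                        config$tick_length / 60, numeric(1)))
  out
}

#' Replay-validate a session log against the transition table
#'
#' Every consecutive pair of records must satisfy the next-state relation:
#' the state at tick t+1 equals `next_state(state_t, inputs_t)`, except on
#' delay-gated ticks, where the register must have held its value.
#'
#' @param log a [run_session()] log.
#' @param table the `transition_table` to replay against.
#' @return `TRUE` if the log replays exactly; otherwise a data frame of
#'   violating ticks.
#' @export
replay_check <- function(log, table) {
  rec <- log$records
  if (nrow(rec) < 2L) return(TRUE)
  inputs_mat <- as.matrix(rec[, PD_INPUTS])
  bad <- integer(0)
  for (i in seq_len(nrow(rec) - 1L)) {
    cur <- rec$state[i]
    nxt <- rec$state[i + 1L]
    if (rec$delay_hold[i]) {
      if (nxt != cur) bad <- c(bad, i)
    } else {
      if (nxt != next_state(table, cur, inputs_mat[i, ])) bad <- c(bad, i)
    }
  }
  if (!length(bad)) return(TRUE)
  data.frame(tick = rec$tick[bad],
             state = rec$state_code[bad],
             next_observed = rec$state_code[bad + 1L])
}

#' Write a session log as JSON Lines plus a summary document
#'
#' One JSON object per tick (tick, state code and name, inputs as a
#' name-to-bit map, analog readings, delay_hold), and the summary block as a
#' separate JSON file.
#'
#' @param log a [run_session()] log.
#' @param path output path for the JSON Lines log.
#' @param summary_path output path for the summary JSON (default: `path`
#'   with a `_summary.json` suffix).
#' @return invisibly, the paths written.
#' @export
write_session_log <- function(log, path,
                              summary_path = sub("\\.jsonl?$", "", path) |>
                                paste0("_summary.json")) {
  rec <- log$records
  an_cols <- c("temperature", "level", "pressure", "flow1", "flow2", "flow3",
               "flow4", "turbidity")
  lines <- vapply(seq_len(nrow(rec)), function(i) {
    jsonlite::toJSON(list(
      tick = rec$tick[i],
      state_code = rec$state_code[i],
      state_name = rec$state_name[i],
      inputs = as.list(rec[i, PD_INPUTS]),
      analog = as.list(round(rec[i, an_cols], 4)),
      delay_hold = rec$delay_hold[i]),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  jsonlite::write_json(log$summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(path, summary_path))
}
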