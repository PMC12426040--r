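tbl <- pd_transition_table()

test_that("input generation thresholds analog readings correctly", {
  cfg <- sim_config()
  # all-zero analog, no faults, no buttons -> the all-zero vector
  expect_identical(unname(generate_inputs(analog_state(), cfg)),
                   rep(0L, 16L))
  # temperature exactly at the setpoint asserts T
  v <- generate_inputs(analog_state(temperature = 37), cfg)
  expect_equal(unname(v["T"]), 1L)
  expect_equal(unname(generate_inputs(analog_state(temperature = 36.9),
                                      cfg)["T"]), 0L)
  # turbidity must persist for the whole window before TU asserts
  dirty <- analog_state(turbidity = 50)
  expect_equal(unname(generate_inputs(dirty, cfg, tu_streak = 2)["TU"]), 0L)
  expect_equal(unname(generate_inputs(dirty, cfg, tu_streak = 3)["TU"]), 1L)
  expect_equal(unname(generate_inputs(analog_state(turbidity = 5), cfg,
                                      tu_streak = 99)["TU"]), 0L)
  # pressure asserts only inside the safe band
  expect_equal(unname(generate_inputs(analog_state(pressure = 100),
                                      cfg)["PR"]), 1L)
  expect_equal(unname(generate_inputs(analog_state(pressure = 200),
                                      cfg)["PR"]), 0L)
  # faults raise both danger-value and fault flags
  vf <- generate_inputs(analog_state(), cfg, fault_active = TRUE)
  expect_equal(unname(vf[c("DV", "F")]), c(1L, 1L))
})

test_that("a nominal dialysis session walks the canonical stage path", {
  cfg <- fast_config()
  log <- run_session(tbl, cfg)
  expect_identical(log$summary$path,
                   c("00000", "00001", "00011", "00100", "00101", "00110",
                     "00111", "01000", "01001", "01011", "01100", "01101",
                     "01110", "01111", "10000", "00000"))
  expect_true(log$summary$terminated)
  expect_equal(log$summary$cycles, turbidity_cycles(cfg))
  expect_true(isTRUE(replay_check(log, tbl)))
  # ticks strictly increasing, consecutive states related by next_state
  expect_true(all(diff(log$records$tick) == 1))
})

test_that("flush mode enters the flush stage directly from standby", {
  log <- run_session(tbl, fast_config(), mode = "flush")
  expect_equal(log$summary$path[2], "01101")
  expect_true(log$summary$terminated)
  expect_true(isTRUE(replay_check(log, tbl)))
})

test_that("faults reach the alarm in one tick and recovery returns to standby", {
  log <- run_session(tbl, fast_config(),
                     faults = list(fault_spec(5, "sensor_fault",
                                              cleared_at = 9)))
  r <- log$records
  expect_equal(r$state_code[r$tick == 6], "11111")
  expect_equal(r$state_code[r$tick == 9], "11111")  # last alarmed tick
  expect_equal(r$state_code[r$tick == 10], "00000") # recovery within a tick
  expect_true(isTRUE(replay_check(log, tbl)))
  # a fault during a delay-gated tick preempts the timer
  nominal <- run_session(tbl, fast_config())
  t_hold <- nominal$records$tick[which(nominal$records$delay_hold)[1]]
  log2 <- run_session(tbl, fast_config(),
                      faults = list(fault_spec(t_hold, "danger_value",
                                               cleared_at = t_hold + 3)))
  r2 <- log2$records
  expect_true(nominal$records$delay_hold[nominal$records$tick == t_hold])
  expect_equal(r2$state_code[r2$tick == t_hold + 1], "11111")
})

test_that("delay states hold for their configured duration", {
  cfg <- fast_config()
  log <- run_session(tbl, cfg)
  r <- log$records
  dwm_ticks <- sum(r$state == 7L)   # downward movement, one delay per cycle
  expect_equal(dwm_ticks, (cfg$delay_duration + 1) * log$summary$cycles)
  fe_ticks <- sum(r$state == 6L)    # filling end dwells for dwell_duration
  expect_equal(fe_ticks, (cfg$dwell_duration + 1) * log$summary$cycles)
})

test_that("turbidity decay fixes the cycle count", {
  expect_equal(turbidity_cycles(sim_config(turbidity_initial = 100,
                                           turbidity_threshold = 10,
                                           turbidity_decay_ratio = 0.5)), 4L)
  expect_equal(turbidity_cycles(sim_config(turbidity_initial = 5,
                                           turbidity_threshold = 10)), 1L)
  expect_equal(turbidity_cycles(sim_config(turbidity_decay_ratio = 0.999,
                                           max_cycles = 12)), 12L)
})

test_that("flush metrics report duration and delivered volume per interval", {
  cfg <- fast_config()
  log <- run_session(tbl, cfg)
  fm <- flush_metrics(log)
  expect_equal(nrow(fm), log$summary$cycles)
  expect_true(all(fm$duration_min >= cfg$flush_min_duration))
  # volume is flow rate times pumped time
  expect_true(all(abs(fm$volume_ml -
                        cfg$flush_flow_rate * cfg$flush_min_duration) < 1e-6))
  # a log with no flush interval yields an empty report
  log_cut <- log
  log_cut$records <- log$records[log$records$state != 13L, ]
  expect_equal(nrow(flush_metrics(log_cut, cfg)), 0L)
})

test_that("identical config and seed reproduce the log exactly", {
  a <- run_session(tbl, fast_config(random_seed = 11))
  b <- run_session(tbl, fast_config(random_seed = 11))
  expect_identical(a$records, b$records)
  c <- run_session(tbl, fast_config(random_seed = 12))
  expect_false(identical(a$records$temperature, c$records$temperature))
})

test_that("the audible-instructions branch passes through state 00010", {
  intent <- operator_intent(start = TRUE, dialysis_mode = TRUE,
                            audible = TRUE, start_dialysis = TRUE)
  log <- run_session(tbl, fast_config(), intent = intent)
  expect_true("00010" %in% log$summary$path)
  expect_true(log$summary$terminated)
  expect_true(isTRUE(replay_check(log, tbl)))
})

test_that("exceeding the tick cap raises a timeout carrying the partial log", {
  cfg <- fast_config(max_ticks = 30)
  err <- tryCatch(run_session(tbl, cfg), pdfsm_timeout = function(e) e)
  expect_s3_class(err, "pdfsm_timeout")
  expect_s3_class(err$log, "session_log")
  expect_false(err$log$summary$terminated)
  expect_equal(nrow(err$log$records), 31L)
})

test_that("session logs round-trip to JSON lines", {
  log <- run_session(tbl, fast_config())
  p <- tempfile(fileext = ".jsonl")
  paths <- write_session_log(log, p)
  lines <- readLines(p)
  expect_equal(length(lines), nrow(log$records))
  first <- jsonlite::fromJSON(lines[1])
  expect_equal(first$state_code, "00000")
  expect_named(first$inputs, pdfsm:::PD_INPUTS, ignore.order = TRUE)
  summ <- jsonlite::fromJSON(paths[2])
  expect_equal(summ$cycles, log$summary$cycles)
})

test_that("fault and config constructors validate their arguments", {
  expect_error(fault_spec(-1), "non-negative")
  expect_error(fault_spec(5, cleared_at = 5), "after")
  expect_error(sim_config(turbidity_decay_ratio = 1.2), "in \\(0, 1\\)")
  expect_error(sim_config(tick_length = 0), "positive")
  expect_error(analog_state(level = -1), "non-negative")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(tick = 3, kind = "danger_value",
                                 cleared_at = 8)), f, auto_unbox = TRUE)
  fs <- read_fault_specs(f)
  expect_equal(fs[[1]]$cleared_at, 8L)
  cfgf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(dwell_duration = 12), cfgf, auto_unbox = TRUE)
  expect_equal(read_sim_config(cfgf)$dwell_duration, 12)
  jsonlite::write_json(list(nonsense = 1), cfgf, auto_unbox = TRUE)
  expect_error(read_sim_config(cfgf), "unknown config field")
})
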