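tbl <- pd_transition_table()

test_that("the shipped table parses to 49 rows over 20 current-state codes", {
  expect_equal(nrow(tbl$rows), 49L)
  expect_equal(length(unique(tbl$rows$state)), 20L)
  expect_equal(length(tbl$catalog$inputs), 16L)
  expect_equal(length(tbl$catalog$outputs), 18L)
  # every printed case count was captured
  expect_false(anyNA(tbl$rows$cases))
})

test_that("parse errors name the offending cell; duplicates are deduplicated", {
  lines <- readLines(system.file("extdata", "transition_table.tsv",
                                 package = "pdfsm"))
  # corrupt one pattern symbol
  bad <- sub("\t0\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\t00000",
             "\t2\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\tX\t00000",
             lines)
  f <- tempfile(fileext = ".tsv"); writeLines(bad, f)
  expect_error(read_transition_table(f), "row 2, column S.*'2'")

  # wrong column set
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("state\tnext", "00000\t00001"), f2)
  expect_error(read_transition_table(f2), "wrong columns")

  # exact duplicate row -> warning, deduplicated
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c(lines, lines[2]), f3)
  expect_warning(t3 <- read_transition_table(f3), "duplicate")
  expect_equal(nrow(t3$rows), 49L)

  # header-only file: zero rows, everything uncovered
  f4 <- tempfile(fileext = ".tsv")
  writeLines(lines[1], f4)
  t4 <- read_transition_table(f4)
  expect_equal(nrow(t4$rows), 0L)
  expect_true(all(validate_table(t4)$coverage$uncovered_fraction == 1))

  expect_error(read_transition_table(tempfile()), "not found")
})

test_that("row matching honours don't-cares and the current state", {
  standby_hold <- transition_row(tbl, 2L)   # S = 0, rest X
  expect_true(row_matches(standby_hold, 0L, input_vector(DM = 1, TU = 1)))
  expect_false(row_matches(standby_hold, 0L, input_vector(S = 1)))
  expect_false(row_matches(standby_hold, 1L, input_vector()))

  stay_filling <- transition_row(tbl, 20L)  # the 128-case self-loop at 00101
  base <- input_vector(S = 1, DM = 1, T = 1, F2 = 1, L = 1, PR = 1)
  expect_true(row_matches(stay_filling, 5L, base))
  for (free in c("AI", "P", "SD", "F1", "F3", "F4", "TU")) {
    v <- base; v[free] <- 1L
    expect_true(row_matches(stay_filling, 5L, v))
  }
  v <- base; v["PR"] <- 0L
  expect_false(row_matches(stay_filling, 5L, v))
})

test_that("coverage counts equal 2^(number of don't-cares)", {
  pick <- function(cur, nxt) which(tbl$rows$state == bits_to_code(cur) &
                                     tbl$rows$next_state == bits_to_code(nxt))
  expect_equal(coverage_count(tbl, pick("00000", "00000")), 32768)
  expect_equal(coverage_count(tbl, pick("00101", "00101")), 128)
  expect_equal(coverage_count(tbl, pick("01011", "01100")), 256)
  expect_equal(coverage_count(tbl, pick("00100", "00101")), 512)
  expect_equal(coverage_count(tbl, pick("01111", "10000")), 4096)
  expect_equal(coverage_count(tbl, pick("00000", "11111")), 8192)
  expect_equal(coverage_count(tbl, pick("10001", "11111")), 65536)
  expect_equal(coverage_count(tbl, pick("11111", "00000")), 8192)
  # fully specified pattern covers exactly one vector
  row <- transition_row(tbl, 1L)
  row$pattern[] <- 0L
  expect_equal(coverage_count(row), 1)
})

test_that("next_state follows the table, traps unused codes and completes", {
  go <- input_vector(S = 1, DM = 1)           # FM=0, DV=0, F=0 implicit
  expect_equal(next_state(tbl, 0L, go), 1L)                     # to w.ins
  expect_equal(next_state(tbl, 0L, input_vector(S = 1, FM = 1)), 13L)
  expect_equal(next_state(tbl, 16L, go), 0L)                    # TU=0 -> standby
  expect_equal(next_state(tbl, 16L, input_vector(S = 1, DM = 1, TU = 1)), 3L)
  expect_equal(next_state(tbl, 18L, input_vector()), 31L)       # unused trap
  expect_equal(next_state(tbl, 30L, go), 31L)
  # draining-end sink: no row matches fault-free inputs -> completion
  expect_equal(next_state(tbl, 10L, go), 10L)                   # hold
  tbl_alarm <- pd_transition_table(completion_policy = "alarm")
  expect_equal(next_state(tbl_alarm, 10L, go), 31L)
  # uncovered standby input under hold: S=1 but neither mode pressed
  expect_equal(next_state(tbl, 1L, input_vector(S = 0)), 1L)
})

test_that("a more specific overlapping row takes priority", {
  # heater-off with start-dialysis pressed goes to filling, not the self-loop
  expect_equal(next_state(tbl, 4L, input_vector(S = 1, DM = 1, T = 1, SD = 1)),
               5L)
  expect_equal(next_state(tbl, 4L, input_vector(S = 1, DM = 1, T = 1)), 4L)
  # flush stage with flow-4 stopped advances, otherwise stays
  expect_equal(next_state(tbl, 13L, input_vector(S = 1, FM = 1)), 14L)
  expect_equal(next_state(tbl, 13L, input_vector(S = 1, FM = 1, F4 = 1)), 13L)
})

test_that("scalar and vectorised next-state evaluation agree", {
  set.seed(3)
  for (s in c(0L, 4L, 5L, 13L, 16L, 22L, 31L)) {
    v <- next_state_vector(tbl, s)
    for (i in sample(0:65535, 50)) {
      inputs <- pdfsm:::index_to_inputs(i)
      expect_identical(v[i + 1L], next_state(tbl, s, inputs))
    }
  }
})

test_that("equal-specificity conflicting matches raise an internal error", {
  bad <- tt_build(tt_row("00000", "00001"), tt_row("00000", "00010"))
  expect_error(next_state(bad, 0L, input_vector()), "internal consistency")
})

test_that("validation reports conflicts, sinks and coverage faithfully", {
  v <- validate_table(tbl)
  expect_equal(nrow(v$hard_conflicts), 0L)
  expect_true(v$ok)
  # the two containment overlaps of the published table
  expect_equal(sum(v$conflicts$containment), 2L)
  expect_setequal(v$conflicts$state, c("00100", "01101"))
  # draining end is the only state with no fault-free exit
  expect_identical(v$sinks, "01010")

  collision <- tt_build(tt_row("00000", "00001"), tt_row("00000", "00010"))
  vc <- validate_table(collision)
  expect_equal(nrow(vc$hard_conflicts), 1L)
  expect_false(vc$ok)
})

test_that("each state's row union plus uncovered residue tiles the input space", {
  v <- validate_table(tbl)
  for (s in tbl$catalog$state_codes) {
    idx <- which(tbl$rows$state == s)
    cubes <- lapply(idx, function(i) tbl$pattern[i, ])
    union_size <- pdfsm:::cubes_union_size(cubes)
    residue <- v$coverage$uncovered[v$coverage$state == code_to_bits(s)]
    expect_equal(union_size + residue, 65536)
    # rows are pairwise disjoint (coverage sums to the union) everywhere
    # except the two containment-overlap states
    if (!s %in% c(4L, 13L))
      expect_equal(sum(coverage_count(tbl, idx)), union_size)
  }
})

test_that("the printed case counts audit clean; constructed errors are caught", {
  a <- audit_cases(tbl)
  expect_equal(nrow(a$audit), 49L)
  expect_equal(nrow(a$mismatches), 0L)

  bad <- tt_build(tt_row("00000", "00001", S = 1, DM = 0, FM = 1, cases = 100))
  ab <- audit_cases(bad)
  expect_equal(nrow(ab$mismatches), 1L)
  expect_equal(ab$audit$computed[1], 8192)
})
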