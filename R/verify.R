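# Safety-property checks by exhaustive enumeration, and reachability over
# the row graph. Properties are one-step: they quantify over (state, input)
# pairs and check the next-state relation directly.

property_result <- function(name, universe, counterexamples, cap = 100L) {
  if (nrow(counterexamples) > cap)
    counterexamples <- counterexamples[seq_len(cap), , drop = FALSE]
  structure(list(property = name,
                 holds = nrow(counterexamples) == 0L,
                 universe = universe,
                 counterexamples = counterexamples),
            class = "property_result")
}

#' @export
print.property_result <- function(x, ...) {
  cat(sprintf("%-18s %s  (universe %d)\n", x$property,
              if (x$holds) "HOLDS" else "FAILS", x$universe))
  if (!x$holds) {
    cat("  counterexamples (capped):\n")
    print(utils::head(x$counterexamples, 5), row.names = FALSE)
  }
  invisible(x)
}

ce_frame <- function(states, input_idx) {
  if (!length(states))
    return(data.frame(state = character()))
  df <- data.frame(state = code_to_bits(states))
  cbind(df, t(vapply(input_idx, index_to_inputs, integer(16))))
}

#' Fault-to-alarm property
#'
#' For every defined state and every input vector with the start button held
#' and both fault flags raised (S = 1, DV = 1, F = 1), the next state must be
#' the alarm 11111. Enumerated exhaustively: 18 states times 2^13 free-bit
#' vectors. With `require_start = FALSE` a stricter variant is checked (fault
#' implies alarm regardless of the start button); the table as written does
#' not satisfy it, because the standby hold row matches S = 0 whatever the
#' fault flags say.
#'
#' @param table a `transition_table`.
#' @param require_start guard the property on S = 1 (the table's own alarm
#'   rows do).
#' @param cap maximum counterexamples kept.
#' @return a `property_result`.
#' @export
check_fault_to_alarm <- function(table, require_start = TRUE, cap = 100L) {
  im <- input_matrix()
  sel <- im[, "DV"] == 1L & im[, "F"] == 1L
  if (require_start) sel <- sel & im[, "S"] == 1L
  sel <- which(sel)
  nsm <- next_state_matrix(table)
  states <- integer(0); idx <- integer(0)
  for (s in table$catalog$state_codes) {
    bad <- sel[nsm[sel, s + 1L] != ALARM_CODE]
    if (length(bad)) {
      states <- c(states, rep(s, length(bad)))
      idx <- c(idx, bad - 1L)
    }
  }
  property_result(
    if (require_start) "fault_to_alarm" else "fault_to_alarm_strict",
    universe = length(sel) * length(table$catalog$state_codes),
    ce_frame(states, idx), cap)
}

#' Alarm-recovery property
#'
#' Every input vector matching the alarm state's recovery row (S = 1,
#' DV = 0, F = 0) must send 11111 back to standby 00000.
#'
#' @inheritParams check_fault_to_alarm
#' @return a `property_result` (universe 8192).
#' @export
check_alarm_recovery <- function(table, cap = 100L) {
  im <- input_matrix()
  sel <- which(im[, "S"] == 1L & im[, "DV"] == 0L & im[, "F"] == 0L)
  nsm <- next_state_matrix(table)
  bad <- sel[nsm[sel, ALARM_CODE + 1L] != 0L]
  property_result("alarm_recovery", universe = length(sel),
                  ce_frame(rep(ALARM_CODE, length(bad)), bad - 1L), cap)
}

#' Unused-code trap property
#'
#' Every register code from 17 (10001) to 30 (11110) must map to the alarm
#' 11111 for all 65,536 input vectors.
#'
#' @inheritParams check_fault_to_alarm
#' @return a `property_result` (universe 14 x 65536 = 917504).
#' @export
check_unused_trap <- function(table, cap = 100L) {
  nsm <- next_state_matrix(table)
  states <- integer(0); idx <- integer(0)
  for (s in 17:30) {
    bad <- which(nsm[, s + 1L] != ALARM_CODE)
    if (length(bad)) {
      states <- c(states, rep(s, length(bad)))
      idx <- c(idx, bad - 1L)
    }
  }
  property_result("unused_trap", universe = 14L * 65536L,
                  ce_frame(states, idx), cap)
}

#' Totality of the next-state function
#'
#' Counts the enumerated (state, input) pairs - all 32 register codes times
#' all 65,536 input vectors, 2,097,152 assignments - and checks every next
#' state is a valid code.
#'
#' @inheritParams check_fault_to_alarm
#' @return a `property_result` with universe 2097152.
#' @export
check_totality <- function(table, cap = 100L) {
  nsm <- next_state_matrix(table)
  ok <- !is.na(nsm) & nsm >= 0L & nsm <= 31L
  bad <- which(!ok, arr.ind = TRUE)
  ces <- if (nrow(bad)) ce_frame(bad[, 2L] - 1L, bad[, 1L] - 1L)
         else data.frame(state = character())
  property_result("totality", universe = length(nsm), ces, cap)
}

#' States reachable from a start code
#'
#' Breadth-first closure of the next-state relation. The `"rows"` method
#' walks the row graph symbolically (one edge per table row, plus the
#' unused-code trap and, under the alarm completion policy, the residue edge
#' to 11111); the `"enumerate"` method computes successors by evaluating
#' next_state over all 65,536 input vectors per visited state. Both return
#' identical sets.
#'
#' @param table a `transition_table`.
#' @param start integer start code.
#' @param method `"rows"` (symbolic, default) or `"enumerate"` (brute
#'   force).
#' @return an object of class `reachability_set`: list with `start`,
#'   `reached` (integer codes) and `order` (first-visit order, starting at
#'   `start`).
#' @examples
#' r <- reachable(pd_transition_table(), 0L)
#' length(r$reached)  # 18 defined states
#' @export
reachable <- function(table, start, method = c("rows", "enumerate")) {
  method <- match.arg(method)
  succ <- if (method == "rows") {
    function(s) {
      if (is_unused_code(s)) return(ALARM_CODE)
      idx <- which(table$rows$state == s)
      out <- unique(table$rows$next_state[idx])
      # completion residue: hold only adds a self-loop; alarm adds 11111
      if (table$completion_policy == "alarm") {
        cubes <- lapply(idx, function(i) table$pattern[i, ])
        if (cubes_union_size(cubes) < 65536) out <- c(out, ALARM_CODE)
      }
      unique(out)
    }
  } else {
    function(s) unique(next_state_vector(table, s))
  }
  visited <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, succ)))
    nxt <- setdiff(nxt, visited)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  structure(list(start = start, reached = sort(visited), order = visited),
            class = "reachability_set")
}

#' @export
print.reachability_set <- function(x, ...) {
  cat(sprintf("reachable from %s: %d states\n", code_to_bits(x$start),
              length(x$reached)))
  cat("  first-visit order:", paste(code_to_bits(x$order), collapse = " "),
      "\n")
  invisible(x)
}

#' Run the full verification suite
#'
#' Fault-to-alarm, alarm recovery, unused-code trap and totality by
#' exhaustive enumeration, plus reachability from standby, plus the stricter
#' unguarded fault property as an advisory (reported, but not counted
#' against `ok`: the table's alarm rows are themselves guarded on S = 1).
#'
#' @param table a `transition_table`.
#' @return an object of class `verification_report`: list with `properties`
#'   (the four gating `property_result`s), `advisory` (the strict variant),
#'   `reachability` and `ok`.
#' @export
verify_controller <- function(table) {
  props <- list(check_fault_to_alarm(table),
                check_alarm_recovery(table),
                check_unused_trap(table),
                check_totality(table))
  reach <- reachable(table, 0L)
  structure(list(properties = props,
                 advisory = check_fault_to_alarm(table, require_start = FALSE),
                 reachability = reach,
                 ok = all(vapply(props, `[[`, logical(1), "holds"))),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  for (p in x$properties) print(p)
  cat("advisory (not gating):\n  ")
  print(x$advisory)
  print(x$reachability)
  cat(if (x$ok) "all gating properties hold\n"
      else "SOME PROPERTIES FAIL\n")
  invisible(x)
}

#' Write a verification report as JSON
#'
#' @param report a [verify_controller()] report.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_verification_report <- function(report, path) {
  as_json <- function(p)
    list(property = p$property, holds = p$holds, universe = p$universe,
         counterexamples = p$counterexamples)
  jsonlite::write_json(
    list(properties = lapply(report$properties, as_json),
         advisory = as_json(report$advisory),
         reachable_from_standby = code_to_bits(report$reachability$reached),
         ok = report$ok),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
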