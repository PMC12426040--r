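# The controller's behaviour lives in a ternary transition table: each row
# pairs a current 5-bit register code with a 16-symbol pattern over the
# inputs (0, 1, or X for don't-care) and names the next register code. A row
# matches a (state, input-vector) pair when the state equals its current code
# and every specified pattern symbol agrees with the corresponding input bit.

#' Construct a transition table
#'
#' Builds the controller's complete behaviour description from a data frame
#' of ternary rows. Most users will want [read_transition_table()] or the
#' shipped table from [pd_transition_table()] instead.
#'
#' @param rows a data frame with columns `state` and `next` (5-character
#'   binary strings or integers 0-31), optionally `cases` (the printed
#'   coverage count) and `comment`, plus one column per input signal
#'   (`S`, `DM`, ..., `F`) holding `"0"`, `"1"` or `"X"`. Missing input
#'   columns default to all-`X`.
#' @param catalog a [signal_catalog()].
#' @param completion_policy what `next_state()` does for (state, input) pairs
#'   no row covers: `"hold"` remains in the current state, `"alarm"`
#'   escalates to 11111.
#' @param source provenance string stored on the object.
#' @return an object of class `transition_table`.
#' @seealso [next_state()], [validate_table()], [audit_cases()]
#' @export
transition_table <- function(rows, catalog = signal_catalog(),
                             completion_policy = c("hold", "alarm"),
                             source = "constructed") {
  completion_policy <- match.arg(completion_policy)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)

  state <- normalize_codes(rows$state, "state")
  nxt <- normalize_codes(rows[["next"]], "next")

  pattern <- matrix(NA_integer_, nrow = nrow(rows), ncol = N_INPUTS,
                    dimnames = list(NULL, catalog$inputs))
  for (j in seq_along(catalog$inputs)) {
    nm <- catalog$inputs[j]
    col <- if (nm %in% names(rows)) as.character(rows[[nm]])
           else rep("X", nrow(rows))
    col <- toupper(trimws(col))
    bad <- !(col %in% c("0", "1", "X"))
    if (any(bad)) {
      k <- which(bad)[1]
      stop(sprintf("row %d, column %s: invalid symbol '%s' (must be 0, 1 or X)",
                   k, nm, col[k]))
    }
    v <- rep(NA_integer_, length(col))
    v[col != "X"] <- as.integer(col[col != "X"])
    pattern[, j] <- v
  }

  cases <- if ("cases" %in% names(rows)) {
    as.integer(gsub("[, ]", "", as.character(rows$cases)))
  } else rep(NA_integer_, nrow(rows))
  comment <- if ("comment" %in% names(rows)) as.character(rows$comment)
             else rep("", nrow(rows))

  key <- paste(state, apply(pattern, 1, paste, collapse = "|"), nxt)
  if (anyDuplicated(key)) {
    dup <- duplicated(key)
    warning(sum(dup), " duplicate row(s) removed: ",
            paste(which(dup), collapse = ", "))
    state <- state[!dup]; nxt <- nxt[!dup]; cases <- cases[!dup]
    comment <- comment[!dup]; pattern <- pattern[!dup, , drop = FALSE]
  }

  tbl <- structure(list(
    catalog = catalog,
    rows = data.frame(state = state, next_state = nxt, cases = cases,
                      comment = comment, stringsAsFactors = FALSE),
    pattern = pattern,
    nspec = as.integer(rowSums(!is.na(pattern))),
    completion_policy = completion_policy,
    source = source
  ), class = "transition_table")
  attr(tbl, "id") <- table_id(tbl)
  tbl
}

normalize_codes <- function(x, what) {
  if (is.null(x)) stop("missing required column: ", what)
  if (is.character(x)) bits_to_code(trimws(x))
  else {
    x <- as.integer(x)
    if (any(x < 0L | x > 31L)) stop(what, " codes must be in [0, 31]")
    x
  }
}

table_id <- function(tbl) {
  paste(tbl$completion_policy,
        paste(tbl$rows$state, apply(tbl$pattern, 1, paste, collapse = ""),
              tbl$rows$next_state, collapse = ";"),
        sep = "#")
}

#' Read a transition table from a delimited text file
#'
#' The dialect is UTF-8 comma- or tab-separated text with a header row and
#' columns `cases` (optional), `state` (5-character binary), one column per
#' input (`S`, `DM`, `FM`, `AI`, `P`, `T`, `SD`, `F1`, `F2`, `F3`, `F4`,
#' `L`, `PR`, `TU`, `DV`, `F`) with values `0`/`1`/`X`, `next` (5-character
#' binary), and `comment` (optional). Exact duplicate rows are removed with
#' a warning; any symbol other than 0/1/X is a parse error naming the row
#' and column.
#'
#' @inheritParams transition_table
#' @param path path to the table file.
#' @return a `transition_table`.
#' @examples
#' tbl <- read_transition_table(
#'   system.file("extdata", "transition_table.tsv", package = "pdfsm"))
#' nrow(tbl$rows)  # 49
#' @export
read_transition_table <- function(path, catalog = signal_catalog(),
                                  completion_policy = c("hold", "alarm")) {
  if (!file.exists(path)) stop("table file not found: ", path)
  df <- utils::read.delim(path, sep = guess_sep(path), header = TRUE,
                          colClasses = "character", strip.white = TRUE,
                          check.names = FALSE)
  need <- c("state", catalog$inputs, "next")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("table file has wrong columns; missing: ",
         paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(df), c("cases", need, "comment"))
  if (length(unknown))
    stop("table file has wrong columns; unknown: ",
         paste(unknown, collapse = ", "))
  tbl <- transition_table(df, catalog = catalog,
                          completion_policy = completion_policy,
                          source = path)
  tbl$checksum <- unname(tools::md5sum(path))
  tbl
}

#' The shipped peritoneal-dialysis controller table
#'
#' The 49-row transition table of the dialysis-cycle controller, transcribed
#' symbol-for-symbol from the controller's published state transition table
#' (including its printed per-row coverage counts and the two annotated
#' unused-state rows).
#'
#' @inheritParams transition_table
#' @return a `transition_table` with 49 rows.
#' @export
pd_transition_table <- function(completion_policy = c("hold", "alarm")) {
  read_transition_table(
    system.file("extdata", "transition_table.tsv", package = "pdfsm",
                mustWork = TRUE),
    completion_policy = completion_policy)
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("Transition table: %d rows over %d current-state codes (%s)\n",
              nrow(x$rows), length(unique(x$rows$state)), x$source))
  cat(sprintf("  completion policy: %s\n", x$completion_policy))
  invisible(x)
}

#' Extract one transition row
#'
#' @param table a `transition_table`.
#' @param i row index.
#' @return a list with elements `current` (integer code), `pattern` (named
#'   integer vector, `NA` = don't-care), `next_state`, `comment`,
#'   `printed_cases`.
#' @export
transition_row <- function(table, i) {
  stopifnot(i >= 1L, i <= nrow(table$rows))
  list(current = table$rows$state[i],
       pattern = stats::setNames(table$pattern[i, ], colnames(table$pattern)),
       next_state = table$rows$next_state[i],
       comment = table$rows$comment[i],
       printed_cases = table$rows$cases[i])
}

#' Does a row match a (state, input) pair?
#'
#' True iff `state` equals the row's current code and every specified (non-X)
#' pattern symbol equals the corresponding input bit.
#'
#' @param row a row from [transition_row()].
#' @param state integer state code.
#' @param inputs an [input_vector()] (length 16, values 0/1).
#' @return logical scalar.
#' @export
row_matches <- function(row, state, inputs) {
  stopifnot(length(inputs) == N_INPUTS)
  if (state != row$current) return(FALSE)
  !any(row$pattern != as.integer(inputs), na.rm = TRUE)
}

#' Coverage count of a transition row
#'
#' The number of full 16-bit input vectors a ternary row pattern matches:
#' 2 raised to its number of don't-care symbols. This is the quantity the
#' table's "Cases" column prints.
#'
#' @param x a `transition_table` or a single row from [transition_row()].
#' @param i optional row index when `x` is a table; if omitted, counts for
#'   all rows are returned.
#' @return numeric coverage count(s).
#' @examples
#' tbl <- pd_transition_table()
#' coverage_count(tbl, 2)  # the standby-hold row: 32768
#' @export
coverage_count <- function(x, i = NULL) {
  if (inherits(x, "transition_table")) {
    nx <- N_INPUTS - x$nspec
    if (is.null(i)) 2^nx else 2^nx[i]
  } else {
    2^sum(is.na(x$pattern))
  }
}

# ---- next-state evaluation -------------------------------------------------

# Rows for a state in "overwrite order": ascending specificity, file order as
# tie-break. Applying rows in this order and letting later rows overwrite
# earlier ones resolves pattern containment in favour of the more specific
# row, which is how the controller's self-loop rows coexist with their more
# specific exit rows.
state_row_order <- function(table, state) {
  idx <- which(table$rows$state == state)
  idx[order(table$nspec[idx], seq_along(idx))]
}

#' Next-state function of the controller
#'
#' Total over all 2^21 (state, input) pairs: unused register codes (17-30)
#' trap to the alarm 11111; otherwise the matching table rows decide, with a
#' more specific row taking priority over a less specific one it overlaps;
#' if no row matches, the table's completion policy applies (`"hold"` stays
#' in the current state, `"alarm"` returns 11111).
#'
#' @param table a `transition_table`.
#' @param state integer state code in `[0, 31]`.
#' @param inputs an [input_vector()].
#' @return integer: the next state code.
#' @examples
#' tbl <- pd_transition_table()
#' next_state(tbl, 0L, input_vector(S = 1, DM = 1))  # 1 (written instructions)
#' next_state(tbl, 18L, input_vector())              # 31 (unused-code trap)
#' @export
next_state <- function(table, state, inputs) {
  stopifnot(state >= 0L, state <= 31L, length(inputs) == N_INPUTS)
  if (is_unused_code(state)) return(ALARM_CODE)
  inputs <- as.integer(inputs)
  idx <- which(table$rows$state == state)
  if (length(idx)) {
    hit <- idx[vapply(idx, function(i)
      !any(table$pattern[i, ] != inputs, na.rm = TRUE), logical(1))]
    if (length(hit)) {
      nx <- unique(table$rows$next_state[hit])
      if (length(nx) == 1L) return(nx)
      top <- hit[table$nspec[hit] == max(table$nspec[hit])]
      nx <- unique(table$rows$next_state[top])
      if (length(nx) == 1L) return(nx)
      stop(sprintf(
        "internal consistency error: state %s has conflicting matches of equal specificity",
        code_to_bits(state)))
    }
  }
  if (table$completion_policy == "hold") state else ALARM_CODE
}

#' Next states for one current state over every input vector
#'
#' Vectorised evaluation of [next_state()] across all 65,536 input
#' assignments, in input-index order (the 16-bit integer whose most
#' significant bit is `S`).
#'
#' @inheritParams next_state
#' @return integer vector of length 65536.
#' @export
next_state_vector <- function(table, state) {
  if (is_unused_code(state)) return(rep(ALARM_CODE, 65536L))
  im <- input_matrix()
  res <- rep(if (table$completion_policy == "hold") as.integer(state)
             else ALARM_CODE, 65536L)
  for (i in state_row_order(table, state)) {
    mask <- rep(TRUE, 65536L)
    for (j in which(!is.na(table$pattern[i, ])))
      mask <- mask & (im[, j] == table$pattern[i, j])
    res[mask] <- table$rows$next_state[i]
  }
  res
}

# Full 65536 x 32 next-state matrix (column s+1 = state s), memoised on the
# table id. This is the enumeration backbone of the equivalence checker and
# the safety properties.
ns_cache <- new.env(parent = emptyenv())

next_state_matrix <- function(table) {
  key <- attr(table, "id")
  if (!is.null(key) && !is.null(ns_cache[[key]])) return(ns_cache[[key]])
  m <- matrix(ALARM_CODE, nrow = 65536L, ncol = 32L)
  for (s in 0:31)
    m[, s + 1L] <- next_state_vector(table, s)
  if (!is.null(key)) {
    if (length(ls(ns_cache)) > 8L) rm(list = ls(ns_cache), envir = ns_cache)
    ns_cache[[key]] <- m
  }
  m
}

# ---- structural validation -------------------------------------------------

#' Validate a transition table's structural properties
#'
#' Reports, per the table as written (before any completion policy):
#' \describe{
#'   \item{conflicts}{pairs of rows with the same current state, intersecting
#'     patterns and different next states. A pair where one pattern contains
#'     the other is flagged `containment = TRUE`: such overlaps are resolved
#'     deterministically by specificity priority. Overlaps without
#'     containment are hard conflicts and make the table ambiguous.}
#'   \item{coverage}{per defined state, the count and fraction of the 65,536
#'     input vectors matched by no row (the completion residue).}
#'   \item{sinks}{defined states with no outgoing row (to a different state)
#'     whose pattern permits `F = 0`, i.e. states that can only be left
#'     through a system fault.}
#' }
#'
#' @param table a `transition_table`.
#' @return an object of class `pd_validation` with elements `conflicts`,
#'   `hard_conflicts`, `coverage`, `sinks`, `n_rows` and `ok` (no hard
#'   conflicts).
#' @export
validate_table <- function(table) {
  rows <- table$rows
  conflicts <- list()
  for (s in unique(rows$state)) {
    idx <- which(rows$state == s)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        if (rows$next_state[i] == rows$next_state[j]) next
        if (!cube_compatible(table$pattern[i, ], table$pattern[j, ])) next
        # strict containment only: identical patterns with different next
        # states cannot be resolved by specificity and stay hard conflicts
        containment <- xor(
          cube_contains(table$pattern[i, ], table$pattern[j, ]),
          cube_contains(table$pattern[j, ], table$pattern[i, ]))
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          state = code_to_bits(s), row_i = i, row_j = j,
          next_i = code_to_bits(rows$next_state[i]),
          next_j = code_to_bits(rows$next_state[j]),
          containment = containment)
      }
    }
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts)
               else data.frame(state = character(), row_i = integer(),
                               row_j = integer(), next_i = character(),
                               next_j = character(), containment = logical())

  defined <- table$catalog$state_codes
  residue <- vapply(defined, function(s) {
    idx <- which(rows$state == s)
    cubes <- lapply(idx, function(i) table$pattern[i, ])
    65536 - cubes_union_size(cubes)
  }, numeric(1))
  coverage <- data.frame(state = code_to_bits(defined),
                         name = state_name(defined, table$catalog),
                         uncovered = residue,
                         uncovered_fraction = residue / 65536)

  f_col <- match("F", table$catalog$inputs)
  sink <- vapply(defined, function(s) {
    idx <- which(rows$state == s & rows$next_state != s)
    !any(vapply(idx, function(i) {
      f <- table$pattern[i, f_col]
      is.na(f) || f == 0L
    }, logical(1)))
  }, logical(1))

  structure(list(conflicts = conflicts,
                 hard_conflicts = conflicts[!conflicts$containment, ,
                                            drop = FALSE],
                 coverage = coverage,
                 sinks = code_to_bits(defined[sink]),
                 n_rows = nrow(rows),
                 ok = !any(!conflicts$containment)),
            class = "pd_validation")
}

#' @export
print.pd_validation <- function(x, ...) {
  cat(sprintf("%d rows, %d hard conflict(s), %d containment overlap(s)\n",
              x$n_rows, nrow(x$hard_conflicts),
              sum(x$conflicts$containment)))
  if (nrow(x$hard_conflicts)) {
    cat("hard conflicts:\n")
    print(x$hard_conflicts, row.names = FALSE)
  }
  if (length(x$sinks))
    cat("sink state(s) (no fault-free exit):", paste(x$sinks, collapse = " "),
        "\n")
  mean_unc <- mean(x$coverage$uncovered_fraction)
  cat(sprintf("mean uncovered input fraction per state: %.3f\n", mean_unc))
  invisible(x)
}

#' Audit the printed per-row coverage counts
#'
#' Compares each row's printed `cases` value with the computed coverage
#' count 2^(number of don't-cares).
#'
#' @param table a `transition_table` whose rows carry printed case counts.
#' @return an object of class `pd_case_audit`: a list with `audit` (data
#'   frame of row, state, printed, computed, match) and `mismatches`.
#' @examples
#' audit_cases(pd_transition_table())  # 0 mismatches
#' @export
audit_cases <- function(table) {
  computed <- coverage_count(table)
  audit <- data.frame(row = seq_len(nrow(table$rows)),
                      state = code_to_bits(table$rows$state),
                      next_state = code_to_bits(table$rows$next_state),
                      printed = table$rows$cases,
                      computed = computed)
  audit$match <- !is.na(audit$printed) & audit$printed == audit$computed
  structure(list(audit = audit,
                 mismatches = audit[!audit$match, , drop = FALSE]),
            class = "pd_case_audit")
}

#' @export
print.pd_case_audit <- function(x, ...) {
  cat(sprintf("case audit: %d rows, %d mismatch(es)\n",
              nrow(x$audit), nrow(x$mismatches)))
  if (nrow(x$mismatches)) print(x$mismatches, row.names = FALSE)
  invisible(x)
}
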