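# Excitation-function synthesis. The next value of each D flip-flop (D_A,
# most significant, ... D_E) is a boolean function of the 21 variables A..E
# (current register bits) and T_S..T_F (the 16 input transitions). A
# sum-of-products expression for each flip-flop is read off the transition
# table: every row whose next-state bit is 1 contributes a product term of
# the five fully specified state literals plus one literal per specified
# input symbol. Completion-policy behaviour (hold or alarm on uncovered
# inputs) and the unused-code trap contribute their own terms so that the
# expression agrees with next_state() on the entire 2^21 universe, which is
# checked by exhaustive enumeration.

FLIPFLOPS <- c("D_A", "D_B", "D_C", "D_D", "D_E")

sop_vars <- function(catalog = signal_catalog()) {
  c("A", "B", "C", "D", "E", paste0("T_", catalog$inputs))
}

ff_bit_value <- function(flipflop) {
  i <- match(flipflop, FLIPFLOPS)
  if (is.na(i)) stop("unknown flip-flop identifier: ", flipflop,
                     " (expected one of ", paste(FLIPFLOPS, collapse = ", "),
                     ")")
  2L^(5L - i)
}

#' Construct a sum-of-products expression
#'
#' @param flipflop one of `"D_A"` .. `"D_E"`.
#' @param terms a list of product terms, each a named vector over the
#'   21-symbol vocabulary (`A`..`E`, `T_S`..`T_F`) with values 1 (plain
#'   literal) or 0 (negated); or a term matrix with one column per variable
#'   and `NA` for absent literals. An empty list is the constant-0
#'   expression; a term with no literals is the constant 1.
#' @return an object of class `sop_expression`.
#' @examples
#' e <- sop_expression("D_A", list(c(A = 1, B = 1), c(A = 1, B = 0)))
#' simplify_sop(e)  # merges to the single literal A
#' @export
sop_expression <- function(flipflop, terms) {
  vars <- sop_vars()
  if (is.matrix(terms)) {
    stopifnot(identical(colnames(terms), vars))
    m <- terms
  } else {
    m <- matrix(NA_integer_, nrow = length(terms), ncol = length(vars),
                dimnames = list(NULL, vars))
    for (k in seq_along(terms)) {
      t <- terms[[k]]
      if (length(t)) {
        bad <- setdiff(names(t), vars)
        if (length(bad)) stop("unknown literal variable(s): ",
                              paste(bad, collapse = ", "))
        if (!all(t %in% c(0, 1))) stop("literal polarity must be 0 or 1")
        m[k, names(t)] <- as.integer(t)
      }
    }
  }
  structure(list(flipflop = flipflop, terms = m), class = "sop_expression")
}

#' @export
print.sop_expression <- function(x, ...) {
  cat(format_sop(x), "\n")
  invisible(x)
}

#' Number of product terms in an expression
#' @param expr a [sop_expression()].
#' @return integer.
#' @export
n_terms <- function(expr) nrow(expr$terms)

# ---- on-set extraction and synthesis ---------------------------------------

#' Minterms on which a flip-flop's next value is 1
#'
#' Enumerates, over the requested current states, every 21-bit assignment
#' (5 state bits, 16 input bits) for which the indicated bit of
#' [next_state()] equals 1. Assignments are encoded as
#' `state * 65536 + input_index` with `S` the most significant input bit.
#'
#' @param table a `transition_table`.
#' @param flipflop one of `"D_A"` .. `"D_E"`.
#' @param states integer vector of current-state codes to restrict to
#'   (default: the full universe, all 32 codes).
#' @return sorted integer vector of minterm indices.
#' @examples
#' tbl <- pd_transition_table()
#' length(extract_on_set(tbl, "D_E", states = 0L))  # 12288
#' @export
extract_on_set <- function(table, flipflop, states = 0:31) {
  bitval <- ff_bit_value(flipflop)
  nsm <- next_state_matrix(table)
  out <- lapply(states, function(s) {
    hit <- which(bitwAnd(nsm[, s + 1L], bitval) > 0L)
    if (length(hit)) s * 65536L + (hit - 1L) else integer(0)
  })
  sort(unlist(out))
}

#' Synthesise a flip-flop's excitation function from the table
#'
#' One product term per table row whose next-state bit is 1: the five state
#' literals fully specified, plus an input literal per non-don't-care symbol.
#' Where a row is overlapped by a more specific row with a different next
#' state, its term is restricted to the unshadowed region, keeping the
#' expression consistent with the resolved next-state function. With
#' `include_completion = TRUE` (the default) the expression also carries
#' terms for the unused-code trap and for the completion-policy residue of
#' each defined state, so that it agrees with [next_state()] everywhere;
#' with `FALSE` only the table's own rows are synthesised (the
#' covered-rows-only variant), and equivalence should then be checked with
#' `covered_only = TRUE`.
#'
#' @inheritParams extract_on_set
#' @param include_completion include unused-trap and completion-policy terms.
#' @return a [sop_expression()].
#' @export
synthesize_sop <- function(table, flipflop, include_completion = TRUE) {
  bitval <- ff_bit_value(flipflop)
  vars <- sop_vars(table$catalog)
  bit_on <- function(code) bitwAnd(code, bitval) > 0L
  terms <- list()

  add_term <- function(state, cube) {
    t <- rep(NA_integer_, 21L)
    t[1:5] <- code_to_bitmat(state)[1L, ]
    t[6:21] <- cube
    terms[[length(terms) + 1L]] <<- t
  }

  row_states <- if (include_completion) {
    intersect(unique(table$rows$state), table$catalog$state_codes)
  } else unique(table$rows$state)

  for (s in row_states) {
    ord <- state_row_order(table, s)
    for (k in seq_along(ord)) {
      r <- ord[k]
      if (!bit_on(table$rows$next_state[r])) next
      shadows <- ord[seq_along(ord) > k]
      shadows <- shadows[table$rows$next_state[shadows] !=
                           table$rows$next_state[r]]
      regions <- cubes_subtract_all(table$pattern[r, ],
                                    lapply(shadows, function(i)
                                      table$pattern[i, ]))
      for (cube in regions) add_term(s, cube)
    }
  }

  if (include_completion) {
    for (s in table$catalog$state_codes) {
      target <- if (table$completion_policy == "hold") s else ALARM_CODE
      if (!bit_on(target)) next
      idx <- which(table$rows$state == s)
      residue <- cubes_complement(lapply(idx, function(i) table$pattern[i, ]))
      for (cube in residue) add_term(s, cube)
    }
    for (s in 17:30)                       # unused-code trap: next is 11111
      add_term(s, rep(NA_integer_, N_INPUTS))
  }

  m <- do.call(rbind, c(terms, list(matrix(NA_integer_, 0L, 21L))))
  colnames(m) <- vars
  sop_expression(flipflop, m)
}

# ---- evaluation ------------------------------------------------------------

#' Evaluate an expression over every input vector for one current state
#'
#' @param expr a [sop_expression()].
#' @param state integer current-state code.
#' @return logical vector of length 65536 in input-index order.
#' @export
eval_sop <- function(expr, state) {
  im <- input_matrix()
  out <- rep(FALSE, 65536L)
  if (!nrow(expr$terms)) return(out)
  sbits <- code_to_bitmat(state)[1L, ]
  for (k in seq_len(nrow(expr$terms))) {
    t <- expr$terms[k, ]
    sl <- t[1:5]
    if (any(sl != sbits, na.rm = TRUE)) next   # state literals exclude s
    mask <- rep(TRUE, 65536L)
    for (j in which(!is.na(t[6:21])))
      mask <- mask & (im[, j] == t[5L + j])
    out <- out | mask
  }
  out
}

# covered-region mask for one state: assignments matched by at least one row
covered_mask <- function(table, state) {
  im <- input_matrix()
  mask <- rep(FALSE, 65536L)
  for (i in which(table$rows$state == state)) {
    m <- rep(TRUE, 65536L)
    for (j in which(!is.na(table$pattern[i, ])))
      m <- m & (im[, j] == table$pattern[i, j])
    mask <- mask | m
  }
  mask
}

#' Exhaustive equivalence check of an expression against the table
#'
#' Evaluates the expression on all 2,097,152 assignments (32 register codes
#' times 65,536 input vectors) and compares it with the corresponding bit of
#' [next_state()]. With `covered_only = TRUE` the comparison is restricted
#' to assignments matched by at least one table row (for checking
#' covered-rows-only syntheses).
#'
#' @inheritParams extract_on_set
#' @param expr a [sop_expression()].
#' @param cap maximum number of counterexamples to report.
#' @param covered_only restrict the universe to row-covered assignments.
#' @return an object of class `equivalence_report`: list with `flipflop`,
#'   `pass`, `universe` (number of assignments compared), `n_mismatch`, and
#'   `counterexamples` (data frame of state code and the 16 input bits, at
#'   most `cap` rows).
#' @examples
#' tbl <- pd_transition_table()
#' rep <- check_equivalence(synthesize_sop(tbl, "D_B"), tbl, "D_B")
#' rep$pass; rep$universe  # TRUE, 2097152
#' @export
check_equivalence <- function(expr, table, flipflop = expr$flipflop,
                              cap = 100L, covered_only = FALSE) {
  bitval <- ff_bit_value(flipflop)
  nsm <- next_state_matrix(table)
  universe <- 0
  n_mismatch <- 0
  ces <- list()
  for (s in 0:31) {
    truth <- bitwAnd(nsm[, s + 1L], bitval) > 0L
    got <- eval_sop(expr, s)
    if (covered_only) {
      keep <- if (is_unused_code(s) &&
                  !any(table$rows$state == s)) rep(FALSE, 65536L)
              else covered_mask(table, s)
      universe <- universe + sum(keep)
      bad <- which(keep & (truth != got))
    } else {
      universe <- universe + 65536
      bad <- which(truth != got)
    }
    n_mismatch <- n_mismatch + length(bad)
    if (length(bad) && length(ces) < cap) {
      take <- bad[seq_len(min(length(bad), cap - length(ces)))]
      for (i in take)
        ces[[length(ces) + 1L]] <- c(state = s, input = i - 1L)
    }
  }
  cedf <- if (length(ces)) {
    m <- do.call(rbind, ces)
    df <- data.frame(state = code_to_bits(m[, "state"]))
    cbind(df, t(vapply(m[, "input"], index_to_inputs, integer(16))))
  } else data.frame(state = character())
  structure(list(flipflop = flipflop, pass = n_mismatch == 0,
                 universe = universe, n_mismatch = n_mismatch,
                 counterexamples = cedf),
            class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat(sprintf("%s: %s over %d assignments (%d mismatch(es))\n",
              x$flipflop, if (x$pass) "EQUIVALENT" else "NOT equivalent",
              x$universe, x$n_mismatch))
  if (!x$pass) {
    cat("first counterexamples:\n")
    print(utils::head(x$counterexamples, 5), row.names = FALSE)
  }
  invisible(x)
}

# ---- simplification --------------------------------------------------------

#' Simplify a sum-of-products expression
#'
#' Iterated single-variable adjacency merging (terms identical except for one
#' opposed literal collapse into one term without it) and absorption (a term
#' contained in another is dropped), to a fixed point. The result never has
#' more terms and, by construction, the identical on-set; with
#' `verify = TRUE` the on-set is re-checked bit-for-bit against the input
#' expression over all 2^21 assignments.
#'
#' @param expr a [sop_expression()].
#' @param verify exhaustively re-check on-set equality (default `TRUE`).
#' @return a [sop_expression()] with `n_terms()` no larger than the input's.
#' @export
simplify_sop <- function(expr, verify = TRUE) {
  m <- expr$terms
  repeat {
    changed <- FALSE
    # absorption
    drop <- rep(FALSE, nrow(m))
    if (nrow(m) > 1L) {
      for (i in seq_len(nrow(m))) {
        if (drop[i]) next
        for (j in seq_len(nrow(m))) {
          if (i == j || drop[j]) next
          if (cube_contains(m[j, ], m[i, ])) { drop[i] <- TRUE; break }
        }
      }
    }
    if (any(drop)) { m <- m[!drop, , drop = FALSE]; changed <- TRUE }
    # adjacency merge
    if (nrow(m) > 1L) {
      merged <- FALSE
      for (i in seq_len(nrow(m) - 1L)) {
        for (j in (i + 1L):nrow(m)) {
          a <- m[i, ]; b <- m[j, ]
          spec_eq <- (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
          diffpos <- which(!spec_eq)
          if (length(diffpos) == 1L && !is.na(a[diffpos]) &&
              !is.na(b[diffpos])) {
            a[diffpos] <- NA_integer_
            m[i, ] <- a
            m <- m[-j, , drop = FALSE]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (merged) { changed <- TRUE; next }
    }
    if (!changed) break
  }
  out <- sop_expression(expr$flipflop, m)
  if (verify) {
    for (s in 0:31) {
      if (!identical(eval_sop(out, s), eval_sop(expr, s)))
        stop("internal error: simplification changed the on-set at state ",
             code_to_bits(s))
    }
  }
  out
}

# ---- export formats --------------------------------------------------------

#' Format an expression as algebraic text
#'
#' Plain literals print as the variable, negated literals with a prime
#' (e.g. `D_A = A'·B·C·D·E·T_S·T_L·T_DV'·T_F' + ...`). The constant-0
#' expression prints as `0`, a term with no literals as `1`.
#'
#' @param expr a [sop_expression()].
#' @return a single character string.
#' @export
format_sop <- function(expr) {
  if (!nrow(expr$terms)) return(paste(expr$flipflop, "= 0"))
  vars <- colnames(expr$terms)
  terms <- apply(expr$terms, 1L, function(t) {
    spec <- which(!is.na(t))
    if (!length(spec)) return("1")
    paste0(vars[spec], ifelse(t[spec] == 1L, "", "'"), collapse = "·")
  })
  paste(expr$flipflop, "=", paste(terms, collapse = " + "))
}

#' Convert an expression to a JSON-ready structure
#'
#' @param expr a [sop_expression()].
#' @return a list with `flipflop`, `n_terms` and `terms` (each term a named
#'   variable-to-polarity map), suitable for [jsonlite::write_json()].
#' @export
sop_to_json <- function(expr) {
  vars <- colnames(expr$terms)
  terms <- lapply(seq_len(nrow(expr$terms)), function(k) {
    t <- expr$terms[k, ]
    spec <- which(!is.na(t))
    as.list(stats::setNames(as.integer(t[spec]), vars[spec]))
  })
  list(flipflop = expr$flipflop, n_terms = nrow(expr$terms), terms = terms)
}

#' Write an expression to text and JSON files
#'
#' @param expr a [sop_expression()].
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths written.
#' @export
write_sop <- function(expr, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  txt <- file.path(dir, paste0(expr$flipflop, ".txt"))
  js <- file.path(dir, paste0(expr$flipflop, ".json"))
  writeLines(format_sop(expr), txt)
  jsonlite::write_json(sop_to_json(expr), js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(txt, js))
}
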