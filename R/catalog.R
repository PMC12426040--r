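# Canonical input ordering (Table-2 row order); used everywhere: files,
# input vectors, pattern columns, session logs.
PD_INPUTS <- c("S", "DM", "FM", "AI", "P", "T", "SD",
               "F1", "F2", "F3", "F4", "L", "PR", "TU", "DV", "F")

PD_OUTPUTS <- c("SB", "W.INS", "A.INS", "HN", "HF", "FS", "FE", "DWM", "DS",
                "V4F", "DE", "LS", "V31F", "FSH", "V456F", "V31N", "V1F", "A")

# State register values 0..16 carry the 17 sequential stage codes; 31 is the
# alarm; 17..30 are unused codes that trap to the alarm.
PD_STATE_CODES <- c(0:16, 31L)

ALARM_CODE <- 31L
N_INPUTS <- 16L
N_STATE_BITS <- 5L

#' Convert between state-code integers and 5-bit register strings
#'
#' The state register holds five D flip-flops A..E with A most significant;
#' codes print as 5-character binary strings (standby `"00000"`, alarm
#' `"11111"`).
#'
#' @param code integer vector of register values in `[0, 31]`.
#' @param bits character vector of 5-character binary strings.
#' @return `code_to_bits()` returns 5-character strings; `bits_to_code()`
#'   returns integers; `code_to_bitmat()` returns a 0/1 integer matrix with
#'   columns `A`..`E`.
#' @examples
#' code_to_bits(c(0L, 13L, 31L))
#' bits_to_code("01101")
#' @export
code_to_bits <- function(code) {
  stopifnot(all(code >= 0L & code <= 31L))
  vapply(code, function(v)
    paste(as.integer(bitwAnd(bitwShiftR(v, 4:0), 1L)), collapse = ""),
    character(1))
}

#' @rdname code_to_bits
#' @export
bits_to_code <- function(bits) {
  bad <- !grepl("^[01]{5}$", bits)
  if (any(bad))
    stop("not a 5-bit binary state code: ", paste(bits[bad], collapse = ", "))
  vapply(strsplit(bits, ""), function(b)
    sum(as.integer(b) * c(16L, 8L, 4L, 2L, 1L)), numeric(1)) |> as.integer()
}

#' @rdname code_to_bits
#' @export
code_to_bitmat <- function(code) {
  m <- t(vapply(code, function(v)
    as.integer(bitwAnd(bitwShiftR(v, 4:0), 1L)), integer(5)))
  colnames(m) <- c("A", "B", "C", "D", "E")
  m
}

#' Is a register value one of the unused codes?
#'
#' Codes 17 to 30 are not assigned to any stage; the controller traps them
#' straight to the alarm state.
#'
#' @param code integer vector of register values.
#' @return logical vector.
#' @export
is_unused_code <- function(code) code >= 17L & code <= 30L

#' Human-readable name of a state code
#'
#' @param code integer vector of register values in `[0, 31]`.
#' @param catalog a [signal_catalog()]; defaults to the built-in one.
#' @return character vector: the output name (`"SB"`, `"FSH"`, ...) for
#'   defined codes, `"UNUSED"` for codes 17-30.
#' @export
state_name <- function(code, catalog = signal_catalog()) {
  idx <- match(code, catalog$state_codes)
  out <- catalog$outputs[idx]
  out[is.na(idx)] <- "UNUSED"
  out
}

#' The controller's I/O signal catalog
#'
#' Sixteen boolean inputs (buttons and thresholded sensors) and eighteen
#' outputs, each output bound to a state label `S_0`..`S_17` and a 5-bit
#' register code. Codes `S_0`..`S_16` are `00000`..`10000` in binary order;
#' the alarm `S_17` is `11111`.
#'
#' @param path optional path to a catalog file (tab- or comma-separated with
#'   columns `input`, `transition`, `output`, `state_label`, `state_code`);
#'   defaults to the catalog shipped with the package.
#' @return an object of class `signal_catalog`: a list with `inputs` (16
#'   names), `transitions` (the `T_*` symbols), `outputs` (18 names),
#'   `state_labels` and `state_codes` (integer).
#' @examples
#' cat <- signal_catalog()
#' length(cat$inputs)   # 16
#' length(cat$outputs)  # 18
#' @export
signal_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "signal_catalog.tsv", package = "pdfsm",
                        mustWork = TRUE)
  df <- utils::read.delim(path, sep = guess_sep(path), header = TRUE,
                          colClasses = "character", strip.white = TRUE)
  need <- c("input", "transition", "output", "state_label", "state_code")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("signal catalog is missing columns: ",
         paste(missing_cols, collapse = ", "))
  inputs <- df$input[nzchar(df$input)]
  transitions <- df$transition[nzchar(df$transition)]
  outputs <- df$output[nzchar(df$output)]
  codes <- bits_to_code(df$state_code[nzchar(df$output)])
  validate_catalog(inputs, outputs, codes)
  structure(list(inputs = inputs, transitions = transitions,
                 outputs = outputs,
                 state_labels = df$state_label[nzchar(df$output)],
                 state_codes = codes),
            class = "signal_catalog")
}

validate_catalog <- function(inputs, outputs, codes) {
  if (length(inputs) != 16L)
    stop("catalog must define exactly 16 inputs, found ", length(inputs))
  if (length(outputs) != 18L)
    stop("catalog must define exactly 18 outputs, found ", length(outputs))
  if (anyDuplicated(inputs)) stop("duplicate input names in catalog")
  if (anyDuplicated(outputs)) stop("duplicate output names in catalog")
  if (anyDuplicated(codes)) stop("duplicate state codes in catalog")
  if (!identical(codes[1:17], 0:16) || codes[18] != 31L)
    stop("state codes must be 00000..10000 in order, with the alarm 11111")
  invisible(TRUE)
}

#' @export
print.signal_catalog <- function(x, ...) {
  cat("Signal catalog: 16 inputs, 18 outputs\n")
  cat("  inputs: ", paste(x$inputs, collapse = " "), "\n")
  cat("  states: ",
      paste(sprintf("%s=%s", x$outputs, code_to_bits(x$state_codes)),
            collapse = " "), "\n")
  invisible(x)
}

guess_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Construct an input vector
#'
#' One joint boolean reading of the 16 controller inputs, in catalog order
#' (`S` first, `F` last). Unnamed arguments default to 0.
#'
#' @param ... named 0/1 values, e.g. `input_vector(S = 1, DM = 1)`.
#' @return named integer vector of length 16 with values in `{0, 1}`.
#' @examples
#' input_vector(S = 1, DM = 1, FM = 0)
#' @export
input_vector <- function(...) {
  args <- list(...)
  v <- stats::setNames(integer(N_INPUTS), PD_INPUTS)
  if (length(args)) {
    bad <- setdiff(names(args), PD_INPUTS)
    if (length(bad) || is.null(names(args)) || any(!nzchar(names(args))))
      stop("unknown input name(s): ", paste(bad, collapse = ", "))
    vals <- unlist(args)
    if (!all(vals %in% c(0, 1))) stop("input values must be 0 or 1")
    v[names(args)] <- as.integer(vals)
  }
  v
}

# integer in [0, 65535] -> 16-bit 0/1 vector, S = most significant bit
index_to_inputs <- function(i) {
  stats::setNames(as.integer(bitwAnd(bitwShiftR(i, 15:0), 1L)), PD_INPUTS)
}

inputs_to_index <- function(v) {
  sum(as.integer(v) * 2^(15:0))
}

# 65536 x 16 integer matrix of every input assignment, cached per session.
input_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- matrix(0L, nrow = 65536L, ncol = N_INPUTS,
                  dimnames = list(NULL, PD_INPUTS))
      idx <- 0:65535
      for (j in seq_len(N_INPUTS))
        m[, j] <- bitwAnd(bitwShiftR(idx, 16L - j), 1L)
      cache <<- m
    }
    cache
  }
})
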