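# Builders for synthetic transition tables and fast simulation configs.

# one table row as a data frame; unspecified inputs are don't-cares
tt_row <- function(state, nxt, ..., cases = NA, comment = "") {
  pat <- list(...)
  df <- data.frame(state = state, cases = cases, comment = comment,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df[["next"]] <- nxt
  for (nm in names(pat)) df[[nm]] <- as.character(pat[[nm]])
  df
}

tt_build <- function(..., policy = "hold") {
  rows <- list(...)
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_cols, names(r))) r[[nm]] <- "X"
    r
  })
  transition_table(do.call(rbind, rows), completion_policy = policy)
}

# small-duration config so simulator tests run in milliseconds
fast_config <- function(...) {
  args <- utils::modifyList(list(dwell_duration = 10, delay_duration = 2,
                                 fill_volume = 100, flush_min_duration = 0.2,
                                 max_ticks = 5000),
                            list(...))
  do.call(sim_config, args)
}

# brute-force evaluator for cube tests: all assignments of width w
enumerate_cube <- function(cube, w = length(cube)) {
  n <- 2^w
  hits <- logical(n)
  for (i in 0:(n - 1)) {
    bits <- as.integer(bitwAnd(bitwShiftR(i, (w - 1):0), 1L))
    hits[i + 1] <- !any(cube != bits, na.rm = TRUE)
  }
  which(hits) - 1L
}

random_cube <- function(w, p_spec = 0.5) {
  v <- rep(NA_integer_, w)
  spec <- stats::runif(w) < p_spec
  v[spec] <- sample(0:1, sum(spec), replace = TRUE)
  v
}
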