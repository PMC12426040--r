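# Ternary cube algebra over fixed-width boolean spaces.
#
# A cube is an integer vector with entries 0, 1 or NA; NA is the don't-care
# symbol and the cube denotes the set of full assignments agreeing with its
# specified positions. These primitives back pattern-overlap detection in
# table validation, residue computation for completion-policy synthesis, and
# the disjoint covers used by the SOP generator.

# Do two cubes share at least one assignment?
cube_compatible <- function(a, b) {
  !any(a != b, na.rm = TRUE)
}

# Does `outer` contain every assignment of `inner`?
cube_contains <- function(outer, inner) {
  spec <- !is.na(outer)
  all(!is.na(inner[spec]) & inner[spec] == outer[spec])
}

cube_size <- function(cube) 2^sum(is.na(cube))

# Set difference c \ p as a list of pairwise-disjoint cubes.
cube_subtract <- function(c, p) {
  if (!cube_compatible(c, p)) return(list(c))
  pieces <- list()
  cur <- c
  for (i in which(!is.na(p))) {
    if (!is.na(cur[i])) next     # already agrees (incompatible case excluded)
    piece <- cur
    piece[i] <- 1L - p[i]
    pieces[[length(pieces) + 1L]] <- piece
    cur[i] <- p[i]
  }
  pieces
}

# Subtract every cube in `ps` from `c`; result cubes are pairwise disjoint.
cubes_subtract_all <- function(c, ps) {
  result <- list(c)
  for (p in ps) {
    result <- unlist(lapply(result, cube_subtract, p = p), recursive = FALSE)
    if (!length(result)) return(list())
  }
  result
}

# Complement of a union of cubes within the full width-w space, as a list of
# pairwise-disjoint cubes. Used for the uncovered residue of each state.
cubes_complement <- function(cubes, width = N_INPUTS) {
  cubes_subtract_all(rep(NA_integer_, width), cubes)
}

# Number of assignments in the union of (possibly overlapping) cubes.
cubes_union_size <- function(cubes, width = N_INPUTS) {
  if (!length(cubes)) return(0)
  residue <- cubes_complement(cubes, width)
  2^width - sum(vapply(residue, cube_size, numeric(1)))
}
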