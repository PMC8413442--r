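# Small fixture builders shared across test files.

mk_grid <- function(values, mask = NULL, cell_size = 500,
                    origin = c(0, 0), levels = NULL) {
  grid_create(as.matrix(values), mask, cell_size, origin, "", levels)
}

const_grid <- function(value, nr = 3, nc = 3, ...) {
  mk_grid(matrix(value, nr, nc), ...)
}

# score grids with given per-cell constants, aligned
const_scores <- function(values, nr = 2, nc = 2) {
  lapply(values, const_grid, nr = nr, nc = nc)
}

small_scene <- function(seed = 7, shape = c(40, 40), ...) {
  generate_base_scene(scene_spec(shape = shape, seed = seed, ...))
}

# brute-force optimal within-class SSD over all ordered partitions of the
# sorted values into k non-empty contiguous groups (independent oracle)
brute_force_ssd <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssd_of <- function(groups) {
    sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  }
  if (k == 1) return(ssd_of(list(x)))
  best <- Inf
  for (cuts in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    grp <- split(x, findInterval(seq_len(n), cuts + 0.5))
    best <- min(best, ssd_of(grp))
  }
  best
}
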