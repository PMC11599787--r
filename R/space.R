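#' Construct the discrete parent-stranger stimulus space
#'
#' The stimulus space is a one-dimensional, ordered morph continuum between a
#' familiar (parent) face at index 1 and an unfamiliar (stranger) face at the
#' last index. Coordinates start at 0 and are uniformly spaced; the morph
#' fraction at point i is (i-1)/(n_points-1), so the first point is 100%
#' parent and the last 100% stranger. The default 12-point, 0.2-unit space
#' spans coordinates 0 to 2.2.
#'
#' Indices in the user API are 0-based (0 = pure parent, n_points-1 = pure
#' stranger) to match how morph steps are usually labelled.
#'
#' @param n_points number of morph steps (>= 3); default 12.
#' @param spacing coordinate distance between adjacent points (> 0); default 0.2.
#' @return an object of class `stimulus_space` with elements `n_points`,
#'   `spacing`, `coordinates` (length `n_points`, starting at 0) and
#'   `morph_fractions` (fraction of stranger in `[0, 1]`).
#' @examples
#' sp <- make_stimulus_space()
#' sp$coordinates            # 0.0, 0.2, ..., 2.2
#' optimum_parent_distance(sp, 11)
#' @export
make_stimulus_space <- function(n_points = 12L, spacing = 0.2) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 3 ||
      n_points != round(n_points)) {
    stop("`n_points` must be a single integer >= 3", call. = FALSE)
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("`spacing` must be a single positive number", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  structure(
    list(
      n_points = n_points,
      spacing = spacing,
      coordinates = spacing * (seq_len(n_points) - 1),
      morph_fractions = (seq_len(n_points) - 1) / (n_points - 1)
    ),
    class = "stimulus_space"
  )
}

#' @export
print.stimulus_space <- function(x, ...) {
  cat(sprintf("Stimulus space: %d points, spacing %g (coordinates 0 to %g)\n",
              x$n_points, x$spacing, x$coordinates[x$n_points]))
  cat(sprintf("  index 0 = 100%% parent, index %d = 100%% stranger\n",
              x$n_points - 1L))
  invisible(x)
}

check_index <- function(space, index) {
  if (!is.numeric(index) || length(index) != 1L || index != round(index) ||
      index < 0 || index >= space$n_points) {
    stop(sprintf("stimulus index must be an integer in [0, %d]",
                 space$n_points - 1L), call. = FALSE)
  }
  as.integer(index)
}

#' Euclidean distance between a stimulus and the pure-parent face
#'
#' Distance in stimulus-space coordinate units between the point at `index`
#' and the parent extreme (index 0). On the default space this ranges from 0
#' (optimum is the parent's own face) to 2.2 (optimum is the pure stranger).
#'
#' @param space a `stimulus_space`.
#' @param index 0-based stimulus index.
#' @return non-negative distance in coordinate units.
#' @export
optimum_parent_distance <- function(space, index) {
  stopifnot(inherits(space, "stimulus_space"))
  index <- check_index(space, index)
  space$coordinates[index + 1L] - space$coordinates[1L]
}

#' Coordinate of a stimulus index
#' @param space a `stimulus_space`.
#' @param index 0-based stimulus index.
#' @return real coordinate.
#' @export
stimulus_coordinate <- function(space, index) {
  stopifnot(inherits(space, "stimulus_space"))
  index <- check_index(space, index)
  space$coordinates[index + 1L]
}

#' Nearest stimulus index to a coordinate
#' @param space a `stimulus_space`.
#' @param coord real coordinate (clipped to the space range).
#' @return 0-based index of the nearest grid point.
#' @export
nearest_index <- function(space, coord) {
  stopifnot(inherits(space, "stimulus_space"), is.numeric(coord))
  i <- round(coord / space$spacing)
  as.integer(pmin(pmax(i, 0L), space$n_points - 1L))
}

#' Which half of the space an index falls in
#'
#' The 12-point space splits evenly: indices 0 to n/2-1 are the "parent" half,
#' the rest the "stranger" half.
#'
#' @param space a `stimulus_space`.
#' @param index 0-based stimulus index.
#' @return `"parent"` or `"stranger"`.
#' @export
space_side <- function(space, index) {
  stopifnot(inherits(space, "stimulus_space"))
  index <- check_index(space, index)
  if (index < space$n_points / 2) "parent" else "stranger"
}
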