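# small shared helpers

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Minimal-image displacement in a periodic arena
#'
#' Maps a coordinate difference onto the nearest periodic image, so the
#' distance between two points is the minimum over all periodic copies.
#'
#' @param d Coordinate difference(s).
#' @param width Arena period.
#' @return Displacement(s) in `[-width/2, width/2]`.
#' @export
min_image <- function(d, width = 4) {
  d - width * round(d / width)
}

wrap_interval <- function(x, lo, hi) {
  out <- x
  need <- x < lo | x >= hi     # leave in-range values bit-identical
  out[need] <- ((x[need] - lo) %% (hi - lo)) + lo
  out
}
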