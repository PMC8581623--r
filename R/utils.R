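# Internal helpers shared across modules.

#' Minimum-image displacement in a periodic xy box
#'
#' @param d numeric vector or matrix of raw coordinate differences (nm).
#' @param box periodic box lengths, recycled across columns of `d`.
#' @return displacement(s) wrapped into (-box/2, box/2].
#' @keywords internal
#' @noRd
min_image <- function(d, box) {
  # an infinite box length means "not periodic in that direction"
  if (any(!is.finite(box))) box[!is.finite(box)] <- .Machine$double.xmax
  d - box * round(d / box)
}

# Pairwise minimum-image distances between two sets of 2D points.
# a: n x 2, b: m x 2, box: length-2. Returns n x m matrix.
pdist_periodic <- function(a, b, box) {
  dx <- min_image(outer(a[, 1], b[, 1], "-"), box[1])
  dy <- min_image(outer(a[, 2], b[, 2], "-"), box[2])
  sqrt(dx * dx + dy * dy)
}

# 2D rotation matrix (counter-clockwise by `theta` radians).
rot2 <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, -st, ct), 2L, 2L)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Interval matrices are n x 2 (start, end), end > start, sorted, disjoint.
check_intervals <- function(x, name = "intervals") {
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(0), 0L, 2L))
  x <- as.matrix(x)
  if (ncol(x) != 2L)
    stop(sprintf("'%s' must have two columns (start, end)", name), call. = FALSE)
  if (nrow(x) > 1L && is.unsorted(x[, 1L]))
    stop(sprintf("'%s' must be sorted by start time", name), call. = FALSE)
  if (any(x[, 2L] < x[, 1L]))
    stop(sprintf("'%s' has an interval ending before it starts", name), call. = FALSE)
  unname(x)
}
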