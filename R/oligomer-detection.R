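#' Minimum inter-protein distance series for one pair
#'
#' Per-frame minimum over all inter-protein bead pairs, using the
#' minimum-image convention in the periodic xy plane. This is the raw signal
#' from which association/dissociation events are counted once smoothed.
#'
#' @param traj a [cg_trajectory()].
#' @param pair length-2 integer vector of copy indices.
#' @param beads optional bead subset (indices into the body's beads) to use
#'   for both copies; default all beads.
#' @return object of class `distance_series`: list(times, distance, pair).
#' @export
min_distance_series <- function(traj, pair, beads = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"), length(pair) == 2L)
  off <- traj$body$bead_offsets
  if (is.null(beads)) beads <- seq_len(nrow(off))
  beads <- as.integer(beads)
  if (length(beads) == 0L) stop("empty bead selection", call. = FALSE)
  off <- off[beads, , drop = FALSE]
  box <- traj$box
  i <- pair[1L]; j <- pair[2L]

  bead_xy <- function(k) {
    a <- traj$angles[, k]
    ca <- cos(a); sa <- sin(a)
    list(x = traj$centers[, k, 1L] + outer(ca, off[, 1L]) - outer(sa, off[, 2L]),
         y = traj$centers[, k, 2L] + outer(sa, off[, 1L]) + outer(ca, off[, 2L]))
  }
  bi <- bead_xy(i); bj <- bead_xy(j)
  nb <- length(beads)
  dmin <- rep(Inf, n_frames(traj))
  for (a in seq_len(nb)) {
    dx <- min_image(bi$x[, a] - bj$x, box[1L])
    dy <- min_image(bi$y[, a] - bj$y, box[2L])
    d2 <- dx * dx + dy * dy
    dmin <- pmin(dmin, if (nb > 1L) do.call(pmin, asplit(d2, 2L)) else d2[, 1L])
  }
  structure(list(times = traj$times, distance = sqrt(dmin),
                 pair = as.integer(pair), smoothing_window = 1L),
            class = "distance_series")
}

#' Centered moving-average smoothing of a distance series
#'
#' Window must be odd; edges use symmetric windows shrunk to fit, so the
#' output has the same length as the input and `window = 1` is the identity.
#'
#' @param series a `distance_series` (or numeric vector).
#' @param window odd window width in frames.
#' @return the smoothed series, same class as the input.
#' @export
smooth_series <- function(series, window = 31L) {
  x <- if (inherits(series, "distance_series")) series$distance else series
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("'window' must be an odd positive integer", call. = FALSE)
  if (window > length(x))
    stop("'window' exceeds the series length", call. = FALSE)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (inherits(series, "distance_series")) {
    series$distance <- sm
    series$smoothing_window <- window
    series
  } else sm
}

#' Kernel density of pooled minimum-distance samples
#'
#' Estimates the density of pairwise minimum distances and locates its local
#' maxima (peaks) and minima (troughs). The first trough beyond the contact
#' peak is the data-driven justification for (or override of) the
#' association cutoff.
#'
#' @param x numeric vector of distances (>= 100 samples) or a list of
#'   `distance_series` whose distances are pooled.
#' @param bw bandwidth passed to [stats::density()].
#' @return object of class `distance_density`: the density estimate plus
#'   `peaks` and `troughs` (distance locations, increasing).
#' @export
distance_density <- function(x, bw = "nrd0") {
  if (is.list(x) && !is.numeric(x))
    x <- unlist(lapply(x, function(s)
      if (inherits(s, "distance_series")) s$distance else s))
  x <- as.numeric(x)
  if (length(x) < 100L)
    stop("need at least 100 distance samples", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("degenerate (constant) distance input; density is a spike")
    return(structure(list(density = NULL, peaks = x[1L], troughs = numeric(0),
                          degenerate = TRUE), class = "distance_density"))
  }
  if (is.numeric(bw) && bw <= sqrt(.Machine$double.eps))
    warning("near-zero bandwidth gives a degenerate density estimate")
  den <- stats::density(x, bw = bw)
  dy <- diff(den$y)
  s <- sign(dy)
  turn <- which(s[-1L] != s[-length(s)] & s[-length(s)] != 0) + 1L
  peaks <- den$x[turn[s[turn - 1L] > 0]]
  troughs <- den$x[turn[s[turn - 1L] < 0]]
  structure(list(density = den, peaks = peaks, troughs = troughs,
                 degenerate = FALSE), class = "distance_density")
}

# union-find over a thresholded adjacency matrix
components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  cl <- seq_len(n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (adj[i, j]) {
      ci <- cl[i]; cj <- cl[j]
      if (ci != cj) cl[cl == cj] <- ci
    }
  }
  match(cl, unique(cl))
}

#' Assign copies of one frame to oligomers
#'
#' Single-linkage grouping at a fixed distance threshold: two copies are
#' linked when their minimum bead-bead distance is at most `cutoff`, and
#' oligomers are the connected components of the resulting contact graph.
#'
#' @param coords list of bead coordinate matrices (n_beads x 2), one per
#'   copy, e.g. from [frame_coords()].
#' @param box periodic box (nm) for minimum-image distances, or `NULL` for a
#'   non-periodic frame.
#' @param cutoff association cutoff (nm); 0.75 nm discriminates effective
#'   contacts for coarse-grained receptor beads.
#' @return object of class `oligomer_partition`: a list of sorted integer
#'   vectors (the oligomers), with attribute `membership` (integer group id
#'   per copy, numbered by first appearance).
#' @export
assign_oligomers <- function(coords, box = NULL, cutoff = 0.75) {
  n <- length(coords)
  if (n == 0L) stop("no coordinates supplied", call. = FALSE)
  if (is.null(box)) box <- c(Inf, Inf)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- pdist_periodic(coords[[i]], coords[[j]], box)
    adj[i, j] <- adj[j, i] <- min(d) <= cutoff
  }
  membership <- components_from_adjacency(adj)
  groups <- unname(split(seq_len(n), membership))
  groups <- groups[order(vapply(groups, min, integer(1L)))]
  membership <- integer(n)
  for (g in seq_along(groups)) membership[groups[[g]]] <- g
  structure(groups, membership = membership, class = "oligomer_partition")
}

#' Per-frame oligomer partitions of a whole trajectory
#'
#' @param traj a [cg_trajectory()].
#' @param cutoff association cutoff (nm).
#' @param frames frame indices (default all).
#' @return integer matrix (frames x copies) of oligomer ids per frame,
#'   numbered by first appearance within each frame.
#' @export
partition_trajectory <- function(traj, cutoff = 0.75,
                                 frames = seq_len(n_frames(traj))) {
  out <- matrix(NA_integer_, length(frames), n_copies(traj))
  for (k in seq_along(frames)) {
    p <- assign_oligomers(frame_coords(traj, frames[k]), traj$box, cutoff)
    out[k, ] <- attr(p, "membership")
  }
  out
}

#' Merge intervals separated by short gaps
#'
#' Contact intervals whose gap to the next interval is shorter than
#' `gap_tolerance` are treated as one continuous appearance, absorbing the
#' fast flicker in coarse-grained contact distances that does not represent
#' a real dissociation.
#'
#' @param intervals n x 2 matrix of (start, end) times (ns), sorted and
#'   non-overlapping.
#' @param gap_tolerance gaps strictly shorter than this (ns) are bridged;
#'   the conventional value is 100 ns; 0 disables merging.
#' @return merged interval matrix.
#' @export
fill_flickers <- function(intervals, gap_tolerance = 100) {
  iv <- check_intervals(intervals)
  if (nrow(iv) <= 1L || gap_tolerance <= 0) return(iv)
  out <- iv[1L, , drop = FALSE]
  for (r in 2:nrow(iv)) {
    gap <- iv[r, 1L] - out[nrow(out), 2L]
    if (gap < gap_tolerance) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[r, 2L])
    } else {
      out <- rbind(out, iv[r, , drop = FALSE])
    }
  }
  out
}

#' Count association and dissociation events of a pair
#'
#' An association is a downward crossing of the smoothed minimum distance
#' through `cutoff`; a dissociation is the upward crossing. Crossing types
#' alternate by construction.
#'
#' @param series a smoothed `distance_series` (or numeric vector).
#' @param cutoff association cutoff (nm).
#' @param times frame times if `series` is a bare vector.
#' @return list: `n_assoc`, `n_dissoc`, and `events` (data.frame with
#'   columns time, type).
#' @export
count_events <- function(series, cutoff = 0.75, times = NULL) {
  if (inherits(series, "distance_series")) {
    x <- series$distance; times <- series$times
  } else {
    x <- as.numeric(series)
    if (is.null(times)) times <- seq_along(x)
  }
  bound <- x < cutoff
  chg <- which(bound[-1L] != bound[-length(bound)]) + 1L
  type <- ifelse(bound[chg], "assoc", "dissoc")
  ev <- data.frame(time = times[chg], type = type, stringsAsFactors = FALSE)
  list(n_assoc = sum(type == "assoc"), n_dissoc = sum(type == "dissoc"),
       events = ev)
}

#' Bound intervals of a pair from its smoothed distance series
#'
#' Contiguous stretches with distance below the cutoff, as (start, end)
#' times; an interval's end is the time of the first frame after the
#' contact (or the trajectory end when still bound).
#'
#' @inheritParams count_events
#' @return n x 2 matrix of (start, end) times.
#' @export
bound_intervals <- function(series, cutoff = 0.75, times = NULL) {
  if (inherits(series, "distance_series")) {
    x <- series$distance; times <- series$times
  } else {
    x <- as.numeric(series)
    if (is.null(times)) times <- seq_along(x)
  }
  bound <- x < cutoff
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(matrix(numeric(0), 0L, 2L))
  dt <- if (length(times) > 1L) times[2L] - times[1L] else 1
  cbind(times[starts[keep]], times[ends[keep]] + dt)
}

#' Oligomer-order distribution over the final trajectory window
#'
#' Counts oligomers of each order per frame over the last `window` fraction
#' of the trajectory (where the systems are closest to equilibrium) and
#' reports the ensemble mean and standard deviation along the time course.
#'
#' @param membership integer matrix of per-frame oligomer ids, e.g. from
#'   [partition_trajectory()] or the simulator's ground truth.
#' @param window final fraction of frames to use, in (0, 1].
#' @return list: `counts` (frames x orders matrix), `mean` and `sd` (per
#'   order), `orders`.
#' @export
oligomer_distribution <- function(membership, window = 1) {
  if (!is.matrix(membership) || nrow(membership) == 0L)
    stop("'membership' must be a non-empty matrix", call. = FALSE)
  if (window <= 0 || window > 1)
    stop("'window' must be in (0, 1]", call. = FALSE)
  nf <- nrow(membership); n <- ncol(membership)
  first <- nf - max(1L, floor(window * nf)) + 1L
  rows <- first:nf
  counts <- matrix(0L, length(rows), n,
                   dimnames = list(NULL, paste0("order", seq_len(n))))
  for (k in seq_along(rows)) {
    sizes <- tabulate(membership[rows[k], ])
    sizes <- sizes[sizes > 0L]
    tab <- tabulate(sizes, n)
    counts[k, ] <- tab
  }
  list(counts = counts,
       mean = colMeans(counts),
       sd = apply(counts, 2L, stats::sd),
       orders = seq_len(n))
}
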