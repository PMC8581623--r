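#' Rigid pseudo-receptor body
#'
#' Defines the in-plane bead geometry of one receptor copy: a set of 2D bead
#' offsets in the body frame plus the index of the orientation bead whose
#' direction from the centre of geometry defines the body reference axis
#' (the stand-in for the membrane-parallel helix-8 axis used to measure
#' dimer binding angles).
#'
#' The default body is a 12-bead ring of radius 1.5 nm around a central bead,
#' a coarse disc comparable in footprint to a coarse-grained class A GPCR
#' transmembrane bundle. The ring is dense enough that the minimum bead-bead
#' distance between two bodies varies by less than 0.11 nm with orientation,
#' which keeps contact detection at a fixed distance cutoff unambiguous.
#'
#' @param bead_offsets numeric matrix (n_beads x 2) of in-plane offsets (nm)
#'   in the body frame. At least 3 beads.
#' @param orientation_bead index of the bead defining the reference axis;
#'   its offset must be non-zero.
#' @return an object of class `pseudo_receptor`.
#' @export
pseudo_receptor <- function(bead_offsets = default_body_offsets(),
                            orientation_bead = 1L) {
  bead_offsets <- as.matrix(bead_offsets)
  if (nrow(bead_offsets) < 3L)
    stop("a pseudo-receptor needs at least 3 beads", call. = FALSE)
  if (ncol(bead_offsets) != 2L)
    stop("'bead_offsets' must be an n x 2 matrix of in-plane offsets", call. = FALSE)
  orientation_bead <- as.integer(orientation_bead)
  if (orientation_bead < 1L || orientation_bead > nrow(bead_offsets))
    stop("'orientation_bead' out of range", call. = FALSE)
  if (sum(bead_offsets[orientation_bead, ]^2) == 0)
    stop("the orientation bead must have a non-zero offset", call. = FALSE)
  structure(list(bead_offsets = unname(bead_offsets),
                 orientation_bead = orientation_bead),
            class = "pseudo_receptor")
}

#' Default bead layout of the pseudo-receptor body
#'
#' A ring of `n_ring` beads of the given radius around one central bead.
#'
#' @param radius ring radius (nm).
#' @param n_ring number of ring beads.
#' @return an (n_ring + 1) x 2 offset matrix for [pseudo_receptor()].
#' @export
default_body_offsets <- function(radius = 1.5, n_ring = 12L) {
  ang <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring
  rbind(cbind(radius * cos(ang), radius * sin(ang)), c(0, 0))
}

#' @export
print.pseudo_receptor <- function(x, ...) {
  cat("Rigid pseudo-receptor body:", nrow(x$bead_offsets), "beads,",
      "orientation bead", x$orientation_bead, "\n")
  invisible(x)
}

#' Multi-copy in-plane trajectory container
#'
#' The internal array format for multi-copy membrane trajectories: per-frame
#' centres of geometry and body orientations of `n_copies` rigid copies of a
#' shared [pseudo_receptor()] body in a periodic xy box. Bead coordinates are
#' reconstructed on demand with [frame_coords()].
#'
#' @param centers numeric array (n_frames x n_copies x 2) of centres (nm).
#' @param angles numeric matrix (n_frames x n_copies) of body orientations
#'   (radians, counter-clockwise).
#' @param body a [pseudo_receptor()].
#' @param box length-2 periodic box (nm).
#' @param times frame times (ns), strictly increasing.
#' @return an object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(centers, angles, body, box, times) {
  stopifnot(length(dim(centers)) == 3L, dim(centers)[3L] == 2L,
            inherits(body, "pseudo_receptor"), length(box) == 2L,
            all(box > 0), length(times) == dim(centers)[1L])
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  structure(list(centers = centers, angles = as.matrix(angles), body = body,
                 box = as.numeric(box), times = as.numeric(times)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("Multi-copy trajectory: %d copies x %d frames, box %.1f x %.1f nm, %.0f-%.0f ns\n",
              n_copies(x), n_frames(x), x$box[1], x$box[2],
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$centers)[1L]
n_copies <- function(traj) dim(traj$centers)[2L]

#' Bead coordinates of every copy in one frame
#'
#' @param traj a [cg_trajectory()].
#' @param frame frame index.
#' @param copies which copies to return (default all).
#' @return list of bead coordinate matrices (n_beads x 2, nm), one per copy.
#' @export
frame_coords <- function(traj, frame, copies = seq_len(n_copies(traj))) {
  off <- traj$body$bead_offsets
  lapply(copies, function(i) {
    R <- rot2(traj$angles[frame, i])
    sweep(off %*% t(R), 2L, traj$centers[frame, i, ], "+")
  })
}

#' Relabel the copies of a trajectory
#'
#' Applies a permutation to the copy indexing; used to verify that the whole
#' analysis pipeline is invariant to how proteins happen to be numbered.
#'
#' @param traj a [cg_trajectory()].
#' @param perm a permutation of `1:n_copies(traj)`; new copy `i` is old copy
#'   `perm[i]`.
#' @return the relabelled `cg_trajectory`.
#' @export
shuffle_copies <- function(traj, perm) {
  perm <- as.integer(perm)
  if (!identical(sort(perm), seq_len(n_copies(traj))))
    stop("'perm' must be a permutation of the copy indices", call. = FALSE)
  traj$centers <- traj$centers[, perm, , drop = FALSE]
  traj$angles <- traj$angles[, perm, drop = FALSE]
  traj
}
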