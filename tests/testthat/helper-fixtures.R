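# Fixture builders shared across test files; everything is generated in code.

# A minimal 3-bead body whose beads are almost coincident, so the body acts
# as a point particle for distance tests.
point_body <- function() {
  pseudo_receptor(rbind(c(1e-6, 0), c(0, 1e-6), c(0, 0)), orientation_bead = 1L)
}

# Trajectory with explicitly placed (static) copies of a given body.
static_traj <- function(centers, angles = NULL, body = point_body(),
                        box = c(45, 45), n_rep = 1L) {
  n <- nrow(centers)
  if (is.null(angles)) angles <- rep(0, n)
  ca <- array(NA_real_, c(n_rep, n, 2L))
  for (f in seq_len(n_rep)) ca[f, , ] <- centers
  am <- matrix(rep(angles, each = n_rep), n_rep, n)
  cg_trajectory(ca, am, body, box, seq_len(n_rep))
}

# Build an oligomer_structure from member centres and reference-axis
# directions: each member gets a centre bead, an orientation bead at
# centre + axis, and a perpendicular bead (so the body is never degenerate).
make_structure <- function(centers, axes = NULL, frame_time = 0) {
  n <- nrow(centers)
  if (is.null(axes)) axes <- matrix(rep(c(1, 0), each = n), n, 2L)
  coords <- lapply(seq_len(n), function(m) {
    a <- axes[m, ] / sqrt(sum(axes[m, ]^2))
    perp <- c(-a[2L], a[1L])
    ctr <- centers[m, ]
    # rows: orientation bead, perpendicular bead, counterweight beads that
    # keep the centre of geometry at `ctr`
    rbind(ctr + a, ctr + 0.5 * perp, ctr - a, ctr - 0.5 * perp)
  })
  oligomer_structure(coords, seq_len(n), frame_time, orientation_bead = 1L)
}

# Rotate an oligomer_structure rigidly about the origin by `deg` degrees
# (counter-clockwise) and translate by `shift`.
transform_structure <- function(s, deg = 0, shift = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  s$coords <- lapply(s$coords, function(x) sweep(x %*% t(R), 2L, shift, "+"))
  s
}

# Independent connected-components oracle: thresholded bead-distance graph,
# components via igraph (a different code path from the package's
# union-find).
oracle_partition <- function(coords, box, cutoff = 0.75) {
  n <- length(coords)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    dmin <- Inf
    for (a in seq_len(nrow(coords[[i]]))) for (b in seq_len(nrow(coords[[j]]))) {
      d <- coords[[i]][a, ] - coords[[j]][b, ]
      d <- d - box * round(d / box)
      dmin <- min(dmin, sqrt(sum(d^2)))
    }
    adj[i, j] <- dmin <= cutoff
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# Canonical relabelling of a membership vector (by first appearance), so
# partitions can be compared independent of arbitrary group ids.
canon_membership <- function(r) match(r, unique(r))

# A small simulated system reused by the structure/MSM pipeline tests.
demo_sim <- function(n_frames = 2000L, seed = 11L, n_copies = 9L) {
  simulate_association_dynamics(
    sim_config(n_copies = n_copies, n_frames = n_frames, seed = seed))
}
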