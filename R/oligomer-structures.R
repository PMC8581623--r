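#' Oligomer quaternary structure
#'
#' One oligomer observed in one frame: the bead coordinates of its member
#' copies (already unwrapped so the oligomer is spatially contiguous) plus
#' bookkeeping needed by the permutation-invariant clustering.
#'
#' @param coords list of bead coordinate matrices (n_beads x 2, nm), one per
#'   member, all with the same bead count.
#' @param member_ids protein indices of the members, parallel to `coords`.
#' @param frame_time time of the frame (ns).
#' @param orientation_bead index of the bead defining each member's in-plane
#'   reference axis (centre -> bead), used for the dimer binding angles.
#' @return object of class `oligomer_structure` with an `order` field.
#' @export
oligomer_structure <- function(coords, member_ids, frame_time = NA_real_,
                               orientation_bead = 1L) {
  stopifnot(is.list(coords), length(coords) == length(member_ids))
  nb <- vapply(coords, nrow, integer(1L))
  if (length(unique(nb)) != 1L)
    stop("all members must have the same bead count", call. = FALSE)
  structure(list(coords = lapply(coords, unname),
                 member_ids = as.integer(member_ids),
                 order = length(coords),
                 frame_time = frame_time,
                 orientation_bead = as.integer(orientation_bead)),
            class = "oligomer_structure")
}

member_centers <- function(s) {
  t(vapply(s$coords, colMeans, numeric(2L)))
}

# In-plane reference axis (unit vector) of member m: centre -> orientation bead.
member_axis <- function(s, m) {
  ctr <- colMeans(s$coords[[m]])
  v <- s$coords[[m]][s$orientation_bead, ] - ctr
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("degenerate reference axis", call. = FALSE)
  v / nv
}

# Clockwise in-plane angle (degrees, [0, 360)) from vector a to vector b,
# viewed from +z (the extracellular side).
clockwise_angle <- function(a, b) {
  ccw <- atan2(a[1L] * b[2L] - a[2L] * b[1L], sum(a * b)) * 180 / pi
  (-ccw) %% 360
}

# Geometry-determined internal member order, independent of protein labels:
# members sorted by the clockwise angle from their reference axis to the
# direction of the oligomer centroid, then by distance to the centroid.
# Used to canonicalize the reference structure of a pool so the whole
# clustering is invariant to how copies were numbered.
geometric_member_order <- function(s) {
  ctrs <- member_centers(s)
  g <- colMeans(ctrs)
  key1 <- key2 <- numeric(s$order)
  for (m in seq_len(s$order)) {
    to_g <- g - ctrs[m, ]
    d <- sqrt(sum(to_g^2))
    key2[m] <- d
    key1[m] <- if (d < 1e-9) -1 else clockwise_angle(member_axis(s, m), to_g)
  }
  order(round(key1, 9L), round(key2, 9L))
}

reorder_members <- function(s, perm) {
  s$coords <- s$coords[perm]
  s$member_ids <- s$member_ids[perm]
  s
}

stack_coords <- function(s) do.call(rbind, s$coords)

# Optimal in-plane rigid superposition (rotation + translation, no
# reflection) of Y onto X. Returns the fitted Y and the RMSD.
superpose2d <- function(X, Y) {
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
  D <- t(Xc) %*% Yc
  theta <- atan2(D[2L, 1L] - D[1L, 2L], D[1L, 1L] + D[2L, 2L])
  Yfit <- Yc %*% t(rot2(theta))
  rmsd <- sqrt(mean(rowSums((Xc - Yfit)^2)))
  list(coords = sweep(Yfit, 2L, mx, "+"), rmsd = rmsd, theta = theta)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    }
  }
  out
}

#' Permutation-invariant canonical member order
#'
#' Tests every ordering of the structure's members against the reference and
#' returns the permutation whose stacked coordinates give the lowest RMSD
#' after optimal in-plane rigid superposition. This removes the dependence of
#' coordinate RMSD on the arbitrary numbering of identical protein copies.
#' Ties are broken by the lexicographically smallest permutation.
#'
#' @param structure,reference `oligomer_structure`s of equal order (<= 5)
#'   and equal bead counts.
#' @return list: `perm` (member permutation; reordered structure is
#'   `members[perm]`), `rmsd`, and `coords` (the reordered, superposed,
#'   stacked coordinates).
#' @export
canonical_order <- function(structure, reference) {
  stopifnot(inherits(structure, "oligomer_structure"),
            inherits(reference, "oligomer_structure"))
  if (structure$order != reference$order)
    stop("structure and reference must have the same oligomeric order",
         call. = FALSE)
  if (structure$order > 5L)
    stop("exhaustive reordering is limited to order <= 5", call. = FALSE)
  if (nrow(structure$coords[[1L]]) != nrow(reference$coords[[1L]]))
    stop("bead counts differ between structure and reference", call. = FALSE)
  X <- stack_coords(reference)
  best <- NULL
  for (p in all_permutations(structure$order)) {
    Y <- do.call(rbind, structure$coords[p])
    fit <- superpose2d(X, Y)
    if (is.null(best) || fit$rmsd < best$rmsd - 1e-12) {
      best <- list(perm = p, rmsd = fit$rmsd, coords = fit$coords)
    }
  }
  best
}

#' Extract oligomer structures of given orders from a trajectory
#'
#' Walks the per-frame partitions and collects every oligomer whose order is
#' in `orders` as an [oligomer_structure()], unwrapping member coordinates
#' across the periodic boundary so each oligomer is contiguous. Structures
#' are pooled by order, in frame order (the "oligomer pool" of each order).
#'
#' @param traj a [cg_trajectory()].
#' @param membership per-frame oligomer id matrix, e.g. from
#'   [partition_trajectory()].
#' @param orders oligomeric orders to collect (default 2:5; order >= 6 is
#'   counted in the `n_large` attribute but not collected for clustering).
#' @param frames frame indices corresponding to the rows of `membership`.
#' @return named list of pools (one per observed order, names "2".."5"),
#'   each a list of `oligomer_structure`s; attribute `n_large` counts
#'   occurrences of order >= 6.
#' @export
extract_oligomer_structures <- function(traj, membership, orders = 2:5,
                                        frames = seq_len(nrow(membership))) {
  pools <- list()
  n_large <- 0L
  ob <- traj$body$orientation_bead
  for (k in seq_len(nrow(membership))) {
    f <- frames[k]
    row <- membership[k, ]
    gs <- unique(row)
    # within-frame group order keyed to geometry (group centroid), not to
    # the arbitrary group/protein numbering, so pools are invariant to how
    # copies were labelled
    ctr <- vapply(gs, function(g) {
      cm <- matrix(traj$centers[f, which(row == g), ], ncol = 2L)
      colMeans(cm)
    }, numeric(2L))
    gs <- gs[order(round(ctr[1L, ], 6L), round(ctr[2L, ], 6L))]
    for (g in gs) {
      mem <- which(row == g)
      ord <- length(mem)
      if (ord >= 6L) { n_large <- n_large + 1L; next }
      if (!(ord %in% orders)) next
      coords <- frame_coords(traj, f, mem)
      coords <- unwrap_group(coords, traj$box)
      s <- oligomer_structure(coords, mem, traj$times[f], ob)
      key <- as.character(ord)
      pools[[key]] <- c(pools[[key]], list(s))
    }
  }
  attr(pools, "n_large") <- n_large
  pools
}

# Greedy minimum-image unwrapping of a group of bead sets: each subsequent
# member is shifted by whole box vectors to sit next to the already-placed
# member it is closest to.
unwrap_group <- function(coords, box) {
  n <- length(coords)
  if (n == 1L) return(coords)
  ctr <- t(vapply(coords, colMeans, numeric(2L)))
  # anchor at the geometrically first member (lexicographically smallest
  # centre) so which members receive a box shift does not depend on how
  # copies are numbered; shifts then round identically in every relabelling
  placed <- order(round(ctr[, 1L], 9L), round(ctr[, 2L], 9L))[1L]
  remaining <- setdiff(seq_len(n), placed)
  while (length(remaining) > 0L) {
    best <- NULL
    for (r in remaining) for (p in placed) {
      d <- min_image(ctr[r, ] - ctr[p, ], box)
      dist <- sqrt(sum(d^2))
      if (is.null(best) || dist < best$dist) best <- list(r = r, p = p, dist = dist)
    }
    r <- best$r; p <- best$p
    shift <- (ctr[p, ] + min_image(ctr[r, ] - ctr[p, ], box)) - ctr[r, ]
    coords[[r]] <- sweep(coords[[r]], 2L, shift, "+")
    ctr[r, ] <- ctr[r, ] + shift
    placed <- c(placed, r)
    remaining <- setdiff(remaining, placed)
  }
  coords
}

# Mean silhouette width of a kmeans assignment (small pools only).
mean_silhouette <- function(xmat, assign) {
  n <- nrow(xmat)
  dmat <- as.matrix(stats::dist(xmat))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assign == assign[i]
    a <- if (sum(own) > 1L) mean(dmat[i, own & seq_len(n) != i]) else 0
    b <- Inf
    for (k in setdiff(unique(assign), assign[i]))
      b <- min(b, mean(dmat[i, assign == k]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cluster an oligomer pool into configurations
#'
#' KMeans clustering of the flattened, canonically reordered and superposed
#' coordinates of all structures of one order. Clusters are labelled
#' `"A.b"` with `A` the oligomeric order and `b` the cluster rank by
#' descending size.
#'
#' If `k` is not given it is chosen by a mean-silhouette scan over
#' `k = 2..min(15, n - 1)` (with a subsample cap for large pools), since the
#' appropriate cluster count varies between pools.
#'
#' @param pool list of `oligomer_structure`s of equal order.
#' @param k number of clusters, or `NULL` to scan.
#' @param seed integer seed controlling the KMeans initialization.
#' @param reference reference structure; default is the pool's first
#'   structure with its members put in a geometry-determined canonical
#'   order, so results do not depend on protein numbering.
#' @return object of class `configuration_clusters`: `labels` (per
#'   structure), `assignment`, `k`, `sizes`, `centroids`, `order`,
#'   `reference`, `perms` (canonical member permutations), `rmsd`.
#' @export
cluster_configurations <- function(pool, k = NULL, seed = 1L,
                                   reference = NULL) {
  if (length(pool) == 0L) stop("empty pool", call. = FALSE)
  ord <- pool[[1L]]$order
  if (is.null(reference)) {
    reference <- reorder_members(pool[[1L]], geometric_member_order(pool[[1L]]))
  }
  co <- lapply(pool, canonical_order, reference = reference)
  xmat <- t(vapply(co, function(z) as.vector(z$coords),
                   numeric(length(as.vector(co[[1L]]$coords)))))
  n <- nrow(xmat)
  if (!is.null(k) && k > n) stop("'k' exceeds the pool size", call. = FALSE)
  if (is.null(k)) {
    kmax <- min(15L, n - 1L)
    if (kmax < 2L) {
      k <- 1L
    } else {
      idx <- if (n > 1000L) { set.seed(seed); sort(sample.int(n, 1000L)) } else seq_len(n)
      scores <- vapply(2:kmax, function(kk) {
        set.seed(seed)
        cl <- stats::kmeans(xmat[idx, , drop = FALSE], centers = kk,
                            nstart = 5L, iter.max = 100L)
        mean_silhouette(xmat[idx, , drop = FALSE], cl$cluster)
      }, numeric(1L))
      k <- (2:kmax)[which.max(scores)]
    }
  }
  if (k == 1L) {
    assign <- rep(1L, n)
    centroids <- matrix(colMeans(xmat), 1L)
  } else {
    set.seed(seed)
    km <- stats::kmeans(xmat, centers = k, nstart = 10L, iter.max = 200L)
    assign <- km$cluster
    centroids <- km$centers
  }
  sizes <- tabulate(assign, k)
  rank <- order(-sizes, seq_len(k))
  relabel <- integer(k); relabel[rank] <- seq_len(k)
  assign <- relabel[assign]
  centroids <- centroids[rank, , drop = FALSE]
  sizes <- sizes[rank]
  structure(list(order = ord, k = k,
                 labels = paste0(ord, ".", assign),
                 assignment = assign, sizes = sizes, centroids = centroids,
                 reference = reference,
                 perms = lapply(co, `[[`, "perm"),
                 rmsd = vapply(co, `[[`, numeric(1L), "rmsd")),
            class = "configuration_clusters")
}

#' @export
print.configuration_clusters <- function(x, ...) {
  cat(sprintf("Configuration clusters, order %d: %d structures in %d clusters\n",
              x$order, length(x$labels), x$k))
  tab <- table(factor(x$labels, levels = paste0(x$order, ".", seq_len(x$k))))
  print(tab)
  invisible(x)
}

#' Dimer binding angles
#'
#' For each protomer of a dimer, the clockwise in-plane angle (viewed from
#' the extracellular side, +z) from its reference axis (centre ->
#' orientation bead, the helix-8-parallel stand-in) to the direction of its
#' partner's centre of geometry. Both angles are in `[0, 360)` degrees and
#' are invariant under rigid in-plane motion of the whole dimer.
#'
#' @param dimer an `oligomer_structure` of order 2.
#' @return named numeric vector `c(theta1, theta2)`, in member order.
#' @export
dimer_binding_angles <- function(dimer) {
  stopifnot(inherits(dimer, "oligomer_structure"))
  if (dimer$order != 2L) stop("'dimer' must have order 2", call. = FALSE)
  ctrs <- member_centers(dimer)
  sep <- ctrs[2L, ] - ctrs[1L, ]
  if (sqrt(sum(sep^2)) < 1e-9)
    stop("coincident protomer centres", call. = FALSE)
  th1 <- clockwise_angle(member_axis(dimer, 1L), sep)
  th2 <- clockwise_angle(member_axis(dimer, 2L), -sep)
  c(theta1 = th1, theta2 = th2)
}

#' Trimer bending angle
#'
#' The angle (degrees, in (0, 180]) subtended at the vertex protomer by the
#' centres of the other two. For a chain topology the vertex is the protomer
#' in contact with both others; for a cyclic trimer (all pairs in contact)
#' the smallest of the three vertex angles is reported.
#'
#' @param trimer an `oligomer_structure` of order 3.
#' @param cutoff contact cutoff (nm) used to establish the topology.
#' @return named numeric `c(phi = ...)`.
#' @export
trimer_bending_angle <- function(trimer, cutoff = 0.75) {
  stopifnot(inherits(trimer, "oligomer_structure"))
  if (trimer$order != 3L) stop("'trimer' must have order 3", call. = FALSE)
  ctrs <- member_centers(trimer)
  adj <- matrix(FALSE, 3L, 3L)
  for (i in 1:2) for (j in (i + 1L):3L) {
    d <- min(pdist_periodic(trimer$coords[[i]], trimer$coords[[j]], c(Inf, Inf)))
    adj[i, j] <- adj[j, i] <- d <= cutoff
  }
  deg <- rowSums(adj)
  vertex_angle <- function(v) {
    others <- setdiff(1:3, v)
    a <- ctrs[others[1L], ] - ctrs[v, ]
    b <- ctrs[others[2L], ] - ctrs[v, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-9 || nb < 1e-9) stop("coincident protomer centres", call. = FALSE)
    acos(pmin(1, pmax(-1, sum(a * b) / (na * nb)))) * 180 / pi
  }
  if (all(deg == 2L)) {
    phi <- min(vapply(1:3, vertex_angle, numeric(1L)))
  } else {
    v <- which(deg == 2L)
    if (length(v) != 1L)
      stop("trimer contact topology is not connected at this cutoff", call. = FALSE)
    phi <- vertex_angle(v)
  }
  c(phi = phi)
}

#' Principal-axis spans of a tetramer or pentamer
#'
#' Spans (max minus min) of the protomer centres projected on the first and
#' second principal axes of their in-plane covariance; rotation- and
#' translation-invariant descriptors of the overall oligomer shape. When the
#' covariance is isotropic (equal eigenvalues) the x/y axes are used.
#'
#' @param oligomer an `oligomer_structure` (intended for orders 4-5; any
#'   order >= 2 is accepted).
#' @return named numeric vector `c(d1, d2)` (nm), `d1 >= d2`.
#' @export
principal_axis_lengths <- function(oligomer) {
  stopifnot(inherits(oligomer, "oligomer_structure"))
  ctrs <- member_centers(oligomer)
  cc <- sweep(ctrs, 2L, colMeans(ctrs))
  cv <- crossprod(cc) / nrow(cc)
  ev <- eigen(cv, symmetric = TRUE)
  axes <- if (abs(ev$values[1L] - ev$values[2L]) <
              1e-9 * max(ev$values[1L], 1e-12)) diag(2L) else ev$vectors
  proj <- cc %*% axes
  spans <- apply(proj, 2L, function(p) diff(range(p)))
  spans <- sort(spans, decreasing = TRUE)
  c(d1 = spans[1L], d2 = spans[2L])
}

#' Full configuration characterisation of a trajectory
#'
#' Builds the oligomer pools, clusters each order permutation-invariantly,
#' and computes the per-structure configuration metrics: binding angles
#' (theta1, theta2) for dimers, the bending angle (phi) for trimers, and
#' principal-axis spans (d1, d2) for tetramers and pentamers. Dimer angles
#' are reported in the canonical member order of each structure, so the
#' output is independent of how the protein copies were numbered.
#'
#' @param traj a [cg_trajectory()].
#' @param membership per-frame oligomer ids (see [partition_trajectory()]).
#' @param cutoff association cutoff (nm).
#' @param k cluster counts: `NULL` (silhouette scan per pool), a single
#'   number, or a named list by order ("2".."5").
#' @param seed seed for the clustering.
#' @return named list by order; each element has `clusters`
#'   (a `configuration_clusters`) and `metrics` (data.frame: frame_time,
#'   label, and the order's metric columns).
#' @export
characterise_oligomers <- function(traj, membership, cutoff = 0.75, k = NULL,
                                   seed = 1L) {
  pools <- extract_oligomer_structures(traj, membership)
  out <- list()
  for (key in names(pools)) {
    pool <- pools[[key]]
    ord <- as.integer(key)
    kk <- if (is.list(k)) k[[key]] else k
    cl <- cluster_configurations(pool, k = kk, seed = seed)
    met <- lapply(seq_along(pool), function(i) {
      s <- reorder_members(pool[[i]], cl$perms[[i]])
      if (ord == 2L) dimer_binding_angles(s)
      else if (ord == 3L) trimer_bending_angle(s, cutoff)
      else principal_axis_lengths(s)
    })
    met <- as.data.frame(do.call(rbind, met))
    met <- cbind(frame_time = vapply(pool, `[[`, numeric(1L), "frame_time"),
                 label = cl$labels, met, stringsAsFactors = FALSE)
    out[[key]] <- list(clusters = cl, metrics = met)
  }
  attr(out, "n_large") <- attr(pools, "n_large")
  out
}
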