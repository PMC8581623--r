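test_that("minimum distance respects the minimum-image convention", {
  traj <- static_traj(rbind(c(0, 0), c(3, 0)))
  expect_equal(min_distance_series(traj, c(1, 2))$distance, 3, tolerance = 1e-5)
  traj2 <- static_traj(rbind(c(1, 0), c(44, 0)))
  expect_equal(min_distance_series(traj2, c(1, 2))$distance, 2, tolerance = 1e-5)
  expect_error(min_distance_series(traj, c(1, 2), beads = integer(0)), "bead")
})

test_that("minimum distance equals the exhaustive bead-pair oracle", {
  set.seed(42)
  body <- pseudo_receptor(matrix(stats::runif(20, -2, 2), 10, 2),
                          orientation_bead = 1L)
  centers <- matrix(stats::runif(8, 0, 45), 4, 2)
  angles <- stats::runif(4, 0, 2 * pi)
  traj <- static_traj(centers, angles, body = body, n_rep = 3L)
  for (pair in list(c(1, 2), c(2, 4), c(1, 3))) {
    got <- min_distance_series(traj, pair)$distance
    co <- frame_coords(traj, 1L)
    dmin <- Inf
    for (a in 1:10) for (b in 1:10) {
      d <- co[[pair[1]]][a, ] - co[[pair[2]]][b, ]
      d <- d - traj$box * round(d / traj$box)
      dmin <- min(dmin, sqrt(sum(d^2)))
    }
    expect_equal(got, rep(dmin, 3L), tolerance = 1e-10)
  }
})

test_that("moving-average smoothing has the stated identity and edge behaviour", {
  expect_identical(smooth_series(c(5, 1, 4, 2), window = 1L), c(5, 1, 4, 2))
  expect_equal(smooth_series(rep(2.5, 10), window = 5L), rep(2.5, 10))
  sm <- smooth_series(c(0, 3, 0), window = 3L)
  expect_equal(sm[2L], 1.0)
  expect_equal(sm[c(1L, 3L)], c(1.5, 1.5))  # shrunken edge windows
  expect_error(smooth_series(c(1, 2, 3), window = 2L), "odd")
  expect_error(smooth_series(c(1, 2, 3), window = 5L), "length")
})

test_that("distance density locates the trough between contact and free modes", {
  set.seed(7)
  x <- c(stats::rnorm(3000, 0.55, 0.05), stats::rnorm(3000, 4.0, 0.4))
  dd <- distance_density(x)
  troughs <- dd$troughs[dd$troughs > 0.55 & dd$troughs < 4.0]
  expect_gte(length(troughs), 1L)
  # oracle: the trough must fall where a fine histogram is essentially
  # empty, i.e. in the valley separating the two modes
  expect_gt(troughs[1L], 0.7)
  expect_lt(troughs[1L], 3.5)
  expect_lt(mean(abs(x - troughs[1L]) < 0.1), 0.005)
  # a single mode has no trough
  dd1 <- distance_density(stats::rnorm(2000, 2, 0.2))
  expect_length(dd1$troughs, 0L)
  expect_warning(distance_density(rep(1, 200)), "degenerate")
  expect_warning(distance_density(stats::rnorm(200), bw = 1e-12), "bandwidth")
})

test_that("single-linkage assignment groups transitively at the cutoff", {
  # all far apart: three monomers
  p <- assign_oligomers(list(rbind(c(0, 0)), rbind(c(5, 0)), rbind(c(10, 0))),
                        box = c(45, 45))
  expect_identical(attr(p, "membership"), c(1L, 2L, 3L))
  # A-B and B-C in contact, A-C not: one trimer
  p <- assign_oligomers(list(rbind(c(0, 0)), rbind(c(0.7, 0)), rbind(c(1.4, 0))),
                        box = c(45, 45))
  expect_identical(attr(p, "membership"), c(1L, 1L, 1L))
  expect_identical(unclass(p)[[1L]], 1:3)
})

test_that("assignment matches the independent connected-components oracle on random frames", {
  set.seed(101)
  body <- pseudo_receptor(default_body_offsets())
  box <- c(45, 45)
  for (rep in 1:100) {
    centers <- matrix(stats::runif(18, 0, 45), 9, 2)
    angles <- stats::runif(9, 0, 2 * pi)
    traj <- static_traj(centers, angles, body = body, box = box)
    co <- frame_coords(traj, 1L)
    got <- attr(assign_oligomers(co, box), "membership")
    want <- oracle_partition(co, box)
    expect_identical(canon_membership(got), canon_membership(want))
    # conservation: group sizes partition all nine copies
    sizes <- tabulate(got)
    order_counts <- tabulate(sizes[sizes > 0])
    expect_identical(sum(order_counts * seq_along(order_counts)), 9L)
  }
})

test_that("flicker filling merges short gaps and is idempotent and monotone", {
  iv <- rbind(c(0, 500), c(550, 900))
  expect_equal(fill_flickers(iv, 100), rbind(c(0, 900)))
  expect_equal(fill_flickers(iv, 10), iv)
  expect_equal(fill_flickers(iv, 0), iv)
  # boundary: a gap exactly equal to the tolerance is NOT merged
  expect_equal(fill_flickers(rbind(c(0, 100), c(200, 300)), 100),
               rbind(c(0, 100), c(200, 300)))
  expect_error(fill_flickers(rbind(c(10, 20), c(0, 5))), "sorted")
  # idempotence and monotonicity on random interval sets
  set.seed(5)
  for (r in 1:20) {
    starts <- sort(stats::runif(10, 0, 1000))
    iv <- cbind(starts, starts + stats::runif(10, 1, 30))
    iv[, 2] <- pmin(iv[, 2], c(iv[-1, 1], Inf) - 1e-6)
    for (tol in c(0, 20, 80)) {
      m <- fill_flickers(iv, tol)
      expect_equal(fill_flickers(m, tol), m)
    }
    d_small <- sum(fill_flickers(iv, 10)[, 2] - fill_flickers(iv, 10)[, 1])
    d_large <- sum(fill_flickers(iv, 200)[, 2] - fill_flickers(iv, 200)[, 1])
    expect_gte(d_large, d_small)
    expect_gte(nrow(fill_flickers(iv, 10)), nrow(fill_flickers(iv, 200)))
  }
})

test_that("event counting detects alternating cutoff crossings", {
  expect_identical(count_events(c(2, 3, 2, 4))$n_assoc, 0L)
  expect_identical(count_events(c(2, 3, 2, 4))$n_dissoc, 0L)
  sq <- c(2, 0.5, 0.5, 2, 2, 0.5, 0.5, 2)
  ev <- count_events(sq)
  expect_identical(ev$n_assoc, 2L)
  expect_identical(ev$n_dissoc, 2L)
  expect_identical(ev$events$type, c("assoc", "dissoc", "assoc", "dissoc"))
  # starting bound, then rising: a single dissociation
  ev2 <- count_events(c(0.3, 0.4, 2, 3))
  expect_identical(ev2$n_assoc, 0L)
  expect_identical(ev2$n_dissoc, 1L)
  # alternation: assoc and dissoc counts differ by at most 1
  set.seed(3)
  x <- smooth_series(stats::runif(500, 0, 2), 5L)
  ev3 <- count_events(x)
  expect_lte(abs(ev3$n_assoc - ev3$n_dissoc), 1L)
})

test_that("events and partitions are invariant under rigid motion of the whole system", {
  sim <- demo_sim(n_frames = 400, seed = 31)
  traj <- sim$trajectory
  th <- 57 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- traj
  for (f in seq_len(400)) rot$centers[f, , ] <- traj$centers[f, , ] %*% t(R)
  rot$angles <- traj$angles + th
  # rotation is about the origin of a periodic box, so wrap back in
  rot$centers[, , 1] <- rot$centers[, , 1] %% traj$box[1]
  rot$centers[, , 2] <- rot$centers[, , 2] %% traj$box[2]
  s0 <- smooth_series(min_distance_series(traj, c(1, 2)), 31L)
  s1 <- smooth_series(min_distance_series(rot, c(1, 2)), 31L)
  # rotating a periodic system is only exactly rigid within the primary
  # image; distances for pairs in the same image are preserved
  near <- s0$distance < 5
  expect_equal(s0$distance[near], s1$distance[near], tolerance = 1e-8)
})

test_that("oligomer-order distribution counts and conserves copies", {
  m_mono <- matrix(rep(1:9, each = 4), 4, 9)
  d <- oligomer_distribution(m_mono, window = 1)
  expect_equal(unname(d$mean[1L]), 9)
  expect_equal(unname(d$sd[1L]), 0)
  # alternating 9 monomers / 1 dimer + 7 monomers
  m <- rbind(matrix(1:9, 1), matrix(c(1, 1, 2:8), 1))
  m <- m[rep(1:2, 10), ]
  d2 <- oligomer_distribution(m, window = 1)
  expect_equal(unname(d2$mean[2L]), 0.5)
  expect_true(all(d2$counts %*% seq_len(9) == 9))
  expect_error(oligomer_distribution(m, window = 0), "window")
  expect_error(oligomer_distribution(m, window = 1.2), "window")
})
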