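# Hand-built lipid contact trajectory for tests that need full control over
# the epochs (the generator is exercised separately).
manual_lt <- function(epochs, distances, site_members, n_frames,
                      frame_dt = 1, n_residues = 10L) {
  structure(list(n_frames = as.integer(n_frames), frame_dt = frame_dt,
                 n_residues = as.integer(n_residues),
                 epochs = epochs, epoch_distances = distances,
                 site_members = site_members, background_distance = 2.5,
                 ground_truth = NULL),
            class = "lipid_contact_traj")
}

test_that("dual-cutoff detection matches the hand-traced state machine", {
  iv <- detect_contacts_dual_cutoff(c(2.0, 0.5, 0.8, 0.9, 1.2, 0.5, 2.0),
                                    frame_dt = 1)
  expect_equal(iv, cbind(c(1, 5), c(4, 6)))
  expect_equal(iv[, 2] - iv[, 1], c(3, 1))  # frames 1-3 and frame 5
  # never below the entry cutoff: no intervals, even through the buffer band
  expect_identical(nrow(detect_contacts_dual_cutoff(c(2, 1.5, 1.2, 2))), 0L)
  expect_identical(nrow(detect_contacts_dual_cutoff(c(2, 0.7, 0.9, 0.7, 2))), 0L)
  # still in contact at the end: censored at the series end
  iv2 <- detect_contacts_dual_cutoff(c(2, 0.4, 0.4))
  expect_equal(iv2, cbind(1, 3))
  expect_error(detect_contacts_dual_cutoff(c(1, 2), lower = 1, upper = 0.5),
               "below")
})

test_that("detection is idempotent on an interval's own frames", {
  set.seed(9)
  d <- c(2, 2, runif(10, 0.2, 0.5), 0.9, runif(5, 0.2, 0.5), 2, 2)
  iv <- detect_contacts_dual_cutoff(d)
  expect_identical(nrow(iv), 1L)
  # re-run on exactly the frames of the detected interval
  idx <- (iv[1, 1] + 1):(iv[1, 2])  # 0-based times -> 1-based frames
  iv2 <- detect_contacts_dual_cutoff(d[idx])
  expect_equal(iv2[, 2] - iv2[, 1], iv[, 2] - iv[, 1])
})

test_that("interaction graph weights count shared-lipid frames", {
  # residues 1 and 2 share lipid 1 for 50 of 100 frames; residue 3 never
  contacts <- data.frame(
    residue = c(1L, 2L, 3L),
    lipid = c(1L, 1L, 2L),
    start = c(0, 25, 10),
    end = c(75, 100, 20))
  g <- build_interaction_graph(contacts, n_frames = 100)
  w <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("1", "2"))]
  expect_equal(w, 0.5)
  expect_equal(igraph::get_edge_ids(g, c("1", "3")), 0)  # no edge
  # symmetry is inherent to the undirected graph
  expect_false(igraph::is_directed(g))
})

test_that("community detection recovers planted sites", {
  # two disconnected 5-cliques
  el <- rbind(t(combn(1:5, 2)), t(combn(6:10, 2)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(el[, 1]), to = as.character(el[, 2])),
    directed = FALSE)
  igraph::E(g)$weight <- 1
  sites <- detect_binding_sites(g, seed = 1)
  expect_length(sites, 2L)
  expect_identical(sites[[1L]], 1:5)
  expect_identical(sites[[2L]], 6:10)
  # a single edge is one two-residue site
  g1 <- igraph::graph_from_data_frame(
    data.frame(from = "3", to = "7"), directed = FALSE)
  igraph::E(g1)$weight <- 0.4
  s1 <- detect_binding_sites(g1, seed = 1)
  expect_length(s1, 1L)
  expect_identical(s1[[1L]], c(3L, 7L))
  # planted partition: 3 groups of 10, p_in = 0.9, p_out = 0.05
  set.seed(77)
  n <- 30L; groups <- rep(1:3, each = 10L)
  edges <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (groups[i] == groups[j]) 0.9 else 0.05
    if (runif(1) < p) edges <- rbind(edges, c(i, j))
  }
  gp <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(1:n)))
  igraph::E(gp)$weight <- 1
  sp <- detect_binding_sites(gp, seed = 2)
  # assignment accuracy against the planted labels (best label matching)
  lab <- integer(n)
  for (k in seq_along(sp)) lab[sp[[k]]] <- k
  acc <- max(sapply(seq_along(sp), function(offset) {
    mean(sapply(1:3, function(gq) {
      tab <- table(lab[groups == gq])
      max(tab) / 10
    }))
  }))
  expect_gte(acc, 0.95)
  # determinism under a fixed seed
  expect_identical(detect_binding_sites(gp, seed = 2), sp)
})

test_that("planted two-site series recover sites, kinetics and the residence ordering", {
  lt <- generate_lipid_distance_series(koff_site = 0.1, n_residues = 14,
                                       site_members = list(1:5, 8:12),
                                       n_frames = 60000, seed = 10)
  contacts <- lipid_contact_intervals(lt)
  expect_true(all(contacts$residue %in% c(1:5, 8:12)))
  g <- build_interaction_graph(contacts, n_frames = lt$n_frames,
                               frame_dt = lt$frame_dt)
  sites <- detect_binding_sites(g, seed = 3)
  expect_length(sites, 2L)
  expect_setequal(lapply(sites, identity), list(1:5, 8:12))
  # site koff within 15% of the generator truth (>= 500 dwell events)
  sk <- site_kinetics(lt, sites[[1L]])
  expect_gt(sk$n_events, 500L)
  truth <- 1 / mean(lt$ground_truth$dwells_by_site[[
    which(sapply(lt$site_members, function(m) setequal(m, sites[[1L]])))]])
  expect_lt(abs(sk$koff - truth) / truth, 0.15)
  # residue-level profiles: members around the same residence time
  rrt <- residue_residence_times(contacts, total_time = lt$n_frames,
                                 frame_dt = 1, residues = c(1, 7))
  expect_lt(abs(rrt$residence_time[1L] - 1 / truth) / (1 / truth), 0.15)
  expect_identical(rrt$n_events[2L], 0L)
  expect_equal(rrt$occupancy[2L], 0)
  expect_equal(rrt$residence_time[2L], 0)
  # site residence >= max member residence on the same data
  rall <- residue_residence_times(contacts, total_time = lt$n_frames,
                                  residues = sites[[1L]])
  expect_gte(sk$residence_time, max(rall$residence_time) * (1 - 1e-9))
})

test_that("site-level contacts bridge alternating residues and count lipids", {
  # two residues engaged alternately by one lipid with no full exit:
  # the site-level minimum distance stays in contact throughout
  r1 <- c(0.4, 0.4, 1.5, 1.5, 0.4, 0.4)
  r2 <- c(1.5, 1.5, 0.4, 0.4, 1.5, 1.5)
  site_min <- pmin(r1, r2)
  iv_site <- detect_contacts_dual_cutoff(site_min)
  expect_identical(nrow(iv_site), 1L)
  expect_gt(iv_site[1, 2] - iv_site[1, 1],
            max(detect_contacts_dual_cutoff(r1)[, 2] -
                  detect_contacts_dual_cutoff(r1)[, 1]))
  # three concurrent always-bound lipids give a mean lipid count of 3
  nf <- 200L
  ep <- data.frame(site = rep(1L, 3L), lipid = 1:3,
                   start_frame = rep(1L, 3L), end_frame = rep(nf, 3L))
  lt3 <- manual_lt(ep, replicate(3, rep(0.3, nf), simplify = FALSE),
                   site_members = list(1L), n_frames = nf)
  sk3 <- site_kinetics(lt3, 1L)
  expect_equal(sk3$mean_lipid_count, 3, tolerance = 0.02)
  # a one-residue site reduces to that residue's profile
  lt1 <- generate_lipid_distance_series(0.05, n_residues = 3,
                                        site_members = 2L, n_frames = 20000,
                                        seed = 4)
  c1 <- lipid_contact_intervals(lt1)
  sk1 <- site_kinetics(lt1, 2L)
  r1p <- residue_residence_times(c1, total_time = 20000, residues = 2L)
  expect_equal(sk1$koff, r1p$koff[1L], tolerance = 1e-8)
  expect_identical(sk1$n_events, r1p$n_events[1L])
})

test_that("radial distribution is flat for uniform lipids and normalizes away density", {
  set.seed(14)
  box <- c(45, 45)
  nf <- 60L
  lip <- replicate(nf, cbind(runif(400, 0, 45), runif(400, 0, 45)),
                   simplify = FALSE)
  g <- radial_distribution(lip, c(22.5, 22.5), box, r_max = 20, n_bins = 20)
  counts_per_bin <- 400 * nf * pi * diff(seq(0, 20, length.out = 21)^2) / prod(box)
  se <- sqrt(counts_per_bin) / counts_per_bin
  expect_true(all(abs(g$g - 1) <= 3 * pmax(se, 0.02) + 0.05))
  # all lipids pinned at 1 nm: a single occupied bin
  ring <- cbind(22.5 + cos(seq(0, 2 * pi, length.out = 50)),
                22.5 + sin(seq(0, 2 * pi, length.out = 50)))
  gs <- radial_distribution(list(ring), c(22.5, 22.5), box, r_max = 5,
                            n_bins = 10)
  hit <- which(gs$g > 0)
  expect_length(hit, 1L)                      # a single spike bin ...
  expect_lt(abs(gs$r[hit] - 1), 0.5)          # ... at the pinned radius
  # doubling the lipid count leaves g unchanged
  lip2 <- lapply(lip, function(m) rbind(m, m))
  g2 <- radial_distribution(lip2, c(22.5, 22.5), box, r_max = 20, n_bins = 20)
  expect_equal(g2$g, g$g, tolerance = 1e-10)
})
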