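#' Configuration for the Brownian association simulator
#'
#' Bundles the physical and numerical parameters of the in-plane Brownian
#' association/dissociation simulation. Defaults describe the study
#' conditions used throughout the package's validation: 9 receptor copies in
#' a periodic 45 x 45 nm membrane patch, 1 ns frames, and dissociation at
#' 0.05 ns^-1 (20 ns mean bond lifetime). At these rates and densities the
#' system stays dilute (roughly 15% of copies bound at any instant), the
#' regime in which protein-protein association is a second-order reaction.
#'
#' @param n_copies number of receptor copies (>= 1).
#' @param box_xy periodic box lengths (nm), length 2.
#' @param n_frames number of frames to simulate.
#' @param frame_dt time step per frame (ns).
#' @param diffusion_coeff translational diffusion coefficient of a free copy
#'   (nm^2/ns). The rotational diffusion coefficient takes the same numeric
#'   value in rad^2/ns; only relative in-plane geometry feeds the analyses,
#'   so the two need not be tuned independently.
#' @param capture_radius centre-centre distance (nm) below which two copies
#'   in different oligomers bind. Must be < min(box_xy)/4.
#' @param k_off_true true per-bond dissociation rate (ns^-1).
#' @param seed integer RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_copies = 9L, box_xy = c(45, 45), n_frames = 10000L,
                       frame_dt = 1, diffusion_coeff = 0.05,
                       capture_radius = 3.9, k_off_true = 0.05, seed = 1L) {
  n_copies <- as.integer(n_copies)
  if (n_copies < 1L) stop("'n_copies' must be >= 1", call. = FALSE)
  if (length(box_xy) != 2L || any(box_xy <= 0))
    stop("'box_xy' must be two positive lengths", call. = FALSE)
  stopifnot_scalar(frame_dt, "frame_dt", positive = TRUE)
  stopifnot_scalar(diffusion_coeff, "diffusion_coeff", positive = TRUE)
  stopifnot_scalar(capture_radius, "capture_radius", positive = TRUE)
  if (capture_radius >= min(box_xy) / 4)
    stop("'capture_radius' must be < min(box_xy)/4", call. = FALSE)
  if (k_off_true < 0) stop("'k_off_true' must be >= 0", call. = FALSE)
  structure(list(n_copies = n_copies, box_xy = as.numeric(box_xy),
                 n_frames = as.integer(n_frames), frame_dt = frame_dt,
                 diffusion_coeff = diffusion_coeff,
                 capture_radius = capture_radius,
                 k_off_true = k_off_true, seed = as.integer(seed)),
            class = "sim_config")
}

# Connected components of the bond graph; plain BFS, n is tiny.
bond_components <- function(n, bonds) {
  cl <- seq_len(n)
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      ci <- cl[bonds[b, 1L]]; cj <- cl[bonds[b, 2L]]
      if (ci != cj) cl[cl == cj] <- ci
    }
  }
  match(cl, unique(cl))
}

#' Simulate in-plane Brownian association/dissociation dynamics
#'
#' Propagates `n_copies` rigid copies of `body` by 2D Brownian dynamics
#' (translation and rotation) in a periodic box. When the centres of two
#' copies belonging to different oligomers come within `capture_radius` they
#' form a bond and are snapped to a fixed contact distance
#' (0.9 x capture_radius); bonded groups move as rigid units with size-scaled
#' diffusion. Each bond breaks independently with per-step probability
#' 1 - exp(-k_off_true * frame_dt); fragments separate to just outside the
#' capture radius so a dissociation is a real excursion, not an immediate
#' recapture. Higher-order oligomers arise by chaining pairwise bonds.
#'
#' Every association and dissociation is recorded, giving a trajectory with
#' exact ground truth against which the detection, kinetics and Markov-model
#' machinery can be validated.
#'
#' @param config a [sim_config()].
#' @param body a [pseudo_receptor()] shared by all copies.
#' @param keep_coordinates if `FALSE`, per-frame centres/angles are not
#'   stored (events and partitions still are), which saves memory on long
#'   event-counting runs.
#' @param max_placement_tries attempts to place each copy without overlap.
#' @return list with components:
#'   \describe{
#'     \item{trajectory}{a [cg_trajectory()], or `NULL` if
#'       `keep_coordinates = FALSE`.}
#'     \item{ground_truth}{list: `membership` (n_frames x n_copies integer
#'       matrix of oligomer ids per frame), `events` (data.frame: time, i, j,
#'       type \"assoc\"/\"dissoc\"), `durations` (completed bond dwell times,
#'       ns), `durations_censored` (dwells truncated by the trajectory end),
#'       `true_koff`.}
#'   }
#' @export
simulate_association_dynamics <- function(config, body = pseudo_receptor(),
                                          keep_coordinates = TRUE,
                                          max_placement_tries = 1000L) {
  stopifnot(inherits(config, "sim_config"), inherits(body, "pseudo_receptor"))
  set.seed(config$seed)
  n <- config$n_copies
  box <- config$box_xy
  dt <- config$frame_dt
  nf <- config$n_frames
  cap <- config$capture_radius
  contact <- 0.9 * cap
  escape <- 1.1 * cap
  p_off <- 1 - exp(-config$k_off_true * dt)
  sd_t <- sqrt(2 * config$diffusion_coeff * dt)
  sd_r <- sqrt(2 * config$diffusion_coeff * dt)  # rad; see sim_config docs

  # non-overlapping random initial placement
  pos <- matrix(NA_real_, n, 2L)
  pos[1L, ] <- stats::runif(2L) * box
  if (n > 1L) for (i in 2:n) {
    ok <- FALSE
    for (try in seq_len(max_placement_tries)) {
      cand <- stats::runif(2L) * box
      d <- pdist_periodic(matrix(cand, 1L), pos[seq_len(i - 1L), , drop = FALSE], box)
      if (all(d > cap)) { pos[i, ] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("could not place copies without overlap; box too crowded",
                  call. = FALSE)
  }
  ang <- stats::runif(n, 0, 2 * pi)

  # bond state
  bonds <- matrix(integer(0), 0L, 2L)   # (i, j), i < j
  bond_t0 <- numeric(0)
  cl <- seq_len(n)

  # pair index template
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pi_ <- pr[, 1L]; pj_ <- pr[, 2L]

  if (keep_coordinates) {
    centers_arr <- array(NA_real_, c(nf, n, 2L))
    ang_arr <- matrix(NA_real_, nf, n)
  }
  membership <- matrix(NA_integer_, nf, n)

  # growable event store (doubled on overflow; trimmed at the end)
  ev_cap <- 1024L; ev_n <- 0L
  ev_time <- numeric(ev_cap); ev_i <- integer(ev_cap); ev_j <- integer(ev_cap)
  ev_assoc <- logical(ev_cap)
  dur_cap <- 1024L; dur_n <- 0L
  durations <- numeric(dur_cap)
  push_event <- function(tt, i, j, assoc) {
    if (ev_n == ev_cap) {
      ev_cap <<- ev_cap * 2L
      length(ev_time) <<- ev_cap; length(ev_i) <<- ev_cap
      length(ev_j) <<- ev_cap; length(ev_assoc) <<- ev_cap
    }
    ev_n <<- ev_n + 1L
    ev_time[ev_n] <<- tt; ev_i[ev_n] <<- i; ev_j[ev_n] <<- j
    ev_assoc[ev_n] <<- assoc
  }
  push_duration <- function(d) {
    if (dur_n == dur_cap) {
      dur_cap <<- dur_cap * 2L
      length(durations) <<- dur_cap
    }
    dur_n <<- dur_n + 1L
    durations[dur_n] <<- d
  }

  shift_members <- function(mem, delta) {
    pos[mem, 1L] <<- pos[mem, 1L] + delta[1L]
    pos[mem, 2L] <<- pos[mem, 2L] + delta[2L]
  }

  for (f in seq_len(nf)) {
    t_now <- f * dt
    ncl <- max(cl)
    sizes <- tabulate(cl, ncl)
    # rigid-cluster Brownian step; aggregate mobility scales as 1/size
    dxc <- stats::rnorm(ncl, 0, sd_t / sqrt(sizes))
    dyc <- stats::rnorm(ncl, 0, sd_t / sqrt(sizes))
    dth <- stats::rnorm(ncl, 0, sd_r / sqrt(sizes))
    cx <- rowsum(pos[, 1L], cl, reorder = TRUE)[, 1L] / sizes
    cy <- rowsum(pos[, 2L], cl, reorder = TRUE)[, 1L] / sizes
    px <- pos[, 1L] - cx[cl]; py <- pos[, 2L] - cy[cl]
    ct <- cos(dth)[cl]; st <- sin(dth)[cl]
    pos[, 1L] <- cx[cl] + ct * px - st * py + dxc[cl]
    pos[, 2L] <- cy[cl] + st * px + ct * py + dyc[cl]
    ang <- ang + dth[cl]

    just_broken <- matrix(integer(0), 0L, 2L)
    if (nrow(bonds) > 0L && p_off > 0) {
      brk <- stats::runif(nrow(bonds)) < p_off
      if (any(brk)) {
        for (b in which(brk)) {
          push_event(t_now, bonds[b, 1L], bonds[b, 2L], FALSE)
          push_duration(t_now - bond_t0[b])
        }
        just_broken <- bonds[brk, , drop = FALSE]
        bonds <- bonds[!brk, , drop = FALSE]
        bond_t0 <- bond_t0[!brk]
        cl <- bond_components(n, bonds)
        # push fragments apart when a break split an oligomer
        for (b in seq_len(nrow(just_broken))) {
          i <- just_broken[b, 1L]; j <- just_broken[b, 2L]
          if (cl[i] != cl[j]) {
            v <- min_image(pos[j, ] - pos[i, ], box)
            nv <- sqrt(sum(v^2))
            if (nv < 1e-9) { a0 <- stats::runif(1, 0, 2 * pi); v <- c(cos(a0), sin(a0)); nv <- 1 }
            u <- v / nv
            gap <- (escape - nv) / 2
            if (gap > 0) {
              shift_members(which(cl == cl[j]), u * gap)
              shift_members(which(cl == cl[i]), -u * gap)
            }
          }
        }
      }
    }

    # association: centre-centre capture between different oligomers
    dx <- min_image(pos[pi_, 1L] - pos[pj_, 1L], box[1L])
    dy <- min_image(pos[pi_, 2L] - pos[pj_, 2L], box[2L])
    d2 <- dx * dx + dy * dy
    cand <- which(d2 < cap * cap & cl[pi_] != cl[pj_])
    if (length(cand) > 0L) {
      for (kc in cand) {
        i <- pi_[kc]; j <- pj_[kc]
        if (cl[i] == cl[j]) next  # merged earlier this frame
        if (nrow(just_broken) > 0L &&
            any(just_broken[, 1L] == i & just_broken[, 2L] == j)) next
        v <- min_image(pos[j, ] - pos[i, ], box)
        nv <- sqrt(sum(v^2))
        if (nv < 1e-9) next
        # snap the partner oligomer to contact distance, removing any whole
        # box offset so the oligomer is contiguous in raw coordinates (rigid
        # rotations only commute with the minimum image for contiguous groups)
        shift_members(which(cl == cl[j]),
                      pos[i, ] + v * (contact / nv) - pos[j, ])
        bonds <- rbind(bonds, c(i, j))
        bond_t0 <- c(bond_t0, t_now)
        cl[cl == cl[j]] <- cl[i]
        cl <- match(cl, unique(cl))
        push_event(t_now, i, j, TRUE)
      }
    }

    if (keep_coordinates) {
      centers_arr[f, , 1L] <- pos[, 1L] %% box[1L]
      centers_arr[f, , 2L] <- pos[, 2L] %% box[2L]
      ang_arr[f, ] <- ang
    }
    membership[f, ] <- cl
  }

  durations_censored <- if (length(bond_t0) > 0L) nf * dt - bond_t0 else numeric(0)
  traj <- NULL
  if (keep_coordinates)
    traj <- cg_trajectory(centers_arr, ang_arr, body, box, seq_len(nf) * dt)
  idx <- seq_len(ev_n)
  list(trajectory = traj,
       ground_truth = list(
         membership = membership,
         events = data.frame(time = ev_time[idx], i = ev_i[idx],
                             j = ev_j[idx],
                             type = ifelse(ev_assoc[idx], "assoc", "dissoc"),
                             stringsAsFactors = FALSE),
         durations = durations[seq_len(dur_n)],
         durations_censored = durations_censored,
         true_koff = config$k_off_true))
}

#' Draw dwell times from a two-component exponential mixture
#'
#' Generates i.i.d. durations from `w1 * Exp(k1) + (1 - w1) * Exp(k2)`, the
#' ground-truth model behind the biexponential survival fits.
#'
#' @param k1,k2 component rates (> 0, same time unit as the output).
#' @param w1 mixture weight of the `k1` component, in `[0, 1]`.
#' @param n number of draws (> 0).
#' @param seed integer RNG seed.
#' @return numeric vector of `n` durations.
#' @export
generate_dwell_durations <- function(k1, k2, w1 = 1, n, seed = 1L) {
  stopifnot_scalar(k1, "k1", positive = TRUE)
  stopifnot_scalar(k2, "k2", positive = TRUE)
  if (w1 < 0 || w1 > 1) stop("'w1' must be in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  if (n <= 0L) stop("'n' must be a positive count", call. = FALSE)
  set.seed(seed)
  comp1 <- stats::runif(n) < w1
  d <- numeric(n)
  d[comp1] <- stats::rexp(sum(comp1), rate = k1)
  d[!comp1] <- stats::rexp(sum(!comp1), rate = k2)
  d
}

#' Generate lipid head-group contact series with planted binding sites
#'
#' Emulates the input of the dual-cutoff lipid contact analysis: each planted
#' binding site alternates between unbound stretches and bound epochs whose
#' lengths are exponential with rate `koff_site`. During a bound epoch one
#' lipid (a fresh lipid id per epoch) sits below the 0.55 nm entry cutoff of
#' every member residue of the site; at all other times, and for all
#' non-member residues, head-group distances stay above the 1.0 nm exit
#' cutoff. Lipids are never shared across sites, so the planted sites are
#' exactly the communities of the residue co-interaction graph.
#'
#' @param koff_site site dissociation rate(s), ns^-1; recycled over sites.
#' @param n_residues total number of residues.
#' @param site_members integer vector (one site) or list of disjoint integer
#'   vectors (several sites) of member residues.
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param frame_dt frame spacing (ns).
#' @param mean_gap mean unbound stretch (ns) between epochs; default twice
#'   the mean bound dwell, i.e. roughly one-third occupancy.
#' @return object of class `lipid_contact_traj`: frame geometry, the epoch
#'   table (`site`, `lipid`, `start_frame`, `end_frame`), per-epoch distance
#'   traces, and `ground_truth` (site memberships, realized dwells per site,
#'   true koff per site).
#' @export
generate_lipid_distance_series <- function(koff_site, n_residues, site_members,
                                           n_frames, seed = 1L, frame_dt = 1,
                                           mean_gap = NULL) {
  if (!is.list(site_members)) site_members <- list(site_members)
  site_members <- lapply(site_members, as.integer)
  all_m <- unlist(site_members)
  if (any(all_m < 1L | all_m > n_residues))
    stop("'site_members' must be residue indices in 1..n_residues", call. = FALSE)
  if (anyDuplicated(all_m))
    stop("'site_members' sets must be disjoint", call. = FALSE)
  n_sites <- length(site_members)
  koff_site <- rep_len(koff_site, n_sites)
  if (any(koff_site <= 0)) stop("'koff_site' must be > 0", call. = FALSE)
  n_frames <- as.integer(n_frames)
  if (n_frames <= 0L) stop("'n_frames' must be positive", call. = FALSE)
  set.seed(seed)

  epochs <- list()
  dists <- list()
  dwell_by_site <- vector("list", n_sites)
  lipid_id <- 0L
  for (s in seq_len(n_sites)) {
    gap_mean <- if (is.null(mean_gap)) 2 / koff_site[s] else mean_gap
    f <- 1L
    dwells <- numeric(0)
    while (f <= n_frames) {
      gap <- max(1L, as.integer(round(stats::rexp(1L, 1 / gap_mean) / frame_dt)))
      f <- f + gap
      if (f > n_frames) break
      len <- max(1L, as.integer(ceiling(stats::rexp(1L, koff_site[s]) / frame_dt)))
      len <- min(len, n_frames - f + 1L)
      lipid_id <- lipid_id + 1L
      epochs[[length(epochs) + 1L]] <-
        c(site = s, lipid = lipid_id, start_frame = f, end_frame = f + len - 1L)
      dists[[length(dists) + 1L]] <- stats::runif(len, 0.15, 0.50)
      dwells <- c(dwells, len * frame_dt)
      f <- f + len
    }
    dwell_by_site[[s]] <- dwells
  }
  ep <- if (length(epochs)) as.data.frame(do.call(rbind, epochs))
        else data.frame(site = integer(0), lipid = integer(0),
                        start_frame = integer(0), end_frame = integer(0))
  structure(list(n_frames = n_frames, frame_dt = frame_dt,
                 n_residues = as.integer(n_residues),
                 epochs = ep, epoch_distances = dists,
                 site_members = site_members,
                 background_distance = 2.5,
                 ground_truth = list(site_members = site_members,
                                     dwells_by_site = dwell_by_site,
                                     true_koff = koff_site)),
            class = "lipid_contact_traj")
}

#' Head-group distance series for one (residue, lipid) pair
#'
#' Reconstructs the full per-frame distance series implied by a
#' [generate_lipid_distance_series()] object: the stored epoch trace where
#' the residue's site is engaged by that lipid, the far background elsewhere.
#'
#' @param lt a `lipid_contact_traj`.
#' @param residue residue index.
#' @param lipid lipid id.
#' @return numeric vector of length `lt$n_frames` (nm).
#' @export
contact_distance_series <- function(lt, residue, lipid) {
  stopifnot(inherits(lt, "lipid_contact_traj"))
  d <- rep(lt$background_distance, lt$n_frames)
  site_of <- which(vapply(lt$site_members, function(m) residue %in% m, logical(1L)))
  if (length(site_of) == 0L) return(d)
  rows <- which(lt$epochs$site == site_of & lt$epochs$lipid == lipid)
  for (r in rows) {
    idx <- lt$epochs$start_frame[r]:lt$epochs$end_frame[r]
    d[idx] <- lt$epoch_distances[[r]]
  }
  d
}

#' Sample a discrete Markov chain
#'
#' @param P square row-stochastic transition matrix (rows sum to 1 within
#'   1e-12).
#' @param n_steps number of steps to sample (the returned sequence has
#'   `n_steps` states including the initial one).
#' @param seed integer RNG seed.
#' @param init initial state index.
#' @return integer vector of state indices in `1..nrow(P)`.
#' @export
generate_markov_chain <- function(P, n_steps, seed = 1L, init = 1L) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("'P' must be square", call. = FALSE)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("'P' must be row-stochastic (rows summing to 1 within 1e-12)",
         call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (n_steps <= 0L) stop("'n_steps' must be positive", call. = FALSE)
  init <- as.integer(init)
  if (init < 1L || init > nrow(P)) stop("'init' out of range", call. = FALSE)
  set.seed(seed)
  m <- nrow(P)
  cum <- t(apply(P, 1L, cumsum))
  s <- integer(n_steps)
  s[1L] <- init
  u <- stats::runif(n_steps)
  for (t in seq_len(n_steps - 1L)) {
    s[t + 1L] <- findInterval(u[t], cum[s[t], ], left.open = TRUE) + 1L
  }
  s
}
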