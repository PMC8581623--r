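#' Dual-cutoff contact interval detection
#'
#' Hysteresis state machine over a head-group distance series: a contact
#' starts when the distance drops below `lower` (0.55 nm) and ends only when
#' it rises above `upper` (1.0 nm). Excursions into the band between the two
#' cutoffs neither start nor end a contact, which suppresses boundary
#' flicker.
#'
#' @param distance numeric distance series (nm).
#' @param frame_dt frame spacing (ns).
#' @param lower entry cutoff (nm), must be < `upper`.
#' @param upper exit cutoff (nm).
#' @param times frame times (ns); default `0, frame_dt, 2 frame_dt, ...`.
#' @return n x 2 matrix of contact (start, end) times; an interval's end is
#'   the time of the first frame above `upper` (or the end of the series +
#'   one frame when still in contact), so its duration is the number of
#'   contact frames times `frame_dt`.
#' @export
detect_contacts_dual_cutoff <- function(distance, frame_dt = 1, lower = 0.55,
                                        upper = 1.0, times = NULL) {
  if (lower >= upper)
    stop("'lower' must be strictly below 'upper'", call. = FALSE)
  d <- as.numeric(distance)
  n <- length(d)
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  if (is.null(times)) times <- (seq_len(n) - 1L) * frame_dt
  dt <- if (n > 1L) times[2L] - times[1L] else frame_dt
  in_contact <- FALSE
  starts <- ends <- numeric(0)
  for (f in seq_len(n)) {
    if (!in_contact && d[f] < lower) {
      in_contact <- TRUE
      starts <- c(starts, times[f])
    } else if (in_contact && d[f] > upper) {
      in_contact <- FALSE
      ends <- c(ends, times[f])
    }
  }
  if (in_contact) ends <- c(ends, times[n] + dt)
  cbind(starts, ends, deparse.level = 0)
}

#' All (residue, lipid) contact intervals of a lipid contact trajectory
#'
#' Runs the dual-cutoff detection over every epoch window of a
#' [generate_lipid_distance_series()] object (distances outside epochs sit
#' at the far background and cannot contribute contacts).
#'
#' @param lt a `lipid_contact_traj`.
#' @param lower,upper dual cutoffs (nm).
#' @return data.frame: residue, lipid, start, end (ns).
#' @export
lipid_contact_intervals <- function(lt, lower = 0.55, upper = 1.0) {
  stopifnot(inherits(lt, "lipid_contact_traj"))
  dt <- lt$frame_dt
  rows <- list()
  for (r in seq_len(nrow(lt$epochs))) {
    ep <- lt$epochs[r, ]
    members <- lt$site_members[[ep$site]]
    # pad with one background frame on each side so the state machine sees
    # the entry and the exit
    trace <- c(lt$background_distance, lt$epoch_distances[[r]],
               lt$background_distance)
    t0 <- (ep$start_frame - 2L) * dt
    iv <- detect_contacts_dual_cutoff(trace, frame_dt = dt, lower = lower,
                                      upper = upper,
                                      times = t0 + (seq_along(trace) - 1L) * dt)
    for (m in members) for (k in seq_len(nrow(iv))) {
      rows[[length(rows) + 1L]] <-
        data.frame(residue = m, lipid = ep$lipid,
                   start = iv[k, 1L], end = iv[k, 2L])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(residue = integer(0), lipid = integer(0),
                      start = numeric(0), end = numeric(0)))
  do.call(rbind, rows)
}

#' Per-residue lipid residence times and occupancies
#'
#' Pools each residue's contact durations over all lipids, fits the
#' biexponential survival model, and reports the residence time (1/koff)
#' together with the occupancy (fraction of frames with at least one lipid
#' in contact). Residues whose fit fails (or with too few events) are
#' flagged with `NA` kinetics but keep their occupancy.
#'
#' @param contacts data.frame of contact intervals (residue, lipid, start,
#'   end), e.g. from [lipid_contact_intervals()].
#' @param total_time total trajectory time T (ns).
#' @param frame_dt frame spacing (ns), used to count occupied frames.
#' @param residues residues to report (default: all with contacts).
#' @return data.frame: residue, n_events, occupancy, koff, residence_time.
#' @export
residue_residence_times <- function(contacts, total_time, frame_dt = 1,
                                    residues = NULL) {
  if (is.null(residues)) residues <- sort(unique(contacts$residue))
  out <- lapply(residues, function(rr) {
    iv <- contacts[contacts$residue == rr, , drop = FALSE]
    if (nrow(iv) == 0L)
      return(data.frame(residue = rr, n_events = 0L, occupancy = 0,
                        koff = NA_real_, residence_time = 0))
    frames <- unique(unlist(mapply(
      function(s, e) seq(s, e - frame_dt / 2, by = frame_dt),
      iv$start, iv$end, SIMPLIFY = FALSE)))
    occ <- min(1, length(frames) * frame_dt / total_time)
    durs <- iv$end - iv$start
    fit <- tryCatch(fit_biexponential(durs), error = function(e) NULL)
    data.frame(residue = rr, n_events = nrow(iv), occupancy = occ,
               koff = if (is.null(fit)) NA_real_ else fit$koff,
               residence_time = if (is.null(fit)) NA_real_
                                else fit$residence_time)
  })
  do.call(rbind, out)
}

#' Residue interaction graph from shared lipid contacts
#'
#' Nodes are residues; the weight of edge (i, j) is the frequency with which
#' residues i and j were simultaneously in contact with the same lipid
#' molecule, counted per frame and normalized by the total number of frames.
#'
#' @param contacts contact interval data.frame (residue, lipid, start, end).
#' @param n_frames total number of frames (normalization).
#' @param frame_dt frame spacing (ns).
#' @param min_occupancy residues whose total contact occupancy is below this
#'   fraction are dropped to avoid noise communities.
#' @return an undirected weighted [igraph::graph] whose vertex names are
#'   residue indices.
#' @export
build_interaction_graph <- function(contacts, n_frames, frame_dt = 1,
                                    min_occupancy = 1e-4) {
  w <- new.env(parent = emptyenv())
  res_frames <- new.env(parent = emptyenv())
  for (lip in unique(contacts$lipid)) {
    sub <- contacts[contacts$lipid == lip, , drop = FALSE]
    res <- unique(sub$residue)
    fr <- lapply(res, function(rr) {
      iv <- sub[sub$residue == rr, , drop = FALSE]
      unique(unlist(mapply(
        function(s, e) seq(s, e - frame_dt / 2, by = frame_dt),
        iv$start, iv$end, SIMPLIFY = FALSE)))
    })
    names(fr) <- as.character(res)
    for (rr in res) {
      key <- as.character(rr)
      res_frames[[key]] <- c(res_frames[[key]], fr[[key]])
    }
    if (length(res) > 1L) {
      for (a in seq_len(length(res) - 1L)) for (b in (a + 1L):length(res)) {
        shared <- length(intersect(fr[[a]], fr[[b]]))
        if (shared > 0L) {
          i <- min(res[a], res[b]); j <- max(res[a], res[b])
          key <- paste(i, j)
          w[[key]] <- (if (is.null(w[[key]])) 0 else w[[key]]) + shared
        }
      }
    }
  }
  keep <- vapply(ls(res_frames), function(k)
    length(unique(res_frames[[k]])) / n_frames >= min_occupancy, logical(1L))
  keep_res <- as.integer(ls(res_frames))[keep]
  keys <- ls(w)
  edges <- if (length(keys) > 0L) {
    el <- do.call(rbind, strsplit(keys, " "))
    data.frame(i = as.integer(el[, 1L]), j = as.integer(el[, 2L]),
               weight = vapply(keys, function(k) w[[k]], numeric(1L)) / n_frames)
  } else data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  edges <- edges[edges$i %in% keep_res & edges$j %in% keep_res, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$i), to = as.character(edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(sort(keep_res))))
  igraph::E(g)$weight <- edges$weight
  g
}

#' Detect lipid binding sites by community analysis
#'
#' Modularity-maximizing (Louvain) community detection on the residue
#' interaction graph; each community of residues that jointly engage the
#' same lipids is one binding site. Residues with no edges are excluded.
#'
#' @param graph the residue interaction graph from
#'   [build_interaction_graph()].
#' @param seed integer seed (Louvain tie-breaking).
#' @param resolution Louvain resolution parameter.
#' @return list of binding sites, each a sorted integer vector of residues,
#'   ordered by decreasing size.
#' @export
detect_binding_sites <- function(graph, seed = 1L, resolution = 1.0) {
  deg <- igraph::degree(graph)
  g <- igraph::induced_subgraph(graph, which(deg > 0))
  if (igraph::vcount(g) == 0L) return(list())
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                  resolution = resolution)
  sites <- lapply(igraph::groups(comm), function(v) sort(as.integer(v)))
  sites <- unname(sites[order(-vapply(sites, length, integer(1L)),
                              vapply(sites, min, integer(1L)))])
  sites
}

#' Binding-site residence time and lipid count
#'
#' A continuous lipid contact with a binding site starts when the head group
#' comes below the entry cutoff of any member residue and ends when it moves
#' beyond the exit cutoff of all of them; the dual-cutoff machine is run on
#' the per-lipid minimum distance over the site's residues. The site
#' residence time comes from the biexponential survival fit of these
#' site-level durations, and `mean_lipid_count` is the time-average number
#' of distinct lipids simultaneously bound to the site.
#'
#' @param lt a `lipid_contact_traj`.
#' @param site integer vector of member residues.
#' @param lower,upper dual cutoffs (nm).
#' @return list: `residence_time`, `koff`, `mean_lipid_count`, `n_events`,
#'   `durations`, `intervals` (data.frame lipid/start/end).
#' @export
site_kinetics <- function(lt, site, lower = 0.55, upper = 1.0) {
  stopifnot(inherits(lt, "lipid_contact_traj"))
  dt <- lt$frame_dt
  site <- as.integer(site)
  site_of <- vapply(seq_len(nrow(lt$epochs)), function(r)
    any(site %in% lt$site_members[[lt$epochs$site[r]]]), logical(1L))
  rows <- which(site_of)
  iv_list <- list()
  for (r in rows) {
    ep <- lt$epochs[r, ]
    trace <- c(lt$background_distance, lt$epoch_distances[[r]],
               lt$background_distance)
    t0 <- (ep$start_frame - 2L) * dt
    iv <- detect_contacts_dual_cutoff(trace, frame_dt = dt, lower = lower,
                                      upper = upper,
                                      times = t0 + (seq_along(trace) - 1L) * dt)
    for (k in seq_len(nrow(iv)))
      iv_list[[length(iv_list) + 1L]] <-
        data.frame(lipid = ep$lipid, start = iv[k, 1L], end = iv[k, 2L])
  }
  if (length(iv_list) == 0L)
    return(list(residence_time = 0, koff = NA_real_, mean_lipid_count = 0,
                n_events = 0L, durations = numeric(0),
                intervals = data.frame(lipid = integer(0), start = numeric(0),
                                       end = numeric(0))))
  ivd <- do.call(rbind, iv_list)
  # merge per lipid: the same lipid re-entering before leaving all residues
  # is one continuous site contact
  merged <- lapply(split(ivd, ivd$lipid), function(sub) {
    m <- fill_flickers(as.matrix(sub[order(sub$start), c("start", "end")]),
                       gap_tolerance = dt / 2)
    data.frame(lipid = sub$lipid[1L], start = m[, 1L], end = m[, 2L])
  })
  ivd <- do.call(rbind, merged)
  durs <- ivd$end - ivd$start
  total_time <- lt$n_frames * dt
  fit <- tryCatch(fit_biexponential(durs), error = function(e) NULL)
  list(residence_time = if (is.null(fit)) NA_real_ else fit$residence_time,
       koff = if (is.null(fit)) NA_real_ else fit$koff,
       mean_lipid_count = sum(durs) / total_time,
       n_events = nrow(ivd), durations = durs, intervals = ivd)
}

#' In-plane radial distribution of lipids around a reference point
#'
#' 2D g(r) of lipid head-group positions relative to a per-frame reference
#' (typically the receptor centre of geometry), normalized by ideal-density
#' annulus areas in the periodic box so that an unstructured lipid
#' distribution gives g(r) = 1.
#'
#' @param lipid_xy list of per-frame lipid coordinate matrices (n x 2, nm),
#'   or one matrix reused for every frame.
#' @param ref_xy per-frame reference points (n_frames x 2 matrix, or a
#'   single length-2 vector).
#' @param box periodic box (nm).
#' @param r_max maximum radius (default `min(box)/2`).
#' @param n_bins number of radial bins.
#' @return data.frame: r (bin centres, nm), g.
#' @export
radial_distribution <- function(lipid_xy, ref_xy, box, r_max = NULL,
                                n_bins = 50L) {
  if (is.matrix(lipid_xy)) lipid_xy <- list(lipid_xy)
  if (is.null(dim(ref_xy))) ref_xy <- matrix(ref_xy, 1L, 2L)
  nfr <- max(length(lipid_xy), nrow(ref_xy))
  if (length(lipid_xy) == 1L) lipid_xy <- rep(lipid_xy, nfr)
  if (nrow(ref_xy) == 1L) ref_xy <- ref_xy[rep(1L, nfr), , drop = FALSE]
  if (is.null(r_max)) r_max <- min(box) / 2
  breaks <- seq(0, r_max, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  n_lip_total <- 0
  for (f in seq_len(nfr)) {
    d <- pdist_periodic(lipid_xy[[f]], ref_xy[f, , drop = FALSE], box)[, 1L]
    counts <- counts + graphics::hist(d[d < r_max], breaks = breaks,
                                      plot = FALSE)$counts
    n_lip_total <- n_lip_total + nrow(lipid_xy[[f]])
  }
  area <- pi * diff(breaks^2)
  density0 <- n_lip_total / (box[1L] * box[2L])   # summed over frames
  ideal <- density0 * area
  data.frame(r = (breaks[-1L] + breaks[-length(breaks)]) / 2,
             g = ifelse(ideal > 0, counts / ideal, NA_real_))
}
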