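#' Composition label of one partition
#'
#' Labels a membrane oligomerization state as `"A^a-B^b-..."` where the
#' orders A < B < ... are the oligomer sizes present and a, b, ... how many
#' oligomers of each size exist (e.g. nine monomers is `"1^9"`, seven
#' monomers plus one dimer `"1^7-2^1"`).
#'
#' @param sizes integer vector of oligomer sizes in one frame.
#' @return the composition label string.
#' @export
composition_label <- function(sizes) {
  tab <- tabulate(as.integer(sizes))
  ords <- which(tab > 0L)
  paste0(ords, "^", tab[ords], collapse = "-")
}

#' Discretize a partition trajectory into composition states
#'
#' Converts per-frame oligomer partitions into a discrete trajectory over
#' whole-membrane composition states, building the state dictionary over
#' observed states only (in order of first appearance).
#'
#' @param membership integer matrix (frames x copies) of per-frame oligomer
#'   ids, or a list of such matrices (replicates).
#' @param n_copies expected copy count; every frame's composition must sum
#'   to it (consistency check).
#' @param frame_dt frame spacing (ns).
#' @return object of class `discrete_trajectory`: `states` (integer vector,
#'   or list of vectors for replicates), `labels` (state dictionary),
#'   `frame_dt`.
#' @export
label_states <- function(membership, n_copies = NULL, frame_dt = 1) {
  reps <- if (is.list(membership)) membership else list(membership)
  if (is.null(n_copies)) n_copies <- ncol(reps[[1L]])
  dict <- character(0)
  states <- lapply(reps, function(mm) {
    out <- integer(nrow(mm))
    for (f in seq_len(nrow(mm))) {
      sizes <- tabulate(mm[f, ])
      sizes <- sizes[sizes > 0L]
      if (sum(sizes) != n_copies)
        stop(sprintf("frame %d: composition sums to %d, expected %d",
                     f, sum(sizes), n_copies), call. = FALSE)
      lab <- composition_label(sizes)
      idx <- match(lab, dict)
      if (is.na(idx)) { dict <<- c(dict, lab); idx <- length(dict) }
      out[f] <- idx
    }
    out
  })
  structure(list(states = if (is.list(membership)) states else states[[1L]],
                 labels = dict, frame_dt = frame_dt),
            class = "discrete_trajectory")
}

#' Transition counts at a lag
#'
#' Sliding-window transition counts `c_ij = #{t : s(t) = i, s(t + lag) = j}`
#' over one or several replicate state sequences; replicates are summed,
#' never bridged.
#'
#' @param dtraj a `discrete_trajectory`, or an integer state sequence, or a
#'   list of sequences.
#' @param lag lag in frames (positive integer, shorter than every
#'   replicate).
#' @param n_states number of states (default: largest index observed).
#' @return integer count matrix with attributes `lag` (frames) and
#'   `frame_dt`.
#' @export
count_transitions <- function(dtraj, lag, n_states = NULL) {
  frame_dt <- 1
  if (inherits(dtraj, "discrete_trajectory")) {
    frame_dt <- dtraj$frame_dt
    seqs <- if (is.list(dtraj$states)) dtraj$states else list(dtraj$states)
    if (is.null(n_states)) n_states <- length(dtraj$labels)
    labels <- dtraj$labels
  } else {
    seqs <- if (is.list(dtraj)) dtraj else list(dtraj)
    labels <- NULL
  }
  lag <- as.integer(lag)
  if (lag < 1L) stop("'lag' must be a positive number of frames", call. = FALSE)
  if (any(vapply(seqs, length, integer(1L)) <= lag))
    stop("'lag' must be shorter than every trajectory", call. = FALSE)
  if (is.null(n_states)) n_states <- max(unlist(seqs))
  C <- matrix(0L, n_states, n_states)
  for (s in seqs) {
    from <- s[seq_len(length(s) - lag)]
    to <- s[(lag + 1L):length(s)]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + unclass(tab)
  }
  dimnames(C) <- if (!is.null(labels)) list(labels, labels) else NULL
  attr(C, "lag") <- lag
  attr(C, "frame_dt") <- frame_dt
  C
}

# reversible MLE by the standard detailed-balance fixed-point iteration
reversible_mle <- function(C, tol = 1e-10, maxiter = 10000L) {
  Csym <- C + t(C)
  ci <- rowSums(C)
  X <- Csym / sum(C)
  for (it in seq_len(maxiter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, "+")
    Xn <- Csym / denom
    Xn <- Xn / sum(Xn)
    if (max(abs(Xn - X)) < tol) { X <- Xn; break }
    X <- Xn
  }
  X / rowSums(X)
}

#' Estimate a Markov state model
#'
#' Maximum-likelihood transition matrix at the given lag from transition
#' counts, restricted to the largest strongly connected set of states. The
#' default estimator is the non-reversible row-normalized MLE
#' `P_ij = c_ij / sum_k c_ik`; a reversible MLE (detailed-balance
#' fixed-point iteration) is available with `reversible = TRUE`.
#'
#' The returned model carries the stationary distribution, eigenvalues,
#' implied timescales `-tau/ln(mu)`, the mean-first-passage-time matrix,
#' and per-state lifetimes `tau / (1 - P_ii)`.
#'
#' @param x a `discrete_trajectory` (or state sequence / list of sequences),
#'   or a count matrix from [count_transitions()].
#' @param lag lag in frames (required unless `x` is a count matrix).
#' @param reversible use the reversible MLE.
#' @param frame_dt frame spacing (ns) when `x` carries none.
#' @return an object of class `msm_model`.
#' @export
estimate_msm <- function(x, lag = NULL, reversible = FALSE, frame_dt = NULL) {
  if (is.matrix(x) && !is.null(attr(x, "lag"))) {
    C <- x
  } else {
    if (is.null(lag)) stop("'lag' is required", call. = FALSE)
    C <- count_transitions(x, lag)
  }
  lag_frames <- attr(C, "lag")
  dt <- if (!is.null(frame_dt)) frame_dt else attr(C, "frame_dt")
  tau <- lag_frames * dt
  labels <- rownames(C)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(C)))

  # largest strongly connected set (most total counts on ties)
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sets <- split(seq_len(nrow(C)), comp$membership)
  wt <- vapply(sets, function(ix) sum(C[ix, ix, drop = FALSE]), numeric(1L))
  sz <- vapply(sets, length, integer(1L))
  active <- sets[[order(-sz, -wt)[1L]]]
  if (sum(C[active, active]) == 0)
    stop("no transitions within the largest connected set", call. = FALSE)
  Ca <- C[active, active, drop = FALSE]

  P <- if (reversible) reversible_mle(Ca) else Ca / rowSums(Ca)
  dimnames(P) <- list(labels[active], labels[active])

  e <- eigen(t(P))
  iperron <- which.max(Re(e$values) - abs(Im(e$values)))
  pi_ <- Re(e$vectors[, iperron])
  pi_ <- abs(pi_) / sum(abs(pi_))
  for (it in 1:50) pi_ <- as.vector(pi_ %*% P)  # polish the fixed point
  pi_ <- pi_ / sum(pi_)
  mu <- eigen(P, only.values = TRUE)$values
  mu <- mu[order(-abs(mu))]

  model <- structure(list(P = P, pi = stats::setNames(pi_, labels[active]),
                          mu = mu, tau = tau, lag = lag_frames,
                          frame_dt = dt, counts = Ca,
                          states = labels[active], active_set = active,
                          excluded = setdiff(seq_len(nrow(C)), active),
                          reversible = reversible),
                     class = "msm_model")
  model$implied_timescales <- implied_timescales_from_eigen(mu, tau)
  model$mfpt <- mean_first_passage_times(model)
  model$lifetimes <- state_lifetimes(model)
  model
}

implied_timescales_from_eigen <- function(mu, tau) {
  mu <- mu[-1L]  # drop the unit (Perron) eigenvalue
  m <- abs(mu)   # complex pairs and negative eigenvalues enter by modulus
  ts <- ifelse(m > 0 & m < 1, -tau / log(m), NA_real_)
  ts[m >= 1] <- Inf
  ts
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("Markov state model: %d states, lag %d frames (tau = %g ns)%s\n",
              nrow(x$P), x$lag, x$tau,
              if (x$reversible) ", reversible MLE" else ""))
  if (length(x$excluded) > 0L)
    cat(sprintf("  %d state(s) outside the largest connected set excluded\n",
                length(x$excluded)))
  cat("  stationary distribution:\n")
  print(round(x$pi, 4))
  invisible(x)
}

#' @export
summary.msm_model <- function(object, ...) {
  out <- list(n_states = nrow(object$P), lag = object$lag, tau = object$tau,
              pi = object$pi,
              implied_timescales = object$implied_timescales,
              lifetimes = object$lifetimes,
              mfpt = object$mfpt, excluded = object$excluded)
  class(out) <- "summary.msm_model"
  out
}

#' @export
print.summary.msm_model <- function(x, ...) {
  cat(sprintf("MSM over %d composition states at tau = %g ns\n",
              x$n_states, x$tau))
  cat("implied timescales (ns):",
      paste(signif(x$implied_timescales, 4), collapse = ", "), "\n")
  cat("state lifetimes (ns):\n")
  print(signif(x$lifetimes, 4))
  invisible(x)
}

#' Mean first passage times between states
#'
#' `mfpt(i -> j)` solves `m_i = tau + sum_{k != j} P_ik m_k` with
#' `m_j = 0`; the model must be irreducible (guaranteed when estimated on
#' the largest strongly connected set). Reaction rates between states are
#' the reciprocals of these times.
#'
#' @param model an `msm_model` (or a row-stochastic matrix; then `tau` must
#'   be supplied).
#' @param tau lag time in ns when `model` is a bare matrix.
#' @return matrix of mean first passage times (ns); `mfpt(i, i) = 0`.
#' @export
mean_first_passage_times <- function(model, tau = NULL) {
  if (inherits(model, "msm_model")) {
    P <- model$P; tau <- model$tau
  } else {
    P <- as.matrix(model)
    if (is.null(tau)) stop("'tau' required for a bare matrix", call. = FALSE)
  }
  m <- nrow(P)
  out <- matrix(0, m, m, dimnames = dimnames(P))
  for (j in seq_len(m)) {
    if (m == 1L) break
    Q <- P[-j, -j, drop = FALSE]
    rhs <- rep(tau, m - 1L)
    sol <- tryCatch(solve(diag(m - 1L) - Q, rhs), error = function(e)
      stop(sprintf("state '%s' unreachable: reducible transition matrix",
                   rownames(P)[j]), call. = FALSE))
    out[-j, j] <- sol
  }
  out
}

#' Lifetimes of the composition states
#'
#' The lifetime of state i is its mean first passage time to the set of all
#' other states, which for a jump process observed at lag tau is
#' `tau / (1 - P_ii)`. A state with `P_ii = 1` has an infinite lifetime.
#'
#' @param model an `msm_model` (or a row-stochastic matrix with `tau`).
#' @param tau lag time (ns) when `model` is a bare matrix.
#' @return named numeric vector of lifetimes (ns).
#' @export
state_lifetimes <- function(model, tau = NULL) {
  if (inherits(model, "msm_model")) {
    P <- model$P; tau <- model$tau
  } else {
    P <- as.matrix(model)
    if (is.null(tau)) stop("'tau' required for a bare matrix", call. = FALSE)
  }
  lt <- tau / (1 - diag(P))
  lt[diag(P) >= 1] <- Inf
  stats::setNames(lt, rownames(P))
}

#' Reaction-rate network between composition states
#'
#' Rates (s^-1) between states as the reciprocal of the mean first passage
#' times, as an edge list; rates below `threshold` can be filtered for
#' display while the full matrix stays available from the model.
#'
#' @param model an `msm_model` with times in ns.
#' @param threshold minimum rate (s^-1) to keep; default 0 keeps all.
#' @return data.frame: from, to, rate_per_s, mfpt_ns.
#' @export
rate_network <- function(model, threshold = 0) {
  stopifnot(inherits(model, "msm_model"))
  m <- nrow(model$P)
  idx <- which(row(model$mfpt) != col(model$mfpt))
  df <- data.frame(from = rownames(model$P)[row(model$mfpt)[idx]],
                   to = colnames(model$P)[col(model$mfpt)[idx]],
                   mfpt_ns = model$mfpt[idx])
  df$rate_per_s <- 1e9 / df$mfpt_ns
  df[df$rate_per_s >= threshold, c("from", "to", "rate_per_s", "mfpt_ns")]
}

#' Implied timescale scan over lag times
#'
#' Estimates an MSM at each lag and reports the implied timescales
#' `-tau/ln(mu)`. For an exactly Markovian process the timescales are flat
#' in the lag; the smallest lag at which they stop changing is the
#' appropriate MSM lag.
#'
#' @param dtraj a `discrete_trajectory` (or state sequence(s)).
#' @param lags integer vector of lags (frames).
#' @param n_timescales how many of the slowest timescales to report.
#' @param frame_dt frame spacing (ns) when `dtraj` carries none.
#' @return data.frame: lag (frames), tau (ns), ts1, ts2, ... (ns).
#' @export
implied_timescales <- function(dtraj, lags, n_timescales = 3L,
                               frame_dt = NULL) {
  rows <- lapply(as.integer(lags), function(lg) {
    m <- estimate_msm(dtraj, lag = lg, frame_dt = frame_dt)
    ts <- m$implied_timescales
    ts <- c(ts, rep(NA_real_, max(0L, n_timescales - length(ts))))
    c(lag = lg, tau = m$tau, stats::setNames(ts[seq_len(n_timescales)],
                                             paste0("ts", seq_len(n_timescales))))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Monte Carlo trajectory from an estimated MSM
#'
#' @param object an `msm_model`.
#' @param nsim number of steps (at the model's lag).
#' @param seed integer RNG seed.
#' @param init initial state (index or label; default the most probable
#'   state under `pi`).
#' @param ... unused.
#' @return integer state sequence of length `nsim` (indices into
#'   `object$states`), with the labels as an attribute.
#' @export
simulate.msm_model <- function(object, nsim = 1000L, seed = NULL,
                               init = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  if (is.null(init)) init <- which.max(object$pi)
  if (is.character(init)) init <- match(init, object$states)
  s <- generate_markov_chain(object$P, n_steps = nsim, seed = seed,
                             init = init)
  attr(s, "labels") <- object$states
  s
}
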