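#' Motion-blur variance-reduction factor
#'
#' For uniform illumination over a pulse of duration `t_e` inside a frame of
#' duration `dt`, time-averaging of the molecule's position shortens the
#' apparent displacement between consecutive frames. The per-dimension
#' displacement variance of free diffusion becomes
#' `2 D dt (1 - 2 R)` with blur factor `R = t_e / (6 dt)`; `R = 1/6` in the
#' full-frame exposure limit and 0 for instantaneous exposure.
#'
#' @param t_e pulse duration, seconds.
#' @param dt frame interval, seconds; must satisfy `0 < t_e <= dt`.
#' @return The dimensionless blur factor.
#' @export
blur_factor <- function(t_e, dt) {
  if (!is.numeric(t_e) || !is.numeric(dt) || dt <= 0)
    stop("t_e and dt must be positive numbers", call. = FALSE)
  if (any(t_e < 0) || any(t_e > dt))
    stop("pulse duration must satisfy 0 <= t_e <= dt", call. = FALSE)
  t_e / (6 * dt)
}

#' Simulation configuration
#'
#' Defines the generative model for synthetic tracking data: `K` diffusion
#' states with coefficients `D` switched by a continuous-time Markov process
#' with off-diagonal rate matrix `rates`, Brownian motion confined to
#' spherocylindrical cells, 2D projection, stroboscopic exposure averaging,
#' Gaussian localization error, geometric photobleaching, and independent
#' missed detections.
#'
#' The defaults emulate the live-cell study conditions: two apparent states
#' (ribosome-bound at 0.1 um^2/s, free at 3 um^2/s) with mean dwell times
#' 0.3 s and 0.7 s (stationary occupancy 0.3/0.7), ~0.8 x 3 um cells, 3 ms
#' laser pulses in 5 ms frames, 30 nm localization error, mean trajectory
#' length 30 frames, up to 3-frame detection gaps, and 3 independent
#' experiments.
#'
#' @param K number of states.
#' @param D per-state diffusion coefficients, um^2/s.
#' @param rates K x K switching-rate matrix (1/s); only off-diagonal entries
#'   are used. With `K = 1` pass a 1 x 1 zero matrix.
#' @param dwell alternative to `rates` for `K = 2`: mean dwell times
#'   (seconds) in each state, converted to exit rates `1/dwell`.
#' @param cell_length_meanlog,cell_length_sdlog lognormal parameters of the
#'   pole-to-pole cell length (um).
#' @param cell_width cell diameter, um.
#' @param frame_interval,pulse_duration seconds.
#' @param loc_sd isotropic localization error SD, um.
#' @param mean_traj_len mean trajectory length in frames (geometric).
#' @param p_gap per-frame missed-detection probability.
#' @param max_gap largest allowed run of consecutive missed frames.
#' @param n_traj number of trajectories.
#' @param n_experiments number of independent experiments the trajectories
#'   are spread over.
#' @param n_cells number of cells (default one per 5 trajectories).
#' @param n_sub Brownian sub-steps per frame used for confinement and
#'   exposure averaging.
#' @return A list of class `spt_sim_config`.
#' @export
sim_config <- function(K = 2,
                       D = c(0.1, 3.0),
                       rates = NULL,
                       dwell = c(0.3, 0.7),
                       cell_length_meanlog = log(3), cell_length_sdlog = 0.15,
                       cell_width = 0.8,
                       frame_interval = 0.005, pulse_duration = 0.003,
                       loc_sd = 0.03,
                       mean_traj_len = 30,
                       p_gap = 0.1, max_gap = 3,
                       n_traj = 1000, n_experiments = 3, n_cells = NULL,
                       n_sub = 50) {
  if (length(D) != K) stop("D must have length K", call. = FALSE)
  if (any(D < 0)) stop("D must be non-negative", call. = FALSE)
  if (is.null(rates)) {
    if (K == 1) {
      rates <- matrix(0, 1, 1)
    } else if (K == 2 && length(dwell) == 2) {
      rates <- matrix(c(0, 1 / dwell[1], 1 / dwell[2], 0), 2, 2, byrow = TRUE)
    } else stop("provide a K x K rates matrix for K > 2", call. = FALSE)
  }
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(K, K))) stop("rates must be K x K", call. = FALSE)
  offd <- rates; diag(offd) <- 0
  if (any(offd < 0)) stop("off-diagonal rates must be >= 0", call. = FALSE)
  if (pulse_duration <= 0 || pulse_duration > frame_interval)
    stop("0 < pulse_duration <= frame_interval required", call. = FALSE)
  if (p_gap < 0 || p_gap >= 1) stop("0 <= p_gap < 1 required", call. = FALSE)
  if (is.null(n_cells)) n_cells <- max(n_experiments, ceiling(n_traj / 5))
  dt_sub <- frame_interval / n_sub
  if (max(rowSums(offd)) * dt_sub > 0.1)
    warning("switching rate times sub-step exceeds 0.1; increase n_sub",
            call. = FALSE)
  structure(list(K = K, D = D, rates = offd,
                 cell_length_meanlog = cell_length_meanlog,
                 cell_length_sdlog = cell_length_sdlog,
                 cell_width = cell_width,
                 frame_interval = frame_interval,
                 pulse_duration = pulse_duration,
                 loc_sd = loc_sd, mean_traj_len = mean_traj_len,
                 p_gap = p_gap, max_gap = max_gap,
                 n_traj = n_traj, n_experiments = n_experiments,
                 n_cells = n_cells, n_sub = n_sub),
            class = "spt_sim_config")
}

# stationary distribution of a continuous-time rate matrix (off-diagonal)
.rate_stationary <- function(rates) {
  K <- nrow(rates)
  if (K == 1) return(1)
  Q <- rates
  diag(Q) <- -rowSums(rates)
  # solve pi Q = 0, sum(pi) = 1
  M <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  p <- tryCatch(as.vector(qr.solve(M, b)), error = function(e) NULL)
  if (is.null(p) || any(!is.finite(p)) || any(p < -1e-9))
    stop("stationary distribution undefined: rate matrix appears reducible",
         call. = FALSE)
  p <- pmax(p, 0)
  p / sum(p)
}

# per-frame transition probability matrix implied by the rate matrix
.rate_to_A <- function(rates, dt) {
  K <- nrow(rates)
  if (K == 1) return(matrix(1, 1, 1))
  Q <- rates
  diag(Q) <- -rowSums(rates)
  as.matrix(Matrix::expm(Q * dt))
}

# uniform start point inside a spherocylinder (axis x, centered at origin)
.sample_interior <- function(halflen, radius) {
  repeat {
    p <- c(runif(1, -halflen - radius, halflen + radius),
           runif(1, -radius, radius), runif(1, -radius, radius))
    cx <- min(max(p[1], -halflen), halflen)
    if (sum((p - c(cx, 0, 0))^2) <= radius^2) return(p)
  }
}

# continuous-time state path mapped onto a sub-step grid
.state_substeps <- function(K, rates, pi0, n_steps, dt_sub) {
  s <- sample.int(K, 1, prob = pi0)
  if (K == 1) return(rep(1L, n_steps))
  out <- integer(n_steps)
  exit <- rowSums(rates)
  t_next <- if (exit[s] > 0) rexp(1, exit[s]) else Inf
  tcur <- 0
  for (i in seq_len(n_steps)) {
    tcur <- tcur + dt_sub
    while (t_next <= tcur) {
      s <- sample.int(K, 1, prob = rates[s, ])
      t_next <- t_next + if (exit[s] > 0) rexp(1, exit[s]) else Inf
    }
    out[i] <- s
  }
  out
}

# drop frames with probability p_gap, never allowing a run of more than
# max_gap consecutive drops (the middle frame of an offending run is kept)
.gap_mask <- function(n, p_gap, max_gap) {
  keep <- c(TRUE, runif(n - 1) >= p_gap)
  if (n >= 2) keep[n] <- TRUE  # bleaching defines the last observed frame
  repeat {
    r <- rle(keep)
    bad <- which(!r$values & r$lengths > max_gap)
    if (!length(bad)) break
    ends <- cumsum(r$lengths)
    for (b in bad) {
      start <- ends[b] - r$lengths[b] + 1L
      keep[start + r$lengths[b] %/% 2L] <- TRUE
    }
  }
  keep
}

#' Simulate a tracking dataset with ground truth
#'
#' Draws trajectories of molecules switching between `K` diffusion states
#' while undergoing Brownian motion confined to spherocylindrical cells.
#' Per frame, the emitted localization is the average of the sub-step
#' positions falling inside the laser-pulse window at the start of the frame
#' (motion blur), projected to the image plane and perturbed by isotropic
#' Gaussian localization error. Trajectory lengths are geometric
#' (photobleaching); frames are then dropped independently to emulate missed
#' detections, subject to the maximum-gap rule.
#'
#' @param config an [sim_config()].
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A list with elements `dataset` (an [spt_dataset()]) and `truth`
#'   (data.frame with the hidden state index of every emitted localization
#'   and the blur-free true position), plus `config`.
#' @export
simulate_spt <- function(config, seed = NULL) {
  stopifnot(inherits(config, "spt_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  pi0 <- .rate_stationary(cf$rates)
  dt_sub <- cf$frame_interval / cf$n_sub
  # sub-step nodes averaged per frame: 0..n_pulse (a vanishing pulse keeps
  # only the frame-start position, i.e. no blur)
  n_pulse <- as.integer(round(cf$n_sub * cf$pulse_duration / cf$frame_interval))

  # cells: random pose in a 100 x 100 um field, split across experiments
  ncell <- cf$n_cells
  cells <- data.frame(
    cell_id = paste0("c", seq_len(ncell)),
    experiment_id = paste0("e", rep_len(seq_len(cf$n_experiments), ncell)),
    center_x_um = runif(ncell, 10, 90),
    center_y_um = runif(ncell, 10, 90),
    orientation_rad = runif(ncell, 0, pi),
    length_um = pmax(rlnorm(ncell, cf$cell_length_meanlog, cf$cell_length_sdlog),
                     cf$cell_width),
    width_um = cf$cell_width,
    stringsAsFactors = FALSE)

  cell_of <- sample.int(ncell, cf$n_traj, replace = TRUE)
  n_frames <- rgeom(cf$n_traj, 1 / cf$mean_traj_len) + 1L

  loc <- vector("list", cf$n_traj)
  tru <- vector("list", cf$n_traj)
  for (tr in seq_len(cf$n_traj)) {
    N <- max(2L, n_frames[tr])
    ci <- cell_of[tr]
    L <- cells$length_um[ci]; w <- cells$width_um[ci]
    halflen <- (L - w) / 2; radius <- w / 2
    nsub_tot <- N * cf$n_sub
    st <- .state_substeps(cf$K, cf$rates, pi0, nsub_tot, dt_sub)
    sdsub <- sqrt(2 * cf$D[st] * dt_sub)
    path <- propagate_cpp(sdsub, halflen, radius,
                          .sample_interior(halflen, radius))
    # exposure average over the pulse window at the start of each frame
    f0 <- (seq_len(N) - 1L) * cf$n_sub
    xm <- vapply(f0, function(o) mean(path[o + seq_len(n_pulse + 1L), 1]),
                 numeric(1))
    ym <- vapply(f0, function(o) mean(path[o + seq_len(n_pulse + 1L), 2]),
                 numeric(1))
    state_fr <- st[f0 + 1L]

    keep <- .gap_mask(N, cf$p_gap, cf$max_gap)
    frames <- which(keep) - 1L

    # cell frame -> image frame
    th <- cells$orientation_rad[ci]
    xs <- xm[keep]; ys <- ym[keep]
    xi <- cells$center_x_um[ci] + cos(th) * xs - sin(th) * ys
    yi <- cells$center_y_um[ci] + sin(th) * xs + cos(th) * ys
    nobs <- length(frames)
    loc[[tr]] <- data.frame(
      traj_id = sprintf("t%05d", tr),
      cell_id = cells$cell_id[ci],
      experiment_id = cells$experiment_id[ci],
      frame = frames,
      x_um = xi + rnorm(nobs, 0, cf$loc_sd),
      y_um = yi + rnorm(nobs, 0, cf$loc_sd),
      stringsAsFactors = FALSE)
    tru[[tr]] <- data.frame(
      traj_id = sprintf("t%05d", tr),
      frame = frames,
      state = state_fr[keep],
      x_true_um = xi, y_true_um = yi,
      stringsAsFactors = FALSE)
  }
  traj <- do.call(rbind, loc)
  truth <- do.call(rbind, tru)
  rownames(traj) <- rownames(truth) <- NULL
  ds <- spt_dataset(traj, cells, cf$frame_interval, cf$pulse_duration)
  list(dataset = ds, truth = truth, config = cf)
}
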