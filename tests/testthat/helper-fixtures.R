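# Small in-code fixtures shared across test files.

# one cell record centered at the origin-ish with zero rotation
fixture_cells <- function(n = 1, length_um = 3, width_um = 0.8,
                          experiment_id = "e1") {
  data.frame(cell_id = paste0("c", seq_len(n)),
             experiment_id = experiment_id,
             center_x_um = 5, center_y_um = 5,
             orientation_rad = 0,
             length_um = length_um, width_um = width_um,
             stringsAsFactors = FALSE)
}

# build a dataset from a list of per-trajectory frame/x/y tables
fixture_dataset <- function(tracks, cells = fixture_cells(),
                            dt = 0.005, pulse = 0.003) {
  traj <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(traj_id = paste0("t", i), cell_id = cells$cell_id[1],
               experiment_id = cells$experiment_id[1],
               frame = tr$frame, x_um = tr$x, y_um = tr$y,
               stringsAsFactors = FALSE)
  }))
  spt_dataset(traj, cells, dt, pulse)
}

# random-walk track with given per-step sd and frame vector
fixture_track <- function(frames, sd_step = 0.05, start = c(5, 5)) {
  n <- length(frames)
  list(frame = frames,
       x = start[1] + cumsum(c(0, rnorm(n - 1, 0, sd_step))),
       y = start[2] + cumsum(c(0, rnorm(n - 1, 0, sd_step))))
}

# exhaustive hidden-path log-likelihood oracle for small chains.
# Displacement i has per-dim variance step_variance(D[k], span[i]) and the
# transition between consecutive displacement states is A^(span[i]).
oracle_loglik <- function(r2, span, D, A, pi0, sigma, Rblur, dt) {
  K <- length(D)
  n <- length(r2)
  Apow <- list(A)
  for (m in seq_len(max(span))[-1]) Apow[[m]] <- Apow[[m - 1]] %*% A
  dens <- function(i, k) {
    v <- step_variance(D[k], span[i], sigma, Rblur, dt)
    exp(-log(2 * pi * v) - r2[i] / (2 * v))
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  tot <- 0
  for (p in seq_len(nrow(paths))) {
    s <- paths[p, ]
    pr <- pi0[s[1]] * dens(1, s[1])
    if (n > 1) for (i in 2:n) {
      pr <- pr * Apow[[span[i - 1]]][s[i - 1], s[i]] * dens(i, s[i])
    }
    tot <- tot + pr
  }
  log(tot)
}

# dhmm-shaped object built directly from known parameters
mock_fit <- function(D, A, dt = 0.005) {
  pi0 <- sptHMM:::.stationary(A)
  structure(list(K = length(D), D = D, A = A, pi = pi0, sigma_loc = 0.02,
                 sigma_fitted = FALSE, R = 0.1, dt = dt,
                 condition = NA_character_),
            class = "dhmm")
}

# coarse_dhmm-shaped object from known per-class occupancies/dwells
mock_coarse <- function(occ, dwell, labels = c("bound", "free")) {
  structure(list(classes = data.frame(label = labels,
                                      D_lo = c(0, 1), D_hi = c(1, Inf)),
                 occ = setNames(occ, labels), dwell = setNames(dwell, labels),
                 empty = setNames(occ <= 0, labels)),
            class = "coarse_dhmm")
}

# per-trajectory fraction of per-frame chain states in state 1, for n_traj
# chains of length len started from the stationary distribution; vectorized
# across trajectories (used for experiment-level sampling-noise simulations)
sim_chain_occ <- function(A, n_traj, len) {
  K <- nrow(A)
  pi0 <- sptHMM:::.stationary(A)
  cA <- t(apply(A, 1, cumsum))
  s <- sample.int(K, n_traj, replace = TRUE, prob = pi0)
  cnt <- as.integer(s == 1L)
  for (t in 2:len) {
    u <- runif(n_traj)
    s <- rowSums(u > cA[s, , drop = FALSE]) + 1L
    cnt <- cnt + (s == 1L)
  }
  cnt / len
}

# weak-confinement simulation config used by the recovery suite: the cell is
# much larger than any diffusion length so the free-diffusion emission model
# holds and fitter accuracy is isolated from confinement bias
recovery_config <- function(...) {
  sim_config(cell_length_meanlog = log(30), cell_length_sdlog = 0.01,
             cell_width = 10, ...)
}
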