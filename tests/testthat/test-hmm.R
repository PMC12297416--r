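test_that("step variance reproduces closed-form limits and worked values", {
  # pure-noise limit
  expect_equal(step_variance(0, 1, 0.03, 0.1, 0.005), 2 * 0.03^2)
  # direct evaluation
  expect_equal(step_variance(1, 1, 0.03, 0.1, 0.005),
               2 * 1 * 0.005 * 0.8 + 2 * 9e-4)
  # ideal Brownian limit, including gap spans
  for (n in 1:4)
    expect_equal(step_variance(2.5, n, 0, 0, 0.005), 2 * 2.5 * n * 0.005)
  expect_error(step_variance(1, 1, 0, 0, -1), "positive")
})

test_that("forward log-likelihood equals exhaustive path enumeration", {
  set.seed(21)
  dt <- 0.005; Rb <- blur_factor(0.003, dt)
  for (K in c(2, 3)) {
    D <- sort(exp(runif(K, log(0.05), log(5))))
    A <- matrix(runif(K * K, 0.05, 1), K, K)
    A <- A / rowSums(A)
    pi0 <- sptHMM:::.stationary(A)
    # one trajectory, 7 steps with gaps of 1 and 2 missing frames
    frames <- c(0, 1, 3, 4, 5, 8, 9, 10)
    track <- fixture_track(frames, sd_step = 0.1)
    ds <- fixture_dataset(list(track))
    model <- list(D = D, A = A, pi = pi0, sigma_loc = 0.02)
    ll <- dhmm_loglik(ds, model)
    r2 <- diff(track$x)^2 + diff(track$y)^2
    ll_oracle <- oracle_loglik(r2, diff(frames), D, A, pi0, 0.02, Rb, dt)
    expect_equal(ll, ll_oracle, tolerance = 1e-10)
  }
})

test_that("likelihood is additive and closed-form for a single state", {
  set.seed(22)
  ds <- fixture_dataset(list(fixture_track(0:10), fixture_track(0:7)))
  model <- list(D = 0.5, A = matrix(1, 1, 1), pi = 1, sigma_loc = 0.02)
  ll <- dhmm_loglik(ds, model)
  d <- ds$trajectories
  r2 <- unlist(lapply(split(d, d$traj_id),
                      function(x) diff(x$x_um)^2 + diff(x$y_um)^2))
  v <- step_variance(0.5, 1, 0.02, blur_factor(0.003, 0.005), 0.005)
  expect_equal(ll, sum(-log(2 * pi * v) - r2 / (2 * v)), tolerance = 1e-12)
  # duplicating every trajectory doubles the log-likelihood exactly
  d2 <- d; d2$traj_id <- paste0(d2$traj_id, "b")
  dds <- spt_dataset(rbind(d, d2), ds$cells, 0.005, 0.003)
  expect_equal(dhmm_loglik(dds, model), 2 * ll, tolerance = 1e-12)
})

test_that("forward and backward recursions agree on the total likelihood", {
  set.seed(23)
  K <- 3
  D <- c(0.05, 0.8, 4)
  A <- matrix(c(0.9, 0.05, 0.05, 0.1, 0.8, 0.1, 0.02, 0.08, 0.9),
              3, 3, byrow = TRUE)
  pi0 <- sptHMM:::.stationary(A)
  frames <- c(0:4, 6, 7, 10)
  track <- fixture_track(frames, sd_step = 0.08)
  ds <- fixture_dataset(list(track))
  ll <- dhmm_loglik(ds, list(D = D, A = A, pi = pi0, sigma_loc = 0.02))
  # independent backward-only recursion in R
  dt <- 0.005; Rb <- blur_factor(0.003, dt)
  span <- diff(frames)
  r2 <- diff(track$x)^2 + diff(track$y)^2
  dens <- function(i, k) {
    v <- step_variance(D[k], span[i], 0.02, Rb, dt)
    exp(-log(2 * pi * v) - r2[i] / (2 * v))
  }
  Apow <- list(A); for (m in 2:max(span)) Apow[[m]] <- Apow[[m - 1]] %*% A
  n <- length(r2)
  beta <- rep(1, K)
  for (i in n:2) {
    b <- vapply(1:K, function(k) dens(i, k), numeric(1))
    beta <- Apow[[span[i - 1]]] %*% (b * beta)
  }
  b1 <- vapply(1:K, function(k) dens(1, k), numeric(1))
  expect_equal(ll, log(sum(pi0 * b1 * beta)), tolerance = 1e-9)
})

test_that("posterior marginals are consistent and likelihood is rigid-motion invariant", {
  set.seed(24)
  sim <- simulate_spt(sim_config(n_traj = 30, mean_traj_len = 15), seed = 24)
  ds <- suppressMessages(filter_trajectories(sim$dataset))
  fit <- dhmm(ds, K = 2, n_starts = 2, seed = 1, sigma_loc = 0.03)
  post <- posterior(fit, ds)
  g <- as.matrix(post$steps[, -1])
  expect_true(all(abs(rowSums(g) - 1) < 1e-10))
  lp <- as.matrix(post$localizations[, -1])
  expect_true(all(abs(rowSums(lp) - 1) < 1e-10))
  # global translation + rotation leaves the likelihood unchanged
  ll0 <- dhmm_loglik(ds, fit)
  th <- 0.71
  ds2 <- ds
  x <- ds$trajectories$x_um; y <- ds$trajectories$y_um
  ds2$trajectories$x_um <- cos(th) * x - sin(th) * y + 12
  ds2$trajectories$y_um <- sin(th) * x + cos(th) * y - 3
  expect_equal(dhmm_loglik(ds2, fit), ll0, tolerance = 1e-9)
})

test_that("single-state ML estimate matches the MSD estimator", {
  cf <- sim_config(K = 1, D = 1, rates = matrix(0, 1, 1), loc_sd = 0,
                   cell_length_meanlog = log(300), cell_length_sdlog = 1e-3,
                   cell_width = 100, pulse_duration = 1e-9,
                   n_traj = 400, mean_traj_len = 40, p_gap = 0, n_sub = 8)
  sim <- simulate_spt(cf, seed = 25)
  ds <- suppressMessages(filter_trajectories(sim$dataset))
  fit <- dhmm(ds, K = 1, n_starts = 1, seed = 1, sigma_loc = 0)
  d <- ds$trajectories
  r2 <- unlist(lapply(split(d, d$traj_id),
                      function(x) diff(x$x_um)^2 + diff(x$y_um)^2))
  expect_equal(fit$D, mean(r2) / (4 * 0.005), tolerance = 1e-3)
})

test_that("EM is monotone and self-consistent at its fixed point", {
  set.seed(26)
  sim <- recovery_config(n_traj = 120, mean_traj_len = 20)
  ds <- suppressMessages(filter_trajectories(simulate_spt(sim, seed = 26)$dataset))
  fit <- dhmm(ds, K = 2, n_starts = 3, seed = 2, sigma_loc = 0.03)
  # monotone log-likelihood up to the stationarity-tie slack
  dll <- diff(fit$ll_trace)
  expect_true(all(dll > -1e-6 * abs(fit$logL)))
  # refitting from the fitted parameters moves them only negligibly
  st <- sptHMM:::.step_table(ds)
  ref <- sptHMM:::.em_run(st, fit$D, fit$A, fit$sigma_loc, FALSE,
                          fit$R, fit$dt, 1e-8, 3)
  expect_equal(ref$D, fit$D, tolerance = 1e-3)
  expect_equal(ref$A, fit$A, tolerance = 5e-3)
  # and its log-likelihood cannot exceed the converged one materially
  expect_lt(abs(ref$loglik - fit$logL), 1e-4 * abs(fit$logL))
})

test_that("AIC counts parameters correctly and prefers the true model size", {
  f <- structure(list(K = 2, logL = -1000, n_params = 4), class = "dhmm")
  expect_equal(AIC(f), 2008)
  sim <- recovery_config(n_traj = 250, mean_traj_len = 25)
  ds <- suppressMessages(filter_trajectories(simulate_spt(sim, seed = 27)$dataset))
  f1 <- dhmm(ds, K = 1, n_starts = 2, seed = 1, sigma_loc = 0.03)
  f2 <- dhmm(ds, K = 2, n_starts = 4, seed = 1, sigma_loc = 0.03)
  expect_equal(f1$n_params, 1)
  expect_equal(f2$n_params, 2 + 2)
  expect_lt(f2$aic, f1$aic)
  # nested models: AIC difference identity
  expect_equal(f2$aic - f1$aic,
               2 * (f2$n_params - f1$n_params) - 2 * (f2$logL - f1$logL))
})

test_that("model scan conserves occupancy-weighted mean D and returns all sizes", {
  sim <- recovery_config(n_traj = 250, mean_traj_len = 25)
  ds <- suppressMessages(filter_trajectories(simulate_spt(sim, seed = 28)$dataset))
  sc <- dhmm_scan(ds, K_range = 1:3, n_starts = 3, seed = 1, sigma_loc = 0.03)
  expect_named(sc$fits, c("K1", "K2", "K3"))
  mD <- vapply(sc$fits, function(f) sum(f$pi * f$D), numeric(1))
  # mass conservation across model sizes (K >= K_true = 2)
  expect_equal(unname(mD["K3"] / mD["K2"]), 1, tolerance = 0.05)
  sc1 <- dhmm_scan(ds, K_range = 1, n_starts = 1, seed = 1, sigma_loc = 0.03)
  expect_length(sc1$fits, 1)
})

test_that("states come out sorted by D with stationary occupancies", {
  sim <- recovery_config(n_traj = 150, mean_traj_len = 20)
  ds <- suppressMessages(filter_trajectories(simulate_spt(sim, seed = 29)$dataset))
  fit <- dhmm(ds, K = 3, n_starts = 3, seed = 1, sigma_loc = 0.03)
  expect_false(is.unsorted(fit$D))
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
  expect_equal(as.vector(fit$pi %*% fit$A), fit$pi, tolerance = 1e-8)
  expect_true(all(abs(rowSums(fit$A) - 1) < 1e-10))
})
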