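test_that("normalized coordinates hit the landmarks and respect rigid motion", {
  cells <- fixture_cells(length_um = 4, width_um = 1)
  mk <- function(x, y) {
    data.frame(traj_id = "t1", cell_id = "c1", experiment_id = "e1",
               frame = seq_along(x) - 1L, x_um = x, y_um = y,
               stringsAsFactors = FALSE)
  }
  # center and the pole on the axis
  ds <- spt_dataset(mk(c(5, 7), c(5, 5)), cells, 0.005, 0.003)
  np <- normalize_positions(ds)
  expect_equal(np$u, c(0, 1), tolerance = 1e-12)
  expect_equal(np$v, c(0, 0), tolerance = 1e-12)
  # a point clearly outside is excluded with a message
  ds2 <- spt_dataset(mk(c(5, 9), c(5, 5)), cells, 0.005, 0.003)
  expect_message(np2 <- normalize_positions(ds2), "excluded 1")
  expect_equal(nrow(np2), 1)
  # invariance under a shared rigid transform of cell and points
  set.seed(51)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi); sh <- runif(2, -20, 20)
    x <- runif(4, 4, 6); y <- runif(4, 4.8, 5.2)
    base <- normalize_positions(spt_dataset(mk(x, y), cells, 0.005, 0.003))
    c2 <- cells
    c2$orientation_rad <- cells$orientation_rad + th
    c2$center_x_um <- cos(th) * (cells$center_x_um) - sin(th) * cells$center_y_um + sh[1]
    c2$center_y_um <- sin(th) * (cells$center_x_um) + cos(th) * cells$center_y_um + sh[2]
    xr <- cos(th) * x - sin(th) * y + sh[1]
    yr <- sin(th) * x + cos(th) * y + sh[2]
    moved <- normalize_positions(spt_dataset(mk(xr, yr), c2, 0.005, 0.003))
    expect_equal(moved$u, base$u, tolerance = 1e-9)
    expect_equal(moved$v, base$v, tolerance = 1e-9)
  }
})

test_that("occupancy maps normalize, stay flat for uniform data, and fold", {
  set.seed(52)
  sim <- simulate_spt(sim_config(n_traj = 150, mean_traj_len = 20), seed = 52)
  ds <- suppressMessages(filter_trajectories(sim$dataset))
  fit <- dhmm(ds, K = 2, n_starts = 2, seed = 1, sigma_loc = 0.03)
  hm <- occupancy_heatmap(ds, fit, thresholds = 1, class = "bound",
                          bins = c(20, 10))
  expect_equal(dim(hm), c(10, 20))
  expect_equal(sum(hm), 1, tolerance = 1e-12)
  expect_true(all(hm >= 0))
  hf <- occupancy_heatmap(ds, fit, thresholds = 1, class = "bound",
                          bins = c(20, 10), fold = TRUE)
  expect_equal(unclass(hf), unclass(hf)[10:1, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(hf), unclass(hf)[, 20:1], tolerance = 1e-12,
               ignore_attr = TRUE)
  # left/right half-masses of symmetric simulated data agree within noise
  expect_equal(sum(hm[, 1:10]), sum(hm[, 11:20]), tolerance = 0.1)
})

test_that("posterior mass is additive across nested threshold classes", {
  set.seed(53)
  sim <- simulate_spt(sim_config(K = 3, D = c(0.1, 0.6, 3),
                                 rates = matrix(c(0, 2, 1, 2, 0, 1, 1, 2, 0),
                                                3, 3, byrow = TRUE),
                                 n_traj = 120, mean_traj_len = 20), seed = 53)
  ds <- suppressMessages(filter_trajectories(sim$dataset))
  fit <- dhmm(ds, K = 3, n_starts = 3, seed = 1, sigma_loc = 0.03)
  args <- list(ds = ds, fit = fit, bins = c(20, 10), normalize = "none")
  m_fine1 <- do.call(occupancy_heatmap,
                     c(args, list(thresholds = c(0.25, 1), class = 1L)))
  m_fine2 <- do.call(occupancy_heatmap,
                     c(args, list(thresholds = c(0.25, 1), class = 2L)))
  m_coarse <- do.call(occupancy_heatmap,
                      c(args, list(thresholds = 1, class = "bound")))
  expect_equal(unclass(m_fine1) + unclass(m_fine2), unclass(m_coarse),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a class confined to the nucleoid region keeps its mass there", {
  # constructed dataset: slow steps only inside |u| < 0.5, fast elsewhere
  set.seed(54)
  cells <- fixture_cells(length_um = 4, width_um = 1)
  L <- cells$length_um; W <- cells$width_um
  mktrack <- function(id, slow) {
    n <- 30
    if (slow) {
      x <- 5 + cumsum(c(0, rnorm(n - 1, 0, 0.02)))
      x <- pmin(pmax(x, 5 - 0.45 * L / 2), 5 + 0.45 * L / 2)
      y <- 5 + cumsum(c(0, rnorm(n - 1, 0, 0.02)))
      y <- pmin(pmax(y, 5 - 0.9 * W / 2), 5 + 0.9 * W / 2)
    } else {
      # fast Gaussian walk reflected into the cell: visits the whole outline
      x <- 5 + pmin(pmax(cumsum(c(0, rnorm(n - 1, 0, 0.25))),
                         -L / 2 * 0.9), L / 2 * 0.9)
      y <- 5 + pmin(pmax(cumsum(c(0, rnorm(n - 1, 0, 0.25))),
                         -W / 2 * 0.9), W / 2 * 0.9)
    }
    data.frame(traj_id = id, cell_id = "c1", experiment_id = "e1",
               frame = 0:(n - 1), x_um = x, y_um = y,
               stringsAsFactors = FALSE)
  }
  traj <- rbind(do.call(rbind, lapply(1:25, function(i) mktrack(paste0("s", i), TRUE))),
                do.call(rbind, lapply(1:25, function(i) mktrack(paste0("f", i), FALSE))))
  ds <- spt_dataset(traj, cells, 0.005, 0.003)
  fit <- dhmm(ds, K = 2, n_starts = 3, seed = 1, sigma_loc = 0.02)
  hm <- occupancy_heatmap(ds, fit, thresholds = 1, class = "bound",
                          bins = c(40, 10))
  ub <- attr(hm, "u_breaks")
  centers <- (ub[-1] + ub[-length(ub)]) / 2
  inside <- abs(centers) < 0.5
  expect_gte(sum(hm[, inside]), 0.95)
})
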