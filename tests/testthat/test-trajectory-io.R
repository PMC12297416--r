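test_that("round trip through the CSV dialect preserves the data", {
  set.seed(11)
  ds <- fixture_dataset(list(fixture_track(0:5), fixture_track(c(0, 2, 5, 6))))
  tf <- tempfile(fileext = ".csv"); cf <- tempfile(fileext = ".csv")
  write_trajectories(ds, tf, cf)
  ds2 <- read_trajectories(tf, cf, 0.005, 0.003)
  expect_identical(ds2$trajectories$traj_id, ds$trajectories$traj_id)
  expect_identical(ds2$trajectories$frame, ds$trajectories$frame)
  expect_equal(ds2$trajectories$x_um, ds$trajectories$x_um, tolerance = 1e-9)
  expect_equal(ds2$trajectories$y_um, ds$trajectories$y_um, tolerance = 1e-9)
})

test_that("gap rule accepts gaps up to 3 missing frames and rejects larger", {
  set.seed(12)
  ok <- fixture_dataset(list(fixture_track(c(0, 2, 5))))  # gaps 1 and 2
  expect_s3_class(ok, "spt_dataset")
  tf <- tempfile(); cf <- tempfile()
  write_trajectories(fixture_dataset(list(fixture_track(c(0, 5)))), tf, cf)
  expect_error(read_trajectories(tf, cf, 0.005, 0.003), "gap larger than")
  # split mode keeps both segments under derived ids
  ds <- read_trajectories(tf, cf, 0.005, 0.003, on_gap_violation = "split")
  expect_equal(length(unique(ds$trajectories$traj_id)), 2L)
})

test_that("malformed input is rejected with informative errors", {
  set.seed(13)
  ds <- fixture_dataset(list(fixture_track(0:3)))
  tf <- tempfile(); cf <- tempfile()
  tr <- ds$trajectories
  write.csv(tr[, setdiff(names(tr), "x_um")], tf, row.names = FALSE)
  write.csv(ds$cells, cf, row.names = FALSE)
  expect_error(read_trajectories(tf, cf, 0.005, 0.003), "x_um")
  # non-monotone frames name the trajectory
  bad <- tr; bad$frame <- c(0L, 2L, 1L, 3L)
  expect_error(spt_dataset(bad, ds$cells, 0.005, 0.003),
               "strictly increasing.*t1")
  # unresolved cell link
  bad2 <- tr; bad2$cell_id <- "nope"
  expect_error(spt_dataset(bad2, ds$cells, 0.005, 0.003), "no cell record")
})

test_that("length filter is strict, idempotent, and order preserving", {
  set.seed(14)
  lens <- c(3, 5, 6, 30)
  ds <- fixture_dataset(lapply(lens, function(L) fixture_track(0:(L - 1))))
  f1 <- suppressMessages(filter_trajectories(ds, min_length = 5))
  kept <- table(f1$trajectories$traj_id)
  expect_setequal(as.integer(kept), c(6L, 30L))
  f2 <- filter_trajectories(f1, min_length = 5)
  expect_identical(f1$trajectories, f2$trajectories)
  # identity on long gap-free data
  ds2 <- fixture_dataset(list(fixture_track(0:99)))
  expect_identical(filter_trajectories(ds2)$trajectories, ds2$trajectories)
  # localization order within trajectories untouched
  expect_false(is.unsorted(match(f1$trajectories$frame[f1$trajectories$traj_id == "t4"],
                                 ds$trajectories$frame[ds$trajectories$traj_id == "t4"])))
})

test_that("retained fraction of geometric-length tracks matches direct count", {
  set.seed(15)
  sim <- simulate_spt(sim_config(n_traj = 1000, p_gap = 0, mean_traj_len = 30),
                      seed = 15)
  lens <- table(sim$dataset$trajectories$traj_id)
  expected <- sum(lens > 5)
  f <- suppressMessages(filter_trajectories(sim$dataset, min_length = 5))
  expect_equal(length(unique(f$trajectories$traj_id)), expected)
})

test_that("cell size window keeps exactly the cells inside it", {
  cells <- fixture_cells(4)
  cells$length_um <- c(1.8, 2.6, 3.0, 4.5)
  set.seed(16)
  tracks <- lapply(1:4, function(i) fixture_track(0:9))
  traj <- do.call(rbind, lapply(1:4, function(i) {
    tr <- tracks[[i]]
    data.frame(traj_id = paste0("t", i), cell_id = cells$cell_id[i],
               experiment_id = "e1", frame = tr$frame, x_um = tr$x,
               y_um = tr$y, stringsAsFactors = FALSE)
  }))
  ds <- spt_dataset(traj, cells, 0.005, 0.003)
  out <- suppressMessages(sort_cells_by_size(ds, 2.2, 4.0))
  expect_setequal(out$cells$length_um, c(2.6, 3.0))
  expect_setequal(unique(out$trajectories$cell_id), out$cells$cell_id)
  # [0, Inf) is the identity
  expect_identical(sort_cells_by_size(ds)$cells, ds$cells)
  # brute-force count on a lognormal population
  sim <- simulate_spt(sim_config(n_traj = 200), seed = 16)
  w <- c(2.5, 3.5)
  direct <- sum(sim$dataset$cells$length_um >= w[1] &
                  sim$dataset$cells$length_um <= w[2])
  expect_equal(nrow(suppressMessages(
    sort_cells_by_size(sim$dataset, w[1], w[2]))$cells), direct)
})
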