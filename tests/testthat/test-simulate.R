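test_that("zero arrival rate with no initial population gives background only", {
  p <- sim_params(n_frames = 10, fov = c(24, 24), arrival_rate = 0,
                  n_initial = 0, seed = 2)
  sim <- simulate_movie(p)
  expect_equal(nrow(sim$truth$particles), 0L)
  expect_equal(nrow(sim$truth$positions), 0L)
  # pure background: mean close to the background parameter
  expect_lt(abs(mean(sim$stack$pixels) - p$background), 1)
})

test_that("identical seeds give bit-identical movies and ground truth", {
  p <- sim_params(n_frames = 15, fov = c(32, 32), arrival_rate = 0.3,
                  seed = 77)
  s1 <- simulate_movie(p)
  s2 <- simulate_movie(p)
  expect_identical(s1$stack$pixels, s2$stack$pixels)
  expect_identical(s1$truth$particles, s2$truth$particles)
  expect_identical(s1$truth$positions, s2$truth$positions)
  s3 <- simulate_movie(sim_params(n_frames = 15, fov = c(32, 32),
                                  arrival_rate = 0.3, seed = 78))
  expect_false(identical(s1$stack$pixels, s3$stack$pixels))
})

test_that("sampled dwells match the exponential mean within 3 SE", {
  # long movie so almost no truncation; compare the sample mean of
  # un-truncated dwells against the 3.0 s parameter
  p <- sim_params(n_frames = 4000, fov = c(24, 24), arrival_rate = 0.5,
                  dwell_law = list(type = "exponential", mean_s = 3.0),
                  n_initial = 0, seed = 11)
  set.seed(p$seed)
  gt <- smkymo:::draw_particles(p)
  ok <- !gt$particles$right_censored & gt$particles$death_cause == "departure"
  dw <- gt$particles$true_dwell_s[ok]
  expect_gt(length(dw), 1500)
  se <- 3.0 / sqrt(length(dw))
  # ceil-discretisation to frames adds up to ~half a frame interval
  expect_lt(abs(mean(dw) - 3.0), 3 * se + 0.15 / 2)
})

test_that("every rendered particle-frame has a ground-truth position and vice versa", {
  p <- sim_params(n_frames = 30, fov = c(32, 32), arrival_rate = 0.4,
                  seed = 5)
  sim <- simulate_movie(p)
  gt <- sim$truth
  for (i in seq_len(nrow(gt$particles))) {
    pr <- gt$particles[i, ]
    frames <- gt$positions$frame[gt$positions$id == pr$id]
    expect_identical(sort(frames), pr$birth_frame:pr$death_frame)
  }
  expect_true(all(gt$particles$birth_frame <= gt$particles$death_frame))
  expect_true(all(gt$particles$true_dwell_s > 0))
})

test_that("occupancy approaches arrival_rate x mean dwell at stationarity", {
  p <- sim_params(n_frames = 400, fov = c(24, 24), arrival_rate = 1.0,
                  dwell_law = list(type = "exponential", mean_s = 1.5),
                  diffusion_coeff = 0, seed = 21)
  set.seed(p$seed)
  gt <- smkymo:::draw_particles(p)
  mean_frames <- 1.5 / 0.15
  # occupancy per frame in the stationary half of the movie
  tail_frames <- 200:399
  occ <- vapply(tail_frames, function(t) {
    sum(gt$particles$birth_frame <= t & gt$particles$death_frame >= t)
  }, numeric(1))
  expect_lt(abs(mean(occ) - 1.0 * mean_frames) / (1.0 * mean_frames), 0.25)
})

test_that("dwell truncation at the movie end is recorded, not resampled", {
  p <- sim_params(n_frames = 50, fov = c(24, 24), arrival_rate = 0.3,
                  dwell_law = list(type = "exponential", mean_s = 60),
                  bleach_rate = 0, seed = 31)
  set.seed(p$seed)
  gt <- smkymo:::draw_particles(p)
  expect_gt(nrow(gt$particles), 0)
  expect_true(all(gt$particles$death_frame <= 49))
  # with 60 s mean dwell in a 7.5 s movie nearly everything is truncated
  expect_gt(mean(gt$particles$right_censored), 0.8)
  expect_true(all(gt$particles$death_cause[gt$particles$right_censored] ==
                    "movie_end"))
})

test_that("bleaching deaths are distinguished from departures", {
  p <- sim_params(n_frames = 200, fov = c(24, 24), arrival_rate = 0.5,
                  dwell_law = list(type = "exponential", mean_s = 10),
                  bleach_rate = 0.2, n_initial = 0, seed = 13)
  set.seed(p$seed)
  gt <- smkymo:::draw_particles(p)
  causes <- table(gt$particles$death_cause)
  # at 0.2/frame bleaching dominates a 10 s dwell law
  expect_gt(causes[["bleach"]], causes[["departure"]])
})

test_that("two-channel partner assignment matches coloc_fraction", {
  base <- sim_params(n_frames = 60, fov = c(48, 48), arrival_rate = 2.5,
                     n_initial = 0, seed = 41)
  # coloc_fraction = 0: no links
  s0 <- simulate_two_channel(two_channel_params(base, coloc_fraction = 0))
  expect_true(all(is.na(s0$truth$particles$coloc_partner)))
  # coloc_fraction = 1, zero shift: each A path equals its partner's path
  s1 <- simulate_two_channel(two_channel_params(base, coloc_fraction = 1,
                                                channel_shift_px = c(0, 0)))
  pa <- s1$truth$particles[s1$truth$particles$channel == "A", ]
  expect_true(all(!is.na(pa$coloc_partner)))
  one <- pa[1, ]
  path_a <- s1$truth$positions[s1$truth$positions$id == one$id, ]
  path_b <- s1$truth$positions[s1$truth$positions$id == one$coloc_partner, ]
  expect_equal(path_a$x, path_b$x)
  expect_equal(path_a$y, path_b$y)
  # coloc_fraction = 0.6 at n ~ 200: within the binomial 99% CI
  s6 <- simulate_two_channel(two_channel_params(base, coloc_fraction = 0.6))
  pa6 <- s6$truth$particles[s6$truth$particles$channel == "A", ]
  n <- nrow(pa6)
  expect_gt(n, 120)
  phat <- mean(!is.na(pa6$coloc_partner))
  half <- qnorm(0.995) * sqrt(0.6 * 0.4 / n)
  expect_lt(abs(phat - 0.6), half)
})

test_that("the channel shift displaces B ground truth by exactly (dx, dy)", {
  base <- sim_params(n_frames = 30, fov = c(48, 48), arrival_rate = 1,
                     n_initial = 0, seed = 51)
  sh <- c(2.5, -1.25)
  s <- simulate_two_channel(two_channel_params(base, coloc_fraction = 1,
                                               channel_shift_px = sh))
  pa <- s$truth$particles[s$truth$particles$channel == "A", ]
  for (i in seq_len(min(5, nrow(pa)))) {
    path_a <- s$truth$positions[s$truth$positions$id == pa$id[i], ]
    path_b <- s$truth$positions[s$truth$positions$id == pa$coloc_partner[i], ]
    expect_equal(path_b$x, path_a$x + sh[1])
    expect_equal(path_b$y, path_a$y + sh[2])
  }
})

test_that("fov too small for the PSF support is a parameter error", {
  expect_error(sim_params(fov = c(5, 5), psf_sigma_px = 2), "fov too small")
})

test_that("ground-truth CSV export writes both tables", {
  sim <- simulate_movie(sim_params(n_frames = 10, fov = c(24, 24),
                                   arrival_rate = 0.5, seed = 3))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, f1, f2)
  p <- read.csv(f1)
  expect_equal(nrow(p), nrow(sim$truth$particles))
  expect_true(all(c("id", "birth_frame", "death_frame", "true_dwell_s") %in%
                    names(p)))
})
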