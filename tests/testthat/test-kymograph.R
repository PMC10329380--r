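test_that("sample_line follows the unit-spacing endpoint rule", {
  # horizontal integer line
  p <- sample_line(scan_line(0, 0, 4, 0, 1))
  expect_equal(p$x, 0:4)
  expect_equal(p$y, rep(0, 5))
  # 3-4-5 diagonal: length 5 -> 6 points spaced exactly 1
  p <- sample_line(scan_line(0, 0, 3, 4, 1))
  expect_equal(nrow(p), 6L)
  sp <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  expect_equal(sp, rep(1, 5))
  # fractional endpoint: floor rule
  p <- sample_line(scan_line(0, 0, 2.5, 0, 1))
  expect_equal(p$x, 0:2)
  expect_error(scan_line(3, 3, 3, 3), "zero-length")
})

test_that("even linewidths are rejected, odd accepted", {
  expect_error(scan_line(0, 0, 5, 0, 4), "odd")
  expect_error(scan_line(0, 0, 5, 0, 0), "odd")
  expect_silent(scan_line(0, 0, 5, 0, 11))
})

test_that("a time-ramp stack gives constant kymograph rows equal to t", {
  arr <- array(0, c(16, 16, 5))
  for (t in 1:5) arr[, , t] <- t - 1
  st <- image_stack(arr, 0.15, 0.1)
  ky <- extract_kymograph(st, scan_line(2, 8, 12, 8, 1))
  for (t in 1:5) expect_equal(ky$matrix[t, ], rep(t - 1, 11))
})

test_that("extract_kymograph matches the brute-force oracle", {
  st <- random_stack(t = 10L, h = 32L, w = 32L, seed = 6)
  cases <- list(
    list(x0 = 3, y0 = 7, x1 = 27, y1 = 7),     # axis-aligned
    list(x0 = 6, y0 = 6, x1 = 25, y1 = 23),    # oblique
    list(x0 = 8.5, y0 = 20.2, x1 = 24.1, y1 = 9.7)  # fractional endpoints
  )
  for (cs in cases) {
    for (lw in c(1L, 3L, 11L)) {
      for (red in c("max", "mean")) {
        ky <- extract_kymograph(st, scan_line(cs$x0, cs$y0, cs$x1, cs$y1, lw),
                                red)
        K0 <- brute_force_kymograph(st, cs$x0, cs$y0, cs$x1, cs$y1, lw, red)
        expect_lt(max(abs(ky$matrix - K0)), 1e-9)
      }
    }
  }
  # linewidth 1 on an axis-aligned integer line is an exact pixel read
  ky <- extract_kymograph(st, scan_line(3, 7, 27, 7, 1), "max")
  expect_identical(ky$matrix[4, 5], as.numeric(st$pixels[8, 8, 4]))
})

test_that("out-of-bounds lines are geometry errors", {
  st <- random_stack(t = 3L, h = 16L, w = 16L)
  expect_error(extract_kymograph(st, scan_line(0, 1, 15, 1, 11)), "bounds")
  expect_error(extract_kymograph(st, scan_line(-2, 8, 10, 8, 1)), "bounds")
})

test_that("segment detection reproduces run-length structure with gap bridging", {
  # synthetic kymograph: one bright column with runs 5-9 and 12-20 (0-based)
  K <- matrix(0, 30, 9)
  K[c(6:10, 13:21), 5] <- 100
  ky <- structure(list(matrix = K, positions = data.frame(x = 0:8, y = 0),
                       reduction = "max", linewidth = 1L,
                       frame_interval_s = 0.15), class = "Kymograph")
  s0 <- detect_segments(ky, max_gap_frames = 0L)
  expect_equal(nrow(s0), 2L)
  expect_equal(s0$start_frame, c(5L, 12L))
  expect_equal(s0$end_frame, c(9L, 20L))
  s2 <- detect_segments(ky, max_gap_frames = 2L)
  expect_equal(nrow(s2), 1L)
  expect_equal(c(s2$start_frame, s2$end_frame), c(5L, 20L))
})

test_that("all-zero kymographs give no segments; saturated ones error", {
  kz <- structure(list(matrix = matrix(0, 20, 5),
                       positions = data.frame(x = 0:4, y = 0),
                       reduction = "max", linewidth = 1L,
                       frame_interval_s = 0.15), class = "Kymograph")
  expect_equal(nrow(detect_segments(kz)), 0L)
  ks <- kz; ks$matrix <- matrix(4095, 20, 5)
  expect_error(detect_segments(ks), "degenerate|saturated")
})

test_that("segments spanning the whole movie are censored at both ends", {
  K <- matrix(0, 200, 5)
  K[, 3] <- 100
  K <- K + matrix(rexp(1000, 2), 200, 5)  # background texture so MAD > 0
  ky <- structure(list(matrix = K, positions = data.frame(x = 0:4, y = 0),
                       reduction = "max", linewidth = 1L,
                       frame_interval_s = 0.15), class = "Kymograph")
  s <- detect_segments(ky)
  expect_equal(nrow(s), 1L)
  expect_true(s$censored_left)
  expect_true(s$censored_right)
  expect_true(is.na(s$dwell_s))
})

test_that("dwell arithmetic counts frames inclusively", {
  segs <- data.frame(start_frame = c(10L, 42L, 0L),
                     end_frame = c(29L, 42L, 199L),
                     censored_left = c(FALSE, FALSE, TRUE),
                     censored_right = c(FALSE, FALSE, TRUE))
  expect_equal(measure_dwell(segs[1, ], 0.15), 3.0)   # 20 frames x 0.15 s
  expect_equal(measure_dwell(segs[2, ], 0.1), 0.1)    # single frame
  expect_true(is.na(measure_dwell(segs[3, ], 0.15)))  # overlength: censored
})

test_that("a single supported segment validates; noise segments do not", {
  st <- camera_noise(noiseless_stack(list(list(x = 20, y = 20, birth = 4,
                                               death = 14, photons = 1000)),
                                     t = 20L), seed = 1)
  tr <- link_trajectories(detect_movie(st))
  ky <- extract_kymograph(st, scan_line(17, 20, 23, 20, 11))
  segs <- validate_segments(detect_segments(ky), ky, tr)
  v <- segs[segs$status == "validated", ]
  expect_equal(nrow(v), 1L)
  expect_lte(abs(v$start_frame - 4), 2)
  expect_lte(abs(v$end_frame - 14), 2)
  # a segment over empty space with no trajectory nearby is unsupported
  ky2 <- extract_kymograph(st, scan_line(30, 36, 36, 36, 11))
  fake <- data.frame(start_frame = 5L, end_frame = 12L, j_min = 0L,
                     j_max = 6L, censored_left = FALSE,
                     censored_right = FALSE, dwell_s = 1.2,
                     status = "candidate", reason = NA_character_)
  out <- validate_segments(fake, ky2, tr)
  expect_equal(out$status, "rejected")
  expect_equal(out$reason, "unsupported")
})

test_that("two particles fusing into one streak are rejected as merged", {
  # the classic artifact: particle 1 occupies the line, particle 2 arrives
  # at an overlapping time 4 px away; their kymograph runs fuse into one
  # long streak, but the trajectories prove there were two particles
  st <- camera_noise(noiseless_stack(
    list(list(x = 18, y = 20, birth = 2, death = 10, photons = 1000),
         list(x = 22, y = 20, birth = 8, death = 17, photons = 1000)),
    t = 20L), seed = 2)
  tr <- link_trajectories(detect_movie(st))
  expect_gte(nrow(trajectory_summary(tr)[trajectory_summary(tr)$n_locs > 2, ]), 2L)
  ky <- extract_kymograph(st, scan_line(15, 20, 25, 20, 11))
  segs <- detect_segments(ky)
  segs <- validate_segments(segs, ky, tr)
  main <- segs[which.max(segs$end_frame - segs$start_frame), ]
  expect_equal(main$start_frame, 2L)
  expect_equal(main$end_frame, 17L)
  expect_equal(main$status, "rejected")
  expect_equal(main$reason, "merged")
})

test_that("censored segments are rejected before any trajectory check", {
  fake <- data.frame(start_frame = 0L, end_frame = 19L, j_min = 0L,
                     j_max = 4L, censored_left = TRUE, censored_right = TRUE,
                     dwell_s = NA_real_, status = "candidate",
                     reason = NA_character_)
  ky <- structure(list(matrix = matrix(0, 20, 5),
                       positions = data.frame(x = 0:4, y = 0),
                       reduction = "max", linewidth = 1L,
                       frame_interval_s = 0.15), class = "Kymograph")
  out <- validate_segments(fake, ky, data.frame(traj_id = integer(),
                                                frame = integer(),
                                                x = numeric(), y = numeric()))
  expect_equal(out$reason, "censored")
})

test_that("render_views writes a kymograph image of the right size", {
  st <- random_stack(t = 8L, h = 24L, w = 24L, seed = 12)
  ky <- extract_kymograph(st, scan_line(4, 12, 19, 12, 3))
  pre <- file.path(withr::local_tempdir(), "v")
  files <- render_views(ky, st, pre)
  expect_length(files, 4L)
  img <- png::readPNG(paste0(pre, "_kymo.png"))
  expect_equal(dim(img), c(8, 16))         # T rows x L columns
  xy <- png::readPNG(paste0(pre, "_xy.png"))
  expect_equal(dim(xy), c(24, 24))
  # a 2 s span covers 2/dt kymograph rows
  expect_equal(2 / ky$frame_interval_s, 2 / 0.15)
})

test_that("projections of a single-particle movie show one streak per view", {
  st <- noiseless_stack(list(list(x = 12, y = 30, birth = 0, death = 7,
                                  photons = 1000)), t = 8L)
  pre <- file.path(withr::local_tempdir(), "p")
  render_views(NULL, st, pre)
  for (v in c("xy", "xt", "yt")) {
    img <- png::readPNG(paste0(pre, "_", v, ".png"))
    mask <- img > 0.5
    lab <- smkymo:::label_components(mask)
    expect_equal(max(lab), 1L)
  }
})

test_that("scan lines round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x0 = c(0, 5), y0 = c(1, 6), x1 = c(9, 5),
                       y1 = c(1, 15), linewidth = c(3L, 11L)),
            f, row.names = FALSE)
  lines <- read_scan_lines(f)
  expect_length(lines, 2L)
  expect_equal(lines[[1]]$linewidth, 3L)
  expect_equal(lines[[2]]$p1, c(5, 15))
})
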