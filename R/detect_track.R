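# Per-frame spot detection and frame-to-frame linking into 2D+t trajectories.
#
# Trajectories are the automated replacement for eyeballing a rotated 2D+t
# volume: every kymograph dwell segment is later cross-checked against them.

#' Detect diffraction-limited spots in one frame
#'
#' Band-passes the image with a scale-normalised Laplacian-of-Gaussian filter
#' at the PSF scale, takes strict 8-neighbour local maxima, keeps maxima
#' whose filter response exceeds `threshold_k` times the robust noise SD of
#' the filtered image (1.4826 x MAD), and refines each to sub-pixel by an
#' intensity-weighted centroid in a `(2 ceil(3 sigma) + 1)^2` window on the
#' locally background-subtracted image.
#'
#' @param frame_image 2D numeric matrix (one movie frame).
#' @param psf_sigma_px expected spot SD in pixels (> 0).
#' @param threshold_k detection threshold in robust noise SDs (default 3).
#' @return data.frame with one row per spot: `x, y` (0-based sub-pixel
#'   coordinates), `intensity` (background-subtracted amplitude), `snr`, and
#'   `edge` (TRUE when the centroid window was clipped by the image border;
#'   such spots are retained but should not anchor sub-pixel accuracy
#'   claims). A blank or constant frame yields zero rows, not an error.
#' @export
detect_spots <- function(frame_image, psf_sigma_px = 1.0, threshold_k = 3) {
  stopifnot(is.matrix(frame_image))
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  h <- nrow(frame_image); w <- ncol(frame_image)
  empty <- data.frame(x = numeric(), y = numeric(), intensity = numeric(),
                      snr = numeric(), edge = logical())
  if (h < 3 || w < 3 || max(frame_image) == min(frame_image)) return(empty)
  resp <- conv2_replicate(frame_image, log_kernel(psf_sigma_px))
  noise_sd <- max(stats::mad(resp), 1e-12)
  thr <- threshold_k * noise_sd

  # strict local maxima over the 8-neighbourhood (border excluded)
  core <- resp[2:(h - 1), 2:(w - 1)]
  is_max <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (core > resp[(2 + di):(h - 1 + di), (2 + dj):(w - 1 + dj)])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  py <- idx[, 1] + 1L   # 1-based row in full image
  px <- idx[, 2] + 1L
  wr <- as.integer(ceiling(3 * psf_sigma_px))
  raw_noise <- max(stats::mad(frame_image), 1e-12)

  out <- lapply(seq_along(px), function(i) {
    rows <- max(1L, py[i] - wr):min(h, py[i] + wr)
    cols <- max(1L, px[i] - wr):min(w, px[i] + wr)
    edge <- length(rows) < 2L * wr + 1L || length(cols) < 2L * wr + 1L
    win <- frame_image[rows, cols, drop = FALSE]
    bg <- stats::median(win)
    wts <- pmax(win - bg, 0)
    s <- sum(wts)
    if (s <= 0) return(NULL)
    # 0-based centroid coordinates
    cy <- sum(rep(rows - 1L, times = ncol(win)) * wts) / s
    cx <- sum(rep(cols - 1L, each = nrow(win)) * wts) / s
    amp <- max(win) - bg
    data.frame(x = cx, y = cy, intensity = amp, snr = amp / raw_noise,
               edge = edge)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out[order(out$x, out$y), , drop = FALSE]
}

#' Detect spots in every frame of a stack
#'
#' @param stack an [image_stack()].
#' @param psf_sigma_px,threshold_k passed to [detect_spots()].
#' @param first_n_frames optionally restrict detection to the first n frames
#'   (a common convention for dynamics analysis); default all frames.
#' @return data.frame of localizations with a leading 0-based `frame` column.
#' @export
detect_movie <- function(stack, psf_sigma_px = 1.0, threshold_k = 3,
                         first_n_frames = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  Tn <- n_frames(stack)
  if (!is.null(first_n_frames)) Tn <- min(Tn, as.integer(first_n_frames))
  res <- lapply(seq_len(Tn), function(t1) {
    d <- detect_spots(stack$pixels[, , t1], psf_sigma_px, threshold_k)
    if (nrow(d) == 0L) return(NULL)
    cbind(frame = t1 - 1L, d)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      intensity = numeric(), snr = numeric(), edge = logical())
  }
  res
}

#' Link per-frame localizations into trajectories
#'
#' Greedy nearest-neighbour assignment: all candidate (trajectory, spot)
#' pairs within the displacement gate are sorted globally by distance (ties
#' broken by lower trajectory id, then spot order) and assigned greedily.
#' Unassigned spots seed new trajectories. A trajectory may bridge up to
#' `max_gap` missing frames when the reappearance lies within
#' `max_disp_px x (gap + 1)`. Input ordering of localizations within a frame
#' does not affect the result (localizations are canonically sorted first).
#'
#' @param locs data.frame of localizations as from [detect_movie()] (columns
#'   `frame, x, y`, optionally `intensity, snr, edge`).
#' @param max_disp_px maximum per-frame displacement gate, pixels (> 0).
#' @param max_gap maximum number of bridged missing frames (default 1).
#' @return data.frame `traj_id, frame, x, y, ...` sorted by (traj_id, frame);
#'   each localization belongs to exactly one trajectory.
#' @export
link_trajectories <- function(locs, max_disp_px = 3, max_gap = 1L) {
  if (!is.numeric(max_disp_px) || max_disp_px <= 0) {
    stop("max_disp_px must be > 0")
  }
  cols <- intersect(c("frame", "x", "y", "intensity", "snr", "edge"),
                    names(locs))
  locs <- locs[do.call(order, locs[c("frame", "x", "y")]), cols, drop = FALSE]
  n <- nrow(locs)
  traj_id <- integer(n)
  if (n == 0L) return(cbind(traj_id = integer(), locs))
  # per-trajectory tail state
  last_frame <- integer(0); last_x <- numeric(0); last_y <- numeric(0)
  next_id <- 1L
  rows_by_frame <- split(seq_len(n), locs$frame)
  frame_order <- order(as.integer(names(rows_by_frame)))
  for (fi in frame_order) {
    t <- as.integer(names(rows_by_frame))[fi]
    rows <- rows_by_frame[[fi]]
    live <- which(last_frame >= t - 1L - max_gap & last_frame < t)
    assigned_spot <- rep(FALSE, length(rows))
    if (length(live) > 0L) {
      gapf <- t - last_frame[live]                # gap + 1
      cand <- expand.grid(ti = seq_along(live), si = seq_along(rows))
      dx <- last_x[live][cand$ti] - locs$x[rows][cand$si]
      dy <- last_y[live][cand$ti] - locs$y[rows][cand$si]
      d <- sqrt(dx^2 + dy^2)
      ok <- d <= max_disp_px * gapf[cand$ti]
      cand <- cand[ok, , drop = FALSE]; d <- d[ok]
      if (nrow(cand) > 0L) {
        ord <- order(d, live[cand$ti], cand$si)
        used_traj <- rep(FALSE, length(live))
        for (k in ord) {
          ti <- cand$ti[k]; si <- cand$si[k]
          if (used_traj[ti] || assigned_spot[si]) next
          used_traj[ti] <- TRUE; assigned_spot[si] <- TRUE
          id <- live[ti]
          traj_id[rows[si]] <- id
          last_frame[id] <- t
          last_x[id] <- locs$x[rows[si]]
          last_y[id] <- locs$y[rows[si]]
        }
      }
    }
    for (si in which(!assigned_spot)) {
      traj_id[rows[si]] <- next_id
      last_frame[next_id] <- t
      last_x[next_id] <- locs$x[rows[si]]
      last_y[next_id] <- locs$y[rows[si]]
      next_id <- next_id + 1L
    }
  }
  out <- cbind(traj_id = traj_id, locs)
  out[order(out$traj_id, out$frame), , drop = FALSE]
}

#' Summarise trajectories
#'
#' @param trajs tidy trajectory table from [link_trajectories()].
#' @param frame_interval_s frame interval, seconds, for durations.
#' @return one row per trajectory: `traj_id, n_locs, start_frame, end_frame,
#'   duration_s, x_med, y_med` (time-median position).
#' @export
trajectory_summary <- function(trajs, frame_interval_s = NA_real_) {
  if (nrow(trajs) == 0L) {
    return(data.frame(traj_id = integer(), n_locs = integer(),
                      start_frame = integer(), end_frame = integer(),
                      duration_s = numeric(), x_med = numeric(),
                      y_med = numeric()))
  }
  idx <- split(seq_len(nrow(trajs)), trajs$traj_id)
  ids <- as.integer(names(idx))
  start <- vapply(idx, function(i) min(trajs$frame[i]), numeric(1))
  end <- vapply(idx, function(i) max(trajs$frame[i]), numeric(1))
  out <- data.frame(
    traj_id = ids,
    n_locs = lengths(idx),
    start_frame = as.integer(start),
    end_frame = as.integer(end),
    duration_s = (end - start + 1) * frame_interval_s,
    x_med = vapply(idx, function(i) stats::median(trajs$x[i]), numeric(1)),
    y_med = vapply(idx, function(i) stats::median(trajs$y[i]), numeric(1))
  )
  rownames(out) <- NULL
  out[order(out$traj_id), , drop = FALSE]
}

#' Match trajectories to ground-truth particles
#'
#' For each trajectory, finds the simulated particle minimising the mean
#' distance over co-occurring frames; matches beyond `max_dist_px` are
#' dropped. Used in parameter-recovery analyses.
#'
#' @param trajs tidy trajectory table.
#' @param truth GroundTruth list from the simulator.
#' @param max_dist_px maximum acceptable mean distance, pixels.
#' @return data.frame `traj_id, particle_id, mean_dist_px, n_common`.
#' @export
match_trajectories_to_truth <- function(trajs, truth, max_dist_px = 2) {
  if (nrow(trajs) == 0L) {
    return(data.frame(traj_id = integer(), particle_id = integer(),
                      mean_dist_px = numeric(), n_common = integer()))
  }
  m <- merge(trajs, truth$positions, by = "frame",
             suffixes = c("_t", "_g"))
  if (nrow(m) == 0L) {
    return(data.frame(traj_id = integer(), particle_id = integer(),
                      mean_dist_px = numeric(), n_common = integer()))
  }
  m$d <- sqrt((m$x_t - m$x_g)^2 + (m$y_t - m$y_g)^2)
  agg <- stats::aggregate(d ~ traj_id + id, data = m,
                          FUN = function(z) c(mean(z), length(z)))
  res <- data.frame(traj_id = agg$traj_id, particle_id = agg$id,
                    mean_dist_px = agg$d[, 1], n_common = as.integer(agg$d[, 2]))
  res <- res[order(res$traj_id, res$mean_dist_px), , drop = FALSE]
  res <- res[!duplicated(res$traj_id), , drop = FALSE]
  res[res$mean_dist_px <= max_dist_px, , drop = FALSE]
}

#' Write localizations/trajectories to CSV
#'
#' @param trajs tidy trajectory table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  utils::write.csv(trajs, path, row.names = FALSE)
  invisible(path)
}
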