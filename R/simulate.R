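# Synthetic VA-TIRFM movie generator with full per-particle ground truth.
#
# The generator emulates the acquisition regime used for plasma-membrane
# single-particle imaging: short (~30 s) movies of 200 frames at 150 ms,
# diffraction-limited Gaussian spots, stochastic particle arrival, an
# exponential membrane dwell, slow 2D diffusion, Poisson shot noise, camera
# read noise and photobleaching. Every analysis stage in the package is
# validated against the ground truth these functions emit.

#' Simulation parameters
#'
#' Defaults describe a 200-frame, 150-ms-exposure movie (30 s total) of
#' nearly immobile membrane-resident particles, the regime in which kymograph
#' dwell analysis is applicable.
#'
#' @param n_frames number of frames (default 200).
#' @param frame_interval_s frame interval in seconds (default 0.15).
#' @param fov field of view, `c(H, W)` pixels.
#' @param pixel_size_um pixel size, micrometers.
#' @param arrival_rate expected new particle arrivals per frame (Poisson).
#' @param dwell_law membrane dwell-time law: `list(type = "exponential",
#'   mean_s = ...)` or `list(type = "fixed", value_s = ...)`.
#' @param n_initial number of particles already resident at frame 0, or
#'   `"steady"` (default) to draw Poisson(arrival_rate x mean dwell in
#'   frames), the stationary occupancy. Pre-existing particles arrived before
#'   recording started, so their traces touch frame 0 and are left-censored —
#'   the behaviour characteristic of stable raft-resident proteins.
#' @param diffusion_coeff lateral diffusion coefficient, um^2/s (0 =
#'   immobile; default 0.005, a pit/raft-confined particle).
#' @param psf_sigma_px Gaussian PSF standard deviation, pixels.
#' @param photons_per_frame expected signal photons per particle per frame.
#' @param background mean background level, counts per pixel.
#' @param read_noise_sd Gaussian camera read-noise SD, counts.
#' @param bleach_rate per-frame photobleaching probability.
#' @param seed RNG seed; identical seeds give bit-identical movies.
#' @return a `SimParams` list.
#' @export
sim_params <- function(n_frames = 200L, frame_interval_s = 0.15,
                       fov = c(96L, 96L), pixel_size_um = 0.1,
                       arrival_rate = 0.3,
                       dwell_law = list(type = "exponential", mean_s = 3.8),
                       n_initial = "steady",
                       diffusion_coeff = 0.005, psf_sigma_px = 1.0,
                       photons_per_frame = 500, background = 20,
                       read_noise_sd = 2, bleach_rate = 0.002,
                       seed = 1L) {
  p <- list(n_frames = as.integer(n_frames),
            frame_interval_s = frame_interval_s, fov = as.integer(fov),
            pixel_size_um = pixel_size_um, arrival_rate = arrival_rate,
            dwell_law = dwell_law, n_initial = n_initial,
            diffusion_coeff = diffusion_coeff, psf_sigma_px = psf_sigma_px,
            photons_per_frame = photons_per_frame, background = background,
            read_noise_sd = read_noise_sd, bleach_rate = bleach_rate,
            seed = as.integer(seed))
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (p$n_frames < 1L) stop("n_frames must be >= 1")
  if (p$frame_interval_s <= 0 || p$pixel_size_um <= 0) {
    stop("frame_interval_s and pixel_size_um must be positive")
  }
  if (p$psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  rates <- c(p$arrival_rate, p$diffusion_coeff, p$photons_per_frame,
             p$background, p$read_noise_sd, p$bleach_rate)
  if (any(rates < 0)) stop("rates and noise SDs must be non-negative")
  if (p$bleach_rate > 1) stop("bleach_rate is a per-frame probability")
  pad <- ceiling(3 * p$psf_sigma_px)
  if (any(p$fov < 2 * pad + 3)) {
    stop("fov too small to contain the PSF support")
  }
  invisible(p)
}

mean_dwell_frames <- function(p) {
  switch(p$dwell_law$type,
         exponential = p$dwell_law$mean_s / p$frame_interval_s,
         fixed = p$dwell_law$value_s / p$frame_interval_s,
         stop("unknown dwell law: ", p$dwell_law$type))
}

draw_dwell_s <- function(n, law) {
  switch(law$type,
         exponential = stats::rexp(n, rate = 1 / law$mean_s),
         fixed = rep(law$value_s, n),
         stop("unknown dwell law: ", law$type))
}

# Build the particle table (births, scheduled deaths, bleaching, censoring)
# and per-frame Brownian paths. Shared by single- and two-channel movies.
draw_particles <- function(p, id_offset = 0L, channel = "A") {
  Tn <- p$n_frames
  n_init <- if (identical(p$n_initial, "steady")) {
    stats::rpois(1L, p$arrival_rate * mean_dwell_frames(p))
  } else as.integer(p$n_initial)
  arrivals <- stats::rpois(Tn, p$arrival_rate)
  birth <- c(rep(0L, n_init), rep(seq_len(Tn) - 1L, arrivals))
  pre_existing <- c(rep(TRUE, n_init), rep(FALSE, sum(arrivals)))
  n <- length(birth)
  if (n == 0L) {
    return(list(
      particles = data.frame(
        id = integer(), channel = character(), birth_frame = integer(),
        death_frame = integer(), death_cause = character(),
        pre_existing = logical(), right_censored = logical(),
        dwell_frames = integer(), true_dwell_s = numeric(),
        coloc_partner = integer()),
      positions = data.frame(id = integer(), frame = integer(),
                             x = numeric(), y = numeric())
    ))
  }
  # residual dwell for pre-existing particles: exponential is memoryless so
  # the same law applies; a fixed law gives the full value from frame 0
  dwell_s <- draw_dwell_s(n, p$dwell_law)
  dwell_frames_sched <- pmax(1L, as.integer(ceiling(dwell_s / p$frame_interval_s)))
  death_sched <- birth + dwell_frames_sched - 1L
  if (p$bleach_rate > 0) {
    bleach_after <- stats::rgeom(n, p$bleach_rate) # frames survived before bleach
    death_bleach <- birth + bleach_after
  } else {
    death_bleach <- rep(.Machine$integer.max, n)
  }
  death <- pmin(death_sched, death_bleach, Tn - 1L)
  cause <- ifelse(death == death_sched, "departure",
                  ifelse(death == death_bleach, "bleach", "movie_end"))
  # a scheduled death truncated by the movie end is right-censored
  cause[death == Tn - 1L & death_sched > Tn - 1L & death_bleach > Tn - 1L] <- "movie_end"
  right_censored <- cause == "movie_end"

  pad <- ceiling(3 * p$psf_sigma_px)
  H <- p$fov[1]; W <- p$fov[2]
  x0 <- stats::runif(n, pad, W - 1 - pad)
  y0 <- stats::runif(n, pad, H - 1 - pad)
  step_sd_px <- sqrt(2 * p$diffusion_coeff * p$frame_interval_s) / p$pixel_size_um

  nframes_alive <- death - birth + 1L
  ids <- id_offset + seq_len(n)
  pos <- vector("list", n)
  for (i in seq_len(n)) {
    k <- nframes_alive[i]
    if (step_sd_px > 0 && k > 1L) {
      xs <- x0[i] + cumsum(c(0, stats::rnorm(k - 1L, 0, step_sd_px)))
      ys <- y0[i] + cumsum(c(0, stats::rnorm(k - 1L, 0, step_sd_px)))
    } else {
      xs <- rep(x0[i], k); ys <- rep(y0[i], k)
    }
    pos[[i]] <- data.frame(id = ids[i], frame = birth[i] + seq_len(k) - 1L,
                           x = xs, y = ys)
  }
  list(
    particles = data.frame(
      id = ids, channel = channel, birth_frame = birth, death_frame = death,
      death_cause = cause, pre_existing = pre_existing,
      right_censored = right_censored, dwell_frames = nframes_alive,
      true_dwell_s = nframes_alive * p$frame_interval_s,
      coloc_partner = NA_integer_),
    positions = do.call(rbind, pos)
  )
}

# Render expected photon maps frame by frame and apply the noise model:
# pixel ~ Poisson(signal + background) + N(0, read_noise_sd), rounded and
# clamped at 0 (integer camera counts). The Gaussian PSF is integrated over
# pixel bounds (difference of normal CDFs), not sampled at pixel centers.
render_movie <- function(positions, p, shift = c(0, 0)) {
  H <- p$fov[1]; W <- p$fov[2]; Tn <- p$n_frames
  r <- ceiling(4 * p$psf_sigma_px)
  px <- array(0, c(H, W, Tn))
  if (nrow(positions) > 0) {
    positions <- positions[order(positions$frame, positions$id), , drop = FALSE]
    split_frames <- split(seq_len(nrow(positions)), positions$frame)
    for (fr_name in names(split_frames)) {
      t <- as.integer(fr_name)
      idx <- split_frames[[fr_name]]
      sig <- matrix(0, H, W)
      for (i in idx) {
        mx <- positions$x[i] + shift[1]
        my <- positions$y[i] + shift[2]
        x_lo <- max(0, floor(mx) - r); x_hi <- min(W - 1, ceiling(mx) + r)
        y_lo <- max(0, floor(my) - r); y_hi <- min(H - 1, ceiling(my) + r)
        if (x_lo > x_hi || y_lo > y_hi) next   # wandered outside the FOV
        cx <- x_lo:x_hi
        cy <- y_lo:y_hi
        fx <- gauss_pixel_frac(cx, mx, p$psf_sigma_px)
        fy <- gauss_pixel_frac(cy, my, p$psf_sigma_px)
        sig[cy + 1L, cx + 1L] <- sig[cy + 1L, cx + 1L] +
          p$photons_per_frame * outer(fy, fx)
      }
      px[, , t + 1L] <- sig
    }
  }
  lam <- px + p$background
  counts <- array(stats::rpois(length(lam), lam), dim(lam))
  if (p$read_noise_sd > 0) {
    counts <- counts + round(stats::rnorm(length(counts), 0, p$read_noise_sd))
  }
  counts[counts < 0] <- 0
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a single-channel VA-TIRFM movie
#'
#' Particles arrive Poisson per frame (plus a pre-existing population, see
#' [sim_params()]), draw a membrane dwell from the dwell law (truncated at
#' the movie end and recorded as right-censored, never resampled), follow 2D
#' Brownian motion with per-axis step variance `2 D dt`, and render as
#' pixel-integrated Gaussians with Poisson shot noise, Poisson background and
#' Gaussian read noise. Photobleaching terminates emission with the given
#' per-frame probability and is recorded as a distinct death cause, so
#' bleaching deaths can be separated from genuine membrane departures.
#'
#' @param params a [sim_params()] list.
#' @return `list(stack = ImageStack, truth = GroundTruth)` where the ground
#'   truth holds `$particles` (one row per particle: id, birth/death frame,
#'   death cause, censoring flags, dwell) and `$positions` (per-frame true
#'   sub-pixel positions).
#' @examples
#' sim <- simulate_movie(sim_params(n_frames = 20, fov = c(32, 32), seed = 7))
#' sim$stack
#' head(sim$truth$particles)
#' @export
simulate_movie <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  gt <- draw_particles(params)
  counts <- render_movie(gt$positions, params)
  stack <- image_stack(counts, params$frame_interval_s, params$pixel_size_um,
                       channel_label = "sim")
  list(stack = stack, truth = gt)
}

#' Two-channel simulation parameters
#'
#' @param base_a,base_b [sim_params()] for channels A and B. Channel B's
#'   independent (non-partner) population uses `base_b`; by default it
#'   shares channel A's geometry and acquisition settings with its own RNG
#'   seed.
#' @param coloc_fraction probability that an A-particle is assigned a
#'   B-partner sharing its exact path (Bernoulli per particle), in \[0, 1\].
#' @param channel_shift_px true `c(dx, dy)` chromatic/geometric misalignment
#'   applied to channel B at render time.
#' @return a `TwoChannelSimParams` list.
#' @export
two_channel_params <- function(base_a = sim_params(),
                               base_b = NULL,
                               coloc_fraction = 0.5,
                               channel_shift_px = c(0, 0)) {
  if (is.null(base_b)) {
    base_b <- base_a
    base_b$seed <- base_a$seed + 1L
  }
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    stop("coloc_fraction must be in [0, 1]")
  }
  list(base_a = base_a, base_b = base_b,
       coloc_fraction = coloc_fraction,
       channel_shift_px = as.numeric(channel_shift_px))
}

#' Simulate a two-channel movie with a known colocalised fraction
#'
#' Channel A is simulated as in [simulate_movie()]. A `coloc_fraction` of
#' A-particles receive a channel-B partner that reuses the A-path exactly
#' (co-moving pair); channel B additionally carries its own independent
#' particle population. Channel B is rendered after applying the true
#' chromatic shift `channel_shift_px`, and its ground-truth positions are
#' recorded in the shifted (channel-B) coordinate frame — registration is
#' the analysis step that undoes it.
#'
#' @param params a [two_channel_params()] list.
#' @return `list(stack_a, stack_b, truth)`; `truth$particles$coloc_partner`
#'   links partners by id in both directions.
#' @export
simulate_two_channel <- function(params) {
  pa <- params$base_a; pb <- params$base_b
  validate_sim_params(pa); validate_sim_params(pb)
  if (any(pa$fov != pb$fov) || pa$n_frames != pb$n_frames) {
    stop("channels must share fov and n_frames")
  }
  set.seed(pa$seed)
  gta <- draw_particles(pa, id_offset = 0L, channel = "A")
  na <- nrow(gta$particles)
  gtb <- draw_particles(pb, id_offset = na, channel = "B")
  shift <- params$channel_shift_px
  # partner assignment: Bernoulli(coloc_fraction) per A-particle; partners
  # reuse the A-path rather than being re-simulated
  has_partner <- if (na > 0) {
    stats::runif(na) < params$coloc_fraction
  } else logical(0)
  next_id <- na + nrow(gtb$particles)
  partner_particles <- NULL; partner_positions <- NULL
  if (any(has_partner)) {
    src <- gta$particles[has_partner, , drop = FALSE]
    pid <- next_id + seq_len(nrow(src))
    partner_particles <- src
    partner_particles$id <- pid
    partner_particles$channel <- "B"
    partner_particles$coloc_partner <- src$id
    gta$particles$coloc_partner[has_partner] <- pid
    pp <- gta$positions[gta$positions$id %in% src$id, , drop = FALSE]
    pp$id <- pid[match(pp$id, src$id)]
    # B ground truth lives in the shifted channel-B frame
    pp$x <- pp$x + shift[1]
    pp$y <- pp$y + shift[2]
    partner_positions <- pp
  }
  gtb$positions$x <- gtb$positions$x + shift[1]
  gtb$positions$y <- gtb$positions$y + shift[2]
  truth <- list(
    particles = rbind(gta$particles, gtb$particles, partner_particles),
    positions = rbind(gta$positions, gtb$positions, partner_positions)
  )
  counts_a <- render_movie(gta$positions, pa)
  pos_b <- rbind(gtb$positions, partner_positions)
  counts_b <- render_movie(pos_b, pb)
  list(
    stack_a = image_stack(counts_a, pa$frame_interval_s, pa$pixel_size_um, "A"),
    stack_b = image_stack(counts_b, pb$frame_interval_s, pb$pixel_size_um, "B"),
    truth = truth
  )
}

#' Ground-truth positions as trajectories
#'
#' Converts the simulator's per-frame true positions into the tidy trajectory
#' table produced by [link_trajectories()], for oracle comparisons and for
#' colocalization analyses that bypass detection.
#'
#' @param truth a GroundTruth list from the simulator.
#' @param channel optional channel filter ("A"/"B").
#' @return data.frame with columns `traj_id, frame, x, y`.
#' @export
truth_trajectories <- function(truth, channel = NULL) {
  pos <- truth$positions
  if (!is.null(channel)) {
    ids <- truth$particles$id[truth$particles$channel == channel]
    pos <- pos[pos$id %in% ids, , drop = FALSE]
  }
  data.frame(traj_id = pos$id, frame = pos$frame, x = pos$x, y = pos$y)
}

#' Export ground truth as CSV tables
#'
#' Writes one row per particle plus a per-frame positions table.
#'
#' @param truth GroundTruth list.
#' @param particles_path,positions_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_ground_truth <- function(truth, particles_path, positions_path) {
  utils::write.csv(truth$particles, particles_path, row.names = FALSE)
  utils::write.csv(truth$positions, positions_path, row.names = FALSE)
  invisible(c(particles_path, positions_path))
}
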