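# Kymograph extraction along scan lines, dwell-segment detection with
# censoring at the observation window, and trajectory-based validation.
#
# A kymograph is a T x L space-time image: one spatial axis along a scan
# line, one time axis. A membrane-resident particle appears as a horizontal
# streak whose length is its dwell time. Two failure modes drive the design:
# streaks touching the first/last frame ("overlength" traces) have unknown
# true duration and must be censored, and streaks formed by two distinct
# particles successively occupying the same line position masquerade as one
# long dwell and must be rejected. Both are handled explicitly; the second by
# cross-validating every segment against 2D+t trajectories.

#' Define a scan line
#'
#' @param x0,y0,x1,y1 endpoints, 0-based pixel coordinates.
#' @param linewidth width of the averaged band perpendicular to the line, in
#'   pixels; must be odd (11 is a good default for plant-cell particles).
#' @return a `ScanLine` list.
#' @export
scan_line <- function(x0, y0, x1, y1, linewidth = 11L) {
  if (x0 == x1 && y0 == y1) stop("zero-length scan line")
  linewidth <- as.integer(linewidth)
  if (linewidth < 1L || linewidth %% 2L == 0L) {
    stop("linewidth must be an odd positive integer (e.g. 11); got ",
         linewidth)
  }
  structure(list(p0 = c(x0, y0), p1 = c(x1, y1), linewidth = linewidth),
            class = "ScanLine")
}

#' Sample points along a scan line
#'
#' Unit-spaced points from `p0` towards `p1`, starting at `p0`:
#' `L = floor(|p1 - p0|) + 1` points, so the last point may fall short of
#' `p1` by a fraction of a pixel (the endpoint rule).
#'
#' @param line a [scan_line()].
#' @return data.frame `x, y` of L sample positions (0-based).
#' @export
sample_line <- function(line) {
  stopifnot(inherits(line, "ScanLine"))
  d <- line$p1 - line$p0
  len <- sqrt(sum(d^2))
  u <- d / len
  s <- 0:floor(len)
  data.frame(x = line$p0[1] + s * u[1], y = line$p0[2] + s * u[2])
}

#' Extract a kymograph along a scan line
#'
#' For each frame t and each of the L unit-spaced positions along the line,
#' intensity is sampled (bilinear interpolation) at `linewidth` points spaced
#' 1 px along the perpendicular through that position and reduced by `max`
#' (default) or `mean`; row t of the kymograph derives only from frame t.
#' Axis-aligned integer lines with linewidth 1 reduce to exact pixel reads.
#'
#' @param stack an [image_stack()].
#' @param line a [scan_line()]; the line expanded by its width must stay
#'   inside the image.
#' @param reduction `"max"` or `"mean"` across the width.
#' @return an object of class `Kymograph`: `matrix` (T x L), `positions`
#'   (the L line samples), `reduction`, `linewidth`, `frame_interval_s`.
#' @export
extract_kymograph <- function(stack, line, reduction = c("max", "mean")) {
  stopifnot(inherits(stack, "ImageStack"), inherits(line, "ScanLine"))
  reduction <- match.arg(reduction)
  pos <- sample_line(line)
  L <- nrow(pos)
  if (L < 2L) stop("scan line must sample at least 2 points")
  d <- line$p1 - line$p0
  u <- d / sqrt(sum(d^2))
  perp <- c(-u[2], u[1])
  half <- (line$linewidth - 1L) / 2L
  offs <- (-half):half
  # all sample coordinates: L positions x linewidth offsets
  sx <- outer(pos$x, offs * perp[1], `+`)
  sy <- outer(pos$y, offs * perp[2], `+`)
  dm <- dim(stack$pixels)
  if (any(sx < 0 | sx > dm[2] - 1 | sy < 0 | sy > dm[1] - 1)) {
    stop("scan line (expanded by linewidth) exceeds image bounds")
  }
  Tn <- dm[3]
  K <- matrix(0, Tn, L)
  red <- if (reduction == "max") {
    function(m) apply(m, 1, max)
  } else {
    function(m) rowMeans(m)
  }
  for (t in seq_len(Tn)) {
    vals <- matrix(bilinear_sample(stack$pixels[, , t], as.vector(sx),
                                   as.vector(sy)), L, line$linewidth)
    K[t, ] <- red(vals)
  }
  structure(list(matrix = K, positions = pos, reduction = reduction,
                 linewidth = line$linewidth,
                 frame_interval_s = stack$frame_interval_s, line = line),
            class = "Kymograph")
}

#' @export
print.Kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d frames x %d positions (%s over linewidth %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$reduction, x$linewidth))
  invisible(x)
}

# Robust background threshold for a kymograph matrix: median + k*MAD by
# default, Otsu (via EBImage) as alternative.
kymo_threshold <- function(K, method = "mad", k = 3) {
  if (method == "mad") {
    stats::median(K) + k * stats::mad(K)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("threshold_method 'otsu' requires the EBImage package")
    }
    rng <- range(K)
    EBImage::otsu(EBImage::Image((K - rng[1]) / max(rng[2] - rng[1], 1e-12))) *
      (rng[2] - rng[1]) + rng[1]
  }
}

# 8-connected component labelling of a logical mask by BFS; masks here are
# small (T x L), so plain R is adequate.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% h + 1L
      j <- (p - 1L) %/% h + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > h || jj < 1L || jj > w) next
        q <- (jj - 1L) * h + ii
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Detect dwell segments in a kymograph
#'
#' Binarizes the kymograph (default: median + k x MAD of the kymograph,
#' a robust background threshold; `"otsu"` as alternative), groups signal
#' pixels into 8-connected spatiotemporal components, merges components
#' whose spatial extents overlap and whose time runs are separated by at
#' most `max_gap_frames` (tolerating blinking), and reports each group's
#' time run as a dwell segment. Segments touching frame 0 or the last frame
#' are flagged `censored_left` / `censored_right`: their true duration
#' exceeds the observation window (the "overlength" case) and they never
#' contribute a dwell value.
#'
#' @param kymo a [extract_kymograph()] result.
#' @param threshold_method `"mad"` (default) or `"otsu"` (requires EBImage).
#' @param threshold_k multiplier on the MAD scale (default 3).
#' @param max_gap_frames bridge time gaps up to this many frames (default 1).
#' @param min_area_px discard connected components smaller than this many
#'   kymograph pixels (default 3): a real particle's PSF covers several
#'   samples along the line even in a single frame, whereas isolated
#'   above-threshold noise pixels do not.
#' @return data.frame, one row per segment: `start_frame, end_frame`
#'   (0-based, inclusive), `j_min, j_max` (spatial extent, 0-based indices
#'   along the line), `censored_left, censored_right`, `dwell_s` (NA when
#'   censored), `status` (`"candidate"` until validated), `reason`.
#' @export
detect_segments <- function(kymo, threshold_method = c("mad", "otsu"),
                            threshold_k = 3, max_gap_frames = 1L,
                            min_area_px = 3L) {
  stopifnot(inherits(kymo, "Kymograph"))
  threshold_method <- match.arg(threshold_method)
  K <- kymo$matrix
  if (max(K) == min(K) && max(K) > 0) {
    stop("degenerate threshold: kymograph is uniformly saturated")
  }
  thr <- kymo_threshold(K, threshold_method, threshold_k)
  mask <- K > thr
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      j_min = integer(), j_max = integer(),
                      censored_left = logical(), censored_right = logical(),
                      dwell_s = numeric(), status = character(),
                      reason = character())
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  comps <- lapply(seq_len(max(lab)), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    if (nrow(w) < min_area_px) return(NULL)
    c(t0 = min(w[, 1]) - 1L, t1 = max(w[, 1]) - 1L,
      j0 = min(w[, 2]) - 1L, j1 = max(w[, 2]) - 1L)
  })
  comps <- do.call(rbind, comps)
  if (is.null(comps)) return(empty)
  # bridge: merge components overlapping spatially with time gap <= max_gap
  repeat {
    merged <- FALSE
    n <- nrow(comps)
    if (n <= 1L) break
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        sp_overlap <- comps[a, "j0"] <= comps[b, "j1"] &&
          comps[b, "j0"] <= comps[a, "j1"]
        gap <- max(comps[a, "t0"], comps[b, "t0"]) -
          min(comps[a, "t1"], comps[b, "t1"]) - 1L
        if (sp_overlap && gap <= max_gap_frames) {
          comps[a, ] <- c(min(comps[a, "t0"], comps[b, "t0"]),
                          max(comps[a, "t1"], comps[b, "t1"]),
                          min(comps[a, "j0"], comps[b, "j0"]),
                          max(comps[a, "j1"], comps[b, "j1"]))
          comps <- comps[-b, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  Tn <- nrow(K)
  out <- data.frame(
    start_frame = as.integer(comps[, "t0"]),
    end_frame = as.integer(comps[, "t1"]),
    j_min = as.integer(comps[, "j0"]),
    j_max = as.integer(comps[, "j1"]),
    censored_left = comps[, "t0"] == 0L,
    censored_right = comps[, "t1"] == Tn - 1L
  )
  out$dwell_s <- ifelse(out$censored_left | out$censored_right, NA_real_,
                        (out$end_frame - out$start_frame + 1L) *
                          kymo$frame_interval_s)
  out$status <- "candidate"
  out$reason <- NA_character_
  out[order(out$start_frame, out$j_min), , drop = FALSE]
}

#' Dwell time of segments
#'
#' `(end - start + 1) x dt` for uncensored segments — a particle visible in
#' one frame dwelt at least one exposure. Censored segments (touching either
#' end of the movie) return `NA`: their duration is unknown and they are
#' excluded from dwell summaries rather than imputed, mirroring the practice
#' of abandoning overlength kymograph lines.
#'
#' @param segments data.frame from [detect_segments()].
#' @param frame_interval_s frame interval, seconds.
#' @return numeric vector of dwell times in seconds, `NA` where censored.
#' @export
measure_dwell <- function(segments, frame_interval_s) {
  ifelse(segments$censored_left | segments$censored_right, NA_real_,
         (segments$end_frame - segments$start_frame + 1L) * frame_interval_s)
}

#' Validate dwell segments against trajectories
#'
#' The scriptable replacement for manually rotating the 2D+t volume: a
#' segment is trusted only when the full spatiotemporal trajectories confirm
#' that exactly one particle produced it. Trajectories with a localization
#' within `match_radius_px` of the segment's scan-line footprint during its
#' time run are collected; exactly one supporter whose start/end agree with
#' the segment within `frame_tol` frames validates the segment. Two or more
#' distinct supporters mean two particles fused into one streak —
#' `rejected(merged)`. No supporter (or one that disagrees in extent) —
#' `rejected(unsupported)`. Censored segments are `rejected(censored)`
#' before any trajectory check.
#'
#' @param segments data.frame from [detect_segments()].
#' @param kymo the source [extract_kymograph()].
#' @param trajs tidy trajectory table from [link_trajectories()], computed
#'   on the same stack.
#' @param match_radius_px spatial match radius around the line footprint.
#' @param frame_tol endpoint agreement window in frames (default 2,
#'   tolerating sub-threshold first/last frames).
#' @param min_support_frames a trajectory counts as a supporter only when it
#'   has at least this many localizations near the footprint within the
#'   segment's run (default 2): a genuine co-occupying particle is present
#'   for many frames, whereas spurious single-frame detections are not.
#' @return `segments` with `status` (`"validated"`/`"rejected"`), `reason`
#'   (`merged`/`unsupported`/`censored` for rejections) and `support_traj`
#'   (the validating trajectory id, NA otherwise).
#' @export
validate_segments <- function(segments, kymo, trajs, match_radius_px = 3,
                              frame_tol = 2L, min_support_frames = 2L) {
  stopifnot(inherits(kymo, "Kymograph"))
  if (nrow(segments) == 0L) {
    segments$support_traj <- integer(0)
    return(segments)
  }
  segments$support_traj <- NA_integer_
  tsum <- trajectory_summary(trajs, kymo$frame_interval_s)
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    if (s$censored_left || s$censored_right) {
      segments$status[i] <- "rejected"
      segments$reason[i] <- "censored"
      next
    }
    foot <- kymo$positions[(s$j_min:s$j_max) + 1L, , drop = FALSE]
    # trajectories with any localization near the footprint during the run
    supporters <- integer(0)
    if (nrow(trajs) > 0L) {
      inwin <- trajs[trajs$frame >= s$start_frame - frame_tol &
                       trajs$frame <= s$end_frame + frame_tol, , drop = FALSE]
      if (nrow(inwin) > 0L) {
        # min distance from each localization to the footprint, vectorised
        d2 <- outer(inwin$x, foot$x, `-`)^2 + outer(inwin$y, foot$y, `-`)^2
        dmin2 <- d2[, 1]
        for (jc in seq_len(ncol(d2))[-1]) dmin2 <- pmin(dmin2, d2[, jc])
        dmin <- sqrt(dmin2)
        near <- inwin[dmin <= match_radius_px, , drop = FALSE]
        # supporters must overlap the segment's time run itself, for at
        # least min_support_frames frames
        near <- near[near$frame >= s$start_frame & near$frame <= s$end_frame, ,
                     drop = FALSE]
        if (nrow(near) > 0L) {
          tab <- table(near$traj_id)
          supporters <- as.integer(names(tab)[tab >= min_support_frames])
        }
      }
    }
    if (length(supporters) == 0L) {
      segments$status[i] <- "rejected"
      segments$reason[i] <- "unsupported"
    } else if (length(supporters) >= 2L) {
      segments$status[i] <- "rejected"
      segments$reason[i] <- "merged"
    } else {
      ts <- tsum[tsum$traj_id == supporters, ]
      if (abs(ts$start_frame - s$start_frame) <= frame_tol &&
          abs(ts$end_frame - s$end_frame) <= frame_tol) {
        segments$status[i] <- "validated"
        segments$reason[i] <- NA_character_
        segments$support_traj[i] <- supporters
      } else {
        segments$status[i] <- "rejected"
        segments$reason[i] <- "unsupported"
      }
    }
  }
  segments
}

#' Render a kymograph and orthogonal projections to image files
#'
#' Writes (a) the kymograph as a grayscale PNG (rows = time, annotated time
#' axis omitted from pixels; time spans `T x dt` seconds) and (b) three
#' maximum-intensity projections of the 2D+t volume (xy, xt, yt) — the
#' static, scriptable analogue of interactively rotating a 3D rendering.
#'
#' @param kymo a [extract_kymograph()] result, or NULL to skip.
#' @param stack an [image_stack()] or NULL to skip the projections.
#' @param prefix output path prefix; files `<prefix>_kymo.png`,
#'   `<prefix>_xy.png`, `<prefix>_xt.png`, `<prefix>_yt.png`.
#' @return character vector of files written, invisibly.
#' @export
render_views <- function(kymo = NULL, stack = NULL, prefix = "views") {
  norm01 <- function(m) {
    rng <- range(m)
    if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  }
  files <- character(0)
  if (!is.null(kymo)) {
    f <- paste0(prefix, "_kymo.png")
    png::writePNG(norm01(kymo$matrix), f)
    files <- c(files, f)
  }
  if (!is.null(stack)) {
    px <- stack$pixels
    proj <- list(
      xy = apply(px, c(1, 2), max),            # H x W
      xt = t(apply(px, c(2, 3), max)),         # T x W
      yt = t(apply(px, c(1, 3), max))          # T x H
    )
    for (nm in names(proj)) {
      f <- paste0(prefix, "_", nm, ".png")
      png::writePNG(norm01(proj[[nm]]), f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Read scan lines from a CSV file
#'
#' Expected columns: `x0, y0, x1, y1` and optionally `linewidth`
#' (ImageJ-style line ROI coordinates, 0-based).
#'
#' @param path CSV path.
#' @param default_linewidth used when the file has no linewidth column.
#' @return list of [scan_line()] objects.
#' @export
read_scan_lines <- function(path, default_linewidth = 11L) {
  d <- utils::read.csv(path)
  lapply(seq_len(nrow(d)), function(i) {
    lw <- if ("linewidth" %in% names(d)) d$linewidth[i] else default_linewidth
    scan_line(d$x0[i], d$y0[i], d$x1[i], d$y1[i], lw)
  })
}
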